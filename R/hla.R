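# HLA data model: haplotype frequency tables, random-mating population
# synthesis, serologic broad/split resolution and ET-style mismatch grading.

#' Loci carried by a haplotype
#'
#' Haplotypes span HLA-A, -B, -C, -DRB1 and -DQB1 (the loci used as epitope
#' peptide sources); serologic match grading uses only A, B and DRB1.
#'
#' @return character vector of locus names.
#' @export
hla_loci <- function() c("A", "B", "C", "DRB1", "DQB1")

# loci entering the A-B-DR match grade, with their serologic level
.grade_loci <- function() c(A = "broad", B = "broad", DRB1 = "split")

#' Construct a haplotype frequency table
#'
#' Rows with identical allele tuples are merged by summing their frequencies;
#' frequencies are then renormalized to sum to one (public frequency tables
#' rarely sum exactly to 1).
#'
#' @param df data.frame with one character column per locus in [hla_loci()]
#'   and a numeric `freq` column of positive frequencies.
#' @return a `haplotype_table`: a data.frame of unique haplotypes whose
#'   `freq` column sums to 1.
#' @export
haplotype_table <- function(df) {
  loci <- hla_loci()
  missing <- setdiff(c(loci, "freq"), names(df))
  if (length(missing))
    stop("haplotype table is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, c(loci, "freq")]
  if (!is.numeric(df$freq)) stop("'freq' must be numeric")
  if (any(!is.finite(df$freq)) || any(df$freq <= 0))
    stop("all haplotype frequencies must be positive and finite")
  for (l in loci) {
    df[[l]] <- as.character(df[[l]])
    if (any(is.na(df[[l]]) | !nzchar(df[[l]])))
      stop("locus ", l, " contains blank or missing allele codes; incomplete rows are rejected")
  }
  key <- do.call(paste, c(df[loci], sep = "\r"))
  if (anyDuplicated(key)) {
    freq <- tapply(df$freq, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$freq <- as.numeric(freq[match(do.call(paste, c(df[loci], sep = "\r")), names(freq))])
  }
  df$freq <- df$freq / sum(df$freq)
  rownames(df) <- NULL
  attr(df, "normalized") <- TRUE
  class(df) <- c("haplotype_table", "data.frame")
  df
}

#' Read a haplotype frequency table from a delimited file
#'
#' The file must have a header with one column per locus
#' (`A,B,C,DRB1,DQB1`) plus `freq`; the delimiter (comma or tab) is
#' auto-detected from the header line.
#'
#' @param path path to a CSV/TSV file.
#' @return a [haplotype_table()].
#' @export
read_haplotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  haplotype_table(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}

#' Write a haplotype table to CSV
#' @param table a [haplotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype frequency table: %d haplotypes over loci %s (freq sum %.9f)\n",
              nrow(x), paste(hla_loci(), collapse = "-"), sum(x$freq)))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Synthesize a virtual population by random mating
#'
#' Each individual is formed from two independent haplotype draws proportional
#' to the table frequencies (Hardy-Weinberg random mating). The population is
#' stored compactly as an n-by-2 matrix of haplotype indices into `table`;
#' use [genotype()] to extract an individual.
#'
#' @param table a normalized [haplotype_table()].
#' @param n number of individuals (>= 1).
#' @param seed integer seed; identical seed and table give a byte-identical
#'   population.
#' @return a `genotype_population` (list with the index matrix `haps` and the
#'   haplotype `table`).
#' @export
sample_population <- function(table, n, seed) {
  stopifnot(inherits(table, "haplotype_table"), n >= 1)
  if (nrow(table) == 0L) stop("empty haplotype table")
  set.seed(as.integer(seed))
  h1 <- sample.int(nrow(table), n, replace = TRUE, prob = table$freq)
  h2 <- sample.int(nrow(table), n, replace = TRUE, prob = table$freq)
  haps <- cbind(pmin(h1, h2), pmax(h1, h2))
  colnames(haps) <- c("h1", "h2")
  structure(list(haps = haps, table = table), class = "genotype_population")
}

#' @export
print.genotype_population <- function(x, ...) {
  cat(sprintf("Virtual population: %d genotypes drawn from %d haplotypes\n",
              nrow(x$haps), nrow(x$table)))
  invisible(x)
}

#' Number of individuals in a population
#' @param population a `genotype_population`.
#' @return integer count.
#' @export
population_size <- function(population) nrow(population$haps)

#' Extract one genotype from a population
#'
#' @param population a `genotype_population` from [sample_population()].
#' @param i individual index.
#' @return an `hla_genotype`: the unordered haplotype pair with its per-locus
#'   allele pairs.
#' @export
genotype <- function(population, i) {
  stopifnot(i >= 1, i <= nrow(population$haps))
  h <- population$haps[i, ]
  alleles <- lapply(hla_loci(), function(l)
    as.character(population$table[[l]][h]))
  names(alleles) <- hla_loci()
  structure(list(alleles = alleles, hap = as.integer(h)),
            class = "hla_genotype")
}

#' Build a genotype directly from allele codes
#'
#' Mainly for toy examples and tests; simulator-scale genotypes come from
#' [sample_population()].
#'
#' @param alleles named list, one character vector of 1 or 2 allele codes per
#'   locus (1 means homozygous).
#' @return an `hla_genotype`.
#' @export
genotype_from_alleles <- function(alleles) {
  stopifnot(is.list(alleles), all(nzchar(names(alleles))))
  alleles <- lapply(alleles, function(a) {
    a <- as.character(a)
    if (length(a) == 1L) a <- c(a, a)
    if (length(a) != 2L) stop("each locus needs 1 or 2 allele codes")
    sort(a)
  })
  structure(list(alleles = alleles, hap = NULL), class = "hla_genotype")
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat("HLA genotype:",
      paste(vapply(names(x$alleles), function(l)
        paste0(l, "[", paste(x$alleles[[l]], collapse = ","), "]"),
        character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Construct a serology map
#'
#' Maps allele codes to their serologic broad and split antigens per locus.
#' A split may equal its broad (no serologic split defined).
#'
#' @param df data.frame with character columns `locus`, `allele`, `broad`,
#'   `split`.
#' @return a `serology_map`.
#' @export
serology_map <- function(df) {
  need <- c("locus", "allele", "broad", "split")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("serology map is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (cn in need) df[[cn]] <- as.character(df[[cn]])
  if (any(!nzchar(df$broad)) || any(!nzchar(df$split)))
    stop("blank broad/split entries in serology map")
  key <- paste(df$locus, df$allele, sep = "|")
  if (anyDuplicated(key)) stop("duplicate locus/allele rows in serology map")
  lk <- new.env(parent = emptyenv(), size = nrow(df) * 2L)
  for (i in seq_len(nrow(df)))
    assign(key[i], c(broad = df$broad[i], split = df$split[i]), envir = lk)
  structure(list(table = df, lookup = lk), class = "serology_map")
}

#' Read a serology map from CSV (`locus,allele,broad,split`)
#' @param path CSV path.
#' @return a [serology_map()].
#' @export
read_serology_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  serology_map(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a serology map to CSV
#' @param serology a [serology_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_serology_map <- function(serology, path) {
  utils::write.csv(serology$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.serology_map <- function(x, ...) {
  cat(sprintf("Serology map: %d alleles over loci %s\n", nrow(x$table),
              paste(sort(unique(x$table$locus)), collapse = ", ")))
  invisible(x)
}

# internal: resolve one allele to c(broad, split); error names the allele
.resolve_allele <- function(serology, locus, allele) {
  v <- get0(paste(locus, allele, sep = "|"), envir = serology$lookup,
            inherits = FALSE)
  if (is.null(v))
    stop(sprintf("allele '%s' at locus %s is not resolvable in the serology map",
                 allele, locus))
  v
}

#' Serologic antigen set of a genotype at one locus
#'
#' Returns the set of distinct antigens displayed: two for a heterozygote
#' whose alleles resolve to different antigens, one for homozygotes or when
#' both alleles collapse to the same broad.
#'
#' @param genotype an `hla_genotype`.
#' @param locus locus name.
#' @param level `"broad"` or `"split"`.
#' @param serology a [serology_map()].
#' @return character vector of 1 or 2 antigens.
#' @export
antigen_set <- function(genotype, locus, level = c("broad", "split"), serology) {
  level <- match.arg(level)
  al <- genotype$alleles[[locus]]
  if (is.null(al)) stop("genotype has no locus ", locus)
  unique(vapply(al, function(a) .resolve_allele(serology, locus, a)[[level]],
                character(1), USE.NAMES = FALSE))
}

#' ET-style HLA-A, -B, -DR mismatch grade
#'
#' Donor-relative serologic set difference: per locus, the number of donor
#' antigens absent from the recipient's antigen set, with A and B compared at
#' broad and DR at split level. A homozygous donor displays a single antigen
#' per locus, so it can be 0-mismatched to a heterozygous recipient carrying
#' that antigen.
#'
#' @param donor,recipient `hla_genotype` objects.
#' @param serology a [serology_map()].
#' @return named integer vector `c(A=, B=, DR=)`, each in 0..2.
#' @export
mismatch_grade <- function(donor, recipient, serology) {
  lv <- .grade_loci()
  mm <- vapply(names(lv), function(l) {
    d <- antigen_set(donor, l, lv[[l]], serology)
    r <- antigen_set(recipient, l, lv[[l]], serology)
    length(setdiff(d, r))
  }, integer(1))
  names(mm) <- c("A", "B", "DR")
  mm
}

#' Is a donor-recipient pair a full-house HLA match?
#'
#' True iff the A-B-DR mismatch grade is (0,0,0); full-house pairs are
#' prioritized above all point scores in ETKAS.
#'
#' @inheritParams mismatch_grade
#' @return logical flag.
#' @export
is_full_house <- function(donor, recipient, serology) {
  sum(mismatch_grade(donor, recipient, serology)) == 0L
}

#' Number of homozygous match-relevant loci
#'
#' Counts the loci among A (broad), B (broad) and DR (split) at which the
#' genotype displays a single antigen.
#'
#' @param genotype an `hla_genotype`.
#' @param serology a [serology_map()].
#' @return integer in 0..3.
#' @export
homozygosity_count <- function(genotype, serology) {
  lv <- .grade_loci()
  sum(vapply(names(lv), function(l)
    length(antigen_set(genotype, l, lv[[l]], serology)) == 1L, logical(1)))
}
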