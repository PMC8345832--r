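# Eplet tables, eplet mismatching, eplet population frequencies, and
# virtual-PRA sensitization (unacceptable-antigen assignment).

#' Construct an eplet table
#'
#' An eplet is a small polymorphic patch shared by a set of alleles; the
#' table records which alleles carry which eplet (long format, one row per
#' eplet-allele incidence), mirroring antibody-epitope registries.
#'
#' @param df data.frame with character columns `eplet` and `allele`; an
#'   optional numeric `weight` column carries immunogenicity weights used by
#'   the surrogate epitope scorer (default weight 1).
#' @return an `eplet_table` with the incidence data.frame, the eplet name
#'   vector and per-eplet weights.
#' @export
eplet_table <- function(df) {
  missing <- setdiff(c("eplet", "allele"), names(df))
  if (length(missing))
    stop("eplet table is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)
  df$eplet <- as.character(df$eplet)
  df$allele <- as.character(df$allele)
  if (any(!nzchar(df$eplet)) || any(!nzchar(df$allele)))
    stop("blank eplet or allele entries")
  df <- df[!duplicated(paste(df$eplet, df$allele, sep = "|")), , drop = FALSE]
  eplets <- sort(unique(df$eplet))
  if (!is.null(df$weight)) {
    w <- tapply(as.numeric(df$weight), df$eplet, function(x) x[1L])[eplets]
    w <- as.numeric(w)
    if (any(!is.finite(w)) || any(w < 0)) stop("eplet weights must be nonnegative")
  } else {
    w <- rep(1, length(eplets))
  }
  names(w) <- eplets
  by_allele <- split(df$eplet, df$allele)
  structure(list(incidence = df[, c("eplet", "allele")], eplets = eplets,
                 weights = w, by_allele = by_allele),
            class = "eplet_table")
}

#' Read an eplet table from CSV (`eplet,allele[,weight]`)
#' @param path CSV path.
#' @return an [eplet_table()].
#' @export
read_eplet_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  eplet_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an eplet table to CSV
#' @param table an [eplet_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eplet_table <- function(table, path) {
  df <- table$incidence
  df$weight <- as.numeric(table$weights[df$eplet])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.eplet_table <- function(x, ...) {
  cat(sprintf("Eplet table: %d eplets over %d alleles (%d incidences)\n",
              length(x$eplets), length(x$by_allele), nrow(x$incidence)))
  invisible(x)
}

#' Eplet repertoire of a genotype
#'
#' Union of the eplets carried by any of the genotype's alleles, pooled
#' across loci. Alleles absent from the table contribute no eplets
#' (permissive, so partial eplet registries remain usable).
#'
#' @param genotype an `hla_genotype`.
#' @param table an [eplet_table()].
#' @return character vector of eplet names (possibly empty).
#' @export
eplet_set <- function(genotype, table) {
  alleles <- unique(unlist(genotype$alleles, use.names = FALSE))
  sort(unique(unlist(table$by_allele[alleles], use.names = FALSE)))
}

#' Interlocus eplet mismatch
#'
#' Eplets carried by any donor allele and by no recipient allele — the
#' interlocus set difference of the two repertoires.
#'
#' @param donor,recipient `hla_genotype` objects.
#' @param table an [eplet_table()].
#' @return character vector of mismatched eplet names.
#' @export
eplet_mismatch <- function(donor, recipient, table) {
  setdiff(eplet_set(donor, table), eplet_set(recipient, table))
}

#' Population frequency of each eplet
#'
#' Fraction of genotypes in the population carrying at least one allele that
#' bears the eplet.
#'
#' @param table an [eplet_table()].
#' @param population a `genotype_population` or a list of `hla_genotype`s.
#' @return named numeric vector, one proportion per eplet in the table.
#' @export
eplet_frequencies <- function(table, population) {
  if (inherits(population, "genotype_population")) {
    if (nrow(population$haps) == 0L) stop("empty population")
    M <- hap_eplet_incidence(population$table, table)
    carr <- M[population$haps[, 1L], , drop = FALSE] |
      M[population$haps[, 2L], , drop = FALSE]
    f <- colMeans(carr)
  } else {
    if (length(population) == 0L) stop("empty population")
    sets <- lapply(population, eplet_set, table = table)
    f <- vapply(table$eplets, function(e)
      mean(vapply(sets, function(s) e %in% s, logical(1))), numeric(1))
  }
  names(f) <- table$eplets
  f
}

#' Haplotype-by-eplet incidence matrix
#'
#' Logical matrix with one row per haplotype of `haplotypes` and one column
#' per eplet: TRUE when any allele of the haplotype carries the eplet. This
#' is the workhorse representation behind population-scale eplet operations.
#'
#' @param haplotypes a [haplotype_table()].
#' @param table an [eplet_table()].
#' @return logical matrix, `nrow(haplotypes)` x `length(table$eplets)`.
#' @export
hap_eplet_incidence <- function(haplotypes, table) {
  E <- length(table$eplets)
  M <- matrix(FALSE, nrow(haplotypes), E,
              dimnames = list(NULL, table$eplets))
  for (l in hla_loci()) {
    al <- haplotypes[[l]]
    for (a in unique(al)) {
      eps <- table$by_allele[[a]]
      if (length(eps)) M[al == a, match(eps, table$eplets)] <- TRUE
    }
  }
  M
}

#' Assign unacceptable antigens to reach a target virtual PRA
#'
#' Emulates sensitization: eplets not present in the patient's own repertoire
#' are drawn one at a time (uniformly by default, frequency-weighted when
#' `weighted = TRUE`) until the sum of the drawn eplets' population
#' frequencies reaches `target_pra/100`, or the non-self pool is exhausted.
#' The drawn eplets are then translated into serologic antigens: every broad
#' and split antigen of any allele carrying a drawn eplet, excluding the
#' patient's own antigens. A target of 0 short-circuits to an empty set.
#'
#' @param genotype the patient's `hla_genotype`.
#' @param target_pra target panel-reactive antibody percentage in \[0, 100\].
#' @param table an [eplet_table()].
#' @param freqs per-eplet population frequencies from [eplet_frequencies()].
#' @param serology a [serology_map()]; alleles without serologic assignment
#'   contribute no antigens.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @param weighted draw eplets proportionally to their frequency instead of
#'   uniformly.
#' @return character vector of unacceptable antigen names (prefixed with
#'   locus, e.g. `"B|B7"`), with attribute `eplets` holding the drawn eplets.
#' @export
assign_unacceptables <- function(genotype, target_pra, table, freqs, serology,
                                 seed = NULL, weighted = FALSE) {
  stopifnot(target_pra >= 0, target_pra <= 100)
  if (target_pra == 0) return(character(0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  self <- eplet_set(genotype, table)
  pool <- setdiff(table$eplets, self)
  if (!length(pool)) return(character(0))
  prob <- if (weighted) pmax(freqs[pool], 1e-12) else NULL
  drawn_order <- sample(pool, length(pool), prob = prob)
  cum <- cumsum(as.numeric(freqs[drawn_order]))
  k <- which(cum >= target_pra / 100)[1L]
  if (is.na(k)) k <- length(drawn_order)  # pool exhausted below target
  drawn <- drawn_order[seq_len(k)]
  structure(.eplets_to_antigens(drawn, genotype, table, serology),
            eplets = drawn)
}

# internal: translate eplets -> locus-prefixed broad/split antigens of all
# carrying alleles, minus the patient's own antigens
.eplets_to_antigens <- function(eplets, genotype, table, serology) {
  inc <- table$incidence
  alleles <- unique(inc$allele[inc$eplet %in% eplets])
  st <- serology$table
  hit <- st[st$allele %in% alleles, , drop = FALSE]
  ags <- unique(c(paste(hit$locus, hit$broad, sep = "|"),
                  paste(hit$locus, hit$split, sep = "|")))
  own <- unlist(lapply(names(genotype$alleles), function(l) {
    al <- genotype$alleles[[l]]
    o <- st[st$locus == l & st$allele %in% al, , drop = FALSE]
    c(paste(o$locus, o$broad, sep = "|"), paste(o$locus, o$split, sep = "|"))
  }), use.names = FALSE)
  sort(setdiff(ags, own))
}

#' Realized PRA of an unacceptable-antigen set
#'
#' Fraction of population genotypes displaying at least one of the
#' unacceptable antigens — the verification metric for how closely the
#' eplet-sum approximation hits the target PRA.
#'
#' @param unacceptables character vector of locus-prefixed antigens as
#'   returned by [assign_unacceptables()].
#' @param population a `genotype_population`.
#' @param serology a [serology_map()].
#' @return proportion in \[0, 1\].
#' @export
realized_pra <- function(unacceptables, population, serology) {
  if (!length(unacceptables)) return(0)
  tab <- population$table
  st <- serology$table
  hap_hit <- rep(FALSE, nrow(tab))
  for (l in unique(st$locus)) {
    sl <- st[st$locus == l, , drop = FALSE]
    if (!l %in% names(tab)) next
    bag <- c(paste(l, sl$broad, sep = "|"), paste(l, sl$split, sep = "|"))
    bad <- sl$allele[bag[seq_len(nrow(sl))] %in% unacceptables |
                       bag[nrow(sl) + seq_len(nrow(sl))] %in% unacceptables]
    hap_hit <- hap_hit | tab[[l]] %in% bad
  }
  mean(hap_hit[population$haps[, 1L]] | hap_hit[population$haps[, 2L]])
}
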