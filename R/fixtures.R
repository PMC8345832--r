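# Synthetic-data generators: haplotype frequency tables, serology maps,
# eplet tables with immunogenicity weights, and bundled demographics — so
# every module is buildable and testable with no external download. The
# generated content emulates the *shape* of real registry data (heavy-tailed
# haplotype frequencies, broads with serologic splits, shared + private
# eplets), not any real frequencies or eplet definitions.

#' Specification for the synthetic fixture generators
#'
#' @param profile `"default"` (study-scale: 200 haplotypes over wide allele
#'   alphabets) or `"tiny"` (8 haplotypes, for runs that complete in
#'   seconds).
#' @param seed integer seed; generation is deterministic per seed.
#' @param n_haplotypes number of unique haplotypes.
#' @param alleles_per_locus named integer vector of allele-alphabet sizes.
#' @param n_shared_eplets number of shared (multi-allele) eplets on top of
#'   the one private eplet per allele that guarantees any two distinct
#'   alleles differ in at least one eplet.
#' @param freq_decay geometric decay of the haplotype frequency ranks; values
#'   below 1 give the heavy tail (a few common, many rare haplotypes) seen
#'   in real registry tables.
#' @param target_mean_score surrogate-score calibration target: eplet weights
#'   are scaled once so the mean score of random donor-recipient pairs hits
#'   this value, placing the score range at the 0-300 scale typical of
#'   class-II epitope counts and making all four risk strata reachable.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(profile = c("default", "tiny"), seed = 2015L,
                         n_haplotypes = NULL, alleles_per_locus = NULL,
                         n_shared_eplets = NULL, freq_decay = NULL,
                         target_mean_score = 65) {
  profile <- match.arg(profile)
  if (is.null(n_haplotypes))
    n_haplotypes <- if (profile == "default") 200L else 8L
  if (is.null(alleles_per_locus))
    alleles_per_locus <- if (profile == "default")
      c(A = 20L, B = 30L, C = 15L, DRB1 = 20L, DQB1 = 12L)
  else c(A = 4L, B = 5L, C = 3L, DRB1 = 4L, DQB1 = 3L)
  if (is.null(n_shared_eplets))
    n_shared_eplets <- if (profile == "default") 80L else 20L
  if (is.null(freq_decay))
    freq_decay <- if (profile == "default") 0.97 else 0.80
  stopifnot(n_haplotypes >= 1, all(alleles_per_locus >= 1),
            n_shared_eplets >= 1, freq_decay > 0, freq_decay <= 1,
            target_mean_score > 0,
            setequal(names(alleles_per_locus), hla_loci()))
  structure(list(profile = profile, seed = as.integer(seed),
                 n_haplotypes = as.integer(n_haplotypes),
                 alleles_per_locus = alleles_per_locus[hla_loci()],
                 n_shared_eplets = as.integer(n_shared_eplets),
                 freq_decay = freq_decay,
                 target_mean_score = target_mean_score),
            class = "fixture_spec")
}

# per-locus serologic prefixes for synthetic antigen names
.locus_prefix <- c(A = "A", B = "B", C = "Cw", DRB1 = "DR", DQB1 = "DQ")

# internal: synthetic allele codes for one locus, e.g. "A*01".."A*12"
.allele_codes <- function(locus, n)
  sprintf("%s*%02d", locus, seq_len(n))

#' Generate a synthetic haplotype frequency table
#'
#' Haplotypes are unique random allele tuples over the synthetic alphabets;
#' frequencies decay geometrically in rank so a few haplotypes are common
#' and many are rare, echoing real registry tables.
#'
#' @param spec a [fixture_spec()].
#' @return a [haplotype_table()] (frequencies normalized, rank-ordered).
#' @export
synth_haplotype_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(child_seed(spec$seed, "haplotypes"))
  n <- spec$n_haplotypes
  ap <- spec$alleles_per_locus
  seen <- character(0)
  rows <- vector("list", n)
  guard <- 0L
  while (length(seen) < n) {
    guard <- guard + 1L
    if (guard > 50L * n) stop("cannot draw ", n, " unique haplotypes; ",
                              "enlarge the allele alphabets")
    tup <- vapply(hla_loci(), function(l)
      .allele_codes(l, ap[[l]])[sample.int(ap[[l]], 1L)], character(1))
    key <- paste(tup, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(seen)]] <- tup
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- hla_loci()
  df$freq <- spec$freq_decay^(seq_len(n) - 1L)
  haplotype_table(df)
}

#' Generate a synthetic serology map
#'
#' Every synthetic allele maps to a broad antigen; consecutive allele pairs
#' share a broad, in which case each member gets its own split antigen
#' (otherwise the split equals the broad). This yields homozygote collapse,
#' broad collapse of two splits, and split-level discrimination within a
#' broad — the serologic phenomena the match grade depends on.
#'
#' @param spec a [fixture_spec()].
#' @return a [serology_map()] covering every allele of every locus.
#' @export
synth_serology_map <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rows <- lapply(hla_loci(), function(l) {
    n <- spec$alleles_per_locus[[l]]
    al <- .allele_codes(l, n)
    broad_idx <- ceiling(seq_len(n) / 2)
    broad <- sprintf("%s%d", .locus_prefix[[l]], broad_idx)
    has_partner <- tabulate(broad_idx)[broad_idx] > 1L
    split <- ifelse(has_partner,
                    sprintf("%s%d", .locus_prefix[[l]], 100L + seq_len(n)),
                    broad)
    data.frame(locus = l, allele = al, broad = broad, split = split,
               stringsAsFactors = FALSE)
  })
  serology_map(do.call(rbind, rows))
}

#' Generate a synthetic eplet table with calibrated weights
#'
#' Each allele carries one private eplet (so any two distinct alleles differ
#' in at least one eplet, and the surrogate score is strictly positive
#' whenever the donor carries an allele the recipient lacks) plus
#' membership in shared eplets drawn over random allele
#' subsets within a locus. Immunogenicity weights are gamma-distributed and
#' then scaled once so the mean surrogate score of random donor-recipient
#' pairs from `haplotypes` matches the calibration target in `spec`.
#'
#' @param spec a [fixture_spec()].
#' @param haplotypes the [synth_haplotype_table()] output used for score
#'   calibration.
#' @return an [eplet_table()] with a `weight` per eplet.
#' @export
synth_eplet_table <- function(spec, haplotypes) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(haplotypes, "haplotype_table"))
  set.seed(child_seed(spec$seed, "eplets"))
  ap <- spec$alleles_per_locus
  rows <- list()
  for (l in hla_loci()) {
    al <- .allele_codes(l, ap[[l]])
    rows[[l]] <- data.frame(eplet = sprintf("pe_%s", sub("\\*", "", al)),
                            allele = al, weight = stats::rgamma(length(al), 2, 1),
                            stringsAsFactors = FALSE)
  }
  loci_w <- ap / sum(ap)
  shared <- lapply(seq_len(spec$n_shared_eplets), function(k) {
    l <- hla_loci()[.sample_cat(1L, loci_w)]
    n <- ap[[l]]
    size <- sample(2:min(5L, n), 1L)
    members <- .allele_codes(l, n)[sample.int(n, size)]
    data.frame(eplet = sprintf("se%03d", k), allele = members,
               weight = stats::rgamma(1L, 2, 0.5),
               stringsAsFactors = FALSE)
  })
  df <- rbind(do.call(rbind, rows), do.call(rbind, shared))
  tab <- eplet_table(df)
  # calibrate: Monte-Carlo mean score of random pairs -> target
  M <- hap_eplet_incidence(haplotypes, tab)
  w <- unname(tab$weights[colnames(M)])
  draws <- matrix(sample.int(nrow(haplotypes), 4L * 400L, replace = TRUE,
                             prob = haplotypes$freq), ncol = 4L)
  mean_score <- mean(vapply(seq_len(nrow(draws)), function(i) {
    d <- M[draws[i, 1L], ] | M[draws[i, 2L], ]
    r <- M[draws[i, 3L], ] | M[draws[i, 4L], ]
    sum(w[d & !r])
  }, numeric(1)))
  if (mean_score <= 0) stop("degenerate eplet table: zero mean score")
  df$weight <- df$weight * spec$target_mean_score / mean_score
  eplet_table(df)
}

#' Generate the complete fixture bundle
#'
#' One-stop generator: haplotype table, serology map, calibrated eplet table
#' and the matching demographics configuration.
#'
#' @param profile fixture profile, passed to [fixture_spec()] and
#'   [default_demographics_config()].
#' @param seed integer seed.
#' @param spec optional pre-built [fixture_spec()] (overrides `profile` and
#'   `seed`).
#' @return a `fixture_set`: list with `haplotypes`, `serology`, `eplets`,
#'   `demographics` and the `spec`.
#' @export
fixture_set <- function(profile = c("default", "tiny"), seed = 2015L,
                        spec = NULL) {
  if (is.null(spec)) spec <- fixture_spec(profile, seed = seed)
  haplotypes <- synth_haplotype_table(spec)
  structure(list(haplotypes = haplotypes,
                 serology = synth_serology_map(spec),
                 eplets = synth_eplet_table(spec, haplotypes),
                 demographics = default_demographics_config(spec$profile),
                 spec = spec),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf(paste0("Fixture set (%s, seed %d): %d haplotypes, ",
                     "%d alleles, %d eplets\n"),
              x$spec$profile, x$spec$seed, nrow(x$haplotypes),
              sum(x$spec$alleles_per_locus), length(x$eplets$eplets)))
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Writes `haplotypes.csv`, `serology.csv`, `eplets.csv` and
#' `demographics.yaml` in the formats the corresponding loaders read back.
#'
#' @param fx a [fixture_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fx, dir) {
  stopifnot(inherits(fx, "fixture_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_haplotype_table(fx$haplotypes, file.path(dir, "haplotypes.csv"))
  write_serology_map(fx$serology, file.path(dir, "serology.csv"))
  write_eplet_table(fx$eplets, file.path(dir, "eplets.csv"))
  write_demographics_config(fx$demographics, file.path(dir, "demographics.yaml"))
  invisible(dir)
}
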