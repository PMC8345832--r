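# The pluggable donor-by-recipient epitope score contract, its deterministic
# eplet-load surrogate, the three match-point functions that redistribute the
# 400 match points over epitope scores, the genotype reference panel, the
# risk-profile weighted median, and both mismatch-probability mappings.

#' Deterministic eplet-load surrogate epitope scorer
#'
#' Stands in for an external T-cell epitope prediction service with a
#' deterministic, cacheable contract: the score of a donor-recipient pair is
#' the weighted count of eplets carried by the donor and absent from the
#' recipient (interlocus mismatch load), scaled to the 0-300 range typical of
#' class-II epitope counts. It is 0 for identical genotypes, strictly
#' positive when any source-locus allele differs (the fixture generator
#' guarantees every pair of distinct alleles differs in at least one eplet),
#' and adding a mismatched allele never decreases it.
#'
#' @param table an [eplet_table()] whose weights set the score scale.
#' @param scale extra multiplicative scale on the weights.
#' @return an `epitope_scorer` with a per-pair result cache.
#' @export
surrogate_scorer <- function(table, scale = 1) {
  stopifnot(inherits(table, "eplet_table"), scale > 0)
  w <- table$weights * scale
  structure(list(kind = "surrogate", table = table, weights = w,
                 name = sprintf("surrogate-eplet-load/scale=%g", scale),
                 cache = new.env(parent = emptyenv())),
            class = "epitope_scorer")
}

#' Epitope scorer backed by a precomputed score table
#'
#' Plugs real donor-by-recipient epitope score exports (CSV columns
#' `donor_genotype_id,recipient_genotype_id,score`) in place of the
#' surrogate. Genotypes are matched by their `id` field (set by
#' [genotype()]).
#'
#' @param df data.frame or CSV path with the three columns above.
#' @return an `epitope_scorer`.
#' @export
table_scorer <- function(df) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  need <- c("donor_genotype_id", "recipient_genotype_id", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("score table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$score < 0)) stop("scores must be nonnegative")
  lk <- new.env(parent = emptyenv(), size = nrow(df) * 2L)
  for (i in seq_len(nrow(df)))
    assign(paste(df$donor_genotype_id[i], df$recipient_genotype_id[i], sep = "|"),
           df$score[i], envir = lk)
  structure(list(kind = "table", lookup = lk, name = "precomputed-table",
                 cache = new.env(parent = emptyenv())),
            class = "epitope_scorer")
}

#' @export
print.epitope_scorer <- function(x, ...) {
  cat(sprintf("Epitope scorer '%s' (%d cached pairs)\n", x$name,
              length(ls(x$cache))))
  invisible(x)
}

# internal: canonical digest of a genotype (order-free over the two
# chromosomes), used as cache key
.genotype_digest <- function(g) {
  paste(vapply(g$alleles, function(a) paste(sort(a), collapse = ","),
               character(1)), collapse = ";")
}

#' Score a donor-recipient genotype pair
#'
#' Deterministic per unordered characteristics of the pair; results are
#' cached so a second lookup of any pair returns the identical value.
#'
#' @param scorer an `epitope_scorer`.
#' @param donor,recipient `hla_genotype` objects.
#' @return nonnegative score.
#' @export
epitope_score <- function(scorer, donor, recipient) {
  stopifnot(inherits(scorer, "epitope_scorer"))
  key <- paste(.genotype_digest(donor), .genotype_digest(recipient), sep = ">")
  hit <- get0(key, envir = scorer$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  s <- switch(scorer$kind,
    surrogate = {
      mm <- eplet_mismatch(donor, recipient, scorer$table)
      sum(scorer$weights[mm])
    },
    table = {
      v <- get0(paste(donor$id, recipient$id, sep = "|"),
                envir = scorer$lookup, inherits = FALSE)
      if (is.null(v))
        stop("no precomputed score for pair ", donor$id, " -> ", recipient$id)
      v
    },
    stop("unknown scorer kind"))
  assign(key, s, envir = scorer$cache)
  s
}

#' Match-point function over epitope scores
#'
#' ETKAS distributes up to 400 points by HLA match grade; the epitope-based
#' scenarios redistribute the same budget over the donor-recipient epitope
#' score in one of three shapes:
#' \describe{
#'   \item{strata}{piecewise constant: 400 below 9, 266 on \[9, 35), 133 on
#'     \[35, 90\], 0 above 90.}
#'   \item{exponential}{`400 * 0.958 * exp(-0.032 * s)`.}
#'   \item{linear}{`400 * max(0, 1 - (s + 1)/90)` (0 from score 89 on) by
#'     default; `shifted = FALSE` selects `400 * max(0, 1 - s/90)`.}
#' }
#' All variants are non-increasing in the score and bounded in \[0, 400\].
#'
#' @param variant one of `"strata"`, `"exponential"`, `"linear"`.
#' @param budget point budget (400).
#' @param strata_bounds,strata_points stratum boundaries and the point value
#'   per stratum (one more point than bounds).
#' @param exp_a,exp_b exponential constants.
#' @param linear_cap score at which the linear variant reaches zero.
#' @param shifted use the shifted linear form (see above).
#' @return a `match_point_function`.
#' @export
match_point_function <- function(variant = c("strata", "exponential", "linear"),
                                 budget = 400,
                                 strata_bounds = c(9, 35, 90),
                                 strata_points = c(400, 266, 133, 0),
                                 exp_a = 0.958, exp_b = 0.032,
                                 linear_cap = 90, shifted = TRUE) {
  variant <- match.arg(variant)
  stopifnot(length(strata_points) == length(strata_bounds) + 1L,
            !is.unsorted(strata_bounds), budget > 0, linear_cap > 0)
  structure(list(variant = variant, budget = budget,
                 strata_bounds = strata_bounds, strata_points = strata_points,
                 exp_a = exp_a, exp_b = exp_b,
                 linear_cap = linear_cap, shifted = shifted),
            class = "match_point_function")
}

#' Evaluate a match-point function
#'
#' @param score nonnegative epitope score(s).
#' @param f a [match_point_function()].
#' @return points in \[0, budget\], vectorized over `score`.
#' @export
match_points <- function(score, f) {
  stopifnot(inherits(f, "match_point_function"))
  if (any(score < 0)) stop("negative epitope score")
  switch(f$variant,
    strata = {
      # left-closed strata: [0,9) -> 400, [9,35) -> 266, [35,90] -> 133, >90 -> 0
      nb <- length(f$strata_bounds)
      pts <- rep(f$strata_points[nb + 1L], length(score))
      pts[score <= f$strata_bounds[nb]] <- f$strata_points[nb]
      for (i in rev(seq_len(nb - 1L)))
        pts[score < f$strata_bounds[i]] <- f$strata_points[i]
      pts
    },
    exponential = f$budget * f$exp_a * exp(-f$exp_b * score),
    linear = {
      s <- if (f$shifted) score + 1 else score
      f$budget * pmax(0, 1 - s / f$linear_cap)
    })
}

#' ETKAS match points from an HLA mismatch grade
#'
#' The serologic baseline: `400 * (1 - mm/6)` over the total A+B+DR mismatch
#' count, so a full-house match earns the full budget and a 6-mismatch pair
#' earns none.
#'
#' @param mm_total total mismatch count in 0..6 (vectorized).
#' @param budget point budget (400).
#' @return points in \[0, budget\].
#' @export
hla_grade_points <- function(mm_total, budget = 400) {
  stopifnot(all(mm_total >= 0), all(mm_total <= 6))
  budget * (1 - mm_total / 6)
}

#' Build the reference genotype panel from the most frequent haplotypes
#'
#' All unordered pairs of the `k` most frequent haplotypes, with random-mating
#' genotype frequencies (`f_i^2` for homozygotes, `2 f_i f_j` otherwise).
#' Pairs whose unphased per-locus allele multisets coincide are merged
#' (summing frequency), and panel frequencies are renormalized to 1.
#'
#' @param table a [haplotype_table()].
#' @param k number of top haplotypes; clipped to the table size with a
#'   warning when larger.
#' @return a `genotype_panel`: haplotype index pairs, frequencies, and the
#'   source table.
#' @export
build_genotype_panel <- function(table, k) {
  stopifnot(inherits(table, "haplotype_table"), k >= 1)
  if (k > nrow(table)) {
    warning("k = ", k, " exceeds table size ", nrow(table), "; clipped")
    k <- nrow(table)
  }
  top <- order(table$freq, decreasing = TRUE)[seq_len(k)]
  pairs <- cbind(rep(top, times = seq(k, 1)),
                 unlist(lapply(seq_len(k), function(i) top[i:k])))
  f <- table$freq
  freq <- ifelse(pairs[, 1L] == pairs[, 2L],
                 f[pairs[, 1L]]^2, 2 * f[pairs[, 1L]] * f[pairs[, 2L]])
  # merge phase-equivalent genotypes (same unphased allele multisets)
  key <- apply(pairs, 1L, function(h)
    paste(vapply(hla_loci(), function(l)
      paste(sort(c(table[[l]][h[1L]], table[[l]][h[2L]])), collapse = ","),
      character(1)), collapse = ";"))
  if (anyDuplicated(key)) {
    agg <- tapply(freq, key, sum)
    keep <- !duplicated(key)
    pairs <- pairs[keep, , drop = FALSE]
    freq <- as.numeric(agg[key[keep]])
  }
  structure(list(haps = pairs, freq = freq / sum(freq), table = table),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d unique genotypes (freq sum %.9f)\n",
              nrow(x$haps), sum(x$freq)))
  invisible(x)
}

#' Number of genotypes in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
panel_size <- function(panel) nrow(panel$haps)

#' Extract one panel genotype
#' @param panel a `genotype_panel`.
#' @param i genotype index.
#' @return an `hla_genotype`.
#' @export
panel_genotype <- function(panel, i) {
  g <- genotype(structure(list(haps = panel$haps, table = panel$table),
                          class = "genotype_population"), i)
  g$id <- i
  g
}

#' Epitope risk-profile weighted median
#'
#' Scores the patient against every panel genotype (panel genotypes acting as
#' virtual donors) and aggregates with the frequency-weighted lower median:
#' the smallest score such that panel genotypes scoring at or below it hold
#' at least half the panel frequency mass. Half the virtual donor population
#' is then expected to score below, half above.
#'
#' @param patient the patient's `hla_genotype`.
#' @param panel a [build_genotype_panel()] result.
#' @param scorer an `epitope_scorer`.
#' @return the weighted median score (`rp_median`).
#' @export
risk_profile_median <- function(patient, panel, scorer) {
  if (panel_size(panel) == 0L) stop("empty genotype panel")
  scores <- vapply(seq_len(panel_size(panel)), function(i)
    epitope_score(scorer, panel_genotype(panel, i), patient), numeric(1))
  weighted_median_lower(scores, panel$freq)
}

#' Mismatch-probability parameters
#'
#' @param bloodgroup_frequency donor-pool frequency of the patient's blood
#'   group (probability an arriving donor is ABO-identical).
#' @param relative_pra `(100 - PRA)/100`: the fraction of donors not excluded
#'   by the patient's antibodies, so higher sensitization yields more
#'   mismatch-probability points.
#' @param rp_cap risk-profile cap (200).
#' @param exponent outer exponent (20).
#' @param budget point budget the probability is scaled by downstream.
#' @return an `mmp_params` list.
#' @export
mmp_params <- function(bloodgroup_frequency, relative_pra,
                       rp_cap = 200, exponent = 20, budget = 100) {
  stopifnot(bloodgroup_frequency >= 0, bloodgroup_frequency <= 1,
            relative_pra >= 0, relative_pra <= 1, rp_cap > 0, exponent > 0)
  structure(list(bloodgroup_frequency = bloodgroup_frequency,
                 relative_pra = relative_pra, rp_cap = rp_cap,
                 exponent = exponent, budget = budget),
            class = "mmp_params")
}

#' Convert a PRA percentage to the relative PRA factor
#' @param pra percentage in \[0, 100\].
#' @return `(100 - pra)/100`.
#' @export
relative_pra <- function(pra) {
  stopifnot(all(pra >= 0), all(pra <= 100))
  (100 - pra) / 100
}

#' Epitope-based mismatch probability
#'
#' `(1 - bgFreq * relPRA * (1 - min(1, rp/cap)))^exponent`: patients whose
#' risk-profile median is high (hard to epitope-match), whose blood group is
#' rare or who are highly sensitized approach 1 and receive the full
#' mismatch-probability point budget.
#'
#' @param rp_median risk-profile weighted median from
#'   [risk_profile_median()].
#' @param params an [mmp_params()].
#' @return proportion in \[0, 1\], vectorized over `rp_median`.
#' @export
pirche_mmp <- function(rp_median, params) {
  stopifnot(inherits(params, "mmp_params"), all(rp_median >= 0))
  (1 - params$bloodgroup_frequency * params$relative_pra *
     (1 - pmin(1, rp_median / params$rp_cap)))^params$exponent
}

#' Serologic (HLA) mismatch probability
#'
#' ET-style baseline with the same codomain and exponent as [pirche_mmp()]
#' for comparability: `(1 - bgFreq * relPRA * p_favorable)^exponent`, where
#' `p_favorable` is the estimated fraction of donors giving the patient at
#' most one A-B-DR mismatch (see [p_favorable()]).
#'
#' @param p_favorable proportion of favorable donors in \[0, 1\].
#' @param params an [mmp_params()].
#' @return proportion in \[0, 1\], vectorized over `p_favorable`.
#' @export
hla_mmp <- function(p_favorable, params) {
  stopifnot(inherits(params, "mmp_params"),
            all(p_favorable >= 0), all(p_favorable <= 1))
  (1 - params$bloodgroup_frequency * params$relative_pra * p_favorable)^
    params$exponent
}

#' Fraction of donors giving a patient at most one mismatch
#'
#' Estimated over the reference genotype panel: the frequency-weighted
#' proportion of panel genotypes whose A-B-DR mismatch grade against the
#' patient totals 0 or 1.
#'
#' @param patient an `hla_genotype`.
#' @param panel a [build_genotype_panel()] result.
#' @param serology a [serology_map()].
#' @return proportion in \[0, 1\].
#' @export
p_favorable <- function(patient, panel, serology) {
  if (panel_size(panel) == 0L) stop("empty genotype panel")
  ok <- vapply(seq_len(panel_size(panel)), function(i)
    sum(mismatch_grade(panel_genotype(panel, i), patient, serology)) <= 1L,
    logical(1))
  sum(panel$freq[ok])
}
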