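# Evaluation statistics over event logs: risk-strata and match-grade
# distributions, distribution-weighted mean log-score summaries (WML/SWML),
# Jensen-Shannon distance, graft-survival projection, exchange series and
# run comparisons.

#' Risk-strata distribution of epitope scores
#'
#' Fraction of transplants per risk stratum, using the same left-closed
#' boundary convention as the stratified match-point function: group 1
#' \[0, 9), group 2 \[9, 35), group 3 \[35, 90\], group 4 above 90.
#'
#' @param scores nonnegative epitope scores of transplanted pairs.
#' @param boundaries stratum boundaries.
#' @return a `strata_distribution`: per-group frequencies (summing to 1),
#'   counts and the boundaries.
#' @export
strata_frequencies <- function(scores, boundaries = c(9, 35, 90)) {
  if (!length(scores)) stop("no scores supplied")
  if (any(scores < 0)) stop("negative epitope score")
  g <- .strata_group(scores, boundaries)
  counts <- tabulate(g, nbins = length(boundaries) + 1L)
  structure(list(freq = counts / length(scores), counts = counts,
                 boundaries = boundaries), class = "strata_distribution")
}

# internal: stratum index per score (left-closed, last bound inclusive)
.strata_group <- function(scores, boundaries = c(9, 35, 90)) {
  nb <- length(boundaries)
  g <- rep(nb + 1L, length(scores))
  g[scores <= boundaries[nb]] <- nb
  for (i in rev(seq_len(nb - 1L))) g[scores < boundaries[i]] <- i
  g
}

#' @export
print.strata_distribution <- function(x, ...) {
  b <- x$boundaries
  labs <- c(sprintf("[0,%g)", b[1]),
            if (length(b) > 1) sprintf("[%g,%g)", b[-length(b)], b[-1]),
            sprintf(">%g", b[length(b)]))
  labs[length(labs) - 1L] <- sub(")$", "]", labs[length(labs) - 1L])
  cat("Risk-strata distribution:\n")
  print(stats::setNames(round(x$freq, 4), labs))
  invisible(x)
}

#' Distribution-weighted mean log-score per stratum (WML) and its sum
#'
#' For each stratum g, `WML_g = freq_g * mean(log(score + 1))` over the
#' transplants in g, with frequencies relative to all transplants; the SWML
#' is the exact sum of the group WMLs. Lower SWML means more transplants
#' carried out at lower epitope scores. Natural log with a +1 shift guards
#' zero-score transplants; both are configurable.
#'
#' @param scores nonnegative epitope scores of transplanted pairs.
#' @param boundaries stratum boundaries.
#' @param log_base base of the logarithm (`exp(1)` = natural).
#' @param shift additive shift inside the log.
#' @return a `wml_report`: per-group `wml`, `swml`, group frequencies.
#' @export
wml <- function(scores, boundaries = c(9, 35, 90), log_base = exp(1),
                shift = 1) {
  if (!length(scores)) stop("no scores supplied")
  if (any(scores < 0)) stop("negative epitope score")
  g <- .strata_group(scores, boundaries)
  ng <- length(boundaries) + 1L
  freq <- tabulate(g, nbins = ng) / length(scores)
  wml_g <- vapply(seq_len(ng), function(k) {
    s <- scores[g == k]
    if (!length(s)) return(0)
    freq[k] * mean(log(s + shift, base = log_base))
  }, numeric(1))
  structure(list(wml = wml_g, swml = sum(wml_g), freq = freq,
                 boundaries = boundaries), class = "wml_report")
}

#' @export
print.wml_report <- function(x, ...) {
  cat(sprintf("WML per stratum: %s; SWML = %.4f\n",
              paste(sprintf("%.4f", x$wml), collapse = ", "), x$swml))
  invisible(x)
}

#' Jensen-Shannon distance between two discrete distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithm, so
#' the distance lies in \[0, 1\]: 0 for identical distributions, 1 for
#' distributions with disjoint support.
#'
#' @param p,q probability vectors over the same support (both summing to 1
#'   within 1e-6); when both are named, `q` is aligned to `p`'s names.
#' @return distance in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("distributions are defined over different supports")
    q <- q[names(p)]
  }
  if (length(p) != length(q))
    stop("distributions are defined over different supports")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must each sum to 1")
  if (any(p < 0) || any(q < 0)) stop("negative probability mass")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  d2 <- kl(p, m) / 2 + kl(q, m) / 2
  sqrt(max(0, d2))
}

#' Project graft survival from a strata distribution
#'
#' Multiplies each stratum's transplant frequency with the reported graft
#' survival for that stratum and sums across strata — a convex combination,
#' so the projection always lies between the smallest and largest group
#' survival. Survival rates are explicit inputs (they come from external
#' cohort studies, not from the simulation).
#'
#' @param strata_freqs a `strata_distribution` or a bare frequency vector
#'   summing to 1.
#' @param survival_by_group survival proportion in \[0, 1\] per stratum,
#'   same length as the frequencies.
#' @return projected survival proportion.
#' @export
estimated_graft_survival <- function(strata_freqs, survival_by_group) {
  f <- if (inherits(strata_freqs, "strata_distribution")) strata_freqs$freq
  else strata_freqs
  .check_distribution(f, "strata frequencies", tol = 1e-6)
  if (length(survival_by_group) != length(f))
    stop("need one survival rate per stratum (", length(f), ")")
  if (any(is.na(survival_by_group)) || any(survival_by_group < 0) ||
      any(survival_by_group > 1))
    stop("survival rates must be proportions in [0, 1]")
  sum(f * survival_by_group)
}

# internal: transplant rows of an event log (accepts a run or a data.frame)
.transplants <- function(log) {
  ev <- if (inherits(log, "etkas_run")) log$events else log
  if (!nrow(ev)) stop("empty event log")
  ev[ev$type == "transplant", , drop = FALSE]
}

#' Distribution of total HLA mismatches among transplants
#'
#' @param log an `etkas_run` or its event data.frame.
#' @return named proportion vector over 0..6 total A+B+DR mismatches.
#' @export
match_grade_distribution <- function(log) {
  tx <- .transplants(log)
  mm <- tx$mmA + tx$mmB + tx$mmDR
  stats::setNames(tabulate(mm + 1L, nbins = 7L) / length(mm),
                  as.character(0:6))
}

#' Proportion of cross-border transplants
#'
#' @param log an `etkas_run` or its event data.frame.
#' @return proportion of transplants whose donor and recipient countries
#'   differ.
#' @export
exchange_rate <- function(log) {
  tx <- .transplants(log)
  mean(tx$donor_country != tx$recipient_country)
}

#' Quartile summary of waiting time at transplantation
#'
#' @param log an `etkas_run` or its event data.frame.
#' @return named vector with minimum, quartiles, mean and maximum of the
#'   waited days (accrued plus on-list time) of transplanted patients.
#' @export
waiting_time_summary <- function(log) {
  tx <- .transplants(log)
  q <- stats::quantile(tx$wait_days, c(0, 0.25, 0.5, 0.75, 1))
  c(min = unname(q[1]), q1 = unname(q[2]), median = unname(q[3]),
    q3 = unname(q[4]), max = unname(q[5]), mean = mean(tx$wait_days))
}

#' Compare two runs' transplant epitope scores and yearly metrics
#'
#' Pooled transplant scores are compared with the Wilcoxon rank-sum test;
#' paired per-year values of a summary metric (default: the yearly exchange
#' rate) are compared with the Wilcoxon signed-rank test. Both tests are
#' delegated to [stats::wilcox.test()].
#'
#' @param a,b `etkas_run` objects (or event data.frames).
#' @param burn_in_years years excluded from both logs before testing.
#' @param yearly_metric function mapping a year's transplant events to one
#'   number, used for the paired test.
#' @return list with the two `htest` results (`rank_sum`, `signed_rank`)
#'   and the per-year metric table.
#' @export
compare_runs <- function(a, b, burn_in_years = 2,
                         yearly_metric = function(ev)
                           mean(ev$donor_country != ev$recipient_country)) {
  ta <- .transplants(a); tb <- .transplants(b)
  cutoff <- burn_in_years * 365
  ta <- ta[ta$day > cutoff, , drop = FALSE]
  tb <- tb[tb$day > cutoff, , drop = FALSE]
  if (!nrow(ta) || !nrow(tb)) stop("no post-burn-in transplants to compare")
  rank_sum <- stats::wilcox.test(ta$score, tb$score, exact = FALSE)
  ya <- ceiling(ta$day / 365); yb <- ceiling(tb$day / 365)
  years <- intersect(unique(ya), unique(yb))
  if (length(years) < 2L)
    stop("need at least 2 shared post-burn-in years for the paired test")
  ma <- vapply(years, function(y) yearly_metric(ta[ya == y, , drop = FALSE]),
               numeric(1))
  mb <- vapply(years, function(y) yearly_metric(tb[yb == y, , drop = FALSE]),
               numeric(1))
  signed_rank <- if (all(ma == mb)) {
    # no nonzero paired differences: no evidence against equality
    structure(list(statistic = c(V = 0), p.value = 1,
                   method = "Wilcoxon signed rank test (degenerate: all paired differences zero)",
                   data.name = "yearly metrics"), class = "htest")
  } else {
    stats::wilcox.test(ma, mb, paired = TRUE, exact = FALSE)
  }
  list(rank_sum = rank_sum, signed_rank = signed_rank,
       yearly = data.frame(year = years, a = ma, b = mb))
}
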