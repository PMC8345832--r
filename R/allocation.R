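# The allocation cascade at the level of individual records: eligibility
# filtering, point scoring, priority ordering, ranked offering with
# refusals, and the country-balance ledger. run_simulation() applies the
# same rules through vectorized internals; cross-path agreement is asserted
# in the test suite.

#' Donor-pool frequency of each blood group
#'
#' Probability that an arriving donor carries each blood group, marginalized
#' over the donor-country distribution — the `bloodgroupFrequency` entering
#' the mismatch-probability components.
#'
#' @param config a `demographics_config`.
#' @return named numeric vector over O, A, B, AB.
#' @export
donor_bloodgroup_frequency <- function(config) {
  out <- c(O = 0, A = 0, B = 0, AB = 0)
  for (cc in config$countries)
    out <- out + unlist(config$donor_country[[cc]]) *
      unlist(config$blood_group[[cc]])[names(out)]
  out
}

# internal: all antigen codes displayed by a donor
.donor_antigen_codes <- function(ctx, donor) {
  unique(c(ctx$hap_ags[[donor$h1]], ctx$hap_ags[[donor$h2]]))
}

#' Filter a waiting list to the candidates eligible for a donor
#'
#' Retains patients with the identical ABO blood group, whose country
#' accepts the donor's type (cardiac-death donors are only accepted by the
#' configured countries), and for whom no donor antigen — broad or split, at
#' any serologically mapped locus — is among the patient's unacceptable
#' antigens (the virtual crossmatch).
#'
#' @param donor a `donor_record`.
#' @param waitlist a `patient_records` data.frame.
#' @param context a [sim_context()].
#' @param config a `demographics_config` (supplies the donor-type
#'   acceptance rule).
#' @return the eligible subset of `waitlist` (possibly empty).
#' @export
eligible_candidates <- function(donor, waitlist, context, config) {
  if (!nrow(waitlist)) return(waitlist)
  keep <- waitlist$blood_group == donor$blood_group
  if (donor$donor_type == "DCD")
    keep <- keep & waitlist$country %in% config$dcd_accepting
  d_ags <- names(context$ag_code)[.donor_antigen_codes(context, donor)]
  cross <- vapply(waitlist$unacceptables, function(u)
    length(u) > 0L && any(d_ags %in% u), logical(1))
  waitlist[keep & !cross, , drop = FALSE]
}

#' Score one eligible candidate for a donor
#'
#' Assembles the full points breakdown: waiting-time points (linear in
#' waited days), high-urgency bonus, country-balance points (linear in the
#' patient country's net export balance), national-allocation bonus (the
#' donor-center distance collapses to national versus international at this
#' spatial resolution), match points (serologic grade table or epitope
#' match-point function, per scenario), mismatch-probability points and the
#' pediatric bonus.
#'
#' @param patient one row of a `patient_records` data.frame (or an
#'   equivalent list with the same fields).
#' @param donor a `donor_record`.
#' @param scenario a [scenario_spec()].
#' @param state list with `context` (a [sim_context()]), `config` (a
#'   `demographics_config`), `day` (current simulation day) and optionally
#'   `net_balance` (named per-country net exported-kidney counts, default all
#'   zero).
#' @return a `points_breakdown`: named list of components, their `total`,
#'   plus the underlying `mm` grade and epitope `score`.
#' @export
score_candidate <- function(patient, donor, scenario, state) {
  ctx <- state$context
  cfg <- state$config
  day <- if (is.null(state$day)) 0 else state$day
  nb <- state$net_balance
  w <- scenario$weights

  mmv <- c(.mm_locus(ctx$hA[donor$h1], ctx$hA[donor$h2],
                     ctx$hA[patient$h1], ctx$hA[patient$h2]),
           .mm_locus(ctx$hB[donor$h1], ctx$hB[donor$h2],
                     ctx$hB[patient$h1], ctx$hB[patient$h2]),
           .mm_locus(ctx$hDR[donor$h1], ctx$hDR[donor$h2],
                     ctx$hDR[patient$h1], ctx$hDR[patient$h2]))
  names(mmv) <- c("A", "B", "DR")
  dvec <- ctx$M[donor$h1, ] | ctx$M[donor$h2, ]
  rvec <- ctx$M[patient$h1, ] | ctx$M[patient$h2, ]
  score <- sum(ctx$w[dvec & !rvec])

  wait_days <- patient$accrued_days + day - patient$reg_day
  waiting <- wait_days / 365 * w$waiting_per_year
  urgency <- if (isTRUE(patient$urgent)) w$urgency else 0
  national <- if (identical(patient$country, donor$country)) w$national else 0
  balance <- if (!is.null(nb) && patient$country %in% names(nb))
    w$balance * nb[[patient$country]] else 0
  pediatric <- if (isTRUE(patient$pediatric)) w$pediatric else 0

  match <- if (scenario$match == "hla_grade")
    hla_grade_points(sum(mmv), w$match_budget)
  else match_points(score, scenario$match_fn)
  if (scenario$pediatric_double_match && isTRUE(patient$pediatric))
    match <- match * 2

  bgf <- donor_bloodgroup_frequency(cfg)[[patient$blood_group]]
  params <- mmp_params(bgf, relative_pra(patient$pra), budget = w$mmp_budget)
  mmp <- if (scenario$mmp == "hla")
    w$mmp_budget * hla_mmp(.pfav_hap(ctx, patient$h1, patient$h2), params)
  else
    w$mmp_budget * pirche_mmp(.rp_hap(ctx, patient$h1, patient$h2), params)

  parts <- list(waiting = waiting, urgency = urgency, balance = balance,
                national = national, match = match, mmp = mmp,
                pediatric = pediatric)
  structure(c(parts, list(total = sum(unlist(parts)), mm = mmv, score = score,
                          wait_days = wait_days)),
            class = "points_breakdown")
}

#' @export
print.points_breakdown <- function(x, ...) {
  cat(sprintf(paste0("Points: total %.1f (waiting %.1f, urgency %.0f, ",
                     "balance %.1f, national %.0f, match %.1f, MMP %.1f, ",
                     "pediatric %.0f); mm %d-%d-%d, epitope score %.1f\n"),
              x$total, x$waiting, x$urgency, x$balance, x$national,
              x$match, x$mmp, x$pediatric, x$mm[1], x$mm[2], x$mm[3],
              x$score))
  invisible(x)
}

#' Priority ordering key for one candidate
#'
#' ETKAS ranks lexicographically: the priority tier first (full serologic
#' match, or epitope score below the threshold in the score-based
#' scenarios) — prioritized pairs outrank all others regardless of points —
#' then, inside the priority tier only, the recipient's homozygosity count,
#' then the total point score. Ties in points are broken by longer waiting
#' time, then by patient id, so rankings are deterministic.
#'
#' @inheritParams score_candidate
#' @return numeric vector `c(tier, homozygosity, total, wait_days, -id)`;
#'   candidates sort by descending key.
#' @export
priority_key <- function(patient, donor, scenario, state) {
  ctx <- state$context
  bd <- score_candidate(patient, donor, scenario, state)
  tier <- if (scenario$priority == "full_match") as.numeric(sum(bd$mm) == 0)
  else as.numeric(bd$score < scenario$priority_threshold)
  hz <- if (tier > 0)
    (length(unique(c(ctx$hA[patient$h1], ctx$hA[patient$h2]))) == 1L) +
    (length(unique(c(ctx$hB[patient$h1], ctx$hB[patient$h2]))) == 1L) +
    (length(unique(c(ctx$hDR[patient$h1], ctx$hDR[patient$h2]))) == 1L)
  else 0
  c(tier = tier, homozygosity = as.numeric(hz), total = bd$total,
    wait_days = bd$wait_days, neg_id = -as.numeric(patient$id))
}

#' Rank eligible candidates for a donor
#'
#' @param candidates a `patient_records` data.frame of eligible candidates.
#' @inheritParams score_candidate
#' @return `candidates` reordered best-first, with `points_total`,
#'   `priority_tier`, `mm_total` and `epitope_score` columns appended.
#' @export
rank_candidates <- function(candidates, donor, scenario, state) {
  if (!nrow(candidates)) {
    candidates$points_total <- numeric(0)
    candidates$priority_tier <- numeric(0)
    candidates$mm_total <- integer(0)
    candidates$epitope_score <- numeric(0)
    return(candidates)
  }
  keys <- t(vapply(seq_len(nrow(candidates)), function(i)
    priority_key(as.list(candidates[i, , drop = FALSE]), donor, scenario,
                 state), numeric(5)))
  bds <- lapply(seq_len(nrow(candidates)), function(i)
    score_candidate(as.list(candidates[i, , drop = FALSE]), donor, scenario,
                    state))
  o <- order(keys[, 1L], keys[, 2L], keys[, 3L], keys[, 4L], keys[, 5L],
             decreasing = TRUE)
  out <- candidates[o, , drop = FALSE]
  out$points_total <- vapply(bds, `[[`, numeric(1), "total")[o]
  out$priority_tier <- keys[o, 1L]
  out$mm_total <- vapply(bds, function(b) sum(b$mm), numeric(1))[o]
  out$epitope_score <- vapply(bds, `[[`, numeric(1), "score")[o]
  out
}

#' Offer a kidney down a ranked candidate list
#'
#' Walks the ranking; each candidate independently refuses the offer with
#' the constant probability `refusal_p`. The first acceptor receives the
#' kidney; if every candidate refuses (or the list is empty) the kidney is
#' discarded with the reason recorded.
#'
#' @param ranked a ranked `patient_records` data.frame (best first).
#' @param refusal_p per-offer refusal probability.
#' @return list with `accepted` (row index into `ranked`, or `NA` on
#'   discard), `offers`, `refusals` and `reason` (`NA`, `"all_refused"` or
#'   `"no_candidates"`).
#' @export
place_kidney <- function(ranked, refusal_p = 0.1) {
  n <- nrow(ranked)
  if (!n) return(list(accepted = NA_integer_, offers = 0L, refusals = 0L,
                      reason = "no_candidates"))
  if (refusal_p == 0)
    return(list(accepted = 1L, offers = 1L, refusals = 0L, reason = NA_character_))
  # number of refusals before the first acceptance is geometric; capping at
  # the list length reproduces the per-candidate walk exactly in law
  r <- stats::rgeom(1L, 1 - refusal_p)
  if (r >= n) list(accepted = NA_integer_, offers = n, refusals = n,
                   reason = "all_refused")
  else list(accepted = r + 1L, offers = r + 1L, refusals = r,
            reason = NA_character_)
}

#' Create an empty country-balance ledger
#'
#' @param countries country codes.
#' @return a `balance_ledger` data.frame with zero export/import counts.
#' @export
balance_ledger <- function(countries) {
  structure(data.frame(country = countries, exports = 0L, imports = 0L,
                       stringsAsFactors = FALSE),
            class = c("balance_ledger", "data.frame"))
}

#' Record a transplant in the balance ledger
#'
#' A cross-border transplant increments the donor country's exports and the
#' recipient country's imports; national transplants leave the ledger
#' unchanged. The sum of net balances over countries is always zero.
#'
#' @param ledger a [balance_ledger()].
#' @param donor_country,recipient_country country codes.
#' @return the updated ledger.
#' @export
update_balance <- function(ledger, donor_country, recipient_country) {
  if (!identical(donor_country, recipient_country)) {
    i <- match(donor_country, ledger$country)
    j <- match(recipient_country, ledger$country)
    if (is.na(i) || is.na(j)) stop("country not in ledger")
    ledger$exports[i] <- ledger$exports[i] + 1L
    ledger$imports[j] <- ledger$imports[j] + 1L
  }
  ledger
}

#' Net exported-kidney balance per country
#' @param ledger a [balance_ledger()].
#' @return named numeric vector `exports - imports`.
#' @export
net_balance <- function(ledger) {
  stats::setNames(as.numeric(ledger$exports - ledger$imports), ledger$country)
}
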