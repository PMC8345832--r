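# The seven allocation scenarios: baseline ETKAS and the six epitope-based
# variants, differing only in the priority-tier predicate, the match-point
# function and the mismatch-probability variant.

.scenario_matrix <- function() {
  list(
    "ETKAS"      = list(priority = "full_match", match = "hla_grade", mmp = "hla"),
    "ETKASPIR-A" = list(priority = "score_lt",   match = "hla_grade", mmp = "hla"),
    "ETKASPIR-B" = list(priority = "full_match", match = "strata",    mmp = "hla"),
    "ETKASPIR-C" = list(priority = "full_match", match = "exponential", mmp = "hla"),
    "ETKASPIR-D" = list(priority = "full_match", match = "linear",    mmp = "hla"),
    "ETKASPIR-E" = list(priority = "full_match", match = "linear",    mmp = "pirche"),
    "ETKASPIR-F" = list(priority = "score_lt",   match = "linear",    mmp = "pirche"))
}

#' Construct an allocation scenario
#'
#' Resolves a scenario name to its combination of priority rule (full
#' serologic A-B-DR match versus epitope score below the threshold),
#' match-point function (serologic grade table, strata, exponential or
#' linear over the epitope score) and mismatch-probability variant
#' (serologic or epitope risk profile):
#'
#' | model | priority tier | match points | mismatch probability |
#' |---|---|---|---|
#' | ETKAS | full HLA match | HLA grade | HLA |
#' | ETKASPIR-A | score < 9 | HLA grade | HLA |
#' | ETKASPIR-B | full HLA match | strata | HLA |
#' | ETKASPIR-C | full HLA match | exponential | HLA |
#' | ETKASPIR-D | full HLA match | linear | HLA |
#' | ETKASPIR-E | full HLA match | linear | epitope RP |
#' | ETKASPIR-F | score < 9 | linear | epitope RP |
#'
#' Point weights for the non-HLA components are configurable assumptions
#' (the source system's exact magnitudes are not public): waiting time 33.3
#' points/year, high-urgency bonus 500, national-allocation bonus 100,
#' pediatric one-time bonus 100, country-balance weight 30 per net kidney,
#' mismatch-probability budget 100, match budget 400.
#'
#' @param name scenario name (`"ETKAS"`, `"ETKASPIR-A"` .. `"ETKASPIR-F"`;
#'   `"PIR-X"` shorthands accepted).
#' @param weights named list overriding any of `waiting_per_year`,
#'   `urgency`, `national`, `pediatric`, `balance`, `mmp_budget`,
#'   `match_budget`.
#' @param refusal_p constant per-offer refusal probability.
#' @param priority_threshold epitope score below which a pair enters the
#'   priority tier in the score-based scenarios.
#' @param pediatric_double_match also double the match points for pediatric
#'   recipients (off by default).
#' @param match_fn optional [match_point_function()] override; by default
#'   built from the scenario's variant.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(name = "ETKAS", weights = list(), refusal_p = 0.1,
                          priority_threshold = 9,
                          pediatric_double_match = FALSE, match_fn = NULL) {
  key <- toupper(name)
  if (grepl("^PIR-[A-F]$", key)) key <- paste0("ETKASPIR-", sub("^PIR-", "", key))
  sm <- .scenario_matrix()
  if (!key %in% names(sm))
    stop("unknown scenario '", name, "'; expected one of ",
         paste(names(sm), collapse = ", "))
  base <- sm[[key]]
  w <- list(waiting_per_year = 33.3, urgency = 500, national = 100,
            pediatric = 100, balance = 30, mmp_budget = 100,
            match_budget = 400)
  for (nm in names(weights)) {
    if (!nm %in% names(w)) stop("unknown weight '", nm, "'")
    if (weights[[nm]] < 0) stop("weights must be nonnegative")
    w[[nm]] <- weights[[nm]]
  }
  if (is.null(match_fn) && base$match != "hla_grade")
    match_fn <- match_point_function(base$match, budget = w$match_budget)
  stopifnot(refusal_p >= 0, refusal_p <= 1, priority_threshold >= 0)
  structure(list(name = key, priority = base$priority, match = base$match,
                 mmp = base$mmp, weights = w, refusal_p = refusal_p,
                 priority_threshold = priority_threshold,
                 pediatric_double_match = pediatric_double_match,
                 match_fn = match_fn),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("Scenario %s: priority = %s, match points = %s, ",
                     "MMP = %s, refusal p = %.2f\n"),
              x$name,
              if (x$priority == "full_match") "full HLA match"
              else sprintf("score < %g", x$priority_threshold),
              x$match, x$mmp, x$refusal_p))
  invisible(x)
}

#' Names of the supported allocation scenarios
#' @return character vector.
#' @export
scenario_names <- function() names(.scenario_matrix())
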