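# Waiting-list bootstrap and the patient/donor event-stream samplers,
# driven by the annual-report-style demographics configuration.

#' Sample accrued waiting times from report intervals
#'
#' The annual report gives waiting-time masses per interval; each interval is
#' treated as a continuous uniform distribution and the open-ended last
#' interval is truncated at 9 years. The report's 0-1 / 2-4 / 5+ year bands
#' leave years 1-2 unassigned, so the bundled intervals are the contiguous
#' \[0,2), \[2,5), \[5,9\] with the reported masses.
#'
#' @param intervals list of `c(lo, hi)` year pairs, contiguous.
#' @param probs interval masses, summing to 1.
#' @param n number of draws.
#' @return waiting times in days.
#' @export
sample_waiting_time <- function(intervals, probs, n = 1L) {
  .check_distribution(probs, "waiting_time")
  stopifnot(length(intervals) == length(probs))
  iv <- .sample_cat(n, probs)
  lo <- vapply(intervals, `[`, numeric(1), 1L)[iv]
  hi <- vapply(intervals, `[`, numeric(1), 2L)[iv]
  stats::runif(n, lo, hi) * 365
}

# internal: vectorized non-HLA attribute sampling for n new patients.
# Country, urgency and age are independent; blood group, PRA class and
# waiting time are conditional on country. Returns plain vectors.
.sample_patient_attrs <- function(n, cfg, with_waiting_time = TRUE) {
  countries <- cfg$countries
  ci <- .sample_cat(n, unlist(cfg$patient_country[countries]))
  urgent <- stats::runif(n) < cfg$urgency
  ai <- .sample_cat(n, cfg$age$probs)
  age <- stats::runif(n, cfg$age$breaks[ai], cfg$age$breaks[ai + 1L])
  bg <- integer(n)
  pra <- numeric(n)
  wt <- numeric(n)
  cls <- cfg$pra$classes
  for (k in seq_along(countries)) {
    idx <- which(ci == k)
    if (!length(idx)) next
    cc <- countries[k]
    bg[idx] <- .sample_cat(length(idx), unlist(cfg$blood_group[[cc]]))
    pk <- .sample_cat(length(idx), unlist(cfg$pra$by_country[[cc]]))
    lo <- vapply(cls, `[`, numeric(1), 1L)[pk]
    hi <- vapply(cls, `[`, numeric(1), 2L)[pk]
    pra[idx] <- ifelse(lo == hi, lo, round(stats::runif(length(idx), lo, hi)))
    if (with_waiting_time)
      wt[idx] <- sample_waiting_time(cfg$waiting_time$intervals_years,
                                     unlist(cfg$waiting_time$by_country[[cc]]),
                                     length(idx))
  }
  list(country = ci, urgent = urgent, age = age, blood_group = bg,
       pra = pra, accrued_days = wt)
}

# internal: fast sensitization for one patient given haplotype indices.
# Mirrors assign_unacceptables() on integer codes: permute non-self eplets,
# take the shortest prefix whose frequencies sum to >= target, translate to
# antigen codes, drop self antigens.
.draw_unacceptables <- function(ctx, h1, h2, target_pra, freqs) {
  if (target_pra <= 0) return(integer(0))
  self <- ctx$M[h1, ] | ctx$M[h2, ]
  pool <- which(!self)
  if (!length(pool)) return(integer(0))
  perm <- pool[sample.int(length(pool))]
  cum <- cumsum(freqs[perm])
  k <- which(cum >= target_pra / 100)[1L]
  if (is.na(k)) k <- length(perm)
  ags <- unique(unlist(ctx$ep_ags[perm[seq_len(k)]], use.names = FALSE))
  own <- unique(c(ctx$hap_ags[[h1]], ctx$hap_ags[[h2]]))
  setdiff(ags, own)
}

#' Bootstrap the initial waiting list
#'
#' Randomly selects and removes the configured number of individuals from
#' the virtual population, then assigns the non-HLA characteristics:
#' country, urgency and age independently from their marginals; blood group,
#' PRA class and accrued waiting time conditional on country. Patients with
#' PRA > 0 receive unacceptable antigens by the eplet-frequency procedure of
#' [assign_unacceptables()], using eplet frequencies computed on the
#' population before removal.
#'
#' @param population a `genotype_population` of at least the configured
#'   waiting-list size.
#' @param config a `demographics_config`.
#' @param context a [sim_context()].
#' @param seed optional integer seed for this stage.
#' @return list with `waitlist` (a `patient_records` data.frame with a
#'   list-column of unacceptable antigen names), `population` (the reduced
#'   pool) and `eplet_freqs`.
#' @export
bootstrap_waitlist <- function(population, config, context, seed = NULL) {
  n <- config$waitlist_size
  if (population_size(population) < n)
    stop("population (", population_size(population),
         ") smaller than configured waiting list (", n, ")")
  if (!is.null(seed)) set.seed(child_seed(seed, "bootstrap"))
  freqs <- eplet_frequencies(context$eplets, population)
  if (n == 0L) {
    return(list(waitlist = .empty_patient_records(), population = population,
                eplet_freqs = freqs))
  }
  take <- sample.int(population_size(population), n)
  haps <- population$haps[take, , drop = FALSE]
  reduced <- structure(list(haps = population$haps[-take, , drop = FALSE],
                            table = population$table),
                       class = "genotype_population")
  attrs <- .sample_patient_attrs(n, config)
  unacc <- vector("list", n)
  for (i in seq_len(n))
    unacc[[i]] <- .draw_unacceptables(context, haps[i, 1L], haps[i, 2L],
                                      attrs$pra[i], freqs)
  wl <- data.frame(
    id = seq_len(n), h1 = haps[, 1L], h2 = haps[, 2L],
    country = config$countries[attrs$country],
    urgent = attrs$urgent, age = attrs$age,
    blood_group = c("O", "A", "B", "AB")[attrs$blood_group],
    pra = attrs$pra, accrued_days = attrs$accrued_days,
    reg_day = 0L, pediatric = attrs$age < config$pediatric_age,
    stringsAsFactors = FALSE)
  wl$unacceptables <- lapply(unacc, function(codes)
    names(context$ag_code)[codes])
  class(wl) <- c("patient_records", "data.frame")
  list(waitlist = wl, population = reduced, eplet_freqs = freqs)
}

.empty_patient_records <- function() {
  wl <- data.frame(id = integer(0), h1 = integer(0), h2 = integer(0),
                   country = character(0), urgent = logical(0),
                   age = numeric(0), blood_group = character(0),
                   pra = numeric(0), accrued_days = numeric(0),
                   reg_day = integer(0), pediatric = logical(0),
                   stringsAsFactors = FALSE)
  wl$unacceptables <- list()
  class(wl) <- c("patient_records", "data.frame")
  wl
}

#' @export
print.patient_records <- function(x, ...) {
  cat(sprintf("Waiting list: %d patients (%d sensitized, %d urgent, %d pediatric)\n",
              nrow(x), sum(x$pra > 0), sum(x$urgent), sum(x$pediatric)))
  invisible(x)
}

#' Sample one donor
#'
#' Draws a genotype from the population (removing it), assigns the country
#' of origin independently from the donor-country marginal, and donor type
#' (brain versus cardiac death), blood group and kidney count conditional on
#' the donor country.
#'
#' @param population a non-empty `genotype_population`.
#' @param config a `demographics_config`.
#' @param day arrival day recorded on the donor.
#' @param id donor identifier.
#' @return list with `donor` (a `donor_record`) and the reduced
#'   `population`.
#' @export
sample_donor <- function(population, config, day = 0L, id = 1L) {
  if (population_size(population) == 0L) stop("population pool exhausted")
  i <- sample.int(population_size(population), 1L)
  h <- population$haps[i, ]
  reduced <- structure(list(haps = population$haps[-i, , drop = FALSE],
                            table = population$table),
                       class = "genotype_population")
  cc <- config$countries[.sample_cat(1L, unlist(config$donor_country[config$countries]))]
  type <- c("DBD", "DCD")[.sample_cat(1L, unlist(config$donor_type[[cc]]))]
  bg <- c("O", "A", "B", "AB")[.sample_cat(1L, unlist(config$blood_group[[cc]]))]
  kidneys <- c(1L, 2L)[.sample_cat(1L, unlist(config$kidneys_per_donor[[cc]]))]
  donor <- structure(list(id = id, h1 = h[1L], h2 = h[2L], country = cc,
                          donor_type = type, blood_group = bg,
                          kidneys = kidneys, day = day),
                     class = "donor_record")
  list(donor = donor, population = reduced)
}

#' @export
print.donor_record <- function(x, ...) {
  cat(sprintf("Donor %s: %s, %s, blood group %s, %d kidney(s), day %d\n",
              x$id, x$country, x$donor_type, x$blood_group, x$kidneys, x$day))
  invisible(x)
}

#' Expected kidneys per donor under a configuration
#'
#' Marginalizes the per-country kidneys-per-donor tables over the
#' donor-country marginal; the donor arrival rate is the configured kidney
#' rate divided by this expectation.
#'
#' @param config a `demographics_config`.
#' @return expected kidney count per donor.
#' @export
expected_kidneys_per_donor <- function(config) {
  sum(vapply(config$countries, function(cc)
    unlist(config$donor_country[[cc]]) *
      sum(c(1, 2) * unlist(config$kidneys_per_donor[[cc]])), numeric(1)))
}

#' Sample one day's event counts
#'
#' Daily counts are Poisson with the configured means ("around X events per
#' day"), independent across days; the donor count uses the kidney rate
#' divided by the expected kidneys per donor so that kidneys arrive at the
#' configured rate.
#'
#' @param config a `demographics_config`.
#' @return list with integer `donors`, `departures`, `registrations`.
#' @export
sample_daily_events <- function(config) {
  r <- config$rates
  list(donors = stats::rpois(1L, r$kidneys_per_day /
                               expected_kidneys_per_donor(config)),
       departures = stats::rpois(1L, r$departures_per_day),
       registrations = stats::rpois(1L, r$registrations_per_day))
}
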