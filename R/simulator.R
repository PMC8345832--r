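# The daily-step Markov chain: orchestrates departure/registration/donor
# event sampling, kidney allocation, ledger and waiting-list updates,
# snapshots and reproducible logging.

#' Assemble a simulation configuration
#'
#' @param scenario scenario name or a [scenario_spec()].
#' @param years simulated horizon in years (365-day years).
#' @param seed root seed; every randomized stage draws from a child stream
#'   derived via [child_seed()] (order: `fixtures`, `population`,
#'   `bootstrap`, `chain`), so identical configurations are bit-reproducible.
#' @param demographics a `demographics_config`.
#' @param fixtures a [fixture_set()] (haplotype table, serology map, eplet
#'   table); when `NULL` one is generated to match the demographics profile
#'   from the seed's fixture stream.
#' @param scorer optional `epitope_scorer`; default is the eplet-load
#'   surrogate over the fixture eplet table.
#' @param panel_k top-haplotype count for the reference genotype panel.
#' @param burn_in_years years excluded from steady-state summaries.
#' @param snapshot_every snapshot cadence in days.
#' @param horizon_days overrides `years * 365` when given.
#' @param check_invariants verify the waiting-list conservation identity
#'   against the full active mask every day (always verified via counters;
#'   the full check costs one scan per day).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(scenario = "ETKAS", years = 10, seed = 1,
                              demographics = default_demographics_config(),
                              fixtures = NULL, scorer = NULL, panel_k = 49,
                              burn_in_years = 2, snapshot_every = 365L,
                              horizon_days = NULL, check_invariants = TRUE) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(demographics, "demographics_config"))
  horizon <- if (is.null(horizon_days)) as.integer(round(years * 365))
  else as.integer(horizon_days)
  stopifnot(horizon >= 1, snapshot_every >= 1)
  snapshot_every <- min(snapshot_every, horizon)
  if (is.null(fixtures))
    fixtures <- fixture_set(profile = demographics$profile,
                            seed = child_seed(seed, "fixtures"))
  structure(list(scenario = scenario, horizon = horizon, seed = as.integer(seed),
                 demographics = demographics, fixtures = fixtures,
                 scorer = scorer, panel_k = panel_k,
                 burn_in_years = burn_in_years,
                 snapshot_every = as.integer(snapshot_every),
                 check_invariants = isTRUE(check_invariants)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s, %d days, seed %d, %s demographics\n",
              x$scenario$name, x$horizon, x$seed, x$demographics$profile))
  invisible(x)
}

#' Initialize a simulation
#'
#' Synthesizes the virtual population, bootstraps the waiting list (both on
#' their own seed streams) and builds the mutable simulation state.
#'
#' @param config a [simulation_config()].
#' @return a `simulation_state` environment; advance it with [step_day()].
#' @export
init_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fx <- config$fixtures
  scorer <- if (is.null(config$scorer)) surrogate_scorer(fx$eplets)
  else config$scorer
  ctx <- sim_context(fx$haplotypes, fx$serology, fx$eplets, scorer,
                     panel_k = config$panel_k)
  cfg <- config$demographics
  pop <- sample_population(fx$haplotypes, cfg$population_size,
                           seed = child_seed(config$seed, "population"))

  st <- new.env(parent = emptyenv())
  st$config <- config
  st$ctx <- ctx
  st$cfg <- cfg
  st$scn <- config$scenario
  st$day <- 0L

  # population pool: pre-permuted row order; drawing = advancing a pointer
  set.seed(child_seed(config$seed, "bootstrap"))
  st$pool <- pop$haps[sample.int(nrow(pop$haps)), , drop = FALSE]
  st$pool_ptr <- 0L
  st$eplet_freqs <- eplet_frequencies(ctx$eplets, pop)

  # patient arrays, preallocated for the whole horizon
  cap <- as.integer(cfg$waitlist_size +
                      ceiling(cfg$rates$registrations_per_day *
                                config$horizon * 1.35) + 200L)
  st$cap <- cap
  for (nm in c("h1", "h2", "country", "bg", "reg_day"))
    st[[nm]] <- integer(cap)
  for (nm in c("age", "pra", "accrued", "mmp_pts"))
    st[[nm]] <- numeric(cap)
  for (nm in c("urgent", "ped", "active")) st[[nm]] <- logical(cap)
  st$hz <- integer(cap)
  st$pa1 <- integer(cap); st$pa2 <- integer(cap)
  st$pb1 <- integer(cap); st$pb2 <- integer(cap)
  st$pdr1 <- integer(cap); st$pdr2 <- integer(cap)
  st$Ep <- matrix(FALSE, cap, ncol(ctx$M))
  st$unacc <- matrix(FALSE, cap, ctx$n_ags)
  st$n_pat <- 0L
  st$n_active <- 0L

  st$net_bal <- stats::setNames(numeric(length(cfg$countries)), cfg$countries)
  st$exports <- st$imports <- stats::setNames(integer(length(cfg$countries)),
                                              cfg$countries)
  st$dcd_ok <- cfg$countries %in% cfg$dcd_accepting
  st$dbgf <- donor_bloodgroup_frequency(cfg)
  st$counters <- list(registrations = 0L, departures = 0L, transplants = 0L,
                      discards = 0L, kidneys = 0L, donors = 0L,
                      offers = 0L, refusals = 0L)
  st$donor_seq <- 0L

  # event log accumulators
  ev_cap <- as.integer(ceiling(cfg$rates$kidneys_per_day * config$horizon *
                                 1.35) + 200L)
  st$ev <- new.env(parent = emptyenv())
  for (nm in c("day", "donor_id", "donor_h1", "donor_h2", "recipient_id",
               "mmA", "mmB", "mmDR", "refusals", "n_eligible"))
    st$ev[[nm]] <- integer(ev_cap)
  for (nm in c("score", "wait_days", "pts_match", "pts_waiting",
               "pts_urgency", "pts_balance", "pts_national", "pts_mmp",
               "pts_pediatric", "pts_total"))
    st$ev[[nm]] <- numeric(ev_cap)
  for (nm in c("type", "donor_country", "donor_bg", "donor_type",
               "recipient_country", "reason"))
    st$ev[[nm]] <- character(ev_cap)
  st$ev$n <- 0L
  st$ev$cap <- ev_cap

  st$snapshots <- list()

  # seed the waiting list (same attribute pipeline as daily registrations)
  .add_patients(st, cfg$waitlist_size, reg_day = 0L)
  st$initial_waitlist <- st$n_active

  set.seed(child_seed(config$seed, "chain"))
  class(st) <- "simulation_state"
  st
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf(paste0("Simulation state (%s): day %d, %d active of %d ",
                     "registered patients, %d transplants, %d discards\n"),
              x$scn$name, x$day, x$n_active, x$n_pat,
              x$counters$transplants, x$counters$discards))
  invisible(x)
}

# internal: draw n genotypes from the pre-permuted pool
.draw_pool <- function(st, n) {
  if (st$pool_ptr + n > nrow(st$pool))
    stop("virtual population pool exhausted on day ", st$day,
         " (", nrow(st$pool), " individuals); enlarge population_size")
  idx <- st$pool_ptr + seq_len(n)
  st$pool_ptr <- st$pool_ptr + n
  st$pool[idx, , drop = FALSE]
}

# internal: create n patients (bootstrap and daily registrations share this
# exact pipeline)
.add_patients <- function(st, n, reg_day) {
  if (n == 0L) return(invisible())
  ctx <- st$ctx; cfg <- st$cfg
  haps <- .draw_pool(st, n)
  attrs <- .sample_patient_attrs(n, cfg)
  at <- st$n_pat + seq_len(n)
  if (st$n_pat + n > st$cap) stop("patient capacity exceeded")
  h1 <- haps[, 1L]; h2 <- haps[, 2L]
  .poke(st, "h1", at, h1); .poke(st, "h2", at, h2)
  .poke(st, "country", at, attrs$country)
  .poke(st, "bg", at, attrs$blood_group)
  .poke(st, "urgent", at, attrs$urgent)
  .poke(st, "age", at, attrs$age)
  .poke(st, "pra", at, attrs$pra)
  .poke(st, "accrued", at, attrs$accrued_days)
  .poke(st, "reg_day", at, reg_day)
  .poke(st, "ped", at, attrs$age < cfg$pediatric_age)
  pa1 <- ctx$hA[h1]; pa2 <- ctx$hA[h2]
  pb1 <- ctx$hB[h1]; pb2 <- ctx$hB[h2]
  pdr1 <- ctx$hDR[h1]; pdr2 <- ctx$hDR[h2]
  .poke(st, "pa1", at, pa1); .poke(st, "pa2", at, pa2)
  .poke(st, "pb1", at, pb1); .poke(st, "pb2", at, pb2)
  .poke(st, "pdr1", at, pdr1); .poke(st, "pdr2", at, pdr2)
  .poke(st, "hz", at,
        (pa1 == pa2) + (pb1 == pb2) + (pdr1 == pdr2))
  Ep <- st$Ep; st$Ep <- NULL
  Ep[at, ] <- ctx$M[h1, , drop = FALSE] | ctx$M[h2, , drop = FALSE]
  st$Ep <- Ep
  w <- st$scn$weights
  unacc <- st$unacc; st$unacc <- NULL
  mmp_new <- numeric(n)
  for (k in seq_len(n)) {
    if (attrs$pra[k] > 0) {
      codes <- .draw_unacceptables(ctx, h1[k], h2[k], attrs$pra[k],
                                   st$eplet_freqs)
      if (length(codes)) unacc[at[k], codes] <- TRUE
    }
    params <- mmp_params(st$dbgf[[attrs$blood_group[k]]],
                         relative_pra(attrs$pra[k]), budget = w$mmp_budget)
    mmp_new[k] <- if (st$scn$mmp == "hla")
      w$mmp_budget * hla_mmp(.pfav_hap(ctx, h1[k], h2[k]), params)
    else
      w$mmp_budget * pirche_mmp(.rp_hap(ctx, h1[k], h2[k]), params)
  }
  st$unacc <- unacc
  .poke(st, "mmp_pts", at, mmp_new)
  .poke(st, "active", at, TRUE)
  st$n_pat <- st$n_pat + n
  st$n_active <- st$n_active + n
  st$counters$registrations <- st$counters$registrations + n
  invisible(at)
}

# internal: write one scalar into a vector bound in an environment without
# triggering copy-on-write (the extra binding would otherwise force a full
# duplication of the vector on every event)
.poke <- function(env, name, i, value) {
  tmp <- env[[name]]
  env[[name]] <- NULL
  tmp[i] <- value
  env[[name]] <- tmp
  invisible()
}

# internal: append one event-log row
.log_event <- function(st, type, donor, recipient = NA_integer_,
                       mm = c(NA_integer_, NA_integer_, NA_integer_),
                       score = NA_real_, pts = NULL, wait_days = NA_real_,
                       refusals = 0L, n_eligible = 0L, reason = NA_character_) {
  ev <- st$ev
  if (ev$n >= ev$cap) {
    grow <- ev$cap
    for (nm in setdiff(ls(ev), c("n", "cap"))) {
      tmp <- ev[[nm]]
      ev[[nm]] <- NULL
      length(tmp) <- length(tmp) + grow
      ev[[nm]] <- tmp
    }
    ev$cap <- ev$cap + grow
  }
  i <- ev$n + 1L
  .poke(ev, "day", i, st$day)
  .poke(ev, "type", i, type)
  .poke(ev, "donor_id", i, donor$id)
  .poke(ev, "donor_country", i, st$cfg$countries[donor$country])
  .poke(ev, "donor_bg", i, c("O", "A", "B", "AB")[donor$bg])
  .poke(ev, "donor_type", i, c("DBD", "DCD")[donor$type])
  .poke(ev, "donor_h1", i, donor$h1)
  .poke(ev, "donor_h2", i, donor$h2)
  .poke(ev, "recipient_id", i, recipient)
  .poke(ev, "recipient_country", i,
        if (is.na(recipient)) NA_character_
        else st$cfg$countries[st$country[recipient]])
  .poke(ev, "mmA", i, mm[1L]); .poke(ev, "mmB", i, mm[2L])
  .poke(ev, "mmDR", i, mm[3L])
  .poke(ev, "score", i, score)
  .poke(ev, "wait_days", i, wait_days)
  .poke(ev, "refusals", i, refusals)
  .poke(ev, "n_eligible", i, n_eligible)
  .poke(ev, "reason", i, reason)
  if (is.null(pts)) pts <- rep(NA_real_, 8L)
  .poke(ev, "pts_match", i, pts[1L]); .poke(ev, "pts_waiting", i, pts[2L])
  .poke(ev, "pts_urgency", i, pts[3L]); .poke(ev, "pts_balance", i, pts[4L])
  .poke(ev, "pts_national", i, pts[5L]); .poke(ev, "pts_mmp", i, pts[6L])
  .poke(ev, "pts_pediatric", i, pts[7L]); .poke(ev, "pts_total", i, pts[8L])
  ev$n <- i
}

# internal: allocate one kidney of one donor through the full cascade
.allocate_kidney <- function(st, donor) {
  ctx <- st$ctx; scn <- st$scn; w <- scn$weights
  act <- which(st$active[seq_len(st$n_pat)])
  keep <- st$bg[act] == donor$bg
  if (donor$type == 2L) keep <- keep & st$dcd_ok[st$country[act]]
  cand <- act[keep]
  if (length(cand)) {
    viol <- rowSums(st$unacc[cand, donor$ags, drop = FALSE]) > 0
    cand <- cand[!viol]
  }
  n_elig <- length(cand)
  if (!n_elig) {
    st$counters$discards <- st$counters$discards + 1L
    .log_event(st, "discard", donor, reason = "no_candidates")
    return(invisible(FALSE))
  }
  mmA <- .mm_locus(donor$a1, donor$a2, st$pa1[cand], st$pa2[cand])
  mmB <- .mm_locus(donor$b1, donor$b2, st$pb1[cand], st$pb2[cand])
  mmDR <- .mm_locus(donor$dr1, donor$dr2, st$pdr1[cand], st$pdr2[cand])
  mm_tot <- mmA + mmB + mmDR

  need_scores <- scn$match != "hla_grade" || scn$priority == "score_lt"
  s <- if (need_scores)
    .surrogate_scores(donor$evec, st$Ep[cand, , drop = FALSE], ctx$w)
  else NULL

  tier <- if (scn$priority == "full_match") as.numeric(mm_tot == 0L)
  else as.numeric(s < scn$priority_threshold)
  hz_tier <- ifelse(tier > 0, st$hz[cand], 0L)

  match_pts <- if (scn$match == "hla_grade")
    hla_grade_points(mm_tot, w$match_budget)
  else match_points(s, scn$match_fn)
  if (scn$pediatric_double_match)
    match_pts <- match_pts * (1 + st$ped[cand])
  wait_days <- st$accrued[cand] + st$day - st$reg_day[cand]
  waiting_pts <- wait_days / 365 * w$waiting_per_year
  urgency_pts <- w$urgency * st$urgent[cand]
  national_pts <- w$national * (st$country[cand] == donor$country)
  balance_pts <- w$balance * st$net_bal[st$country[cand]]
  pediatric_pts <- w$pediatric * st$ped[cand]
  total <- match_pts + waiting_pts + urgency_pts + national_pts +
    balance_pts + st$mmp_pts[cand] + pediatric_pts

  o <- order(tier, hz_tier, total, wait_days, -cand, decreasing = TRUE)
  # ranked offer walk with constant per-candidate refusal probability
  if (scn$refusal_p == 0) {
    acc_pos <- 1L; refusals <- 0L
  } else {
    r <- stats::rgeom(1L, 1 - scn$refusal_p)
    if (r >= n_elig) {
      st$counters$offers <- st$counters$offers + n_elig
      st$counters$refusals <- st$counters$refusals + n_elig
      st$counters$discards <- st$counters$discards + 1L
      .log_event(st, "discard", donor, refusals = n_elig,
                 n_eligible = n_elig, reason = "all_refused")
      return(invisible(FALSE))
    }
    acc_pos <- r + 1L; refusals <- r
  }
  st$counters$offers <- st$counters$offers + acc_pos
  st$counters$refusals <- st$counters$refusals + refusals
  j <- o[acc_pos]            # position in cand of the acceptor
  rec <- cand[j]
  .poke(st, "active", rec, FALSE)
  st$n_active <- st$n_active - 1L
  st$counters$transplants <- st$counters$transplants + 1L
  rc_int <- st$country[rec]
  if (rc_int != donor$country) {
    st$exports[donor$country] <- st$exports[donor$country] + 1L
    st$imports[rc_int] <- st$imports[rc_int] + 1L
    st$net_bal[donor$country] <- st$net_bal[donor$country] + 1
    st$net_bal[rc_int] <- st$net_bal[rc_int] - 1
  }
  sc <- if (need_scores) s[j]
  else sum(ctx$w[donor$evec & !st$Ep[rec, ]])
  .log_event(st, "transplant", donor, rec,
             mm = c(mmA[j], mmB[j], mmDR[j]), score = sc,
             pts = c(match_pts[j], waiting_pts[j], urgency_pts[j],
                     balance_pts[j], national_pts[j], st$mmp_pts[rec],
                     pediatric_pts[j], total[j]),
             wait_days = wait_days[j], refusals = refusals,
             n_eligible = n_elig)
  invisible(TRUE)
}

#' Advance the simulation by one day
#'
#' Event order within a day is fixed (it matters for who is offerable the
#' same day): departures first, then new registrations, then donor arrivals
#' with allocation of each kidney in sequence. Kidney rankings are
#' recomputed between a two-kidney donor's offers because the first
#' acceptance removes a patient and may shift the country balance.
#'
#' @param st a `simulation_state` from [init_simulation()].
#' @return the state, invisibly (mutated in place).
#' @export
step_day <- function(st) {
  stopifnot(inherits(st, "simulation_state"))
  cfg <- st$cfg
  st$day <- st$day + 1L
  counts <- sample_daily_events(cfg)

  # departures: country sampled from the patient marginal, patient uniform
  # within country (HLA-independent outflow)
  if (counts$departures > 0L && st$n_active > 0L) {
    act <- which(st$active[seq_len(st$n_pat)])
    act_country <- st$country[act]
    pc <- unlist(cfg$patient_country[cfg$countries])
    for (k in seq_len(counts$departures)) {
      if (!length(act)) break
      ci <- .sample_cat(1L, pc)
      pool <- which(act_country == ci)
      if (!length(pool)) pool <- seq_along(act)
      pick <- pool[sample.int(length(pool), 1L)]
      dep <- act[pick]
      .poke(st, "active", dep, FALSE)
      st$n_active <- st$n_active - 1L
      st$counters$departures <- st$counters$departures + 1L
      act <- act[-pick]; act_country <- act_country[-pick]
    }
  }

  .add_patients(st, counts$registrations, reg_day = st$day)

  if (counts$donors > 0L) {
    ctx <- st$ctx
    haps <- .draw_pool(st, counts$donors)
    for (k in seq_len(counts$donors)) {
      st$donor_seq <- st$donor_seq + 1L
      ci <- .sample_cat(1L, unlist(cfg$donor_country[cfg$countries]))
      cc <- cfg$countries[ci]
      type <- .sample_cat(1L, unlist(cfg$donor_type[[cc]]))
      bg <- .sample_cat(1L, unlist(cfg$blood_group[[cc]]))
      kidneys <- c(1L, 2L)[.sample_cat(1L, unlist(cfg$kidneys_per_donor[[cc]]))]
      h1 <- haps[k, 1L]; h2 <- haps[k, 2L]
      donor <- list(id = st$donor_seq, h1 = h1, h2 = h2, country = ci,
                    type = type, bg = bg,
                    a1 = ctx$hA[h1], a2 = ctx$hA[h2],
                    b1 = ctx$hB[h1], b2 = ctx$hB[h2],
                    dr1 = ctx$hDR[h1], dr2 = ctx$hDR[h2],
                    ags = unique(c(ctx$hap_ags[[h1]], ctx$hap_ags[[h2]])),
                    evec = ctx$M[h1, ] | ctx$M[h2, ])
      st$counters$donors <- st$counters$donors + 1L
      for (kid in seq_len(kidneys)) {
        st$counters$kidneys <- st$counters$kidneys + 1L
        .allocate_kidney(st, donor)
      }
    }
  }

  # conservation identity: active = initial + registrations - departures -
  # transplants (counter form always; mask form optionally)
  expected <- st$initial_waitlist +
    (st$counters$registrations - st$initial_waitlist) -
    st$counters$departures - st$counters$transplants
  if (st$n_active != expected)
    stop("waiting-list conservation violated on day ", st$day)
  if (st$config$check_invariants &&
      sum(st$active[seq_len(st$n_pat)]) != st$n_active)
    stop("active-mask conservation violated on day ", st$day)

  if (st$day %% st$config$snapshot_every == 0L) .take_snapshot(st)
  invisible(st)
}

# internal: record a waiting-list snapshot
.take_snapshot <- function(st) {
  act <- which(st$active[seq_len(st$n_pat)])
  sizes <- tabulate(st$country[act], nbins = length(st$cfg$countries))
  wait <- st$accrued[act] + st$day - st$reg_day[act]
  snap <- c(list(day = st$day, total = length(act),
                 median_wait_days = if (length(act)) stats::median(wait) else NA_real_,
                 transplants = st$counters$transplants,
                 discards = st$counters$discards,
                 registrations = st$counters$registrations,
                 departures = st$counters$departures),
            stats::setNames(as.list(sizes),
                            paste0("size_", st$cfg$countries)))
  st$snapshots[[length(st$snapshots) + 1L]] <- snap
}

#' Run a complete simulation
#'
#' Initializes the chain (population synthesis, bootstrap) and advances it
#' day by day over the horizon, returning the event log, year-aligned
#' waiting-list snapshots and run summary.
#'
#' @param config a [simulation_config()].
#' @param quiet suppress the end-of-run summary line.
#' @return an `etkas_run`: list with `events` (one row per transplant or
#'   discard), `snapshots`, `summary`, `balance`, and the `config`.
#' @export
run_simulation <- function(config, quiet = TRUE) {
  st <- init_simulation(config)
  for (d in seq_len(config$horizon)) step_day(st)
  run <- finalize_run(st)
  if (!quiet)
    cat(sprintf(paste0("%s: %d days, %d transplants, %d discards, ",
                       "%.2f transplants/day, refusal fraction %.3f\n"),
                config$scenario$name, config$horizon,
                run$summary$transplants, run$summary$discards,
                run$summary$transplants / config$horizon,
                run$summary$refusal_fraction))
  run
}

#' Materialize the event log and summary of a simulation state
#'
#' @param st a `simulation_state`.
#' @return an `etkas_run`.
#' @export
finalize_run <- function(st) {
  ev <- st$ev
  n <- ev$n
  events <- data.frame(
    day = ev$day[seq_len(n)], type = ev$type[seq_len(n)],
    donor_id = ev$donor_id[seq_len(n)],
    donor_country = ev$donor_country[seq_len(n)],
    donor_bg = ev$donor_bg[seq_len(n)],
    donor_type = ev$donor_type[seq_len(n)],
    donor_h1 = ev$donor_h1[seq_len(n)],
    donor_h2 = ev$donor_h2[seq_len(n)],
    recipient_id = ev$recipient_id[seq_len(n)],
    recipient_country = ev$recipient_country[seq_len(n)],
    mmA = ev$mmA[seq_len(n)], mmB = ev$mmB[seq_len(n)],
    mmDR = ev$mmDR[seq_len(n)],
    score = ev$score[seq_len(n)], wait_days = ev$wait_days[seq_len(n)],
    pts_match = ev$pts_match[seq_len(n)],
    pts_waiting = ev$pts_waiting[seq_len(n)],
    pts_urgency = ev$pts_urgency[seq_len(n)],
    pts_balance = ev$pts_balance[seq_len(n)],
    pts_national = ev$pts_national[seq_len(n)],
    pts_mmp = ev$pts_mmp[seq_len(n)],
    pts_pediatric = ev$pts_pediatric[seq_len(n)],
    pts_total = ev$pts_total[seq_len(n)],
    refusals = ev$refusals[seq_len(n)],
    n_eligible = ev$n_eligible[seq_len(n)],
    reason = ev$reason[seq_len(n)],
    stringsAsFactors = FALSE)
  snapshots <- if (length(st$snapshots))
    do.call(rbind, lapply(st$snapshots, function(s)
      as.data.frame(s, stringsAsFactors = FALSE)))
  else NULL
  cnt <- st$counters
  summary <- list(
    scenario = st$scn$name, days = st$day,
    transplants = cnt$transplants, discards = cnt$discards,
    kidneys = cnt$kidneys, donors = cnt$donors,
    registrations = cnt$registrations - st$initial_waitlist,
    departures = cnt$departures,
    waitlist_final = st$n_active, waitlist_initial = st$initial_waitlist,
    offers = cnt$offers, refusals = cnt$refusals,
    refusal_fraction = if (cnt$offers > 0) cnt$refusals / cnt$offers else NA_real_,
    transplants_per_day = cnt$transplants / max(1L, st$day))
  balance <- data.frame(country = st$cfg$countries,
                        exports = as.integer(st$exports),
                        imports = as.integer(st$imports),
                        net = as.numeric(st$net_bal),
                        stringsAsFactors = FALSE)
  structure(list(events = events, snapshots = snapshots, summary = summary,
                 balance = balance, config = st$config),
            class = "etkas_run")
}

#' @export
print.etkas_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Simulated %s run: %d days, %d transplants ",
                     "(%.2f/day), %d discards, refusal fraction %.3f, ",
                     "final waiting list %d\n"),
              s$scenario, s$days, s$transplants, s$transplants_per_day,
              s$discards, s$refusal_fraction, s$waitlist_final))
  invisible(x)
}

#' Restrict a run's event log to the post-burn-in window
#'
#' The first years of a run are dominated by the bootstrapped waiting list;
#' match-grade distributions stabilize after about two years, so
#' steady-state metrics exclude the burn-in.
#'
#' @param run an `etkas_run`.
#' @param years burn-in length in years.
#' @return the transplant/discard events with `day > years * 365`.
#' @export
post_burn_in <- function(run, years = 2) {
  cutoff <- years * 365
  if (cutoff >= run$summary$days)
    stop("burn-in (", years, " years) is not shorter than the simulated ",
         "horizon (", run$summary$days, " days)")
  run$events[run$events$day > cutoff, , drop = FALSE]
}

#' Write a run's event log, snapshots and manifest to a directory
#'
#' @param run an `etkas_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(run$snapshots))
    utils::write.csv(run$snapshots, file.path(dir, "snapshots.csv"),
                     row.names = FALSE)
  utils::write.csv(run$balance, file.path(dir, "balance.csv"),
                   row.names = FALSE)
  manifest <- list(scenario = run$config$scenario$name,
                   seed = run$config$seed,
                   horizon_days = run$config$horizon,
                   demographics_profile = run$config$demographics$profile,
                   package_version = as.character(utils::packageVersion("etkasim")),
                   summary = run$summary)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
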