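# Shared fixtures and cached simulation runs. Everything is generated in
# code; the heavyweight study-scale runs are computed once per test session
# and reused across test files.

.tcache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  v <- get0(key, envir = .tcache, inherits = FALSE)
  if (is.null(v)) {
    v <- force(expr)
    assign(key, v, envir = .tcache)
  }
  v
}

# hand-built serology map exercising splits, broad collapse and homozygosity
toy_serology <- function() {
  serology_map(data.frame(
    locus = c("A", "A", "A", "B", "B", "B", "C", "C",
              "DRB1", "DRB1", "DRB1", "DQB1", "DQB1"),
    allele = c("A*01", "A*02", "A*03", "B*01", "B*02", "B*03", "C*01", "C*02",
               "DRB1*01", "DRB1*02", "DRB1*03", "DQB1*01", "DQB1*02"),
    broad = c("A1", "A1", "A3", "B1", "B1", "B3", "Cw1", "Cw2",
              "DR1", "DR1", "DR3", "DQ1", "DQ2"),
    split = c("A101", "A102", "A3", "B101", "B102", "B3", "Cw1", "Cw2",
              "DR101", "DR102", "DR3", "DQ1", "DQ2"),
    stringsAsFactors = FALSE))
}

# genotype builder with defaults covering every locus
toy_genotype <- function(A = "A*01", B = "B*01", C = "C*01",
                         DRB1 = "DRB1*01", DQB1 = "DQB1*01") {
  genotype_from_alleles(list(A = A, B = B, C = C, DRB1 = DRB1, DQB1 = DQB1))
}

# small eplet table over the toy alleles, with round weights
toy_eplets <- function() {
  eplet_table(data.frame(
    eplet  = c("e1", "e1", "e2", "e3", "e3", "e4", "e5", "e5", "e6"),
    allele = c("A*01", "A*02", "A*02", "B*01", "B*02", "B*03",
               "DRB1*01", "DRB1*02", "DRB1*03"),
    weight = c(10, 10, 20, 5, 5, 8, 12, 12, 30),
    stringsAsFactors = FALSE))
}

tiny_fx <- function() memo("tiny_fx", fixture_set("tiny", seed = 42))

tiny_demo <- function() default_demographics_config("tiny")

tiny_run <- function(scenario = "ETKAS", years = 1, seed = 5) {
  memo(paste("tiny_run", scenario, years, seed), {
    run_simulation(simulation_config(
      scenario, years = years, seed = seed, demographics = tiny_demo(),
      fixtures = tiny_fx()))
  })
}

# study-scale baseline: 10-year ETKAS with the default demographics and the
# default fixture profile; state kept for post-hoc safety audits
reference_etkas <- function() {
  memo("reference_etkas", {
    config <- simulation_config("ETKAS", years = 10, seed = 11)
    st <- init_simulation(config)
    for (d in seq_len(config$horizon)) step_day(st)
    list(run = finalize_run(st), st = st)
  })
}

# study-scale epitope-matching scenarios (shorter horizon: 2 burn-in years
# plus a 2-year analysis window)
reference_pir <- function(scenario) {
  memo(paste("reference_pir", scenario), {
    run_simulation(simulation_config(scenario, years = 4, seed = 11))
  })
}

# analysis window of a run: transplants in years (from, to]
window_tx <- function(run, from_year, to_year) {
  ev <- if (inherits(run, "etkas_run")) run$events else run
  ev[ev$type == "transplant" & ev$day > from_year * 365 &
       ev$day <= to_year * 365, , drop = FALSE]
}
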