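# Eplet mismatching, sensitization (virtual PRA), the surrogate epitope
# scorer, match-point functions, the genotype panel, the risk-profile
# weighted median and both mismatch-probability mappings.

test_that("eplet sets and interlocus mismatch follow set semantics", {
  tab <- toy_eplets()
  g1 <- toy_genotype(A = "A*01", B = "B*01", DRB1 = "DRB1*01")
  expect_setequal(eplet_set(g1, tab), c("e1", "e3", "e5"))
  expect_length(eplet_mismatch(g1, g1, tab), 0L)

  # donor carries {e1,e2} via A*02, recipient carries {e1} via A*01 -> {e2}
  d <- toy_genotype(A = "A*02", B = "B*01", DRB1 = "DRB1*01")
  r <- toy_genotype(A = "A*01", B = "B*01", DRB1 = "DRB1*01")
  expect_equal(eplet_mismatch(d, r, tab), "e2")

  # brute-force oracle on a 3-allele toy: enumerate both repertoires by hand
  d2 <- toy_genotype(A = c("A*01", "A*02"), B = "B*03", DRB1 = "DRB1*03")
  r2 <- toy_genotype(A = "A*01", B = "B*01", DRB1 = "DRB1*01")
  # donor eplets: e1,e2 (A) + e4 (B*03) + e6 (DRB1*03); recipient: e1,e3,e5
  expect_setequal(eplet_mismatch(d2, r2, tab), c("e2", "e4", "e6"))

  # alleles missing from the table contribute nothing
  miss <- toy_genotype(A = "A*03", B = "B*01", DRB1 = "DRB1*01")
  expect_setequal(eplet_set(miss, tab), c("e3", "e5"))
})

test_that("eplet population frequencies are carrier fractions", {
  tab <- toy_eplets()
  g_e1 <- toy_genotype(A = "A*01", B = "B*03", DRB1 = "DRB1*03")
  g_no <- toy_genotype(A = "A*03", B = "B*03", DRB1 = "DRB1*03")
  pop <- list(g_e1, g_e1, g_no, g_no)
  f <- eplet_frequencies(tab, pop)
  expect_equal(f[["e1"]], 0.5)
  expect_equal(f[["e4"]], 1.0)   # B*03 everywhere
  expect_equal(f[["e2"]], 0.0)   # A*02 nowhere
  expect_equal(f[["e6"]], 1.0)
  expect_error(eplet_frequencies(tab, list()), "empty")

  # population-scale path agrees with the per-genotype path
  fx <- tiny_fx()
  pop2 <- sample_population(fx$haplotypes, 40, seed = 4)
  f_fast <- eplet_frequencies(fx$eplets, pop2)
  f_slow <- eplet_frequencies(fx$eplets,
                              lapply(1:40, function(i) genotype(pop2, i)))
  expect_equal(f_fast, f_slow)
})

test_that("sensitization reaches the target PRA by accumulated eplet frequency", {
  tab <- toy_eplets()
  sero <- toy_serology()
  pat <- toy_genotype(A = "A*01", B = "B*01", DRB1 = "DRB1*01")
  freqs <- c(e1 = 0.6, e2 = 0.25, e3 = 0.5, e4 = 0.1, e5 = 0.7, e6 = 0.3)

  expect_length(assign_unacceptables(pat, 0, tab, freqs, sero), 0L)

  # replay the seeded draw: the accumulated frequency must reach the target
  # exactly at the last drawn eplet and not before
  ua <- assign_unacceptables(pat, 50, tab, freqs, sero, seed = 99)
  drawn <- attr(ua, "eplets")
  cum <- cumsum(freqs[drawn])
  expect_gte(cum[length(cum)], 0.5)
  if (length(cum) > 1) expect_lt(cum[length(cum) - 1], 0.5)
  expect_true(all(drawn %in% c("e2", "e4", "e6")))  # non-self only

  # pool exhaustion: target unreachable -> every non-self eplet drawn
  ua2 <- assign_unacceptables(pat, 100, tab, c(e1 = 0, e2 = 0.1, e3 = 0,
                                               e4 = 0.05, e5 = 0, e6 = 0.02),
                              sero, seed = 1)
  expect_setequal(attr(ua2, "eplets"), c("e2", "e4", "e6"))

  # self antigens are never returned, whatever the draw
  self_ags <- c("A|A1", "A|A101", "B|B1", "B|B101", "DRB1|DR1", "DRB1|DR101")
  for (s in 1:10) {
    u <- assign_unacceptables(pat, 80, tab, freqs, sero, seed = s)
    expect_length(intersect(u, self_ags), 0L)
  }
})

test_that("realized PRA counts genotypes displaying an unacceptable antigen", {
  fx <- tiny_fx()
  pop <- sample_population(fx$haplotypes, 200, seed = 6)
  expect_equal(realized_pra(character(0), pop, fx$serology), 0)

  # an antigen carried by every haplotype is rejected by everyone
  all_broads <- unique(unlist(lapply(seq_len(nrow(fx$haplotypes)), function(i)
    antigen_set(genotype(structure(list(haps = cbind(i, i),
                                        table = fx$haplotypes),
                                   class = "genotype_population"), 1),
                "A", "broad", fx$serology))))
  if (length(all_broads) == 1L)
    expect_equal(realized_pra(paste0("A|", all_broads), pop, fx$serology), 1)

  # hand-counted toy: unacceptable = broad of haplotype 1's A allele
  a1 <- fx$haplotypes$A[1]
  br <- fx$serology$table$broad[fx$serology$table$allele == a1 &
                                  fx$serology$table$locus == "A"]
  carriers <- fx$haplotypes$A %in% fx$serology$table$allele[
    fx$serology$table$locus == "A" & fx$serology$table$broad == br]
  expected <- mean(carriers[pop$haps[, 1]] | carriers[pop$haps[, 2]])
  expect_equal(realized_pra(paste0("A|", br), pop, fx$serology), expected)
})

test_that("surrogate scorer is deterministic, zero only at identity, and cached", {
  tab <- toy_eplets()
  sc <- surrogate_scorer(tab)
  g <- toy_genotype(A = "A*01", B = "B*01", DRB1 = "DRB1*01")
  expect_identical(epitope_score(sc, g, g), 0)

  d <- toy_genotype(A = "A*02", B = "B*01", DRB1 = "DRB1*01")
  s1 <- epitope_score(sc, d, g)
  expect_equal(s1, 20)  # e2 (weight 20) is the only mismatched eplet

  # adding a mismatched allele never decreases the score
  d2 <- toy_genotype(A = "A*02", B = c("B*01", "B*03"), DRB1 = "DRB1*01")
  expect_gte(epitope_score(sc, d2, g), s1)

  # cache: second lookup bit-identical, one entry per ordered pair seen
  expect_identical(epitope_score(sc, d, g), s1)
  expect_lte(length(ls(sc$cache)), 3 * 3)

  # vectorized path used by the simulator agrees with the scalar contract
  fx <- tiny_fx()
  ctx <- sim_context(fx$haplotypes, fx$serology, fx$eplets)
  pop <- sample_population(fx$haplotypes, 30, seed = 8)
  sfx <- surrogate_scorer(fx$eplets)
  for (i in 1:10) {
    dg <- genotype(pop, i)
    dvec <- ctx$M[dg$hap[1], ] | ctx$M[dg$hap[2], ]
    R <- ctx$M[pop$haps[11:30, 1], , drop = FALSE] |
      ctx$M[pop$haps[11:30, 2], , drop = FALSE]
    fast <- etkasim:::.surrogate_scores(dvec, R, ctx$w)
    slow <- vapply(11:30, function(j)
      epitope_score(sfx, dg, genotype(pop, j)), numeric(1))
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("match-point functions honor the printed strata and formulas", {
  f_strata <- match_point_function("strata")
  expect_equal(match_points(c(5, 20, 50, 100), f_strata),
               c(400, 266, 133, 0))
  # boundary convention: left-closed, last bound inclusive
  expect_equal(match_points(c(0, 9, 35, 90, 90.0001), f_strata),
               c(400, 266, 133, 133, 0))

  f_exp <- match_point_function("exponential")
  expect_equal(match_points(0, f_exp), 400 * 0.958)
  grid <- seq(0, 300, by = 0.5)
  expect_equal(match_points(grid, f_exp), 400 * 0.958 * exp(-0.032 * grid))

  f_lin <- match_point_function("linear")
  expect_equal(match_points(0, f_lin), 400 * (1 - 1 / 90))
  expect_equal(match_points(89, f_lin), 0)
  expect_equal(match_points(200, f_lin), 0)
  f_lin0 <- match_point_function("linear", shifted = FALSE)
  expect_equal(match_points(0, f_lin0), 400)
  expect_equal(match_points(90, f_lin0), 0)

  # every variant: bounded in [0,400], non-increasing, zero above 90 where
  # the shape demands it
  for (f in list(f_strata, f_exp, f_lin, f_lin0)) {
    pts <- match_points(grid, f)
    expect_true(all(pts >= 0 & pts <= 400))
    expect_true(all(diff(pts) <= 1e-12))
  }
  expect_true(all(match_points(seq(90.5, 300, 0.5), f_strata) == 0))
  expect_true(all(match_points(seq(90.5, 300, 0.5), f_lin) == 0))
  expect_error(match_points(-1, f_strata), "negative")

  expect_equal(hla_grade_points(0), 400)
  expect_equal(hla_grade_points(3), 200)
  expect_equal(hla_grade_points(6), 0)
})

test_that("genotype panel enumerates top-haplotype pairs under random mating", {
  fx <- tiny_fx()
  tab <- fx$haplotypes
  p1 <- build_genotype_panel(tab, 1)
  expect_equal(panel_size(p1), 1L)
  expect_equal(p1$freq, 1)
  expect_equal(p1$haps[1, 1], p1$haps[1, 2])

  p3 <- build_genotype_panel(tab, 3)
  expect_equal(panel_size(p3), 6L)  # 3 homozygous + 3 heterozygous
  f <- tab$freq[order(tab$freq, decreasing = TRUE)[1:3]]
  raw <- c(f[1]^2, 2 * f[1] * f[2], 2 * f[1] * f[3],
           f[2]^2, 2 * f[2] * f[3], f[3]^2)
  expect_equal(sort(p3$freq), sort(raw / sum(raw)))
  expect_lt(abs(sum(p3$freq) - 1), 1e-9)

  expect_warning(pk <- build_genotype_panel(tab, 1000), "clipped")
  expect_equal(panel_size(pk), nrow(tab) * (nrow(tab) + 1) / 2)
})

test_that("risk-profile median is the frequency-weighted lower median", {
  fx <- tiny_fx()
  sc <- surrogate_scorer(fx$eplets)
  p1 <- build_genotype_panel(fx$haplotypes, 1)
  pat <- genotype(sample_population(fx$haplotypes, 1, seed = 12), 1)
  expect_equal(risk_profile_median(pat, p1, sc),
               epitope_score(sc, panel_genotype(p1, 1), pat))

  expect_equal(weighted_median_lower(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median_lower(c(5, 50), c(0.9, 0.1)), 5)

  # brute-force oracle: expand rational weights into a sample and take its
  # lower median, for random small panels
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    x <- round(runif(n, 0, 100), 1)
    counts <- sample(1:6, n, replace = TRUE)
    expanded <- sort(rep(x, counts))
    brute <- expanded[which(seq_along(expanded) / length(expanded) >= 0.5)[1]]
    expect_equal(weighted_median_lower(x, counts / sum(counts)), brute)
  }
})

test_that("mismatch probabilities clamp, vanish and stay monotone", {
  pm <- function(bg, rp_, rp) pirche_mmp(rp, mmp_params(bg, rp_))
  expect_equal(pm(0.4, 0.7, 250), 1)
  expect_equal(pm(1, 1, 0), 0)
  expect_equal(pm(0, 0.5, 10), 1)

  grid_rp <- seq(0, 250, by = 10)
  vals <- pm(0.45, 0.8, grid_rp)
  expect_true(all(diff(vals) >= -1e-12))      # non-decreasing in rp
  for (bgs in seq(0.1, 1, 0.1)) {
    expect_true(all(diff(pm(seq(0.1, 1, 0.1), bgs, 60)) <= 1e-12))
    expect_true(all(diff(pm(bgs, seq(0.1, 1, 0.1), 60)) <= 1e-12))
  }

  expect_equal(hla_mmp(1, mmp_params(1, 1)), 0)
  expect_equal(hla_mmp(0, mmp_params(0.5, 0.5)), 1)
  pf <- seq(0, 1, 0.05)
  expect_true(all(diff(hla_mmp(pf, mmp_params(0.45, 0.8))) <= 1e-12))

  expect_equal(relative_pra(0), 1)
  expect_equal(relative_pra(85), 0.15)
})
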