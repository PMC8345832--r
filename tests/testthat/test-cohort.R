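# Demographics configuration, waiting-list bootstrap and the daily
# patient/donor event-stream samplers.

test_that("bundled demographics configurations validate and carry the study constants", {
  cfg <- default_demographics_config()
  expect_s3_class(cfg, "demographics_config")
  expect_equal(cfg$population_size, 400000L)
  expect_equal(cfg$waitlist_size, 10400L)
  expect_equal(cfg$rates$kidneys_per_day, 6.2)
  expect_equal(cfg$rates$departures_per_day, 10.5)
  expect_equal(cfg$rates$registrations_per_day, 16.7)
  expect_length(cfg$countries, 8L)

  # YAML round-trip revalidates
  path <- withr::local_tempfile(fileext = ".yaml")
  write_demographics_config(cfg, path)
  reread <- read_demographics_config(path)
  expect_equal(reread$rates, cfg$rates)
  expect_equal(reread$blood_group, cfg$blood_group)

  bad <- unclass(cfg)
  bad$patient_country$DE <- bad$patient_country$DE + 0.05
  expect_error(validate_demographics_config(bad), "sums to")
})

test_that("waiting-time draws stay inside their intervals and recover the masses", {
  iv <- list(c(0, 1))
  x <- sample_waiting_time(iv, 1, n = 200)
  expect_true(all(x >= 0 & x <= 365))

  iv3 <- list(c(0, 2), c(2, 5), c(5, 9))
  probs <- c(0.45, 0.40, 0.15)
  set.seed(31)
  y <- sample_waiting_time(iv3, probs, n = 10000)
  expect_true(all(y >= 0 & y <= 9 * 365))   # open-ended interval ends at 9y
  shares <- c(mean(y < 2 * 365), mean(y >= 2 * 365 & y < 5 * 365),
              mean(y >= 5 * 365))
  expect_true(all(abs(shares - probs) < 3 * sqrt(probs * (1 - probs) / 10000)))
})

test_that("bootstrap removes patients from the pool and respects the conditional structure", {
  fx <- tiny_fx()
  ctx <- sim_context(fx$haplotypes, fx$serology, fx$eplets)
  cfg <- tiny_demo()
  pop <- sample_population(fx$haplotypes, 5000, seed = 17)
  bs <- bootstrap_waitlist(pop, cfg, ctx, seed = 17)
  expect_equal(nrow(bs$waitlist), cfg$waitlist_size)
  expect_equal(population_size(bs$population),
               5000L - cfg$waitlist_size)
  expect_true(all(bs$waitlist$pra >= 0 & bs$waitlist$pra <= 100))
  expect_true(all(bs$waitlist$accrued_days >= 0 &
                    bs$waitlist$accrued_days <= 9 * 365))
  expect_identical(bs$waitlist$pediatric,
                   bs$waitlist$age < cfg$pediatric_age)
  # sensitization only for PRA > 0
  n_ua <- lengths(bs$waitlist$unacceptables)
  expect_true(all(n_ua[bs$waitlist$pra == 0] == 0L))

  # zero-size bootstrap leaves the pool untouched
  cfg0 <- cfg; cfg0$waitlist_size <- 0L
  bs0 <- bootstrap_waitlist(pop, cfg0, ctx, seed = 1)
  expect_equal(nrow(bs0$waitlist), 0L)
  expect_equal(population_size(bs0$population), 5000L)

  # a config with all PRA mass at zero yields no unacceptables at all
  cfg_p0 <- unclass(cfg)
  for (cc in cfg_p0$countries)
    cfg_p0$pra$by_country[[cc]] <- list(p0 = 1, low = 0, high = 0, vhigh = 0)
  cfg_p0 <- validate_demographics_config(cfg_p0)
  bs_p0 <- bootstrap_waitlist(pop, cfg_p0, ctx, seed = 2)
  expect_true(all(lengths(bs_p0$waitlist$unacceptables) == 0L))

  expect_error(bootstrap_waitlist(sample_population(fx$haplotypes, 10, seed = 1),
                                  cfg, ctx), "smaller")

  # determinism
  bs2 <- bootstrap_waitlist(pop, cfg, ctx, seed = 17)
  expect_identical(bs$waitlist, bs2$waitlist)
})

test_that("bootstrap attributes follow their (in)dependence structure", {
  fx <- tiny_fx()
  ctx <- sim_context(fx$haplotypes, fx$serology, fx$eplets)
  # push two countries' blood groups far apart so the conditional structure
  # is statistically visible at a 6,000-patient bootstrap
  cfg <- unclass(default_demographics_config("tiny"))
  cfg$waitlist_size <- 6000L
  cfg$patient_country <- as.list(c(AT = 0.5, BE = 0.5, HR = 0, DE = 0,
                                   HU = 0, LU = 0, NL = 0, SI = 0))
  cfg$blood_group$AT <- list(O = 0.70, A = 0.20, B = 0.05, AB = 0.05)
  cfg$blood_group$BE <- list(O = 0.20, A = 0.60, B = 0.10, AB = 0.10)
  cfg <- validate_demographics_config(cfg)
  pop <- sample_population(fx$haplotypes, 8000, seed = 19)
  bs <- bootstrap_waitlist(pop, cfg, ctx, seed = 19)
  wl <- bs$waitlist
  for (cc in c("AT", "BE")) {
    obs <- table(factor(wl$blood_group[wl$country == cc],
                        levels = c("O", "A", "B", "AB")))
    gof <- suppressWarnings(
      chisq.test(obs, p = unlist(cfg$blood_group[[cc]])))
    expect_gt(gof$p.value, 0.001)
  }
  # age is country-independent: similar means across the two countries
  expect_lt(abs(mean(wl$age[wl$country == "AT"]) -
                  mean(wl$age[wl$country == "BE"])), 3)
})

test_that("donor sampling draws from the pool with country-conditional attributes", {
  fx <- tiny_fx()
  cfg <- unclass(tiny_demo())
  cfg$donor_country <- as.list(c(AT = 0, BE = 0, HR = 0, DE = 1,
                                 HU = 0, LU = 0, NL = 0, SI = 0))
  cfg$kidneys_per_donor$DE <- list(k1 = 0, k2 = 1)
  cfg <- validate_demographics_config(cfg)
  pop <- sample_population(fx$haplotypes, 500, seed = 23)
  set.seed(23)
  for (i in 1:5) {
    out <- sample_donor(pop, cfg, day = i, id = i)
    expect_equal(out$donor$country, "DE")
    expect_equal(out$donor$kidneys, 2L)
    expect_equal(population_size(out$population), population_size(pop) - 1L)
    pop <- out$population
  }

  # DBD/DCD split approximates the per-country table over many draws
  cfg2 <- unclass(tiny_demo())
  cfg2$donor_country <- as.list(c(AT = 0, BE = 0, HR = 0, DE = 0,
                                  HU = 0, LU = 0, NL = 1, SI = 0))
  cfg2$donor_type$NL <- list(DBD = 0.5, DCD = 0.5)
  cfg2 <- validate_demographics_config(cfg2)
  pop2 <- sample_population(fx$haplotypes, 3000, seed = 29)
  set.seed(29)
  types <- character(2000)
  for (i in 1:2000) {
    out <- sample_donor(pop2, cfg2, day = 1, id = i)
    types[i] <- out$donor$donor_type
    pop2 <- out$population
  }
  expect_lt(abs(mean(types == "DCD") - 0.5), 3 * sqrt(0.25 / 2000))

  empty_pop <- structure(list(haps = matrix(integer(0), 0, 2),
                              table = fx$haplotypes),
                         class = "genotype_population")
  expect_error(sample_donor(empty_pop, tiny_demo()), "exhausted")
})

test_that("daily event counts recover the configured rates in the long run", {
  cfg <- default_demographics_config()
  ek <- expected_kidneys_per_donor(cfg)
  expect_true(ek > 1 && ek < 2)

  set.seed(37)
  days <- replicate(10000, unlist(sample_daily_events(cfg)))
  reg <- mean(days["registrations", ])
  dep <- mean(days["departures", ])
  kid <- mean(days["donors", ]) * ek
  expect_lt(abs(reg - 16.7), 3 * sqrt(16.7 / 10000))
  expect_lt(abs(dep - 10.5), 3 * sqrt(10.5 / 10000))
  expect_lt(abs(kid - 6.2), 3 * sqrt(6.2 / 10000) * ek)

  cfg0 <- unclass(cfg)
  cfg0$rates$departures_per_day <- 0
  cfg0 <- validate_demographics_config(cfg0)
  set.seed(38)
  expect_true(all(replicate(50, sample_daily_events(cfg0)$departures) == 0L))
})
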