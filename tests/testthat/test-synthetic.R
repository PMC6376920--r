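test_that("frequency spectra live on the repeat grid and normalize", {
  panel <- toy_panel(5)
  sp <- simulate_frequency_panel(panel, n_alleles = 6, concentration = 1,
                                 seed = 11)
  expect_named(sp, panel$name)
  for (s in sp) {
    expect_equal(sum(s$freqs), 1, tolerance = 1e-12)
    expect_true(all(diff(s$alleles) == 2L))
    expect_true(all(s$alleles > 80L & s$alleles < 400L))
  }
  # degenerate simplex
  one <- simulate_frequency_panel(panel, n_alleles = 1, seed = 3)
  expect_equal(one$L1$freqs, 1)
  # determinism
  expect_identical(sp, simulate_frequency_panel(panel, 6, 1, seed = 11))
  expect_error(simulate_frequency_panel(panel, 6, concentration = 0), "positive")
})

test_that("HWE genotype simulation matches the binomial heterozygosity oracle", {
  panel <- toy_panel(1)
  sp <- list(L1 = allele_spectrum("L1", c(150L, 152L), c(0.5, 0.5)))
  het <- vapply(seq_len(10000), function(i) {
    g <- simulate_variety(sp, "V", seed = i)
    g$calls$L1[[1]] != g$calls$L1[[2]]
  }, logical(1))
  # P(het) = 2pq = 0.5; 3 standard errors at n = 10000
  expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / 10000))
  # forced draw from a single-allele spectrum
  mono <- simulate_variety(list(allele_spectrum("L1", 150L, 1)), "V", seed = 1)
  expect_equal(mono$calls$L1, c(150L, 150L))
  expect_identical(simulate_variety(sp, "V", seed = 5),
                   simulate_variety(sp, "V", seed = 5))
})

test_that("detection probability follows the dropout law", {
  m <- dropout_model()
  expect_equal(detection_probability(m, 1, 0), 0.98)
  expect_equal(detection_probability(m, 0.012, 1), 0.4801628,
               tolerance = 1e-6)
  ages <- 0:10
  p <- detection_probability(m, rep(0.5, length(ages)), ages)
  expect_true(all(diff(p) < 0))
  expect_error(detection_probability(m, 0, 1), "proportion")
  expect_error(dropout_model(p_dropin = 0.6), "p_dropin")
})

test_that("the no-noise limit reproduces the blend's allele union exactly", {
  panel <- toy_panel(5)
  sp <- simulate_frequency_panel(panel, 8, seed = 2)
  v1 <- simulate_variety(sp, "V1", seed = 21)
  v2 <- simulate_variety(sp, "V2", seed = 22)
  noiseless <- dropout_model(p_base = 1, gamma = 0, lam = 0, p_dropin = 0)
  blend <- blend_spec("W", c(V1 = 0.6, V2 = 0.4), age_years = 10,
                      n_replicas = 4)
  reps <- simulate_wine_replicas(blend, list(v1, v2), noiseless, sp, seed = 9)
  expect_length(reps, 4L)
  for (obs in reps) for (locus in panel$name) {
    truth <- sort(unique(c(v1$calls[[locus]], v2$calls[[locus]])))
    sz <- obs$peaks[[locus]]$size
    expect_equal(sort(as.integer(round(sz))), truth)
    expect_true(all(abs(sz - round(sz)) <= 0.4))
  }
  expect_identical(
    simulate_wine_replicas(blend, list(v1, v2), noiseless, sp, seed = 9),
    reps)
})

test_that("empirical detection frequency converges to the model probability", {
  panel <- toy_panel(1)
  sp <- list(L1 = allele_spectrum("L1", c(150L, 160L), c(0.5, 0.5)))
  v <- variety_genotype("V1", list(L1 = c(150L, 160L)))
  model <- dropout_model(p_dropin = 0)
  blend <- blend_spec("W", c(V1 = 1), age_years = 0, n_replicas = 3)
  hits <- 0L; total <- 0L
  for (i in seq_len(334)) {   # 334 x 3 replicas ~ 1000 trials
    reps <- simulate_wine_replicas(blend, list(v), model, sp, seed = 1000 + i)
    for (obs in reps) {
      total <- total + 2L
      sz <- obs$peaks$L1$size
      if (!is.null(sz)) hits <- hits + sum(c(150, 160) %in% round(sz))
    }
  }
  p <- 0.98
  expect_lt(abs(hits / total - p), 3 * sqrt(p * (1 - p) / total))
})

test_that("drop-in alleles never coincide with a true contributing allele", {
  panel <- toy_panel(3)
  sp <- simulate_frequency_panel(panel, 6, seed = 5)
  v <- simulate_variety(sp, "V1", seed = 51)
  model <- dropout_model(p_base = 1, gamma = 0, lam = 0, p_dropin = 0.5 - 1e-9)
  blend <- blend_spec("W", c(V1 = 1), n_replicas = 3)
  for (i in 1:50) {
    reps <- simulate_wine_replicas(blend, list(v), model, sp, seed = i)
    for (obs in reps) for (locus in names(obs$peaks)) {
      binned <- round(obs$peaks[[locus]]$size)
      extra <- setdiff(binned, v$calls[[locus]])
      # any extra peak must come from the spectrum, never equal a true allele
      expect_true(all(extra %in% setdiff(sp[[locus]]$alleles,
                                         v$calls[[locus]])))
    }
  }
})

test_that("blend specifications are validated", {
  expect_error(blend_spec("W", c(V1 = 0.5, V2 = 0.4)), "sum to 1")
  expect_error(blend_spec("W", c(V1 = 1), n_replicas = 2), "at least 3")
  expect_error(blend_spec("W", c(1)), "named")
  expect_error(
    simulate_wine_replicas(blend_spec("W", c(V9 = 1)), list(), dropout_model(),
                           list(allele_spectrum("L1", 150L, 1))),
    "V9")
})
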