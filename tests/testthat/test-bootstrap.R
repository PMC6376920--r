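# two clean groups of near-identical profiles; every locus supports the split
two_group_profiles <- function(jitter = FALSE, seed = 1) {
  panel <- toy_panel(6)
  base1 <- lapply(1:6, function(i) c(150L, 152L))
  base2 <- lapply(1:6, function(i) c(300L, 302L))
  names(base1) <- names(base2) <- panel$name
  p <- list(
    variety_genotype("A1", base1), variety_genotype("A2", base1),
    variety_genotype("B1", base2), variety_genotype("B2", base2))
  if (jitter) {
    set.seed(seed)
    p <- lapply(p, function(s) {
      s$calls <- lapply(s$calls, function(a) a + 2L * sample(0:1, 2, TRUE))
      s
    })
  }
  p
}

test_that("a topology supported by every locus gets bp = 1 at all scales", {
  profs <- two_group_profiles()
  s <- multiscale_bootstrap(profs, method = "nj", scales = c(0.5, 1, 1.4),
                            n_boot = 50, min_cotyped = 1, seed = 5)
  expect_true(all(s$bp_by_scale == 1))
  # integer accounting: counts are bp * n_boot exactly
  expect_identical(s$counts, matrix(50L, nrow(s$counts), ncol(s$counts),
                                    dimnames = dimnames(s$counts)))
})

test_that("bootstrap input validation", {
  profs <- two_group_profiles()
  expect_error(multiscale_bootstrap(profs, n_boot = 0), "n_boot")
  expect_error(multiscale_bootstrap(profs[1:2]), "at least 3")
  expect_error(multiscale_bootstrap(profs, scales = c(0.01, 1), n_boot = 5),
               "zero loci")
  one_locus <- lapply(profs, function(s) {
    s$calls <- s$calls["L1"]; s
  })
  expect_error(multiscale_bootstrap(one_locus, n_boot = 5), "at least 2 loci")
})

test_that("the true bipartition outranks false ones in a noisy two-group dataset", {
  profs <- two_group_profiles(jitter = TRUE, seed = 9)
  s <- multiscale_bootstrap(profs, method = "nj", scales = 1, n_boot = 200,
                            min_cotyped = 2, seed = 10)
  truth_key <- paste(sort(c("B1", "B2")), collapse = "|")
  expect_true(truth_key %in% names(s$clusters))
  others <- setdiff(names(s$bp), truth_key)
  if (length(others))
    expect_gt(s$bp[[truth_key]], max(s$bp[others]))
  # determinism under a fixed seed
  s2 <- multiscale_bootstrap(profs, method = "nj", scales = 1, n_boot = 200,
                             min_cotyped = 2, seed = 10)
  expect_identical(s$counts, s2$counts)
})

test_that("AU fit: flat bp = 0.5 gives v = c = 0 and au = 0.5 exactly", {
  scales <- seq(0.5, 1.4, by = 0.1)
  s <- structure(list(
    bp_by_scale = matrix(0.5, 1, 10, dimnames = list("X|Y", paste0("r", scales))),
    bp = c("X|Y" = 0.5), scales = scales, n_boot = 1000L),
    class = "wdf_support")
  tab <- au_from_bp(s)$table
  expect_equal(tab$v, 0)
  expect_equal(tab$c, 0)
  expect_equal(tab$au, 0.5)
})

test_that("AU fit recovers (v, c) from model-generated bp curves", {
  scales <- seq(0.5, 1.4, by = 0.1)
  cases <- list(c(v = 1, c = 0), c(v = 0.5, c = 0.3), c(v = -0.8, c = 0.2))
  for (vc in cases) {
    bp <- 1 - stats::pnorm(vc[["v"]] * sqrt(scales) + vc[["c"]] / sqrt(scales))
    s <- structure(list(
      bp_by_scale = matrix(bp, 1, 10, dimnames = list("K", paste0("r", scales))),
      bp = c(K = bp[[6]]), scales = scales, n_boot = 1000L),
      class = "wdf_support")
    tab <- au_from_bp(s)$table
    expect_equal(tab$v, vc[["v"]], tolerance = 1e-6)
    expect_equal(tab$c, vc[["c"]], tolerance = 1e-6)
    expect_equal(tab$au, 1 - stats::pnorm(vc[["v"]] - vc[["c"]]),
                 tolerance = 1e-6)
  }
})

test_that("AU fallbacks at degenerate bp curves", {
  scales <- seq(0.5, 1.4, by = 0.1)
  mk <- function(bp) structure(list(
    bp_by_scale = matrix(bp, 1, 10, dimnames = list("K", paste0("r", scales))),
    bp = c(K = bp[[6]]), scales = scales, n_boot = 100L),
    class = "wdf_support")
  expect_equal(au_from_bp(mk(rep(0, 10)))$table$au, 0)
  expect_equal(au_from_bp(mk(rep(1, 10)))$table$au, 1)
  expect_error(au_from_bp(mk(c(0.5, rep(0, 9)))), "degenerate")
})

test_that("with c = 0 the fitted au approximates bp at scale 1", {
  scales <- seq(0.5, 1.4, by = 0.1)
  for (v in c(-1, -0.3, 0.4, 1.2)) {
    bp <- 1 - stats::pnorm(v * sqrt(scales))
    s <- structure(list(
      bp_by_scale = matrix(bp, 1, 10, dimnames = list("K", paste0("r", scales))),
      bp = c(K = bp[[6]]), scales = scales, n_boot = 1000L),
      class = "wdf_support")
    tab <- au_from_bp(s)$table
    expect_equal(tab$au, bp[[6]], tolerance = 1e-6)
  }
})

test_that("the WLS fit recovers (v, c) within 2 standard errors under binomial noise", {
  scales <- seq(0.5, 1.4, by = 0.1)
  v <- 0.7; cc <- 0.2; n_boot <- 1000L
  set.seed(55)
  ok_v <- 0L; ok_c <- 0L; n_rep <- 20L
  for (r in seq_len(n_rep)) {
    true_bp <- 1 - stats::pnorm(v * sqrt(scales) + cc / sqrt(scales))
    bp <- stats::rbinom(length(scales), n_boot, true_bp) / n_boot
    if (any(bp == 0 | bp == 1)) next
    z <- stats::qnorm(1 - bp)
    w <- n_boot * stats::dnorm(z)^2 / (bp * (1 - bp))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- stats::lm.wfit(X, z, w)
    se <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
    s <- structure(list(
      bp_by_scale = matrix(bp, 1, 10, dimnames = list("K", paste0("r", scales))),
      bp = c(K = bp[[6]]), scales = scales, n_boot = n_boot),
      class = "wdf_support")
    tab <- au_from_bp(s)$table
    if (abs(tab$v - v) <= 2 * se[[1]]) ok_v <- ok_v + 1L
    if (abs(tab$c - cc) <= 2 * se[[2]]) ok_c <- ok_c + 1L
  }
  # ~95% coverage expected; demand a clear majority of the 20 replicates
  expect_gte(ok_v, 16L)
  expect_gte(ok_c, 16L)
})
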