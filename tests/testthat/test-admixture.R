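test_that("inclusion score counts candidate allele copies found in the wine", {
  w <- wine_profile("W", list(L1 = c(150L, 154L), L2 = c(200L, 202L, 204L)))
  cand <- variety_genotype("V", list(L1 = c(150L, 152L), L2 = c(200L, 200L)))
  # L1: 1 of 2 copies; L2 homozygote: both copies matched -> (1 + 2) / 4
  r <- inclusion_score(w, cand, min_cotyped = 2)
  expect_equal(r$score, 3 / 4)
  expect_equal(r$n_cotyped, 2L)

  # perfect containment scores 1, disjoint scores 0
  w2 <- wine_profile("W", list(L1 = c(150L, 152L), L2 = 200L))
  expect_equal(inclusion_score(w2, cand, 2)$score, 1)
  far <- variety_genotype("F", list(L1 = c(160L, 162L), L2 = c(210L, 210L)))
  expect_equal(inclusion_score(w2, far, 2)$score, 0)

  # extra foreign wine alleles leave the score unchanged
  w3 <- wine_profile("W", list(L1 = c(150L, 152L, 170L, 172L),
                               L2 = c(200L, 220L)))
  expect_equal(inclusion_score(w3, cand, 2)$score, 1)
})

test_that("candidate assessment calls presence and sorts deterministically", {
  w <- wine_profile("W", list(L1 = c(150L, 152L), L2 = c(200L, 202L),
                              L3 = c(300L, 302L), L4 = c(400L, 402L)))
  near <- variety_genotype("Near", list(L1 = c(150L, 152L), L2 = c(200L, 202L),
                                        L3 = c(300L, 302L), L4 = c(400L, 404L)))
  far <- variety_genotype("Far", list(L1 = c(160L, 162L), L2 = c(210L, 212L),
                                      L3 = c(310L, 312L), L4 = c(410L, 412L)))
  off_panel <- variety_genotype("Off", list(L9 = c(150L, 152L)))
  a <- assess_candidates(w, list(far, off_panel, near), theta = 0.75,
                         min_cotyped = 4)
  expect_s3_class(a, "wdf_assessment")
  expect_equal(a$variety_id[[1]], "Near")
  expect_equal(a$presence_call[a$variety_id == "Near"], "compatible")
  expect_equal(a$presence_call[a$variety_id == "Far"], "excluded")
  expect_equal(a$presence_call[a$variety_id == "Off"], "inconclusive")

  # identical candidates tie; label breaks the tie deterministically
  twin1 <- variety_genotype("TwinB", near$calls)
  twin2 <- variety_genotype("TwinA", near$calls)
  a2 <- assess_candidates(w, list(twin1, twin2), min_cotyped = 4)
  expect_equal(a2$variety_id, c("TwinA", "TwinB"))
  expect_equal(a2$inclusion_score[[1]], a2$inclusion_score[[2]])
  expect_error(assess_candidates(w, list()), "at least one")
})

test_that("main-variety assignment applies the distance margin rule", {
  mk <- function(d, ids = paste0("V", seq_along(d)),
                 calls = rep("excluded", length(d))) {
    structure(data.frame(wine_id = "W", variety_id = ids,
                         inclusion_score = 1 - d, distance = d,
                         n_cotyped = 7L, presence_call = calls,
                         stringsAsFactors = FALSE),
              class = c("wdf_assessment", "data.frame"))
  }
  a <- assign_main_variety(mk(c(0.10, 0.45, 0.50)))
  expect_equal(a$variety, "V1")
  expect_equal(a$margin, 0.35)
  expect_false(a$ambiguous)

  amb <- assign_main_variety(mk(c(0.30, 0.31)), epsilon = 0.02)
  expect_true(amb$ambiguous)

  single <- assign_main_variety(mk(0.2))
  expect_equal(single$variety, "V1")
  expect_true(is.na(single$margin))

  none <- assign_main_variety(mk(0.5, calls = "inconclusive"))
  expect_true(none$no_call)
})

test_that("synthetic monovarietal wines rank their true variety first", {
  hits <- 0L
  for (i in 1:20) {
    run <- sim_blend_run(c(V1 = 1), age = 0, seed = 9000 + i)
    a <- assess_candidates(run$profile, unname(run$study$varieties))
    asg <- assign_main_variety(a)
    if (!asg$no_call && asg$variety == "V1") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("PCA ordination of allele incidence decomposes the variance", {
  panel <- toy_panel(4)
  sp <- simulate_frequency_panel(panel, 6, seed = 71)
  profs <- lapply(1:5, function(i) simulate_variety(sp, paste0("V", i),
                                                    seed = 710 + i))
  ord <- ordinate(profs, n_components = 4)
  expect_true(all(ord$explained_variance_ratio >= 0 &
                  ord$explained_variance_ratio <= 1))
  expect_lte(sum(ord$explained_variance_ratio), 1 + 1e-9)
  expect_lte(ncol(ord$coordinates), 4)

  # identical profiles: centered matrix is zero
  same <- lapply(1:3, function(i)
    variety_genotype(paste0("S", i), list(L1 = c(150L, 152L))))
  ord0 <- ordinate(same)
  expect_equal(max(abs(ord0$coordinates)), 0)
  expect_equal(sum(ord0$explained_variance_ratio), 0)

  # exactly two distinct profiles: one axis carries all the variance
  two <- list(variety_genotype("A", list(L1 = c(150L, 152L))),
              variety_genotype("B", list(L1 = c(154L, 156L))),
              variety_genotype("A2", list(L1 = c(150L, 152L))))
  ord2 <- ordinate(two, n_components = 2)
  expect_equal(ord2$explained_variance_ratio[[1]], 1, tolerance = 1e-12)
  expect_error(ordinate(two[1]), "at least 2")
})

test_that("reports validate ids, serialize, and are bytewise reproducible", {
  run <- sim_blend_run(c(V1 = 1), age = 0, seed = 321)
  cands <- unname(run$study$varieties)
  a <- assess_candidates(run$profile, cands)
  asg <- assign_main_variety(a)
  dm <- distance_matrix(c(cands, list(run$profile)))
  tr <- neighbor_joining(dm)
  rep1 <- admixture_report(run$profile, a, asg, tree = tr)
  j1 <- as_json(rep1)
  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$wine_id, "W")
  expect_equal(nrow(parsed$assessments), 4L)
  expect_type(parsed$newick, "character")

  # identical seed -> byte-identical report
  run2 <- sim_blend_run(c(V1 = 1), age = 0, seed = 321)
  a2 <- assess_candidates(run2$profile, unname(run2$study$varieties))
  rep2 <- admixture_report(run2$profile, a2, assign_main_variety(a2),
                           tree = neighbor_joining(
                             distance_matrix(c(unname(run2$study$varieties),
                                               list(run2$profile)))))
  expect_identical(as.character(j1), as.character(as_json(rep2)))

  wrong <- run$profile; wrong$id <- "other"
  expect_error(admixture_report(wrong, a, asg), "disagree")
})
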