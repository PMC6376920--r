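test_that("genotype CSV reading handles wines, homozygotes and unions", {
  panel <- toy_panel(2)
  lines <- c("sample_id,sample_type,locus,alleles",
             "W1,wine,L1,150/152",
             "G1,grapevine,L1,150/150",
             "W1,wine,L1,154/154",
             "W1,wine,L2,200/202")
  d <- read_genotype_table(lines, panel)
  expect_equal(alleles(d$wines$W1, "L1"), c(150L, 152L, 154L))
  expect_equal(alleles(d$wines$W1, "L2"), c(200L, 202L))
  expect_equal(alleles(d$varieties$G1, "L1"), c(150L, 150L))
})

test_that("genotype CSV rejects malformed and conflicting rows", {
  panel <- toy_panel(2)
  hdr <- "sample_id,sample_type,locus,alleles"
  expect_error(read_genotype_table(c(hdr, "G1,grapevine,L1,150"), panel),
               "exactly 2 alleles")
  expect_error(read_genotype_table(
    c(hdr, "G1,grapevine,L1,150/152", "G1,grapevine,L1,150/154"), panel),
    "duplicate grapevine")
  expect_error(read_genotype_table(c(hdr, "X,plant,L1,150/152"), panel),
               "sample_type")
  expect_error(read_genotype_table(c(hdr, "X,wine,L9,150/152"), panel),
               "not in the panel")
  expect_error(read_genotype_table(c(hdr, "X,wine,L1,150/abc"), panel),
               "malformed")
})

test_that("genotype table round-trips exactly", {
  panel <- toy_panel(3)
  d <- wdf_dataset(
    panel,
    varieties = list(toy_variety("G1", list(c(150, 152), c(200, 200)), panel),
                     toy_variety("G2", list(c(148, 150), c(202, 204)), panel)),
    wines = list(wine_profile("W1", list(L1 = c(148L, 150L, 152L),
                                         L3 = c(300L, 302L)), panel)))
  lines <- write_genotype_table(d)
  expect_equal(lines[[1]], "sample_id,sample_type,locus,alleles")
  d2 <- read_genotype_table(lines, panel, label = d$label)
  expect_equal(lapply(d2$varieties, `[[`, "calls"),
               lapply(d$varieties, `[[`, "calls"))
  expect_equal(lapply(d2$wines, `[[`, "calls"),
               lapply(d$wines, `[[`, "calls"))
  # header-only for an empty dataset
  expect_equal(write_genotype_table(wdf_dataset(panel)),
               "sample_id,sample_type,locus,alleles")
})

test_that("peak TSV groups by sample and replicate and flags bounds", {
  panel <- toy_panel(2)
  lines <- c("sample_id\treplicate\tmarker\tsize\theight",
             "W1\t1\tL1\t149.7\t1200",
             "W1\t1\tL1\t151.8\t900",
             "W1\t2\tL1\t149.8\t1100")
  obs <- read_peak_table(lines, panel)
  expect_length(obs, 2L)
  expect_equal(nrow(obs[[1]]$peaks$L1), 2L)
  expect_equal(obs[[2]]$replicate, 2L)
  # out-of-bounds sizes retained but flagged
  oob <- read_peak_table(c("sample_id\treplicate\tmarker\tsize\theight",
                           "W1\t1\tL1\t9999\t100"), panel)
  expect_true(oob[[1]]$peaks$L1$out_of_bounds)
  expect_error(read_peak_table(c("sample_id\treplicate\tmarker\tsize\theight",
                                 "W1\t1.5\tL1\t150\t100"), panel),
               "replicate")
  expect_error(read_peak_table(c("sample_id\treplicate\tmarker\tsize\theight",
                                 "W1\t1\tL1\t150\t-5"), panel),
               "height")
})

test_that("dataset merging deduplicates, detects conflicts, and honours the locus policy", {
  pa <- toy_panel(2)                      # loci L1, L2
  pb <- wdf_panel(c("L2", "L3"), size_min = 80L, size_max = 400L)
  g1 <- toy_variety("G1", list(c(150, 152), c(200, 202)), pa)
  g2 <- variety_genotype("G2", list(L2 = c(204L, 206L), L3 = c(300L, 300L)), pb)
  d1 <- wdf_dataset(pa, varieties = list(g1), label = "a")
  d2 <- wdf_dataset(pb, varieties = list(g2), label = "b")

  expect_equal(merge_datasets(list(d1))$varieties, d1$varieties)
  m_union <- merge_datasets(list(d1, d2))
  expect_setequal(m_union$panel$name, c("L1", "L2", "L3"))
  expect_length(m_union$varieties, 2L)
  m_int <- merge_datasets(list(d1, d2), policy = "intersection")
  expect_equal(m_int$panel$name, "L2")
  # calls outside the merged panel are dropped
  expect_equal(names(m_int$varieties$G1$calls), "L2")

  # identical duplicate deduplicates; conflicting duplicate errors naming loci
  expect_length(merge_datasets(list(d1, d1))$varieties, 1L)
  g1b <- toy_variety("G1", list(c(150, 154), c(200, 202)), pa)
  d1b <- wdf_dataset(pa, varieties = list(g1b), label = "a2")
  expect_error(merge_datasets(list(d1, d1b)), "conflicting duplicate.*L1")
  expect_error(merge_datasets(list()), "at least one")
})

test_that("dataset merging is associative on conflict-free inputs", {
  panel <- toy_panel(3)
  ds <- lapply(1:3, function(i)
    wdf_dataset(panel, varieties = list(
      toy_variety(paste0("G", i), list(c(150, 152), c(200, 204), c(300, 310)), panel)),
      label = paste0("d", i)))
  left <- merge_datasets(list(merge_datasets(ds[1:2]), ds[[3]]))
  right <- merge_datasets(list(ds[[1]], merge_datasets(ds[2:3])))
  expect_equal(lapply(left$varieties, `[[`, "calls"),
               lapply(right$varieties, `[[`, "calls"))
  expect_equal(left$panel$name, right$panel$name)
})

test_that("constructors enforce the domain invariants", {
  panel <- toy_panel(2)
  expect_error(variety_genotype("G", list(L1 = c(150L, 152L, 154L))),
               "exactly 2")
  expect_error(wine_profile("W", list(L1 = integer(0))), "empty allele set")
  expect_error(wine_profile("W", list(L1 = c(150L, 152L)), panel,
                            max_alleles = 1L), "blend cap")
  expect_error(variety_genotype("G", list(L1 = c(50L, 152L)), panel), "bounds")
  expect_error(wdf_dataset(panel, varieties = list(
    toy_variety("X", list(c(150, 152)), panel),
    toy_variety("X", list(c(150, 152)), panel))), "duplicate sample ids")
  expect_error(wdf_panel(character(0)), "at least one")
  expect_error(wdf_panel(c("A", "A")), "duplicate")
  json <- dataset_to_json(wdf_dataset(panel,
    varieties = list(toy_variety("G1", list(c(150, 152)), panel))))
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$varieties$G1$calls$L1, c(150L, 152L))
})
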