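# The synthetic-data generators: step coverage, cohort matrices, UTR
# sequences — all with exact planted truth.

test_that("noise-free coverage is the exact two-isoform step", {
  cp <- simulate_coverage(200, 100, depth_long = 40, depth_short = 60)
  expect_equal(cp$depth, c(rep(100, 100), rep(40, 100)))
  expect_equal(attr(cp, "pdui_true"), 0.4)

  # single-isoform limit: no short isoform, flat coverage
  flat <- simulate_coverage(150, 75, depth_long = 30, depth_short = 0)
  expect_equal(attr(flat, "pdui_true"), 1)
  expect_equal(flat$depth, rep(30, 150))

  expect_error(simulate_coverage(0, 1, 1, 1), "utr_length")
  expect_error(simulate_coverage(200, 250, 1, 1), "proximal_site")
  expect_error(simulate_coverage(200, 100, 0, 0), "positive")
})

test_that("poisson noise is unbiased and reproducible under seed", {
  draws <- vapply(1:500, function(s) {
    simulate_coverage(200, 100, 40, 60, "poisson", seed = s)$depth
  }, numeric(200))
  per_base <- rowMeans(draws)
  expect_true(all(abs(per_base[1:100] - 100) / 100 < 0.05))
  expect_true(all(abs(per_base[101:200] - 40) / 40 < 0.05))

  a <- simulate_coverage(100, 50, 10, 10, "poisson", seed = 7)
  b <- simulate_coverage(100, 50, 10, 10, "poisson", seed = 7)
  d <- simulate_coverage(100, 50, 10, 10, "poisson", seed = 8)
  expect_identical(a$depth, b$depth)
  expect_false(identical(a$depth, d$depth))
  expect_error(simulate_coverage(100, 50, 10, 10, "poisson"), "seed")
})

test_that("cohort simulation honors labels, ranges and the seeding contract", {
  co <- simulate_cohort(seed = 3)
  expect_equal(dim(co$pdui), c(500, 60))
  expect_identical(colnames(co$pdui), colnames(co$expr))
  expect_true(all(co$pdui >= 0 & co$pdui <= 1))
  expect_setequal(unique(co$truth$subgroup), c("A", "B", "C"))
  expect_equal(unname(table(co$truth$subgroup)[c("A", "B", "C")]),
               c(20L, 20L, 20L), ignore_attr = TRUE)
  # subgroup A carries longer 3'UTRs than C by the planted shift
  mean_by <- tapply(colMeans(co$pdui), co$truth$subgroup, mean)
  expect_gt(mean_by["A"], mean_by["B"])
  expect_gt(mean_by["B"], mean_by["C"])

  co2 <- simulate_cohort(seed = 3)
  co3 <- simulate_cohort(seed = 4)
  expect_identical(co$pdui, co2$pdui)
  expect_identical(co$expr, co2$expr)
  expect_false(identical(co$pdui, co3$pdui))
})

test_that("planted event counts are exactly recoverable without noise", {
  for (s in c(1, 2)) {
    co <- simulate_cohort(seed = s, pdui_noise_sd = 0)
    counts <- apa_event_counts(co$pdui, reference = "cohort_median",
                               event_threshold = 0.2)
    expect_identical(counts$n_lengthened, co$truth$event_counts$n_lengthened)
    expect_identical(counts$n_shortened, co$truth$event_counts$n_shortened)
  }
})

test_that("the null configuration carries no subgroup signal", {
  co <- simulate_cohort(seed = 5,
                        effect_sizes = list(subgroup_shift = 0,
                                            regulator_effect = 0))
  groups <- cluster_samples(co$pdui)
  expect_lt(abs(ari(groups[names(co$truth$subgroup)], co$truth$subgroup)), 0.3)
  # key regulator expression is uncorrelated with APA burden
  counts <- apa_event_counts(co$pdui)
  key <- subset(co$truth$regulators, is_key)$gene_id
  expect_lt(abs(cor(co$expr[key, counts$sample_id], counts$n_lengthened)), 0.35)
})

test_that("UTR sequences round-trip their planted PAS truth", {
  sim <- simulate_utr_sequences(n_per_type = 10, seed = 11)
  expect_equal(nrow(sim$truth), 30L)
  got <- classify_utrs(sim$sequences)
  expect_identical(got$pas_type, sim$truth$type_true)

  # the scan finds exactly the planted sites, no extras
  sites <- attr(sim$truth, "sites")
  for (g in sim$truth$gene_id) {
    found <- scan_pas(sim$sequences[[g]])
    expect_identical(found$offset, sites[[g]]$offset)
    expect_identical(found$hexamer, sites[[g]]$hexamer)
  }

  # seeding contract
  sim2 <- simulate_utr_sequences(n_per_type = 10, seed = 11)
  expect_identical(sim$sequences, sim2$sequences)
  expect_false(identical(
    sim$sequences, simulate_utr_sequences(n_per_type = 10, seed = 12)$sequences))
})

test_that("sequence simulation refuses unusable hexamer sets", {
  expect_error(simulate_utr_sequences(1, hexamer_set = "AATAAA", seed = 1),
               "only the canonical")
  expect_error(simulate_utr_sequences(1, hexamer_set = "ATTAAA", seed = 1),
               "canonical")
  expect_error(simulate_utr_sequences(1, hexamer_set = character(0), seed = 1),
               "empty")
})
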