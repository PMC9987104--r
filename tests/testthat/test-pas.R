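# PAS hexamer scanning and type a/b/c classification.

test_that("scan reports all (overlapping) matches sorted by offset", {
  one <- scan_pas("AAAATAAAGG")
  expect_equal(one$offset, 2L)
  expect_true(one$canonical)

  overlap <- scan_pas("AATAAATAAA")
  expect_equal(overlap$offset, c(0L, 4L))
  expect_true(all(overlap$canonical))

  expect_equal(nrow(scan_pas("GGGGGGGG")), 0)
  expect_equal(nrow(scan_pas("AATAA")), 0)          # shorter than a hexamer
  expect_equal(nrow(scan_pas("AANAAA")), 0)         # N never matches
  expect_equal(scan_pas("AAUAAA")$offset, 0L)       # RNA alphabet accepted
  expect_error(scan_pas("AATAXA"), "\\{A,C,G,T,N\\}")
  expect_error(scan_pas("AATAAA", character(0)), "empty")
})

test_that("scan equals the all-windows oracle on random sequences", {
  set.seed(13)
  alphabet <- c("A", "C", "G", "T", "N")
  for (i in 1:200) {
    L <- sample(6:500, 1)
    s <- paste(sample(alphabet, L, replace = TRUE,
                      prob = c(.3, .2, .2, .28, .02)), collapse = "")
    expect_identical(scan_pas(s), oracle_scan(s))
  }
})

test_that("proximal/distal split follows the co-location window", {
  sites <- data.frame(offset = c(50L, 900L),
                      hexamer = c("ATTAAA", "AATAAA"),
                      canonical = c(FALSE, TRUE), stringsAsFactors = FALSE)
  sp <- split_proximal_distal(sites, 1000, distal_window = 50)
  expect_equal(sp$proximal$offset, 50L)
  expect_equal(sp$distal$offset, 900L)

  # a single site cannot define a proximal region
  single <- split_proximal_distal(sites[2, ], 1000)
  expect_equal(nrow(single$proximal), 0)
  expect_equal(nrow(single$distal), 1)

  # two sites co-located at the 3' end are both distal
  near <- data.frame(offset = c(880L, 900L), hexamer = "AATAAA",
                     canonical = TRUE, stringsAsFactors = FALSE)
  sp2 <- split_proximal_distal(near, 1000, distal_window = 50)
  expect_equal(nrow(sp2$proximal), 0)
  expect_equal(sort(sp2$distal$offset), c(880L, 900L))

  # annotated anchor variant
  sp3 <- split_proximal_distal(sites, 1000, distal_anchor = "annotated_distal",
                               distal_window = 50, distal_offset = 920)
  expect_equal(sp3$distal$offset, 900L)
  expect_error(split_proximal_distal(sites, 1000,
                                     distal_anchor = "annotated_distal"),
               "distal_offset")
})

test_that("type assignment matches the proximal inventory definitions", {
  site <- function(off, hex) {
    data.frame(offset = off, hexamer = hex, canonical = hex == "AATAAA",
               stringsAsFactors = FALSE)
  }
  expect_identical(classify_gene(site(10, "ATTAAA"))$pas_type, "a")
  expect_identical(classify_gene(rbind(site(10, "AATAAA"),
                                       site(40, "ATTAAA")))$pas_type, "b")
  expect_identical(classify_gene(site(10, "AATAAA"))$pas_type, "c")
  expect_identical(classify_gene(site(10, "AATAAA")[0, ])$pas_type,
                   "unclassified")

  # invariant to duplicates and row order
  dup <- rbind(site(40, "ATTAAA"), site(10, "AATAAA"), site(40, "ATTAAA"))
  expect_identical(classify_gene(dup)$pas_type, "b")
  expect_identical(classify_gene(dup[3:1, ])$pas_type, "b")
})

test_that("types partition genes and a-union-b tracks proximal non-canonical", {
  sim <- simulate_utr_sequences(n_per_type = 8, seed = 23)
  tab <- classify_utrs(sim$sequences)
  expect_true(all(tab$pas_type %in% c("a", "b", "c", "unclassified")))
  ab <- tab$pas_type %in% c("a", "b")
  expect_identical(ab, tab$n_prox_noncanonical >= 1)
  expect_identical(tab$pas_type %in% c("c"),
                   tab$n_prox_noncanonical == 0 & tab$n_prox_canonical >= 1)
})

test_that("proximal non-canonical proportion is simple arithmetic", {
  expect_equal(proportion_proximal_noncanonical(c("a", "b", "c", "c")), 0.5)
  expect_equal(proportion_proximal_noncanonical(rep("c", 5)), 0)
  expect_warning(p <- proportion_proximal_noncanonical(rep("unclassified", 3)),
                 "undefined")
  expect_true(is.na(p))
  # data.frame input path
  expect_equal(
    proportion_proximal_noncanonical(data.frame(pas_type = c("a", "c"))), 0.5)
})
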