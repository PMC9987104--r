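# The three-criterion target funnel and qPCR quantitation utilities.

toy_tables <- function(flags) {
  # flags: list of c(pas, tumor_up, lengthening) per gene
  genes <- paste0("g", seq_along(flags))
  list(
    pas = data.frame(gene_id = genes,
                     n_pas = ifelse(vapply(flags, `[`, logical(1), 1), 3L, 1L)),
    deg = data.frame(gene_id = genes,
                     direction = ifelse(vapply(flags, `[`, logical(1), 2),
                                        "up", "ns"),
                     fdr = 0.01),
    apa = data.frame(gene_id = genes,
                     delta_pdui = 0.4,
                     p_value = ifelse(vapply(flags, `[`, logical(1), 3),
                                      1e-5, 0.02),
                     call = "lengthened", stringsAsFactors = FALSE)
  )
}

test_that("selection is the strict conjunction of the three criteria", {
  flags <- list(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
                c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                c(TRUE, TRUE, TRUE))
  tb <- toy_tables(flags)
  out <- filter_targets(tb$pas, tb$deg, tb$apa, p_cutoff = 0.001)
  expect_setequal(out$gene_id[out$selected], c("g1", "g5"))
  # a gene with a single PAS is gated regardless of the other criteria
  expect_false(out$selected[out$gene_id == "g4"])
  expect_true(out$pass_tumor_up[out$gene_id == "g4"])
  # sorted by ascending lengthening p
  expect_false(is.unsorted(out$lengthening_p))
})

test_that("genes missing from an input fail closed", {
  tb <- toy_tables(list(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE)))
  out <- filter_targets(tb$pas, tb$deg[-1, ], tb$apa)
  g1 <- out[out$gene_id == "g1", ]
  expect_true(is.na(g1$tumor_up))
  expect_false(g1$selected)
  expect_true(out$selected[out$gene_id == "g2"])
})

test_that("funnel output is independent of input row order", {
  tb <- simulate_target_tables(n_genes = 60, n_selected = 9, seed = 4)
  out1 <- filter_targets(tb$pas, tb$deg, tb$apa)
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  set.seed(1)
  out2 <- filter_targets(shuf(tb$pas), shuf(tb$deg), shuf(tb$apa))
  expect_identical(out1, out2)
  expect_setequal(out1$gene_id[out1$selected], tb$truth$selected)
})

test_that("dropping any criterion yields a superset of the selection", {
  tb <- simulate_target_tables(n_genes = 120, n_selected = 15, seed = 8)
  base <- filter_targets(tb$pas, tb$deg, tb$apa)
  sel <- base$gene_id[base$selected]
  relax <- list(
    filter_targets(transform(tb$pas, n_pas = 5L), tb$deg, tb$apa),
    filter_targets(tb$pas, transform(tb$deg, direction = "up", fdr = 1e-6),
                   tb$apa),
    filter_targets(tb$pas, tb$deg, tb$apa, p_cutoff = 1)
  )
  for (r in relax) {
    expect_true(all(sel %in% r$gene_id[r$selected]))
    expect_gt(sum(r$selected), length(sel))
  }
})

test_that("long-to-total ratio behaves like a PDUI", {
  expect_equal(long_to_total_ratio(5, 5)$ratio, 1)
  expect_equal(long_to_total_ratio(0, 5)$ratio, 0)
  expect_error(long_to_total_ratio(1, 0), "positive")
  expect_error(long_to_total_ratio(6, 5), "long_signal")

  # agrees with the coverage-model estimate on noise-free data
  cp <- simulate_coverage(300, 150, depth_long = 40, depth_short = 60)
  fit <- estimate_pdui(cp, end_margin = 20)
  r <- long_to_total_ratio(fit$long_abundance,
                           fit$long_abundance + fit$short_abundance)
  expect_equal(r$ratio, fit$pdui, tolerance = 1e-6)
})

test_that("ddCt quantitation inverts forward-simulated Ct values", {
  expect_equal(ddct_relative_expression(20, 18, 22, 20), 1)
  expect_equal(ddct_relative_expression(21, 20, 20, 20), 0.5)
  expect_equal(ddct_relative_expression(18, 20, 20, 20), 4)
  expect_error(ddct_relative_expression(NA, 1, 1, 1), "finite")

  # forward-simulate Ct from abundances with planted PDUI 0.4:
  # Ct = 25 - log2(abundance); control has long = total
  pdui <- 0.4
  ct <- function(ab) 25 - log2(ab)
  fold_long <- ddct_relative_expression(ct(pdui), ct(1), ct(1), ct(1))
  fold_total <- ddct_relative_expression(ct(1), ct(1), ct(1), ct(1))
  r <- long_to_total_ratio(fold_long, fold_total)
  expect_equal(r$ratio, pdui, tolerance = 1e-6)
})
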