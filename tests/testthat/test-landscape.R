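# Cohort landscape: clustering, differential expression, and the staged
# regulator screen.

block_matrix <- function() {
  # three clean sample blocks with mean PDUI 0.9 / 0.6 / 0.3
  set.seed(42)
  g <- 40; per <- 5
  base <- matrix(runif(g * per * 3, -0.03, 0.03), g, per * 3)
  m <- base + rep(c(0.9, 0.6, 0.3), each = g * per)
  dimnames(m) <- list(paste0("g", 1:g), paste0("s", 1:(per * 3)))
  m
}

test_that("clustering recovers clean blocks and orders labels by mean PDUI", {
  m <- block_matrix()
  truth <- rep(c("A", "B", "C"), each = 5)
  groups <- cluster_samples(m)
  expect_equal(ari(groups, truth), 1)
  means <- attr(groups, "group_mean_pdui")
  expect_identical(names(means), c("A", "B", "C"))
  expect_true(all(diff(means) < 0))
  expect_equal(unname(groups["s1"]), "A")   # the 0.9 block is labeled A
  expect_equal(unname(groups["s15"]), "C")

  # permutation invariance up to sample identity
  perm <- sample(colnames(m))
  expect_identical(cluster_samples(m[, perm])[colnames(m)],
                   groups[colnames(m)])
})

test_that("clustering rejects bad input and warns on degenerate input", {
  m <- block_matrix()
  expect_error(cluster_samples(m[, 1:2]), "at least k")
  expect_error(cluster_samples(m + 2), "\\[0,1\\]")
  flat <- matrix(0.5, 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_warning(g <- cluster_samples(flat), "indistinguishable")
  expect_length(g, 6)
})

test_that("differential expression calls constructed contrasts", {
  set.seed(7)
  groups <- setNames(rep(c("A", "B", "C"), each = 20),
                     paste0("s", 1:60))
  expr <- matrix(2^rnorm(5 * 60, 7, 0.3), 5, 60,
                 dimnames = list(paste0("g", 1:5), names(groups)))
  expr["g2", ] <- 300                       # constant gene
  expr["g3", groups == "C"] <- expr["g3", groups == "A"] * 4  # exactly 4x

  res <- differential_expression(expr, groups)
  expect_identical(res$direction[res$gene_id == "g2"], "ns")
  g3 <- res[res$gene_id == "g3", ]
  expect_equal(g3$log2_fold_change, 2, tolerance = 0.02)
  expect_identical(g3$direction, "up_in_C")
  expect_error(differential_expression(expr, groups[groups != "C"]),
               ">= 3 samples")
})

test_that("planted cohort DEGs are recovered with the right direction", {
  co <- simulate_cohort(seed = 21)
  groups <- cluster_samples(co$pdui)
  res <- differential_expression(co$expr, groups)
  planted <- merge(co$truth$deg, res, by = "gene_id")
  strong <- planted[abs(planted$planted_log2fc) >= 2, ]
  expect_gt(nrow(strong), 0)
  expect_identical(strong$direction.y, strong$direction.x)
})

test_that("gene-set intersection is plain set arithmetic with roles", {
  degs <- data.frame(
    gene_id = paste0("g", 1:6),
    log2_fold_change = c(-2, -2, -2, -2, -2, 3),
    p_value = 1e-5, fdr = 1e-4,
    direction = c(rep("down_in_C", 5), "up_in_C"),
    stringsAsFactors = FALSE
  )
  sets <- list(apa = c("g1", "g3", "g6", "zzz"))
  out <- intersect_genesets(degs, sets)
  expect_setequal(out$gene_id[out$role == "lengthen_regulator"], c("g1", "g3"))
  expect_identical(out$gene_id[out$role == "shorten_regulator"], "g6")

  empty <- intersect_genesets(degs[degs$direction == "never", ], sets)
  expect_equal(nrow(empty), 0)
  expect_warning(intersect_genesets(degs, list(other = "nope")),
                 "namespace")
  expect_error(intersect_genesets(degs, list()), "non-empty")
})

test_that("correlation screen thresholds and degenerate candidates behave", {
  counts <- data.frame(sample_id = paste0("s", 1:10),
                       n_lengthened = 1:10, n_shortened = 10:1)
  expr <- rbind(exact = 1:10, flat = rep(5, 10), noise = c(2,9,4,7,1,8,3,6,5,10))
  colnames(expr) <- counts$sample_id
  cand <- data.frame(gene_id = c("exact", "flat"),
                     role = "lengthen_regulator", stringsAsFactors = FALSE)
  expect_warning(out <- correlation_screen(expr, counts, cand),
                 "zero variance")
  expect_identical(out$gene_id, "exact")
  expect_equal(out$pearson_r, 1)
  expect_error(
    correlation_screen(expr, counts,
                       data.frame(gene_id = "absent", role = "lengthen_regulator")),
    "absent")
})

test_that("core-factor overlap ranks by |r| with lexicographic ties", {
  short <- data.frame(gene_id = c("PABPN1", "CSTF2", "AAA", "ZZZ"),
                      role = "lengthen_regulator",
                      pearson_r = c(0.48, -0.48, 0.35, 0.9),
                      p_value = 1e-4, stringsAsFactors = FALSE)
  out <- overlap_core_factors(short, c("PABPN1", "CSTF2", "AAA"))
  expect_identical(out$gene_id, c("CSTF2", "PABPN1", "AAA"))
  expect_identical(out$rank, 1:3)
  empty <- overlap_core_factors(short, "NOPE")
  expect_equal(nrow(empty), 0)
  expect_error(overlap_core_factors(short, character(0)), "empty")
})

test_that("the staged screen shrinks monotonically and finds the key regulator", {
  co <- simulate_cohort(seed = 31)
  sc <- screen_apa_regulators(co$expr, co$pdui, co$truth$genesets,
                              co$truth$core_factors)
  dir_degs <- sc$deg$gene_id[sc$deg$direction != "ns"]
  expect_true(all(sc$candidates$gene_id %in% dir_degs))
  expect_true(all(sc$shortlist$gene_id %in% sc$candidates$gene_id))
  expect_true(all(sc$core_overlap$gene_id %in% sc$shortlist$gene_id))
  # planted regulators survive the gene-set stage
  expect_true(all(co$truth$regulators$gene_id %in% sc$candidates$gene_id))
  expect_identical(sc$key_regulator,
                   subset(co$truth$regulators, is_key)$gene_id)
  # label contract after relabeling
  means <- attr(sc$groups, "group_mean_pdui")
  expect_true(all(diff(means) <= 0))
})
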