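# The two-isoform PDUI estimator and condition contrasts.

test_that("estimator recovers the analytic limits", {
  # flat coverage: everything is long isoform
  flat <- estimate_pdui(coverage_profile("g", rep(100, 200)), end_margin = 10)
  expect_equal(flat$pdui, 1)
  expect_equal(flat$short_abundance, 0)

  # coverage vanishing after the proximal site: short-only
  short <- estimate_pdui(
    coverage_profile("g", c(rep(100, 100), rep(0, 100))), end_margin = 10)
  expect_equal(short$pdui, 0)
  expect_equal(short$proximal_site, 100L)

  # mixed two-isoform step
  fit <- estimate_pdui(
    coverage_profile("g", c(rep(100, 100), rep(40, 100))), end_margin = 10)
  expect_equal(fit$long_abundance, 40)
  expect_equal(fit$short_abundance, 60)
  expect_equal(fit$pdui, 0.4)
  expect_equal(fit$proximal_site, 100L)
})

test_that("estimator matches the exhaustive breakpoint oracle", {
  set.seed(101)
  for (i in 1:60) {
    L <- sample(60:300, 1)
    margin <- sample(5:15, 1)
    P_true <- sample((margin + 5):(L - margin - 5), 1)
    mu <- c(rep(runif(1, 20, 120), P_true), rep(runif(1, 5, 60), L - P_true))
    depth <- if (i %% 2 == 0) rpois(L, mu) else mu
    fit <- estimate_pdui(coverage_profile("g", depth), min_mean_depth = 0,
                         end_margin = margin)
    orc <- oracle_pdui(depth, margin)
    expect_equal(fit$fit_sse, orc$sse, tolerance = 1e-9)
    expect_identical(fit$proximal_site, as.integer(orc$proximal_site))
    expect_equal(fit$pdui, orc$pdui, tolerance = 1e-9)
  }
})

test_that("estimated PDUI is monotone in the planted long fraction", {
  pduis <- vapply(seq(0, 1, by = 0.1), function(p) {
    cp <- simulate_coverage(200, 100, depth_long = 100 * p,
                            depth_short = 100 * (1 - p))
    estimate_pdui(cp, end_margin = 20)$pdui
  }, numeric(1))
  expect_true(all(diff(pduis) >= -1e-12))
  # and the noise-free round trip is exact
  cp <- simulate_coverage(300, 130, 35, 65)
  fit <- estimate_pdui(cp, end_margin = 20)
  expect_equal(fit$pdui, 0.35, tolerance = 1e-9)
  expect_identical(fit$proximal_site, 130L)
})

test_that("low coverage yields NA PDUI, not an error", {
  dim_fit <- estimate_pdui(coverage_profile("g", rep(2, 200)))
  expect_identical(dim_fit$status, "low_coverage")
  expect_true(is.na(dim_fit$pdui))
  zero <- estimate_pdui(coverage_profile("g", rep(0, 200)))
  expect_identical(zero$status, "low_coverage")
  expect_error(coverage_profile("g", numeric(0)), "empty")
  expect_error(estimate_pdui(coverage_profile("g", rep(9, 60)),
                             end_margin = 30), "end_margin")
})

test_that("fit methods are mutually consistent", {
  cp <- simulate_coverage(200, 80, 30, 50, "poisson", seed = 2)
  fit <- estimate_pdui(cp, end_margin = 10)
  expect_equal(fitted(fit) + residuals(fit), cp$depth)
  expect_equal(sum(residuals(fit)^2), fit$fit_sse)
  expect_equal(unname(coef(fit)["long_abundance"]), fit$long_abundance)
  expect_equal(predict(fit, c(0, fit$proximal_site)),
               c(sum(coef(fit)), fit$long_abundance))
  reps <- simulate(fit, nsim = 2, seed = 9)
  expect_length(reps, 2)
  expect_identical(simulate(fit, seed = 9)[[1]]$depth, reps[[1]]$depth)
  df <- as.data.frame(fit)
  expect_identical(df$pdui, fit$pdui)
})

test_that("delta PDUI is antisymmetric and sign-called", {
  rec <- function(p, g = "g1") pdui_record(g, 10 * p, 10 * (1 - p), 200)
  ca <- list(rec(0.8), rec(0.8))
  co <- list(rec(0.6), rec(0.6))
  d <- delta_pdui(ca, co)
  expect_equal(d$delta_pdui, 0.2)
  expect_identical(d$call, "lengthened")
  expect_identical(delta_pdui(ca, ca)$call, "unchanged")
  swapped <- delta_pdui(co, ca)
  expect_equal(swapped$delta_pdui, -d$delta_pdui)
  expect_identical(swapped$call, "shortened")
  expect_error(delta_pdui(list(), co), "empty")
  expect_error(delta_pdui(ca, list(rec(0.5, g = "other"))), "shared gene_id")
})

test_that("APA change test matches the hypergeometric oracle and gates calls", {
  # pooled counts 900/100 vs 100/900 over an L=1000 UTR
  ca <- list(pdui_record("g", 0.9, 0.1, 1000))
  co <- list(pdui_record("g", 0.1, 0.9, 1000))
  res <- test_apa_change(ca, co)
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$call, "lengthened")
  expect_equal(res$p_value, oracle_fisher_p(900, 100, 100, 900),
               tolerance = 1e-8)

  # identical pooled counts: p = 1
  same <- test_apa_change(ca, ca)
  expect_equal(same$p_value, 1)
  expect_identical(same$call, "unchanged")

  # tiny effect gated out by min_abs_delta despite significance
  big_ca <- list(pdui_record("g", 0.51, 0.49, 2e5))
  big_co <- list(pdui_record("g", 0.50, 0.50, 2e5))
  gated <- test_apa_change(big_ca, big_co, min_abs_delta = 0.05)
  expect_lt(gated$p_value, 0.05)
  expect_identical(gated$call, "unchanged")

  # zero counts in one condition are untestable
  none <- list(pdui_record("g", 0, 0, 100))
  expect_identical(test_apa_change(ca, none)$call, "unchanged")
  expect_equal(test_apa_change(ca, none)$p_value, 1)
})

test_that("per-sample event counting follows the reference and threshold", {
  m <- matrix(0.5, 10, 5, dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  zero <- apa_event_counts(m)
  expect_true(all(zero$n_lengthened == 0) && all(zero$n_shortened == 0))

  m2 <- m
  m2[1:7, 1] <- 0.8             # 7 genes at median + 0.3 in sample 1
  cnt <- apa_event_counts(m2, event_threshold = 0.2)
  expect_equal(cnt$n_lengthened[1], 7)
  expect_equal(cnt$n_shortened[1], 0)

  expect_error(apa_event_counts(m, reference = "paired_normal"), "pairing")
  expect_error(apa_event_counts(m[, 1:2, drop = FALSE]), "3 samples")
})
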