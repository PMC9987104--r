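#' Estimate PDUI from 3'UTR coverage by two-isoform regression
#'
#' Fits the two-isoform model of 3'UTR coverage: the long isoform covers the
#' whole UTR at abundance `w_L` reads/base and the short isoform covers only
#' positions upstream of the proximal polyadenylation site `P` at abundance
#' `w_S`, so the expected depth is `w_L + w_S` before `P` and `w_L` after.
#' Every candidate breakpoint `P` in `[end_margin, L - end_margin)` is
#' evaluated; for each, the non-negative least-squares solution in
#' `(w_S, w_L)` is available in closed form from the segment means (with the
#' short abundance clipped to 0 when the downstream mean exceeds the upstream
#' mean), and the breakpoint minimizing the residual sum of squares is
#' retained. Ties in SSE resolve to the most proximal (5'-most) site so the
#' fit is deterministic. The Percentage of Distal polyA site Usage Index is
#' then `PDUI = w_L / (w_L + w_S)`: near 1 when the distal site dominates
#' (long 3'UTR), near 0 when the proximal site dominates.
#'
#' Profiles with mean depth below `min_mean_depth` (including all-zero
#' coverage) are flagged `status = "low_coverage"` and return `NA` PDUI
#' rather than an unstable estimate.
#'
#' @param profile A [coverage_profile].
#' @param min_mean_depth Minimum mean reads/base required for a fit
#'   (default 5).
#' @param end_margin Number of nucleotides excluded from each end of the
#'   breakpoint search window (default 50; must satisfy
#'   `2 * end_margin < L`). Prevents degenerate one-sided fits.
#' @param sample_id Optional sample identifier carried into the result.
#' @return An object of class `pdui_fit` with components `gene_id`,
#'   `sample_id`, `long_abundance`, `short_abundance`, `proximal_site`
#'   (0-based offset), `pdui`, `fit_sse`, `status`, and the input `depth`.
#' @examples
#' cp <- simulate_coverage(200, 100, depth_long = 40, depth_short = 60)
#' fit <- estimate_pdui(cp, end_margin = 10)
#' fit$pdui          # 0.4
#' coef(fit)
#' @seealso [delta_pdui()], [test_apa_change()], [simulate_coverage()]
#' @export
estimate_pdui <- function(profile, min_mean_depth = 5, end_margin = 50,
                          sample_id = NA_character_) {
  stopifnot(inherits(profile, "coverage_profile"))
  d <- profile$depth
  L <- length(d)
  stop_if_not_scalar_number(end_margin, "end_margin", lower = 1)
  if (2 * end_margin >= L) {
    stop("end_margin too large: need 2*end_margin < UTR length (", L, ")",
         call. = FALSE)
  }

  res <- structure(
    list(gene_id = profile$gene_id, sample_id = sample_id,
         long_abundance = NA_real_, short_abundance = NA_real_,
         proximal_site = NA_integer_, pdui = NA_real_, fit_sse = NA_real_,
         status = "low_coverage", depth = d,
         min_mean_depth = min_mean_depth, end_margin = as.integer(end_margin)),
    class = "pdui_fit"
  )
  if (mean(d) < min_mean_depth || all(d == 0)) {
    return(res)
  }

  # closed-form NNLS over all breakpoints via cumulative sums:
  # for breakpoint P (P bases covered by both isoforms),
  #   unconstrained optimum: w_L = mean(d[P..L)), w_S = mean(d[0..P)) - w_L;
  #   if w_S < 0 the constrained optimum is w_S = 0, w_L = mean(d).
  P <- seq.int(end_margin, L - end_margin - 1L)
  cs <- cumsum(d)
  tot <- cs[L]
  s1 <- cs[P]
  m1 <- s1 / P
  m2 <- (tot - s1) / (L - P)
  ssq <- sum(d^2)
  sse_free <- ssq - P * m1^2 - (L - P) * m2^2
  sse_clip <- ssq - L * mean(d)^2    # flat fit, independent of P
  feasible <- m1 >= m2
  sse <- ifelse(feasible, sse_free, sse_clip)

  # the cumulative-sum algebra carries O(eps * ssq) cancellation error, so
  # near-ties are re-evaluated with directly summed residuals and resolved
  # to the most proximal strict minimum (deterministic tie-break)
  cand <- P[sse <= min(sse) + 1e-8 * (ssq + 1)]
  best <- NULL
  for (bp in cand) {
    m1b <- mean(d[1:bp])
    m2b <- mean(d[(bp + 1):L])
    if (m1b >= m2b) {
      w_L <- m2b
      w_S <- m1b - m2b
    } else {
      w_L <- mean(d)
      w_S <- 0
    }
    fitv <- c(rep(w_L + w_S, bp), rep(w_L, L - bp))
    sse_b <- sum((d - fitv)^2)
    if (is.null(best) || sse_b < best$sse - 1e-12) {
      best <- list(bp = bp, w_L = w_L, w_S = w_S, sse = sse_b)
    }
  }

  res$long_abundance <- best$w_L
  res$short_abundance <- best$w_S
  res$proximal_site <- as.integer(best$bp)
  res$pdui <- if (best$w_L + best$w_S > 0) best$w_L / (best$w_L + best$w_S) else NA_real_
  res$fit_sse <- best$sse
  res$status <- "ok"
  res
}

#' @export
print.pdui_fit <- function(x, ...) {
  cat("Two-isoform PDUI fit:", x$gene_id)
  if (!is.na(x$sample_id)) cat(" /", x$sample_id)
  cat("\n")
  if (x$status == "low_coverage") {
    cat(sprintf("  status: low_coverage (mean depth %.2f < %.2f); PDUI = NA\n",
                mean(x$depth), x$min_mean_depth))
  } else {
    cat(sprintf("  proximal site: %d nt (0-based, L = %d)\n",
                x$proximal_site, length(x$depth)))
    cat(sprintf("  abundances: long %.3f, short %.3f reads/base\n",
                x$long_abundance, x$short_abundance))
    cat(sprintf("  PDUI = %.4f   (SSE = %.3f)\n", x$pdui, x$fit_sse))
  }
  invisible(x)
}

#' @export
summary.pdui_fit <- function(object, ...) {
  print(object)
  if (object$status == "ok") {
    r <- stats::residuals(object)
    cat(sprintf("  residuals: min %.2f, median %.2f, max %.2f\n",
                min(r), stats::median(r), max(r)))
  }
  invisible(object)
}

#' @export
coef.pdui_fit <- function(object, ...) {
  c(short_abundance = object$short_abundance,
    long_abundance = object$long_abundance)
}

#' Fitted step function of a PDUI fit
#' @param object A `pdui_fit`.
#' @param ... Unused.
#' @export
fitted.pdui_fit <- function(object, ...) {
  if (object$status != "ok") return(rep(NA_real_, length(object$depth)))
  L <- length(object$depth)
  P <- object$proximal_site
  c(rep(object$long_abundance + object$short_abundance, P),
    rep(object$long_abundance, L - P))
}

#' @export
residuals.pdui_fit <- function(object, ...) {
  object$depth - stats::fitted(object)
}

#' Predict expected coverage at 3'UTR offsets
#' @param object A `pdui_fit`.
#' @param newdata Optional vector of 0-based offsets; defaults to all
#'   positions of the fitted UTR.
#' @param ... Unused.
#' @export
predict.pdui_fit <- function(object, newdata = NULL, ...) {
  if (object$status != "ok") stop("cannot predict from a low-coverage fit", call. = FALSE)
  pos <- if (is.null(newdata)) seq_len(length(object$depth)) - 1L else as.integer(newdata)
  ifelse(pos < object$proximal_site,
         object$long_abundance + object$short_abundance,
         object$long_abundance)
}

#' Simulate replicate coverage from a PDUI fit
#'
#' Draws Poisson per-base counts with the fitted step profile as mean —
#' the generative counterpart of the estimator.
#' @param object A `pdui_fit` with `status = "ok"`.
#' @param nsim Number of replicate profiles.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [coverage_profile] objects.
#' @export
simulate.pdui_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$status != "ok") stop("cannot simulate from a low-coverage fit", call. = FALSE)
  mu <- stats::fitted(object)
  draw <- function() coverage_profile(object$gene_id, stats::rpois(length(mu), mu))
  if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
}

#' Plot observed and fitted 3'UTR coverage
#' @param x A `pdui_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.pdui_fit <- function(x, ...) {
  pos <- seq_len(length(x$depth)) - 1L
  plot(pos, x$depth, type = "h", col = "grey70",
       xlab = "3'UTR offset (nt)", ylab = "read depth",
       main = sprintf("%s  PDUI = %.3f", x$gene_id, x$pdui), ...)
  if (x$status == "ok") {
    lines(pos, stats::fitted(x), col = "firebrick", lwd = 2)
    abline(v = x$proximal_site, lty = 2, col = "firebrick")
  }
  invisible(x)
}

#' @export
as.data.frame.pdui_fit <- function(x, ...) {
  data.frame(gene_id = x$gene_id, sample_id = x$sample_id,
             long_abundance = x$long_abundance,
             short_abundance = x$short_abundance,
             proximal_site = x$proximal_site, pdui = x$pdui,
             fit_sse = x$fit_sse, status = x$status,
             utr_length = length(x$depth), stringsAsFactors = FALSE)
}
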