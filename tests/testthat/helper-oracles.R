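# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# exhaustive breakpoint search with per-breakpoint closed-form NNLS,
# computed from plain segment means and an explicit residual sum
oracle_pdui <- function(depth, end_margin) {
  L <- length(depth)
  best <- NULL
  for (P in end_margin:(L - end_margin - 1)) {
    m1 <- mean(depth[1:P])
    m2 <- mean(depth[(P + 1):L])
    if (m1 >= m2) {
      w_L <- m2
      w_S <- m1 - m2
    } else {
      w_L <- mean(depth)
      w_S <- 0
    }
    fit <- c(rep(w_L + w_S, P), rep(w_L, L - P))
    sse <- sum((depth - fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(proximal_site = P, w_L = w_L, w_S = w_S, sse = sse,
                   pdui = if (w_L + w_S > 0) w_L / (w_L + w_S) else NA_real_)
    }
  }
  best
}

# all-windows PAS scan by substring comparison
oracle_scan <- function(sequence, hexamer_set = default_pas_hexamers()) {
  sequence <- chartr("uU", "tT", toupper(sequence))
  n <- nchar(sequence)
  if (n < 6) {
    return(data.frame(offset = integer(0), hexamer = character(0),
                      canonical = logical(0)))
  }
  windows <- substring(sequence, 1:(n - 5), 6:n)
  hit <- windows %in% hexamer_set
  data.frame(offset = which(hit) - 1L, hexamer = windows[hit],
             canonical = windows[hit] == "AATAAA", stringsAsFactors = FALSE)
}

# two-sided Fisher's exact p by direct hypergeometric enumeration
oracle_fisher_p <- function(case_long, case_short, ctrl_long, ctrl_short) {
  m <- case_long + case_short            # row 1 total
  n <- ctrl_long + ctrl_short
  k <- case_long + ctrl_long             # column total
  x_all <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x_all, m, n, k)
  p_obs <- stats::dhyper(case_long, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# adjusted Rand index between two labelings (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
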