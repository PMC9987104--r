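#' Simulate two-isoform 3'UTR coverage with known truth
#'
#' Generates a per-base coverage profile under the two-isoform model that the
#' PDUI estimator inverts: the short isoform contributes `depth_short`
#' reads/base up to (but not including) the proximal polyadenylation site, and
#' the long isoform contributes `depth_long` reads/base over the whole 3'UTR.
#' Expected depth is therefore a downward step of height `depth_short` at the
#' proximal site. With `noise_model = "poisson"` per-base counts are drawn
#' independently from Poisson distributions with those means; with `"none"`
#' the expected values are returned exactly.
#'
#' The planted PDUI is `depth_long / (depth_long + depth_short)`.
#'
#' @param utr_length 3'UTR length in nucleotides (> 0).
#' @param proximal_site 0-based offset of the proximal cleavage site from the
#'   UTR 5' end; must lie strictly inside `(0, utr_length)`. Positions
#'   `< proximal_site` are covered by both isoforms.
#' @param depth_long,depth_short Expected reads/base of the long and short
#'   isoform (>= 0, not both 0).
#' @param noise_model `"none"` or `"poisson"`.
#' @param gene_id Identifier attached to the profile.
#' @param seed Integer seed; required when `noise_model = "poisson"`.
#' @return A [coverage_profile] with attributes `pdui_true`,
#'   `proximal_site_true`, `depth_long`, `depth_short` carrying the planted
#'   truth.
#' @examples
#' cp <- simulate_coverage(200, 100, depth_long = 40, depth_short = 60)
#' attr(cp, "pdui_true")    # 0.4
#' @export
simulate_coverage <- function(utr_length, proximal_site, depth_long,
                              depth_short, noise_model = c("none", "poisson"),
                              gene_id = "sim_gene", seed = NULL) {
  noise_model <- match.arg(noise_model)
  stop_if_not_scalar_number(utr_length, "utr_length", lower = 1)
  stop_if_not_scalar_number(proximal_site, "proximal_site",
                            lower = 1, upper = utr_length - 1)
  stop_if_not_scalar_number(depth_long, "depth_long", lower = 0)
  stop_if_not_scalar_number(depth_short, "depth_short", lower = 0)
  if (depth_long + depth_short <= 0) {
    stop("depth_long + depth_short must be positive", call. = FALSE)
  }
  L <- as.integer(utr_length)
  P <- as.integer(proximal_site)
  mu <- c(rep(depth_long + depth_short, P), rep(depth_long, L - P))
  depth <- switch(noise_model,
    none = mu,
    poisson = {
      if (is.null(seed)) stop("'seed' is required for poisson noise", call. = FALSE)
      with_seed(seed, stats::rpois(L, mu))
    }
  )
  out <- coverage_profile(gene_id, depth)
  attr(out, "pdui_true") <- depth_long / (depth_long + depth_short)
  attr(out, "proximal_site_true") <- P
  attr(out, "depth_long") <- depth_long
  attr(out, "depth_short") <- depth_short
  out
}
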