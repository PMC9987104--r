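# Condition contrasts on PDUI estimates: descriptive ΔPDUI, a count-based
# significance test, and per-sample APA event burden.

pdui_values <- function(records, arg) {
  if (length(records) == 0L) stop("'", arg, "' is empty", call. = FALSE)
  if (inherits(records, "pdui_fit")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "pdui_fit")))
  if (any(vapply(records, function(r) r$status, character(1)) != "ok")) {
    stop("all records in '", arg, "' must have status = 'ok'", call. = FALSE)
  }
  list(gene = unique(vapply(records, function(r) r$gene_id, character(1))),
       pdui = vapply(records, function(r) r$pdui, numeric(1)),
       records = records)
}

#' Mean PDUI difference between two conditions
#'
#' ΔPDUI is the mean PDUI of the case condition minus the mean PDUI of the
#' control condition for one gene: positive values indicate 3'UTR
#' lengthening (shift toward distal polyadenylation-site usage) in the case
#' condition, negative values shortening. The function is antisymmetric in
#' its arguments. The call reported here is purely descriptive (sign of
#' ΔPDUI); use [test_apa_change()] for a significance-gated call.
#'
#' @param case,control Lists of [estimate_pdui()] fits for the same gene
#'   (one per replicate/sample), all with `status = "ok"`.
#' @return A one-row `data.frame` of class `apa_change` with columns
#'   `gene_id`, `mean_pdui_case`, `mean_pdui_control`, `delta_pdui`,
#'   `p_value` (`NA` here), `call`.
#' @examples
#' ca <- lapply(c(.8, .8), function(p)
#'   estimate_pdui(simulate_coverage(200, 100, 10 * p, 10 * (1 - p)), end_margin = 10))
#' co <- lapply(c(.6, .6), function(p)
#'   estimate_pdui(simulate_coverage(200, 100, 10 * p, 10 * (1 - p)), end_margin = 10))
#' delta_pdui(ca, co)$delta_pdui   # +0.2
#' @export
delta_pdui <- function(case, control) {
  a <- pdui_values(case, "case")
  b <- pdui_values(control, "control")
  gene <- union(a$gene, b$gene)
  if (length(gene) != 1L) {
    stop("case and control must cover a single shared gene_id; got: ",
         paste(gene, collapse = ", "), call. = FALSE)
  }
  d <- mean(a$pdui) - mean(b$pdui)
  call <- if (is.na(d) || d == 0) "unchanged"
          else if (d > 0) "lengthened" else "shortened"
  structure(
    data.frame(gene_id = gene, mean_pdui_case = mean(a$pdui),
               mean_pdui_control = mean(b$pdui), delta_pdui = d,
               p_value = NA_real_,
               call = call,
               stringsAsFactors = FALSE),
    class = c("apa_change", "data.frame")
  )
}

# two-sided Fisher's exact p for a 2x2 of pooled isoform counts
fisher_p <- function(case_long, case_short, ctrl_long, ctrl_short) {
  m <- matrix(c(case_long, case_short, ctrl_long, ctrl_short), nrow = 2)
  if (sum(m[, 1]) == 0 || sum(m[, 2]) == 0) return(NA_real_)
  stats::fisher.test(m)$p.value
}

#' Test a gene for significant APA change between conditions
#'
#' Computes ΔPDUI as in [delta_pdui()] and assesses significance with a
#' two-sided Fisher's exact test on pooled long/short isoform read counts.
#' Counts are reconstructed from the fitted abundances as
#' `round(abundance x UTR length)` summed over the replicates of each
#' condition — the natural count scale of the coverage model. A gene is
#' called `lengthened` (`shortened`) only when `p < alpha` and
#' `|ΔPDUI| >= min_abs_delta`; otherwise `unchanged`.
#'
#' @inheritParams delta_pdui
#' @param alpha Significance level in (0,1); default 0.05.
#' @param min_abs_delta Minimum |ΔPDUI| for a directional call; default 0.05.
#' @return A one-row `apa_change` data frame (see [delta_pdui()]) with the
#'   Fisher p-value filled in; zero total counts in either condition give
#'   `call = "unchanged"` with `p_value = 1`.
#' @export
test_apa_change <- function(case, control, alpha = 0.05, min_abs_delta = 0.05) {
  stop_if_not_scalar_number(alpha, "alpha", lower = .Machine$double.eps,
                            upper = 1 - .Machine$double.eps)
  stop_if_not_scalar_number(min_abs_delta, "min_abs_delta", lower = 0, upper = 1)
  out <- delta_pdui(case, control)
  counts <- function(vals) {
    recs <- vals$records
    long <- sum(vapply(recs, function(r) r$long_abundance * length(r$depth), numeric(1)))
    short <- sum(vapply(recs, function(r) r$short_abundance * length(r$depth), numeric(1)))
    round(c(long = long, short = short))
  }
  cc <- counts(pdui_values(case, "case"))
  kk <- counts(pdui_values(control, "control"))
  p <- fisher_p(cc["long"], cc["short"], kk["long"], kk["short"])
  if (is.na(p)) {           # a condition with zero total counts is untestable
    out$p_value <- 1
    out$call <- "unchanged"
    return(out)
  }
  out$p_value <- p
  out$call <- if (p < alpha && abs(out$delta_pdui) >= min_abs_delta) {
    if (out$delta_pdui > 0) "lengthened" else "shortened"
  } else "unchanged"
  out
}

#' Per-sample counts of APA-altered genes
#'
#' For each sample, counts the genes whose PDUI deviates from a per-gene
#' reference by at least `event_threshold`: upward deviations are 3'UTR
#' lengthening events, downward deviations shortening events. The reference
#' is either the cohort median PDUI of the gene (tumor-only cohorts) or the
#' sample's paired normal. These per-sample burdens are the quantity that
#' regulator expression is correlated against in [correlation_screen()].
#'
#' @param pdui_matrix Numeric gene x sample matrix of PDUI values in
#'   \[0,1\] (NA allowed; NA entries are skipped).
#' @param reference `"cohort_median"` or `"paired_normal"`.
#' @param event_threshold Minimum |PDUI - reference| to count as an event
#'   (> 0; default 0.2).
#' @param pairing Named character vector mapping each tumor sample (name)
#'   to its paired normal sample (value); required for
#'   `reference = "paired_normal"`.
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `n_lengthened`, `n_shortened`.
#' @export
apa_event_counts <- function(pdui_matrix,
                             reference = c("cohort_median", "paired_normal"),
                             event_threshold = 0.2, pairing = NULL) {
  reference <- match.arg(reference)
  stopifnot(is.matrix(pdui_matrix))
  if (ncol(pdui_matrix) < 3L) stop("need at least 3 samples", call. = FALSE)
  stop_if_not_scalar_number(event_threshold, "event_threshold",
                            lower = .Machine$double.eps, upper = 1)
  samples <- colnames(pdui_matrix) %||% as.character(seq_len(ncol(pdui_matrix)))
  if (reference == "cohort_median") {
    ref <- apply(pdui_matrix, 1L, stats::median, na.rm = TRUE)
    dev <- pdui_matrix - ref
  } else {
    if (is.null(pairing)) {
      stop("reference = 'paired_normal' requires 'pairing' metadata", call. = FALSE)
    }
    tumor <- intersect(samples, names(pairing))
    if (length(tumor) == 0L) stop("no samples found in 'pairing'", call. = FALSE)
    dev <- pdui_matrix[, tumor, drop = FALSE] -
      pdui_matrix[, pairing[tumor], drop = FALSE]
    samples <- tumor
  }
  data.frame(
    sample_id = samples,
    n_lengthened = colSums(dev >= event_threshold, na.rm = TRUE),
    n_shortened = colSums(dev <= -event_threshold, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
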