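# Three-criterion APA target funnel and the qPCR quantitation utilities
# used to validate nominated targets.

#' Nominate APA target genes by the three-criterion funnel
#'
#' A gene is selected when it (1) carries at least 2 PAS sites in its
#' 3'UTR, (2) is upregulated in tumor, and (3) undergoes significant 3'UTR
#' lengthening in the case condition (`call == "lengthened"` with raw
#' `p < p_cutoff`). Genes missing from any input have that criterion
#' marked unevaluable (`NA`) and fail closed (`selected = FALSE`).
#'
#' @param pas_classifications `data.frame` with `gene_id` and `n_pas`
#'   (e.g. from [classify_utrs()]).
#' @param deg_tumor_vs_normal `data.frame` with `gene_id`, `direction`
#'   and optionally `fdr`: "upregulated in tumor" means
#'   `direction == "up"` and, when an `fdr` column is present,
#'   `fdr < fdr_cutoff`.
#' @param apa_change_results `data.frame` with `gene_id`, `delta_pdui`,
#'   `p_value`, `call` (rows of [test_apa_change()] results).
#' @param p_cutoff Raw p-value cutoff for the lengthening criterion
#'   (default 0.001).
#' @param fdr_cutoff FDR cutoff for the tumor-expression criterion
#'   (default 0.05).
#' @return `data.frame` with one row per gene in the union of the three
#'   inputs: `gene_id`, `n_pas`, `tumor_up`, `delta_pdui`,
#'   `lengthening_p`, `pass_pas`, `pass_tumor_up`, `pass_lengthening`,
#'   `selected`; sorted by ascending `lengthening_p` (ties and NAs by
#'   gene id, NAs last).
#' @export
filter_targets <- function(pas_classifications, deg_tumor_vs_normal,
                           apa_change_results, p_cutoff = 0.001,
                           fdr_cutoff = 0.05) {
  stop_if_not_scalar_number(p_cutoff, "p_cutoff",
                            lower = .Machine$double.xmin, upper = 1)
  genes <- sort(unique(c(pas_classifications$gene_id,
                         deg_tumor_vs_normal$gene_id,
                         apa_change_results$gene_id)))
  i1 <- match(genes, pas_classifications$gene_id)
  i2 <- match(genes, deg_tumor_vs_normal$gene_id)
  i3 <- match(genes, apa_change_results$gene_id)

  n_pas <- pas_classifications$n_pas[i1]
  tumor_up <- deg_tumor_vs_normal$direction[i2] == "up"
  if ("fdr" %in% names(deg_tumor_vs_normal)) {
    tumor_up <- tumor_up & deg_tumor_vs_normal$fdr[i2] < fdr_cutoff
  }
  delta <- apa_change_results$delta_pdui[i3]
  lp <- apa_change_results$p_value[i3]
  lengthening <- apa_change_results$call[i3] == "lengthened" & lp < p_cutoff

  pass1 <- n_pas >= 2L
  out <- data.frame(
    gene_id = genes, n_pas = n_pas, tumor_up = tumor_up,
    delta_pdui = delta, lengthening_p = lp,
    pass_pas = pass1, pass_tumor_up = tumor_up, pass_lengthening = lengthening,
    stringsAsFactors = FALSE
  )
  # unevaluable criteria (NA) fail closed
  out$selected <- !is.na(pass1) & pass1 &
    !is.na(tumor_up) & tumor_up &
    !is.na(lengthening) & lengthening
  out <- out[order(out$lengthening_p, out$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-transcript-to-total-transcript ratio
#'
#' The qPCR analogue of PDUI: the abundance measured with long-isoform
#' specific primers divided by the abundance measured with primers common
#' to both isoforms. Equals the PDUI when the signals are isoform
#' abundances.
#'
#' @param long_signal,total_signal Non-negative abundances;
#'   `total_signal` must be positive and `long_signal <= total_signal`
#'   (up to a clipping tolerance of 1e-9).
#' @param gene_id Optional identifier(s).
#' @return `data.frame` with `gene_id`, `long_signal`, `total_signal`,
#'   `ratio` in \[0,1\].
#' @export
long_to_total_ratio <- function(long_signal, total_signal,
                                gene_id = NA_character_) {
  if (any(!is.finite(total_signal)) || any(total_signal <= 0)) {
    stop("total_signal must be positive", call. = FALSE)
  }
  if (any(long_signal < 0) || any(long_signal > total_signal * (1 + 1e-9))) {
    stop("long_signal must lie in [0, total_signal]", call. = FALSE)
  }
  data.frame(gene_id = gene_id, long_signal = long_signal,
             total_signal = total_signal,
             ratio = clamp01(long_signal / total_signal),
             stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' Converts qPCR cycle thresholds into a fold change:
#' `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in
#'   the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in
#'   the control condition.
#' @return Fold change (1 when ddCt = 0, 0.5 when ddCt = 1, 4 when
#'   ddCt = -2).
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
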