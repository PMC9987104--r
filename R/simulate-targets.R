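#' Construct a PDUI record from isoform abundances
#'
#' Builds the record [test_apa_change()] and [delta_pdui()] consume without
#' a coverage fit, for cases where long/short isoform abundances come from
#' an external source. The record carries the implied noise-free step
#' coverage, so pooled isoform counts (`abundance x UTR length`) and PDUI
#' are consistent with an [estimate_pdui()] fit of the same profile.
#'
#' @param gene_id Gene identifier.
#' @param long_abundance,short_abundance Isoform abundances in reads/base.
#' @param utr_length 3'UTR length in nucleotides.
#' @param proximal_site 0-based proximal-site offset (default mid-UTR).
#' @param sample_id Optional sample identifier.
#' @return A `pdui_fit` object with `status = "ok"`.
#' @export
pdui_record <- function(gene_id, long_abundance, short_abundance, utr_length,
                        proximal_site = utr_length %/% 2,
                        sample_id = NA_character_) {
  stop_if_not_scalar_number(long_abundance, "long_abundance", lower = 0)
  stop_if_not_scalar_number(short_abundance, "short_abundance", lower = 0)
  stop_if_not_scalar_number(utr_length, "utr_length", lower = 2)
  stop_if_not_scalar_number(proximal_site, "proximal_site",
                            lower = 1, upper = utr_length - 1)
  L <- as.integer(utr_length)
  P <- as.integer(proximal_site)
  tot <- long_abundance + short_abundance
  structure(
    list(gene_id = as.character(gene_id), sample_id = sample_id,
         long_abundance = long_abundance, short_abundance = short_abundance,
         proximal_site = P,
         pdui = if (tot > 0) long_abundance / tot else NA_real_,
         fit_sse = 0,
         status = "ok",
         depth = c(rep(tot, P), rep(long_abundance, L - P)),
         min_mean_depth = 0, end_margin = 1L),
    class = "pdui_fit"
  )
}

#' Simulate the three input tables of the target funnel
#'
#' Generates, with planted truth, the inputs [filter_targets()] consumes: a
#' PAS-count table, a tumor-vs-normal DEG table, and per-gene APA-change
#' results contrasting a regulator-overexpression condition against
#' control. Exactly `n_selected` genes satisfy all three criteria; every
#' other gene fails at least one, and each single-criterion failure mode is
#' guaranteed to occur so the funnel's monotonicity is exercised. The
#' APA-change p-values are not assigned: per-gene case/control isoform
#' abundances are constructed and [test_apa_change()] is run on them, so
#' significance comes out of the same test the analysis uses. Genes
#' planted to fail only the lengthening cutoff get a fixed moderate
#' lengthening whose Fisher p lands between `p_cutoff` and 0.05.
#'
#' @param n_genes Number of genes (default 500).
#' @param n_selected Number of genes satisfying all three criteria
#'   (default 47).
#' @param seed Integer seed.
#' @param p_cutoff Lengthening p cutoff the funnel will use
#'   (default 0.001).
#' @return List with `pas`, `deg`, `apa` data frames and `truth`
#'   (list with `selected` gene ids and the per-gene `flags` table).
#' @export
simulate_target_tables <- function(n_genes = 500, n_selected = 47, seed,
                                   p_cutoff = 0.001) {
  stop_if_not_scalar_number(n_genes, "n_genes", lower = 10)
  stop_if_not_scalar_number(n_selected, "n_selected", lower = 1,
                            upper = n_genes - 3)
  with_seed(seed, {
    genes <- sprintf("T%04d", seq_len(n_genes))
    sel <- sort(sample(genes, n_selected))
    rest <- setdiff(genes, sel)

    # failure patterns over (pas, tumor_up, lengthening); the first three
    # non-selected genes fail exactly one criterion each
    patterns <- expand.grid(p1 = c(TRUE, FALSE), p2 = c(TRUE, FALSE),
                            p3 = c(TRUE, FALSE))
    patterns <- patterns[!(patterns$p1 & patterns$p2 & patterns$p3), ]
    single_fail <- patterns[rowSums(patterns) == 2, ]
    idx <- c(seq_len(3), sample(nrow(patterns), length(rest) - 3, replace = TRUE))
    flags <- rbind(
      data.frame(gene_id = sel, p1 = TRUE, p2 = TRUE, p3 = TRUE,
                 stringsAsFactors = FALSE),
      data.frame(gene_id = rest,
                 p1 = c(single_fail$p1, patterns$p1[idx[-(1:3)]]),
                 p2 = c(single_fail$p2, patterns$p2[idx[-(1:3)]]),
                 p3 = c(single_fail$p3, patterns$p3[idx[-(1:3)]]),
                 stringsAsFactors = FALSE)
    )
    flags <- flags[order(flags$gene_id), , drop = FALSE]

    pas <- data.frame(
      gene_id = flags$gene_id,
      n_pas = ifelse(flags$p1, sample(2:4, n_genes, replace = TRUE), 1L),
      stringsAsFactors = FALSE
    )
    deg <- data.frame(
      gene_id = flags$gene_id,
      direction = ifelse(flags$p2, "up",
                         sample(c("down", "ns"), n_genes, replace = TRUE)),
      fdr = ifelse(flags$p2, stats::runif(n_genes, 1e-6, 0.04),
                   stats::runif(n_genes)),
      stringsAsFactors = FALSE
    )

    L <- 200L
    apa_rows <- lapply(seq_len(n_genes), function(i) {
      if (flags$p3[i]) {
        # strong lengthening: p far below any reasonable cutoff
        jit <- stats::runif(1, 0.9, 1.1)
        case <- list(w_L = 6 * jit, w_S = 2)
        ctrl <- list(w_L = 2, w_S = 6 * jit)
      } else {
        mode <- (i %% 3) + 1L
        if (mode == 1L) {          # significant shortening
          case <- list(w_L = 2, w_S = 6)
          ctrl <- list(w_L = 6, w_S = 2)
        } else if (mode == 2L) {   # no change
          case <- list(w_L = 4, w_S = 4)
          ctrl <- list(w_L = 4, w_S = 4)
        } else {                   # lengthened, but only at p ~ 0.01
          case <- list(w_L = 0.625, w_S = 0.375)
          ctrl <- list(w_L = 0.5, w_S = 0.5)
        }
      }
      rec <- function(ab) pdui_record(flags$gene_id[i], ab$w_L, ab$w_S, L)
      test_apa_change(list(rec(case)), list(rec(ctrl)),
                      alpha = 0.05, min_abs_delta = 0.05)
    })
    apa <- do.call(rbind, apa_rows)

    list(pas = pas, deg = deg, apa = apa,
         truth = list(selected = sel, flags = flags,
                      params = list(n_genes = n_genes,
                                    n_selected = n_selected,
                                    p_cutoff = p_cutoff,
                                    seed = as.integer(seed))))
  })
}
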