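# Cohort APA landscape: PDUI-based sample clustering and the staged
# regulator screen (differential expression -> gene-set intersection ->
# correlation with APA burden -> core-factor overlap).

#' Cluster cohort samples by PDUI profile
#'
#' Agglomerative hierarchical clustering of samples on their gene-wise PDUI
#' profiles (Euclidean distance, pairwise-complete over genes with < 20%
#' missing values; average linkage by default), with the tree cut into `k`
#' groups. Groups are relabeled so that label `A` has the highest mean PDUI
#' (globally longest 3'UTRs) and the last label the lowest.
#'
#' @param pdui_matrix Gene x sample matrix with entries in \[0,1\] or NA.
#' @param k Number of subgroups (default 3).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param max_na_frac Genes with a higher fraction of NA entries are
#'   excluded from the distance (default 0.2).
#' @return Named character vector mapping `sample_id` to subgroup label
#'   (`"A"`, `"B"`, ...), with attributes `group_mean_pdui` and `hclust`.
#' @export
cluster_samples <- function(pdui_matrix, k = 3, linkage = "average",
                            max_na_frac = 0.2) {
  stopifnot(is.matrix(pdui_matrix))
  stop_if_not_scalar_number(k, "k", lower = 2)
  if (ncol(pdui_matrix) < k) {
    stop("need at least k = ", k, " samples, got ", ncol(pdui_matrix),
         call. = FALSE)
  }
  rng <- range(pdui_matrix, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("all-NA PDUI matrix", call. = FALSE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("PDUI entries must lie in [0,1]", call. = FALSE)
  }
  keep <- rowMeans(is.na(pdui_matrix)) < max_na_frac
  if (!any(keep)) stop("no gene passes the NA filter", call. = FALSE)
  m <- pdui_matrix[keep, , drop = FALSE]

  d <- stats::dist(t(m))                       # pairwise-complete Euclidean
  if (anyNA(d)) stop("samples with no shared non-NA genes", call. = FALSE)
  hc <- stats::hclust(d, method = linkage)
  if (max(hc$height) <= .Machine$double.eps^0.5) {
    warning("samples are indistinguishable; returning an arbitrary but ",
            "deterministic split")
  }
  cl <- stats::cutree(hc, k = k)

  # relabel by descending group mean PDUI; ties break on cluster index
  means <- vapply(seq_len(k), function(i) mean(m[, cl == i], na.rm = TRUE),
                  numeric(1))
  ord <- order(-means, seq_len(k))
  labels <- LETTERS[seq_len(k)]
  out <- stats::setNames(labels[match(cl, ord)], colnames(m))
  attr(out, "group_mean_pdui") <- stats::setNames(means[ord], labels)
  attr(out, "hclust") <- hc
  out
}

#' Differential expression between two PDUI subgroups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on `log2(expression + 1)`
#' between the case and reference subgroups (default contrast: C, the
#' short-3'UTR subgroup, versus A), with Benjamini-Hochberg FDR control.
#' The log2 fold change is the difference of group means on the log2 scale
#' (case minus reference).
#'
#' @param expr_matrix Gene x sample expression matrix (linear scale).
#' @param groups Named subgroup assignment as from [cluster_samples()].
#' @param contrast Length-2 character vector `c(case, reference)`;
#'   default `c("C", "A")`.
#' @param fdr_threshold,lfc_threshold Thresholds for a directional call
#'   (defaults 0.05 and 1).
#' @return `data.frame` with `gene_id`, `log2_fold_change`, `p_value`,
#'   `fdr`, `direction` (`"up_in_<case>"`, `"down_in_<case>"`, `"ns"`).
#' @export
differential_expression <- function(expr_matrix, groups,
                                    contrast = c("C", "A"),
                                    fdr_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(is.matrix(expr_matrix), length(contrast) == 2L)
  groups <- groups[intersect(names(groups), colnames(expr_matrix))]
  case_s <- names(groups)[groups == contrast[1]]
  ref_s <- names(groups)[groups == contrast[2]]
  if (length(case_s) < 3L || length(ref_s) < 3L) {
    stop("both contrast groups need >= 3 samples (got ", length(case_s),
         " and ", length(ref_s), ")", call. = FALSE)
  }
  lx <- log2(expr_matrix[, case_s, drop = FALSE] + 1)
  ly <- log2(expr_matrix[, ref_s, drop = FALSE] + 1)
  p <- vapply(seq_len(nrow(expr_matrix)), function(i) {
    xi <- lx[i, ]; yi <- ly[i, ]
    if (max(c(xi, yi)) == min(c(xi, yi))) return(1)   # constant gene
    suppressWarnings(stats::wilcox.test(xi, yi, exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  lfc <- rowMeans(lx) - rowMeans(ly)
  fdr <- stats::p.adjust(p, method = "BH")
  up <- paste0("up_in_", contrast[1])
  down <- paste0("down_in_", contrast[1])
  direction <- ifelse(fdr < fdr_threshold & lfc > lfc_threshold, up,
               ifelse(fdr < fdr_threshold & lfc < -lfc_threshold, down, "ns"))
  data.frame(gene_id = rownames(expr_matrix) %||% as.character(seq_len(nrow(expr_matrix))),
             log2_fold_change = lfc, p_value = p, fdr = fdr,
             direction = direction, row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect directional DEGs with APA-related gene sets
#'
#' Genes down in the short-3'UTR subgroup that belong to at least one
#' supplied gene set become candidate 3'UTR-lengthen regulators; genes up
#' in that subgroup become candidate shorten regulators. Membership is the
#' union across sets.
#'
#' @param degs `data.frame` from [differential_expression()].
#' @param genesets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return `data.frame` of candidates: `gene_id`, `role`
#'   (`"lengthen_regulator"` / `"shorten_regulator"`),
#'   `log2_fold_change`, `fdr`, `in_geneset` (always TRUE).
#' @export
intersect_genesets <- function(degs, genesets) {
  if (length(genesets) == 0L) stop("genesets must be non-empty", call. = FALSE)
  universe <- unique(unlist(genesets, use.names = FALSE))
  dir_deg <- degs[degs$direction != "ns", , drop = FALSE]
  if (nrow(dir_deg) > 0L) {
    unmatched <- sum(!dir_deg$gene_id %in% universe)
    if (unmatched == nrow(dir_deg)) {
      warning("none of the ", unmatched, " directional DEGs match the ",
              "gene-set namespace; check gene identifier conventions")
    }
  }
  hit <- dir_deg[dir_deg$gene_id %in% universe, , drop = FALSE]
  role <- ifelse(grepl("^down_in_", hit$direction),
                 "lengthen_regulator", "shorten_regulator")
  out <- data.frame(gene_id = hit$gene_id, role = role,
                    log2_fold_change = hit$log2_fold_change, fdr = hit$fdr,
                    in_geneset = rep(TRUE, nrow(hit)), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Correlate candidate regulator expression with APA burden
#'
#' For each candidate, computes the Pearson correlation between its
#' expression across samples and the per-sample count of APA events
#' matching its role (lengthen regulators against `n_lengthened`, shorten
#' regulators against `n_shortened`), and shortlists candidates with
#' `|r| > r_threshold` and `p < p_threshold`.
#'
#' @param expr_matrix Gene x sample expression matrix.
#' @param apa_counts `data.frame` from [apa_event_counts()].
#' @param candidates `data.frame` from [intersect_genesets()] (columns
#'   `gene_id`, `role`).
#' @param r_threshold,p_threshold Shortlisting thresholds (defaults 0.3
#'   and 0.05).
#' @return Shortlisted candidates (`gene_id`, `role`, `pearson_r`,
#'   `p_value`), ordered by descending `|r|`; the full candidate table is
#'   attached as attribute `"all_candidates"`. Zero-variance candidates
#'   are excluded with a warning.
#' @export
correlation_screen <- function(expr_matrix, apa_counts, candidates,
                               r_threshold = 0.3, p_threshold = 0.05) {
  stop_if_not_scalar_number(r_threshold, "r_threshold", lower = 0, upper = 1)
  stop_if_not_scalar_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  if (nrow(apa_counts) < 3L) stop("need >= 3 samples", call. = FALSE)
  samples <- intersect(apa_counts$sample_id, colnames(expr_matrix))
  if (length(samples) < 3L) {
    stop("APA counts and expression matrix share < 3 samples", call. = FALSE)
  }
  counts <- apa_counts[match(samples, apa_counts$sample_id), , drop = FALSE]
  missing <- setdiff(candidates$gene_id, rownames(expr_matrix))
  if (length(missing) > 0L) {
    stop("candidate genes absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene_id[i]
    x <- expr_matrix[g, samples]
    series <- if (candidates$role[i] == "lengthen_regulator") {
      counts$n_lengthened
    } else {
      counts$n_shortened
    }
    if (stats::sd(x) == 0 || stats::sd(series) == 0) {
      warning("excluding '", g, "': correlation undefined (zero variance)")
      return(NULL)
    }
    ct <- stats::cor.test(x, series, method = "pearson")
    data.frame(gene_id = g, role = candidates$role[i],
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  all_cand <- do.call(rbind, rows)
  if (is.null(all_cand)) {
    all_cand <- data.frame(gene_id = character(0), role = character(0),
                           pearson_r = numeric(0), p_value = numeric(0))
  }
  short <- all_cand[abs(all_cand$pearson_r) > r_threshold &
                      all_cand$p_value < p_threshold, , drop = FALSE]
  short <- short[order(-abs(short$pearson_r), short$gene_id), , drop = FALSE]
  rownames(short) <- NULL
  attr(short, "all_candidates") <- all_cand
  short
}

#' Overlap shortlisted regulators with known core APA factors
#'
#' Intersects the correlation shortlist with a list of core APA machinery
#' genes and ranks the overlap by descending `|r|`; rank 1 is reported as
#' the key regulator. Ties in `|r|` break lexicographically on gene id.
#'
#' @param shortlist `data.frame` from [correlation_screen()].
#' @param core_factors Character vector of core APA factor gene ids.
#' @return The intersected `data.frame` with a `rank` column (0 rows when
#'   the intersection is empty).
#' @export
overlap_core_factors <- function(shortlist, core_factors) {
  if (length(core_factors) == 0L) stop("core factor list is empty", call. = FALSE)
  hit <- shortlist[shortlist$gene_id %in% core_factors, , drop = FALSE]
  hit <- hit[order(-abs(hit$pearson_r), hit$gene_id), , drop = FALSE]
  if (nrow(hit) > 0L) hit$rank <- seq_len(nrow(hit))
  else hit$rank <- integer(0)
  rownames(hit) <- NULL
  hit
}

#' Run the full APA regulator screen
#'
#' Chains [cluster_samples()], [differential_expression()] (contrast: the
#' lowest- vs highest-PDUI subgroup), [intersect_genesets()],
#' [apa_event_counts()], [correlation_screen()] and
#' [overlap_core_factors()] into the staged screen, returning every
#' intermediate result plus the rank-1 key regulator.
#'
#' @param expr_matrix,pdui_matrix Gene x sample matrices sharing sample
#'   identifiers.
#' @param genesets Named list of APA-related gene sets.
#' @param core_factors Character vector of core APA factor gene ids.
#' @param k Number of subgroups (default 3).
#' @param event_threshold Per-sample APA event threshold (default 0.2).
#' @param r_threshold,p_threshold Correlation shortlist thresholds.
#' @param fdr_threshold,lfc_threshold DEG thresholds.
#' @param linkage Clustering linkage (default `"average"`).
#' @return List with `groups`, `deg`, `candidates`, `apa_counts`,
#'   `shortlist`, `core_overlap`, `key_regulator` (gene id or `NA`).
#' @export
screen_apa_regulators <- function(expr_matrix, pdui_matrix, genesets,
                                  core_factors, k = 3,
                                  event_threshold = 0.2, r_threshold = 0.3,
                                  p_threshold = 0.05, fdr_threshold = 0.05,
                                  lfc_threshold = 1, linkage = "average") {
  groups <- cluster_samples(pdui_matrix, k = k, linkage = linkage)
  labels <- LETTERS[seq_len(k)]
  deg <- differential_expression(expr_matrix, groups,
                                 contrast = c(labels[k], labels[1]),
                                 fdr_threshold = fdr_threshold,
                                 lfc_threshold = lfc_threshold)
  candidates <- intersect_genesets(deg, genesets)
  counts <- apa_event_counts(pdui_matrix, reference = "cohort_median",
                             event_threshold = event_threshold)
  shortlist <- correlation_screen(expr_matrix, counts, candidates,
                                  r_threshold = r_threshold,
                                  p_threshold = p_threshold)
  core <- overlap_core_factors(shortlist, core_factors)
  list(groups = groups, deg = deg, candidates = candidates,
       apa_counts = counts, shortlist = shortlist, core_overlap = core,
       key_regulator = if (nrow(core) > 0L) core$gene_id[1] else NA_character_)
}
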