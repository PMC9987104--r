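#' Simulate a tumor cohort with planted APA structure
#'
#' Generates the pair of gene x sample matrices the landscape/screen stages
#' consume — a PDUI matrix and an expression matrix sharing sample
#' identifiers — together with the complete planted truth. The generated
#' cohort emulates a TCGA-style tumor collection:
#'
#' * Three sample subgroups (A/B/C) whose per-gene PDUI baselines are
#'   shifted by `+shift/2`, `0`, `-shift/2`, so subgroup A carries globally
#'   longer 3'UTRs than C by `subgroup_shift`.
#' * Per-sample APA events: a pool of event-capable genes is lengthened or
#'   shortened (by `event_delta`) in individual samples; the number of
#'   events per sample (its APA burden) is itself subgroup-linked, with
#'   separation proportional to `subgroup_shift`.
#' * Four planted regulators (two lengthening, two shortening) whose
#'   expression is constructed to correlate at Pearson `regulator_effect`
#'   with the realized per-sample count of lengthening or shortening
#'   events, as measured by [apa_event_counts()] against the cohort
#'   median. Because burden is subgroup-linked, the regulators are also
#'   differentially expressed between subgroups A and C. Only the key
#'   (first lengthening) regulator appears in the core-factor list, so the
#'   screen's core overlap resolves to it.
#' * Generic differentially expressed genes between the subgroups (fold
#'   scaled by `subgroup_shift`), plus log-normal background expression.
#' * APA-related gene sets containing all planted regulators, and a core
#'   APA-factor list containing the key regulator plus background decoys.
#'
#' Setting `subgroup_shift = 0` and `regulator_effect = 0` yields a null
#' cohort: the matrices carry no information about the (still recorded)
#' labels, so any downstream separation is chance.
#'
#' @param n_genes,n_samples Matrix dimensions (defaults 500 x 60).
#' @param subgroup_sizes Integer vector of 3 subgroup sizes summing to
#'   `n_samples` (default 20/20/20).
#' @param effect_sizes List with `subgroup_shift` (A-vs-C mean PDUI
#'   difference, in \[0, 0.5\]; default 0.25) and `regulator_effect`
#'   (target Pearson correlation of the key regulator, in \[0, 1\];
#'   default 0.6).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param pdui_noise_sd Gaussian jitter added to PDUI entries before
#'   clamping to \[0,1\] (default 0.06; 0 gives the noise-free
#'   configuration in which event counts are exact).
#' @param event_delta PDUI displacement of a planted APA event
#'   (default 0.45; large enough that an event clears the default
#'   [apa_event_counts()] threshold of 0.2 from any subgroup).
#' @param event_pool_size Number of event-capable genes (default: 64% of
#'   `n_genes`, i.e. 320 at the default size). Events per gene are capped
#'   so that no gene's cohort median can be displaced from its baseline.
#' @param burden_mean,burden_sd Mean and SD of the per-sample event count
#'   in subgroup B (defaults 18 and 3); subgroup separation of the burden
#'   is `56 * subgroup_shift` counts.
#' @param n_deg Number of generic DEGs planted in each direction
#'   (default 60, reduced proportionally for small `n_genes`).
#' @return A list with components `pdui` (matrix), `expr` (matrix), and
#'   `truth` — a list with `subgroup`, `tumor_label`, `regulators`
#'   (data.frame: `gene_id`, `role`, `effect`, `is_key`, `in_core`),
#'   `core_factors`, `genesets`, `event_genes` (per-sample lists),
#'   `event_counts`, `deg` (planted fold changes), and `params`.
#' @examples
#' cohort <- simulate_cohort(n_genes = 100, n_samples = 30,
#'                           subgroup_sizes = c(10, 10, 10), seed = 1)
#' dim(cohort$pdui)
#' subset(cohort$truth$regulators, is_key)$gene_id
#' @export
simulate_cohort <- function(n_genes = 500, n_samples = 60,
                            subgroup_sizes = c(20, 20, 20),
                            effect_sizes = list(subgroup_shift = 0.25,
                                                regulator_effect = 0.6),
                            seed,
                            pdui_noise_sd = 0.06, event_delta = 0.45,
                            event_pool_size = NULL,
                            burden_mean = 18, burden_sd = 3, n_deg = NULL) {
  stop_if_not_scalar_number(n_genes, "n_genes", lower = 1)
  stop_if_not_scalar_number(n_samples, "n_samples", lower = 3)
  if (length(subgroup_sizes) != 3L || any(subgroup_sizes < 1) ||
      sum(subgroup_sizes) != n_samples) {
    stop("subgroup_sizes must be 3 positive counts summing to n_samples",
         call. = FALSE)
  }
  shift <- effect_sizes$subgroup_shift %||% 0.25
  r_eff <- effect_sizes$regulator_effect %||% 0.6
  stop_if_not_scalar_number(shift, "subgroup_shift", lower = 0, upper = 0.5)
  stop_if_not_scalar_number(r_eff, "regulator_effect", lower = 0, upper = 1)
  stop_if_not_scalar_number(pdui_noise_sd, "pdui_noise_sd", lower = 0, upper = 0.3)
  stop_if_not_scalar_number(event_delta, "event_delta", lower = 0, upper = 1)
  n_deg <- n_deg %||% min(60L, n_genes %/% 8L)
  event_pool_size <- event_pool_size %||% floor(0.64 * n_genes)
  n_special <- 4L + 7L + 2L * n_deg + event_pool_size
  if (n_genes < n_special) {
    stop("n_genes too small for the planted structure (need >= ", n_special, ")",
         call. = FALSE)
  }

  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    samples <- sprintf("S%03d", seq_len(n_samples))
    subgroup <- rep(c("A", "B", "C"), times = subgroup_sizes)
    names(subgroup) <- samples
    score <- c(A = 1, B = 0, C = -1)[subgroup]   # +1 long-UTR, -1 short-UTR

    # disjoint special gene sets
    special <- sample(genes, n_special)
    reg_ids <- special[1:4]
    decoy_core <- special[5:11]
    deg_up <- special[12:(11 + n_deg)]                     # up in subgroup C
    deg_down <- special[(12 + n_deg):(11 + 2 * n_deg)]     # down in subgroup C
    event_pool <- special[(12 + 2 * n_deg):n_special]

    ## ---- PDUI matrix -------------------------------------------------
    base <- stats::runif(n_genes, 0.35, 0.65)
    names(base) <- genes
    pdui <- matrix(base, n_genes, n_samples, dimnames = list(genes, samples))
    pdui <- sweep(pdui, 2L, shift / 2 * score, `+`)

    # per-sample APA events; burden separation scales with the subgroup shift.
    # Events per gene are capped below 1/6 of the cohort so the per-gene
    # cohort median provably stays at the gene's baseline, which makes the
    # planted event counts exactly recoverable in the noise-free
    # configuration.
    burden_sep <- 56 * shift
    per_gene_cap <- max(1L, floor(n_samples / 6) - 1L)
    draw_burden <- function(mu) {
      pmin(pmax(round(stats::rnorm(n_samples, mu, burden_sd)), 0L),
           event_pool_size %/% 2L)
    }
    n_len <- draw_burden(burden_mean + burden_sep * score)
    n_sh <- draw_burden(burden_mean - burden_sep * score)
    used <- stats::setNames(integer(length(event_pool)), event_pool)
    event_genes <- vector("list", n_samples)
    names(event_genes) <- samples
    for (s in seq_len(n_samples)) {
      eligible <- event_pool[used[event_pool] < per_gene_cap]
      lg <- sample(eligible, min(n_len[s], length(eligible)))
      eligible <- setdiff(eligible, lg)
      sg <- sample(eligible, min(n_sh[s], length(eligible)))
      used[c(lg, sg)] <- used[c(lg, sg)] + 1L
      n_len[s] <- length(lg)
      n_sh[s] <- length(sg)
      pdui[lg, s] <- pdui[lg, s] + event_delta
      pdui[sg, s] <- pdui[sg, s] - event_delta
      event_genes[[s]] <- list(lengthened = lg, shortened = sg)
    }

    if (pdui_noise_sd > 0) {
      pdui <- pdui + stats::rnorm(length(pdui), 0, pdui_noise_sd)
    }
    pdui[] <- clamp01(pdui)

    ## ---- expression matrix -------------------------------------------
    mu_g <- stats::runif(n_genes, 20, 200)
    expr <- matrix(mu_g, n_genes, n_samples, dimnames = list(genes, samples)) *
      2^stats::rnorm(n_genes * n_samples, 0, 0.5)

    # generic DEGs: fold between subgroups proportional to the PDUI shift
    f <- 8 * shift                                  # planted log2FC, C vs A
    fold_up <- 2^(f * (1 - score) / 2)              # A x1, B x2^(f/2), C x2^f
    fold_down <- 2^(-f * (1 - score) / 2)
    expr[deg_up, ] <- sweep(expr[deg_up, , drop = FALSE], 2L, fold_up, `*`)
    expr[deg_down, ] <- sweep(expr[deg_down, , drop = FALSE], 2L, fold_down, `*`)

    # regulators: expression tied to the realized per-sample APA burden
    burden <- apa_event_counts(pdui, reference = "cohort_median",
                               event_threshold = 0.2)
    regulators <- data.frame(
      gene_id = reg_ids,
      role = c("lengthen_regulator", "lengthen_regulator",
               "shorten_regulator", "shorten_regulator"),
      effect = rep(r_eff, 4),
      is_key = c(TRUE, FALSE, FALSE, FALSE),
      in_core = c(TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(regulators))) {
      series <- if (regulators$role[i] == "lengthen_regulator") {
        burden$n_lengthened
      } else {
        burden$n_shortened
      }
      x <- if (stats::sd(series) > 0) as.numeric(scale(series)) else rep(0, n_samples)
      r <- regulators$effect[i]
      z <- stats::rnorm(n_samples)
      expr[regulators$gene_id[i], ] <-
        pmax(0.1, 26 + 25 * (r * x + sqrt(1 - r^2) * z))
    }

    ## ---- gene sets and core factors ----------------------------------
    genesets <- lapply(
      stats::setNames(nm = c("mRNA_processing", "RNA_binding", "Nucleus")),
      function(nm) unique(c(reg_ids, sample(genes, 60)))
    )
    # decoy core factors are background genes: no planted DE or correlation,
    # so they exercise the overlap stage without competing with the key
    core_factors <- sort(c(regulators$gene_id[regulators$in_core], decoy_core))

    truth <- list(
      subgroup = subgroup,
      tumor_label = stats::setNames(rep("tumor", n_samples), samples),
      regulators = regulators,
      core_factors = core_factors,
      genesets = genesets,
      event_genes = event_genes,
      event_counts = data.frame(sample_id = samples, n_lengthened = n_len,
                                n_shortened = n_sh, stringsAsFactors = FALSE),
      deg = data.frame(
        gene_id = c(deg_up, deg_down),
        planted_log2fc = rep(c(f, -f), each = n_deg),
        direction = rep(c("up_in_C", "down_in_C"), each = n_deg),
        stringsAsFactors = FALSE
      ),
      params = list(n_genes = n_genes, n_samples = n_samples,
                    subgroup_sizes = subgroup_sizes, subgroup_shift = shift,
                    regulator_effect = r_eff, pdui_noise_sd = pdui_noise_sd,
                    event_delta = event_delta,
                    event_pool_size = event_pool_size,
                    burden_mean = burden_mean, burden_sd = burden_sd,
                    n_deg = n_deg, seed = as.integer(seed))
    )
    list(pdui = pdui, expr = expr, truth = truth)
  })
}
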