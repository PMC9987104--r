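# End-to-end pipeline over the synthetic study conditions, plus the thin
# command-line surface. Every subcommand reads a validated configuration,
# writes TSV outputs and a JSON run manifest, and logs to stderr.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, cfg, extra = list()) {
  manifest <- c(list(
    tool = "apascreen",
    version = as.character(utils::packageVersion("apascreen")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "hexamer_set")],
    hexamer_set = cfg$hexamer_set
  ), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full APA analysis pipeline on simulated study conditions
#'
#' Chains every stage on one configuration: simulates the cohort matrices,
#' gene sets and core-factor list; clusters samples and runs the staged
#' regulator screen; simulates and classifies 3'UTR sequences; simulates
#' the funnel input tables and applies the three-criterion target funnel.
#' All inputs and outputs are written under `outdir` (TSV/GMT/FASTA plus
#' JSON truth sidecars and a run manifest), so the run is fully
#' reproducible from the directory alone.
#'
#' @param config Named list of settings, validated against
#'   [default_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cohort`, `screen`, `pas`
#'   (classification table and the recovered proximal non-canonical
#'   proportion), `funnel`, and `key_regulator`.
#' @export
run_apa_pipeline <- function(config = list(), outdir = tempfile("apa_run_"),
                             quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[apascreen] ", ...)

  ## stage 1: synthetic cohort ------------------------------------------
  say("simulating cohort (", cfg$n_genes, " genes x ", cfg$n_samples,
      " samples, seed ", cfg$seed, ")")
  cohort <- simulate_cohort(
    n_genes = cfg$n_genes, n_samples = cfg$n_samples,
    subgroup_sizes = cfg$subgroup_sizes,
    effect_sizes = list(subgroup_shift = cfg$subgroup_shift,
                        regulator_effect = cfg$regulator_effect),
    seed = cfg$seed, pdui_noise_sd = cfg$pdui_noise_sd
  )
  write_matrix_tsv(cohort$pdui, file.path(outdir, "pdui_matrix.tsv"))
  write_matrix_tsv(cohort$expr, file.path(outdir, "expression_matrix.tsv"))
  write_gmt(cohort$truth$genesets, file.path(outdir, "apa_genesets.gmt"))
  write_gene_list(cohort$truth$core_factors,
                  file.path(outdir, "core_apa_factors.txt"))
  jsonlite::write_json(
    cohort$truth[c("subgroup", "regulators", "core_factors", "event_counts",
                   "deg", "params")],
    file.path(outdir, "cohort_truth.json"), auto_unbox = TRUE, digits = NA)

  ## stage 2: landscape + regulator screen ------------------------------
  say("clustering samples and screening regulators")
  screen <- screen_apa_regulators(
    cohort$expr, cohort$pdui, cohort$truth$genesets,
    cohort$truth$core_factors, k = cfg$clustering_k,
    event_threshold = cfg$event_threshold, r_threshold = cfg$r_threshold,
    p_threshold = cfg$p_threshold, fdr_threshold = cfg$deg_fdr_threshold,
    lfc_threshold = cfg$deg_lfc_threshold, linkage = cfg$clustering_linkage
  )
  write_tsv(data.frame(sample_id = names(screen$groups),
                       subgroup = unname(screen$groups)),
            file.path(outdir, "subgroups.tsv"))
  write_tsv(screen$deg, file.path(outdir, "differential_expression.tsv"))
  write_tsv(screen$apa_counts, file.path(outdir, "apa_event_counts.tsv"))
  write_tsv(screen$shortlist, file.path(outdir, "regulator_shortlist.tsv"))
  write_tsv(screen$core_overlap, file.path(outdir, "key_regulators.tsv"))
  say("key regulator: ", screen$key_regulator)

  ## stage 3: PAS classification ----------------------------------------
  say("simulating and classifying 3'UTR sequences")
  seqs <- simulate_utr_sequences(cfg$n_per_type, cfg$hexamer_set,
                                 seed = cfg$seed + 1L,
                                 utr_length = cfg$utr_length,
                                 distal_window = cfg$distal_window)
  write_fasta(seqs$sequences, file.path(outdir, "utr_sequences.fasta"))
  pas_table <- classify_utrs(seqs$sequences, cfg$hexamer_set,
                             distal_window = cfg$distal_window)
  write_tsv(pas_table, file.path(outdir, "pas_classification.tsv"))
  prop <- proportion_proximal_noncanonical(pas_table)
  say(sprintf("proximal non-canonical proportion: %.4f", prop))

  ## stage 4: target funnel ---------------------------------------------
  say("simulating funnel inputs and nominating targets")
  tables <- simulate_target_tables(cfg$n_funnel_genes, cfg$n_funnel_selected,
                                   seed = cfg$seed + 2L,
                                   p_cutoff = cfg$funnel_p_cutoff)
  targets <- filter_targets(tables$pas, tables$deg, tables$apa,
                            p_cutoff = cfg$funnel_p_cutoff,
                            fdr_cutoff = cfg$deg_fdr_threshold)
  write_tsv(targets, file.path(outdir, "target_funnel.tsv"))
  say(sum(targets$selected), " genes pass all three funnel criteria")

  write_manifest(outdir, cfg, list(
    key_regulator = screen$key_regulator,
    proportion_proximal_noncanonical = prop,
    n_targets_selected = sum(targets$selected)
  ))
  invisible(list(cohort = cohort, screen = screen,
                 pas = list(table = pas_table, proportion = prop),
                 funnel = list(tables = tables, targets = targets),
                 key_regulator = screen$key_regulator, outdir = outdir))
}

# minimal flag parser: --key value pairs after the subcommand
parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      stop("unexpected argument '", args[i], "' (expected --flag value)",
           call. = FALSE)
    }
    if (i == length(args)) stop("flag ", args[i], " lacks a value", call. = FALSE)
    flags[[substring(args[i], 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_config <- function(flags) {
  cfg <- if (!is.null(flags$config)) {
    load_config(flags$config)
  } else {
    validate_config(list())
  }
  if (!is.null(flags$seed)) {
    cfg$seed <- as.integer(flags$seed)
    cfg <- validate_config(cfg)
  }
  cfg
}

need_file <- function(path, what) {
  if (is.null(path)) stop("missing required flag --", what, call. = FALSE)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  path
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `pdui`, `landscape`, `screen`,
#' `classify-pas`, `funnel` and `run-all` onto the package functions.
#' Shared flags: `--config <yaml>`, `--out <dir>`, `--seed <int>`;
#' `pdui` additionally takes `--coverage <bedGraph>` and
#' `--annotation <bed|gtf>`, `landscape`/`screen` take matrix/GMT/list
#' paths, `classify-pas` takes `--fasta`, and `funnel` takes the three
#' stage tables. All inputs are validated before any computation.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, 0 on success (invisibly). Diagnostics go
#'   to stderr.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: apascreen <simulate|pdui|landscape|screen|classify-pas|funnel|run-all>",
    "[--config cfg.yaml] [--out dir] [--seed int] [stage flags]")
  status <- tryCatch({
    if (length(argv) == 0L) stop(usage, call. = FALSE)
    cmd <- argv[1]
    flags <- parse_flags(argv[-1])
    known <- c("config", "out", "seed", "coverage", "annotation", "pdui",
               "expr", "genesets", "core", "fasta", "pas", "deg", "apa")
    bad <- setdiff(names(flags), known)
    if (length(bad) > 0L) {
      stop("unknown flag(s): ", paste0("--", bad, collapse = ", "),
           call. = FALSE)
    }
    cfg <- cli_config(flags)
    outdir <- flags$out %||% "apascreen_out"
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    switch(cmd,
      "run-all" = {
        run_apa_pipeline(cfg, outdir)
      },
      "simulate" = {
        run <- run_apa_pipeline(cfg, outdir, quiet = TRUE)
        message("[apascreen] simulated inputs written to ", outdir)
        run
      },
      "pdui" = {
        profiles <- read_coverage(need_file(flags$coverage, "coverage"),
                                  need_file(flags$annotation, "annotation"))
        fits <- lapply(profiles, estimate_pdui,
                       min_mean_depth = cfg$min_mean_depth,
                       end_margin = cfg$end_margin)
        write_tsv(do.call(rbind, lapply(fits, as.data.frame)),
                  file.path(outdir, "pdui_estimates.tsv"))
      },
      "landscape" = {
        pdui <- read_matrix_tsv(need_file(flags$pdui, "pdui"))
        groups <- cluster_samples(pdui, k = cfg$clustering_k,
                                  linkage = cfg$clustering_linkage)
        counts <- apa_event_counts(pdui, event_threshold = cfg$event_threshold)
        write_tsv(data.frame(sample_id = names(groups),
                             subgroup = unname(groups)),
                  file.path(outdir, "subgroups.tsv"))
        write_tsv(counts, file.path(outdir, "apa_event_counts.tsv"))
      },
      "screen" = {
        screen <- screen_apa_regulators(
          read_matrix_tsv(need_file(flags$expr, "expr")),
          read_matrix_tsv(need_file(flags$pdui, "pdui")),
          read_gmt(need_file(flags$genesets, "genesets")),
          read_gene_list(need_file(flags$core, "core")),
          k = cfg$clustering_k, event_threshold = cfg$event_threshold,
          r_threshold = cfg$r_threshold, p_threshold = cfg$p_threshold,
          fdr_threshold = cfg$deg_fdr_threshold,
          lfc_threshold = cfg$deg_lfc_threshold,
          linkage = cfg$clustering_linkage)
        write_tsv(screen$core_overlap, file.path(outdir, "key_regulators.tsv"))
        message("[apascreen] key regulator: ", screen$key_regulator)
      },
      "classify-pas" = {
        seqs <- read_fasta(need_file(flags$fasta, "fasta"))
        tab <- classify_utrs(seqs, cfg$hexamer_set,
                             distal_window = cfg$distal_window)
        write_tsv(tab, file.path(outdir, "pas_classification.tsv"))
        message(sprintf("[apascreen] proximal non-canonical proportion: %.4f",
                        proportion_proximal_noncanonical(tab)))
      },
      "funnel" = {
        targets <- filter_targets(
          utils::read.delim(need_file(flags$pas, "pas")),
          utils::read.delim(need_file(flags$deg, "deg")),
          utils::read.delim(need_file(flags$apa, "apa")),
          p_cutoff = cfg$funnel_p_cutoff,
          fdr_cutoff = cfg$deg_fdr_threshold)
        write_tsv(targets, file.path(outdir, "target_funnel.tsv"))
        message("[apascreen] ", sum(targets$selected), " targets selected")
      },
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("[apascreen] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
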