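# Pipeline configuration: defaults, validation, YAML loading.

config_ranges <- function() {
  list(
    seed = c(1, 2^31 - 1),
    n_genes = c(200, 1e6),
    n_samples = c(9, 1e5),
    subgroup_shift = c(0, 0.5),
    regulator_effect = c(0, 1),
    pdui_noise_sd = c(0, 0.3),
    end_margin = c(1, 1e4),
    min_mean_depth = c(0, Inf),
    event_threshold = c(1e-12, 1),
    r_threshold = c(0, 1),
    p_threshold = c(0, 1),
    deg_fdr_threshold = c(0, 1),
    deg_lfc_threshold = c(0, Inf),
    min_abs_delta = c(0, 1),
    funnel_p_cutoff = c(1e-300, 1),
    clustering_k = c(2, 26),
    distal_window = c(1, 1e4),
    utr_length = c(450, 1e5),
    n_funnel_genes = c(10, 1e6),
    n_funnel_selected = c(1, 1e6)
  )
}

#' Pipeline configuration
#'
#' `default_config()` returns every tunable of the pipeline with its
#' default; `validate_config()` merges user settings over the defaults,
#' rejecting unknown keys and out-of-range values (naming the offending
#' key); `load_config()` reads a YAML file and validates it.
#'
#' @param config Named list of settings (possibly partial).
#' @param path Path to a YAML configuration file.
#' @return A complete, validated configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # synthetic cohort (the demo study conditions)
    n_genes = 500L, n_samples = 60L, subgroup_sizes = c(20L, 20L, 20L),
    subgroup_shift = 0.25, regulator_effect = 0.6, pdui_noise_sd = 0.06,
    # PDUI estimator
    end_margin = 50L, min_mean_depth = 5, min_abs_delta = 0.05,
    # landscape / screen
    event_threshold = 0.2, r_threshold = 0.3, p_threshold = 0.05,
    deg_fdr_threshold = 0.05, deg_lfc_threshold = 1,
    clustering_k = 3L, clustering_linkage = "average",
    # PAS classification
    hexamer_set = default_pas_hexamers(), distal_window = 50L,
    n_per_type = c(10L, 10L, 10L), utr_length = 600L,
    # funnel
    funnel_p_cutoff = 0.001, n_funnel_genes = 500L, n_funnel_selected = 47L
  )
}

#' @rdname default_config
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  ranges <- config_ranges()
  for (key in names(ranges)) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < ranges[[key]][1] || v > ranges[[key]][2]) {
      stop("configuration key '", key, "' must be a number in [",
           ranges[[key]][1], ", ", ranges[[key]][2], "]", call. = FALSE)
    }
  }
  if (length(cfg$subgroup_sizes) != 3L ||
      sum(cfg$subgroup_sizes) != cfg$n_samples) {
    stop("configuration key 'subgroup_sizes' must be 3 counts summing to ",
         "n_samples", call. = FALSE)
  }
  if (!cfg$clustering_linkage %in%
      c("average", "complete", "single", "ward.D", "ward.D2", "mcquitty")) {
    stop("configuration key 'clustering_linkage' is not a supported ",
         "hclust method", call. = FALSE)
  }
  cfg$hexamer_set <- check_hexamer_set(cfg$hexamer_set)
  if (length(cfg$n_per_type) == 1L) cfg$n_per_type <- rep(cfg$n_per_type, 3L)
  if (length(cfg$n_per_type) != 3L || any(cfg$n_per_type < 1)) {
    stop("configuration key 'n_per_type' must be 1 or 3 counts >= 1",
         call. = FALSE)
  }
  cfg
}

#' @rdname default_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}
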