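#' Simulate 3'UTR sequences with planted PAS types
#'
#' Generates uniform-ACGT background sequences rejection-sampled to contain
#' no accidental hexamer from the PAS alphabet, then plants proximal and
#' distal PAS hexamers realizing the requested type a/b/c composition:
#' type `a` genes receive only non-canonical proximal PASs, type `b` both
#' canonical and non-canonical, type `c` only canonical; every gene also
#' receives a canonical distal PAS so it carries at least two sites and is
#' typable. After planting, each sequence is re-scanned and regenerated if
#' the scan does not recover exactly the planted sites, so the planted
#' truth is exact by construction.
#'
#' @param n_per_type Number of genes per type: a single count (recycled to
#'   all three types) or a length-3 vector in the order a, b, c.
#' @param hexamer_set PAS alphabet; must contain the canonical hexamer
#'   `AATAAA` and at least one non-canonical hexamer (types a and b cannot
#'   be planted otherwise).
#' @param seed Integer seed.
#' @param utr_length Length of every simulated UTR (default 600 nt).
#' @param distal_window Proximal/distal co-location window the downstream
#'   classifier will use (default 50); planted proximal sites are kept
#'   well upstream of the distal site relative to this window.
#' @return List with `sequences` (named character vector; names
#'   `UTR_a_001`, ...) and `truth` — a `data.frame` with `gene_id`,
#'   `type_true`, `n_proximal`, `n_distal`, plus a `sites` attribute
#'   holding, per gene, the planted `(offset, hexamer)` tables.
#' @examples
#' sim <- simulate_utr_sequences(n_per_type = 2, seed = 1)
#' classify_utrs(sim$sequences)$pas_type
#' @export
simulate_utr_sequences <- function(n_per_type = 10,
                                   hexamer_set = default_pas_hexamers(),
                                   seed, utr_length = 600,
                                   distal_window = 50) {
  hexamer_set <- check_hexamer_set(hexamer_set)
  if (!CANONICAL_PAS %in% hexamer_set) {
    stop("hexamer_set must contain the canonical PAS ", CANONICAL_PAS,
         " (type b/c genes cannot be planted without it)", call. = FALSE)
  }
  noncanonical <- setdiff(hexamer_set, CANONICAL_PAS)
  if (length(noncanonical) == 0L) {
    stop("hexamer_set contains only the canonical PAS; ",
         "types a and b cannot be planted", call. = FALSE)
  }
  if (length(n_per_type) == 1L) n_per_type <- rep(n_per_type, 3L)
  if (length(n_per_type) != 3L || any(n_per_type < 1)) {
    stop("n_per_type must be one count or three counts >= 1 (a, b, c)",
         call. = FALSE)
  }
  # proximal grid tops out at offset 280; the distal site at L-80 must sit
  # more than distal_window beyond it so planted proximal sites stay proximal
  stop_if_not_scalar_number(utr_length, "utr_length",
                            lower = 280 + 80 + distal_window + 10)
  n_per_type <- as.integer(n_per_type)

  distal_off <- as.integer(utr_length - 80L)
  prox_grid <- seq(100L, 280L, by = 20L)      # >= distal_window away from distal

  clean_background <- function(L) {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    for (iter in 1:200) {
      hits <- scan_pas(s, hexamer_set)
      if (nrow(hits) == 0L) return(s)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (off in hits$offset) {
        chars[(off + 1):(off + 6)] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
      }
      s <- paste(chars, collapse = "")
    }
    stop("rejection sampling failed to produce a PAS-free background")
  }

  plant <- function(s, sites) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(sites))) {
      off <- sites$offset[i]
      chars[(off + 1):(off + 6)] <- strsplit(sites$hexamer[i], "")[[1]]
    }
    paste(chars, collapse = "")
  }

  with_seed(seed, {
    types <- rep(c("a", "b", "c"), times = n_per_type)
    ids <- sprintf("UTR_%s_%03d", types,
                   unlist(lapply(n_per_type, seq_len)))
    seqs <- character(length(ids))
    site_list <- vector("list", length(ids))
    truth_rows <- vector("list", length(ids))

    for (g in seq_along(ids)) {
      ty <- types[g]
      for (attempt in 1:50) {
        prox_hex <- switch(ty,
          a = sample(noncanonical, sample(1:2, 1), replace = FALSE),
          b = c(CANONICAL_PAS, sample(noncanonical, 1)),
          c = CANONICAL_PAS
        )
        offs <- sort(sample(prox_grid, length(prox_hex)))
        planted <- rbind(
          data.frame(offset = offs, hexamer = sample(prox_hex),
                     proximal = TRUE, stringsAsFactors = FALSE),
          data.frame(offset = distal_off, hexamer = CANONICAL_PAS,
                     proximal = FALSE, stringsAsFactors = FALSE)
        )
        s <- plant(clean_background(utr_length), planted)
        found <- scan_pas(s, hexamer_set)
        ok <- nrow(found) == nrow(planted) &&
          all(found$offset == planted$offset) &&
          all(found$hexamer == planted$hexamer)
        if (ok) break
      }
      if (!ok) stop("failed to plant sites for ", ids[g])
      seqs[g] <- s
      site_list[[g]] <- planted
      truth_rows[[g]] <- data.frame(
        gene_id = ids[g], type_true = ty,
        n_proximal = sum(planted$proximal),
        n_distal = sum(!planted$proximal), stringsAsFactors = FALSE
      )
    }
    names(seqs) <- ids
    names(site_list) <- ids
    truth <- do.call(rbind, truth_rows)
    attr(truth, "sites") <- site_list
    list(sequences = seqs, truth = truth)
  })
}
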