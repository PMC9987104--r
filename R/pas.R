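# Polyadenylation-signal (PAS) hexamer scanning and the type a/b/c
# classification of a gene's proximal 3'UTR PAS inventory.

#' Default PAS hexamer alphabet
#'
#' The canonical PAS `AATAAA` (DNA alphabet) plus the 12 widely reported
#' human single-substitution variants. The first element is always the
#' canonical hexamer; everything else is treated as non-canonical.
#'
#' @return Character vector of 13 hexamers, canonical first.
#' @export
default_pas_hexamers <- function() {
  c("AATAAA",
    "ATTAAA", "TATAAA", "AGTAAA", "AATACA", "CATAAA", "AATATA",
    "GATAAA", "AATGAA", "AATAGA", "ACTAAA", "AAGAAA", "AATAAG")
}

CANONICAL_PAS <- "AATAAA"

# preprocessed Biostrings dictionaries are costly to build, so cache them
# per hexamer set (scan_pas is called once per gene and per rejection pass)
.pdict_cache <- new.env(parent = emptyenv())
pas_pdict <- function(hexamer_set) {
  key <- paste(hexamer_set, collapse = ",")
  pd <- get0(key, envir = .pdict_cache)
  if (is.null(pd)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(hexamer_set))
    assign(key, pd, envir = .pdict_cache)
  }
  pd
}

normalize_dna <- function(x) chartr("uU", "tT", toupper(x))

check_hexamer_set <- function(hexamer_set) {
  if (length(hexamer_set) == 0L) stop("hexamer set is empty", call. = FALSE)
  hexamer_set <- unique(normalize_dna(hexamer_set))
  if (any(nchar(hexamer_set) != 6L) ||
      any(grepl("[^ACGT]", hexamer_set))) {
    stop("hexamers must be 6-mers over {A,C,G,T} (U is mapped to T)",
         call. = FALSE)
  }
  hexamer_set
}

#' Scan a 3'UTR sequence for PAS hexamers
#'
#' Tests every window of width 6 on the sense strand against the hexamer
#' set; overlapping matches are all reported, `N` never matches.
#'
#' @param sequence DNA (or RNA; `U` is mapped to `T`) string over
#'   `{A,C,G,T,N}`, sense strand of the mRNA.
#' @param hexamer_set Character vector of PAS hexamers; the canonical PAS is
#'   `AATAAA`, anything else in the set is non-canonical. Defaults to
#'   [default_pas_hexamers()].
#' @return `data.frame` with one row per match, sorted by position:
#'   `offset` (0-based start of the hexamer), `hexamer`, `canonical`.
#'   Sequences shorter than 6 nt give zero rows.
#' @examples
#' scan_pas("AAAATAAAGG")        # one canonical site at offset 2
#' scan_pas("AATAAATAAA")        # overlapping sites at offsets 0 and 4
#' @export
scan_pas <- function(sequence, hexamer_set = default_pas_hexamers()) {
  hexamer_set <- check_hexamer_set(hexamer_set)
  sequence <- normalize_dna(as.character(sequence))
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence must be over {A,C,G,T,N}", call. = FALSE)
  }
  empty <- data.frame(offset = integer(0), hexamer = character(0),
                      canonical = logical(0), stringsAsFactors = FALSE)
  if (nchar(sequence) < 6L) return(empty)
  subj <- Biostrings::DNAString(sequence)
  hits <- Biostrings::matchPDict(pas_pdict(hexamer_set), subj)
  idx <- Biostrings::startIndex(hits)
  starts <- lapply(seq_along(hexamer_set), function(i) idx[[i]] %||% integer(0))
  n <- lengths(starts)
  if (sum(n) == 0L) return(empty)
  out <- data.frame(
    offset = unlist(starts) - 1L,    # Biostrings is 1-based
    hexamer = rep(hexamer_set, n),
    canonical = rep(hexamer_set == CANONICAL_PAS, n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split PAS sites into proximal and distal groups
#'
#' The distal PAS region defines the long-isoform 3' end. With
#' `distal_anchor = "last_site"` the 3'-most site, together with any site
#' within `distal_window` nucleotides upstream of it, forms the distal
#' group; every other site is proximal. With `"annotated_distal"` the
#' anchor is a supplied offset instead. Genes with fewer than 2 sites
#' cannot be typed: all their sites are reported distal and the proximal
#' group is empty (the gene classifies as `unclassified`).
#'
#' @param sites `data.frame` from [scan_pas()].
#' @param utr_length 3'UTR length in nucleotides.
#' @param distal_anchor `"last_site"` or `"annotated_distal"`.
#' @param distal_window Co-location window in nucleotides (default 50).
#' @param distal_offset 0-based anchor offset, required for
#'   `"annotated_distal"`.
#' @return List with `proximal` and `distal` data frames.
#' @export
split_proximal_distal <- function(sites, utr_length,
                                  distal_anchor = c("last_site", "annotated_distal"),
                                  distal_window = 50, distal_offset = NULL) {
  distal_anchor <- match.arg(distal_anchor)
  stop_if_not_scalar_number(distal_window, "distal_window", lower = 1)
  sites <- sites[order(sites$offset), , drop = FALSE]
  if (nrow(sites) < 2L && distal_anchor == "last_site") {
    return(list(proximal = sites[0, , drop = FALSE], distal = sites))
  }
  anchor <- if (distal_anchor == "last_site") {
    max(sites$offset)
  } else {
    if (is.null(distal_offset)) {
      stop("distal_anchor = 'annotated_distal' requires 'distal_offset'",
           call. = FALSE)
    }
    stop_if_not_scalar_number(distal_offset, "distal_offset",
                              lower = 0, upper = utr_length - 1)
    distal_offset
  }
  is_distal <- abs(sites$offset - anchor) <= distal_window
  list(proximal = sites[!is_distal, , drop = FALSE],
       distal = sites[is_distal, , drop = FALSE])
}

#' Assign the PAS type of one gene
#'
#' Types classify the proximal PAS inventory: type `a` — only non-canonical
#' PASs in the proximal 3'UTR; type `b` — both canonical and non-canonical;
#' type `c` — only canonical. Genes with an empty proximal inventory are
#' `unclassified`. Duplicate sites and input order do not affect the call.
#'
#' @param proximal_sites,distal_sites Data frames as returned by
#'   [split_proximal_distal()].
#' @param gene_id Identifier carried into the result.
#' @return List of class `pas_classification`: `gene_id`,
#'   `proximal_sites`, `distal_sites`, `pas_type`.
#' @export
classify_gene <- function(proximal_sites, distal_sites = NULL,
                          gene_id = NA_character_) {
  dedupe <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    df <- df[!duplicated(df[c("offset", "hexamer")]), , drop = FALSE]
    df[order(df$offset), , drop = FALSE]
  }
  proximal_sites <- dedupe(proximal_sites)
  distal_sites <- dedupe(distal_sites)
  n_can <- sum(proximal_sites$canonical)
  n_non <- sum(!proximal_sites$canonical)
  pas_type <- if (n_can + n_non == 0L) "unclassified"
  else if (n_non >= 1L && n_can == 0L) "a"
  else if (n_non >= 1L && n_can >= 1L) "b"
  else "c"
  structure(list(gene_id = gene_id, proximal_sites = proximal_sites,
                 distal_sites = distal_sites, pas_type = pas_type),
            class = "pas_classification")
}

#' @export
print.pas_classification <- function(x, ...) {
  cat(sprintf("PAS classification: %s -> type %s (%d proximal, %d distal sites)\n",
              x$gene_id, x$pas_type,
              nrow(x$proximal_sites) %||% 0L, nrow(x$distal_sites) %||% 0L))
  invisible(x)
}

#' Scan, split, and type a set of 3'UTR sequences
#'
#' Convenience wrapper running [scan_pas()], [split_proximal_distal()] and
#' [classify_gene()] over a named set of sequences.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of 3'UTR
#'   sense-strand sequences.
#' @inheritParams scan_pas
#' @inheritParams split_proximal_distal
#' @return `data.frame` with columns `gene_id`, `n_pas` (total sites),
#'   `n_proximal`, `n_distal`, `n_prox_canonical`, `n_prox_noncanonical`,
#'   `pas_type`.
#' @export
classify_utrs <- function(sequences, hexamer_set = default_pas_hexamers(),
                          distal_window = 50) {
  seqs <- vapply(as.character(sequences), identity, character(1))
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    sites <- scan_pas(seqs[[i]], hexamer_set)
    sp <- split_proximal_distal(sites, nchar(seqs[[i]]),
                                distal_window = distal_window)
    cl <- classify_gene(sp$proximal, sp$distal, gene_id = ids[i])
    data.frame(gene_id = ids[i], n_pas = nrow(sites),
               n_proximal = nrow(sp$proximal), n_distal = nrow(sp$distal),
               n_prox_canonical = sum(sp$proximal$canonical),
               n_prox_noncanonical = sum(!sp$proximal$canonical),
               pas_type = cl$pas_type, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Proportion of classified genes with a proximal non-canonical PAS
#'
#' Computes `(#type a + #type b) / (#type a + #type b + #type c)` — the
#' fraction of typable genes harboring at least one non-canonical PAS in
#' the proximal 3'UTR. Unclassified genes are excluded from the
#' denominator.
#'
#' @param classifications Character vector of types, a `data.frame` with a
#'   `pas_type` column (as from [classify_utrs()]), or a list of
#'   `pas_classification` objects.
#' @return Fraction in \[0,1\], or `NA` (with a warning) when no gene is
#'   classified.
#' @export
proportion_proximal_noncanonical <- function(classifications) {
  types <- if (is.character(classifications)) {
    classifications
  } else if (is.data.frame(classifications)) {
    classifications$pas_type
  } else {
    vapply(classifications, function(x) x$pas_type, character(1))
  }
  n <- table(factor(types, levels = c("a", "b", "c", "unclassified")))
  denom <- sum(n[c("a", "b", "c")])
  if (denom == 0L) {
    warning("no classified genes; proportion undefined")
    return(NA_real_)
  }
  as.numeric(sum(n[c("a", "b")]) / denom)
}
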