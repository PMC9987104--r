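#' Per-base 3'UTR coverage profile
#'
#' Container for the read depth along one annotated 3'UTR, stored in
#' transcript (5'->3') orientation: offset 0 is the 5' end of the 3'UTR
#' regardless of genomic strand. Minus-strand tracks are reversed by the
#' readers before construction, so downstream code never needs to know the
#' strand.
#'
#' @param gene_id Gene (or transcript) identifier.
#' @param depth Numeric vector of non-negative per-base read depths, one
#'   value per position of the 3'UTR in transcript orientation.
#' @param chrom Chromosome name (default `"chrS"` for synthetic data).
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open genomic interval of the UTR. Defaults
#'   to `[0, length(depth))`.
#' @return An object of class `coverage_profile`.
#' @examples
#' cp <- coverage_profile("geneA", depth = c(rep(100, 100), rep(40, 100)))
#' cp
#' @export
coverage_profile <- function(gene_id, depth, chrom = "chrS", strand = "+",
                             start = 0L, end = start + length(depth)) {
  if (length(depth) == 0L) stop("empty coverage profile for ", gene_id, call. = FALSE)
  depth <- as.numeric(depth)
  if (anyNA(depth) || any(depth < 0)) {
    stop("coverage depths must be non-negative and non-missing (", gene_id, ")",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (end - start != length(depth)) {
    stop("interval length (", end - start, ") does not match depth length (",
         length(depth), ")", call. = FALSE)
  }
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, start = as.integer(start), end = as.integer(end),
         depth = depth),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("3'UTR coverage profile: %s (%s:%d-%d%s), L = %d nt\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, length(x$depth)))
  cat(sprintf("  mean depth %.2f, range [%.1f, %.1f]\n",
              mean(x$depth), min(x$depth), max(x$depth)))
  invisible(x)
}

#' @export
length.coverage_profile <- function(x) length(x$depth)
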