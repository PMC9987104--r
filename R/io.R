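# Standard-format readers and writers. Coordinate conventions are
# centralized here: bedGraph/BED are 0-based half-open on disk, GTF is
# 1-based closed; internally everything is 0-based half-open, and
# minus-strand coverage is reversed on load so offset 0 is always the
# 3'UTR 5' end.

#' Write / read a gene x sample matrix as TSV
#'
#' Genes as rows, samples as columns, header row, first column `gene_id`.
#' On read, duplicate gene ids and ragged rows are rejected; empty cells
#' and the literal `NA` become missing values.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_matrix_tsv` returns the numeric matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) stop("empty matrix file: ", path, call. = FALSE)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged TSV at line ", bad, " of ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-delimited: set name, description, then member genes.
#' Reading delegates to [fgsea::gmtPathways()].
#'
#' @param path File path.
#' @param genesets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(genesets, path, descriptions = names(genesets)) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], descriptions[i], genesets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA sequence files
#'
#' Reading uses [Biostrings::readDNAStringSet()]; identifiers are truncated
#' at the first whitespace and `U` is mapped to `T`.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read as raw strings first: RNA input (U) is normalized to the DNA
  # alphabet afterwards, which readDNAStringSet would not accept
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- normalize_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  ss <- Biostrings::DNAStringSet(normalize_dna(unlist(sequences)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("empty gene list: ", path, call. = FALSE)
  x
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

validate_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) {
    length(f) != 4L || anyNA(suppressWarnings(as.numeric(f[2:4])))
  }, logical(1)))
  if (length(bad) > 0L) {
    stop("malformed bedGraph line(s) ",
         paste(utils::head(which(body)[bad], 5), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  invisible(TRUE)
}

#' Read 3'UTR coverage profiles from bedGraph + annotation
#'
#' Intersects a per-base bedGraph coverage track with 3'UTR annotations
#' (BED6, or GTF whose 1-based closed coordinates are converted on
#' import), returning one [coverage_profile] per annotated UTR. Positions
#' without coverage are filled with 0; minus-strand profiles are reversed
#' into transcript orientation. Annotations on chromosomes absent from
#' the track are reported with a warning and given all-zero coverage.
#'
#' @param bedgraph_path Path to a bedGraph file (0-based half-open).
#' @param annotation_path Path to a BED6 or GTF annotation of 3'UTRs.
#' @param annotation_format `"auto"` (by file extension), `"bed"` or
#'   `"gtf"`.
#' @return Named list of [coverage_profile] objects.
#' @export
read_coverage <- function(bedgraph_path, annotation_path,
                          annotation_format = c("auto", "bed", "gtf")) {
  annotation_format <- match.arg(annotation_format)
  for (p in c(bedgraph_path, annotation_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  for (pkg in c("rtracklayer", "GenomicRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("read_coverage requires the '", pkg, "' package", call. = FALSE)
    }
  }
  validate_bedgraph(bedgraph_path)
  if (annotation_format == "auto") {
    ext <- tolower(sub(".*\\.", "", annotation_path))
    annotation_format <- if (ext %in% c("gtf", "gff", "gff2", "gff3")) "gtf" else "bed"
  }
  cov <- rtracklayer::import(bedgraph_path, format = "bedGraph")
  ann <- if (annotation_format == "bed") {
    rtracklayer::import(annotation_path, format = "BED")
  } else {
    rtracklayer::import(annotation_path, format = "GTF")
  }
  ids <- if (annotation_format == "bed") {
    ann$name
  } else {
    ann$gene_id %||% as.character(seq_along(ann))
  }
  covrle <- GenomicRanges::coverage(cov, weight = "score")

  profiles <- vector("list", length(ann))
  for (i in seq_along(ann)) {
    chrom <- as.character(GenomicRanges::seqnames(ann))[i]
    s1 <- GenomicRanges::start(ann)[i]          # 1-based inclusive
    e1 <- GenomicRanges::end(ann)[i]
    L <- e1 - s1 + 1L
    depth <- numeric(L)
    if (!chrom %in% names(covrle)) {
      warning("annotation '", ids[i], "' on chromosome '", chrom,
              "' absent from coverage track; using zero coverage")
    } else {
      r <- covrle[[chrom]]
      hi <- min(e1, length(r))
      if (s1 <= hi) depth[seq_len(hi - s1 + 1L)] <- as.numeric(r[s1:hi])
    }
    strand <- as.character(GenomicRanges::strand(ann))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    if (strand == "-") depth <- rev(depth)
    profiles[[i]] <- coverage_profile(ids[i], depth, chrom = chrom,
                                      strand = strand, start = s1 - 1L,
                                      end = e1)
  }
  names(profiles) <- ids
  profiles
}

#' Write coverage profiles as bedGraph, and their UTRs as BED6
#'
#' `write_coverage` run-length encodes each profile back into genomic
#' orientation (minus-strand profiles are un-reversed) as 0-based
#' half-open bedGraph intervals. `write_utr_bed` writes the matching BED6
#' annotation, so a write/read round trip through [read_coverage()] is
#' lossless.
#'
#' @param profiles A [coverage_profile] or list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_coverage <- function(profiles, path) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    depth <- if (p$strand == "-") rev(p$depth) else p$depth
    r <- rle(depth)
    ends <- p$start + cumsum(r$lengths)
    starts <- c(p$start, ends[-length(ends)])
    keep <- r$values != 0            # bedGraph convention: omit zero runs
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", p$chrom, starts[keep], ends[keep],
                         format(r$values[keep], digits = 15, trim = TRUE,
                                scientific = FALSE)), con)
    }
  }
  invisible(path)
}

#' @rdname write_coverage
#' @export
write_utr_bed <- function(profiles, path) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  lines <- vapply(profiles, function(p) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", p$chrom, p$start, p$end, p$gene_id,
            p$strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
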