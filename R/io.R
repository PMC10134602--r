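#' Write an omics matrix as TSV
#'
#' First column `feature`, one column per sample.
#' @param x an `omics_matrix`.
#' @param file output path.
#' @export
write_omics_tsv <- function(x, file) {
  df <- data.frame(feature = rownames(x), om_values(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an omics matrix from TSV
#'
#' @param file path written by [write_omics_tsv()] (feature id column plus
#'   one numeric column per sample).
#' @param kind measurement scale, see [omics_matrix()].
#' @export
read_omics_tsv <- function(file, kind) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omics_matrix(m, kind)
}

#' Write / read a sample table
#' @param samples data.frame of per-sample design information.
#' @param file path.
#' @export
write_sample_tsv <- function(samples, file) {
  utils::write.table(samples, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_sample_tsv
#' @export
read_sample_tsv <- function(file) {
  utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' @param sets named list of character vectors.
#' @param file path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, file, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("gene sets must be named", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read a GMT gene-set file
#' @param file path.
#' @return named list of character vectors (member ids).
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Read a gene list (one identifier per line)
#' @param file path.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file))
  unique(x[nzchar(x)])
}

#' Convert a BED-like table of TSS intervals to a 1-based TSS table
#'
#' BED input is 0-based half-open; the TSS position is the strand-aware
#' interval start (`start` for `+`, `end - 1` for `-`), converted to 1-based.
#' @param bed data.frame with columns chrom, start, end, gene, score (ignored),
#'   strand.
#' @return data.frame with columns gene, chrom, tss_pos (1-based), strand.
#' @export
tss_from_bed <- function(bed) {
  stopifnot(ncol(bed) >= 6)
  names(bed)[1:6] <- c("chrom", "start", "end", "gene", "score", "strand")
  pos <- ifelse(bed$strand == "-", bed$end, bed$start + 1L)
  data.frame(gene = bed$gene, chrom = bed$chrom, tss_pos = pos,
             strand = bed$strand, stringsAsFactors = FALSE)
}
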