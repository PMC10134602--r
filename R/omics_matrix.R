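#' Construct an omics matrix
#'
#' A features x samples numeric matrix carrying a `kind` attribute that
#' records the measurement scale: methylation fractions (`"beta"`),
#' log2-odds M-values (`"m"`), raw counts (`"count"`) or normalized
#' log2 counts-per-million (`"logcpm"`). Feature and sample identifiers are
#' the dimnames and must be unique.
#'
#' @param values numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param kind one of `"beta"`, `"m"`, `"count"`, `"logcpm"`.
#' @return the matrix, classed `omics_matrix`, with attribute `kind`.
#' @export
omics_matrix <- function(values, kind = c("beta", "m", "count", "logcpm")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  if (anyNA(values)) stop("missing values are not supported", call. = FALSE)
  if (kind == "beta" && (min(values) < 0 || max(values) > 1)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "count" &&
      (min(values) < 0 || any(values != round(values)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(values, kind = kind, class = c("omics_matrix", "matrix", "array"))
}

#' Measurement scale of an omics matrix
#' @param x an `omics_matrix`.
#' @return character scalar, the `kind` attribute.
#' @export
om_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) stop("not an omics_matrix: no `kind` attribute", call. = FALSE)
  k
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- attr(x, "kind")
  y <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(y)) return(y)
  structure(y, kind = kind, class = class(x))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

# internal: strip class, keep plain matrix
om_values <- function(x) {
  y <- unclass(x)
  attr(y, "kind") <- NULL
  y
}
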