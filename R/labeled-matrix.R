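#' Labeled square similarity or distance matrix
#'
#' The package's common matrix container: a square numeric matrix indexed
#' by isolate labels on both dimensions, tagged with what its cells mean.
#' Similarity matrices are percentages with a 100 diagonal (self-identity);
#' distance matrices have a zero diagonal; sympatry matrices are binary
#' (1 = same tectonic plate) with a 1 diagonal.
#'
#' @param values square numeric matrix. Row/column names supply the labels
#'   when `labels` is `NULL`.
#' @param kind one of `"similarity_percent"`, `"distance_km"`,
#'   `"distance_percent"`, `"sympatry_binary"`.
#' @param labels optional character vector of labels, overriding dimnames.
#' @param tol absolute tolerance for the symmetry and diagonal checks.
#'   Defaults to 1e-9: inputs are hand-entered percentages or computed
#'   doubles, so anything larger signals a real asymmetry.
#'
#' @return an object of class `labeled_matrix`: a list with elements
#'   `labels`, `values` (with dimnames set) and `kind`.
#' @export
#' @examples
#' m <- labeled_matrix(matrix(c(100, 90, 90, 100), 2, 2,
#'                            dimnames = list(c("a", "b"), c("a", "b"))),
#'                     kind = "similarity_percent")
#' m$values["a", "b"]
labeled_matrix <- function(values,
                           kind = c("similarity_percent", "distance_km",
                                    "distance_percent", "sympatry_binary"),
                           labels = NULL, tol = 1e-9) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    gv_stop("'values' must be a numeric matrix")
  if (nrow(values) != ncol(values))
    gv_stop("matrix is not square: ", nrow(values), " rows vs ",
            ncol(values), " columns")
  if (is.null(labels)) labels <- rownames(values) %||% colnames(values)
  if (is.null(labels))
    gv_stop("labels are required (as an argument or as dimnames)")
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    gv_stop("label count (", length(labels), ") does not match matrix size (",
            nrow(values), ")")
  if (anyDuplicated(labels))
    gv_stop("duplicate labels: ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dimnames(values) <- list(labels, labels)
  m <- structure(list(labels = labels, values = values, kind = kind),
                 class = "labeled_matrix")
  validate_labeled_matrix(m, tol = tol)
  m
}

#' Expected diagonal value for a matrix kind
#' @param kind a `labeled_matrix` kind string.
#' @return 100 for similarity matrices, 1 for sympatry, 0 for distances.
#' @export
diagonal_convention <- function(kind) {
  switch(kind,
         similarity_percent = 100,
         sympatry_binary = 1,
         0)
}

#' Validate a labeled matrix against its kind's invariants
#'
#' Checks squareness, symmetry, the diagonal convention, and the value
#' range implied by `kind` (similarities in \[0, 100\], distances
#' non-negative, sympatry binary). Called by the constructor; exported so
#' pipelines can re-check matrices read from files.
#'
#' @param m a `labeled_matrix`.
#' @param tol absolute tolerance for symmetry/diagonal checks.
#' @return `m`, invisibly.
#' @export
validate_labeled_matrix <- function(m, tol = 1e-9) {
  v <- m$values
  if (anyNA(v) || any(!is.finite(v)))
    gv_stop("matrix contains missing or non-finite values")
  asym <- abs(v - t(v))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    gv_stop("matrix is asymmetric at (", m$labels[ij[1]], ", ",
            m$labels[ij[2]], "): ", v[ij[1], ij[2]], " vs ", v[ij[2], ij[1]])
  }
  dc <- diagonal_convention(m$kind)
  bad <- which(abs(diag(v) - dc) > tol)
  if (length(bad))
    gv_stop("diagonal must be ", dc, " for kind '", m$kind, "'; offending: ",
            paste(m$labels[bad], collapse = ", "))
  if (m$kind == "similarity_percent" && (min(v) < -tol || max(v) > 100 + tol))
    gv_stop("similarity values must lie in [0, 100]; range is [",
            min(v), ", ", max(v), "]")
  if (m$kind %in% c("distance_km", "distance_percent") && min(v) < -tol)
    gv_stop("distances must be non-negative; minimum is ", min(v))
  if (m$kind == "sympatry_binary" && !all(v %in% c(0, 1)))
    gv_stop("sympatry matrix must be binary (0/1)")
  invisible(m)
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix> %d x %d, kind = %s\n",
              length(x$labels), length(x$labels), x$kind))
  print(x$values, ...)
  invisible(x)
}

#' Upper-triangle entries of a labeled matrix
#'
#' Returns the d = n(n-1)/2 off-diagonal upper-triangle entries in
#' column-major order, the vectorization used by the Mantel and Spearman
#' statistics.
#'
#' @param m a `labeled_matrix`.
#' @return numeric vector of length `n * (n - 1) / 2`.
#' @export
upper_triangle <- function(m) {
  m$values[upper.tri(m$values)]
}

#' Reorder or subset a labeled matrix by label
#'
#' @param m a `labeled_matrix`.
#' @param labels character vector; must be a subset of `m$labels`.
#' @return a `labeled_matrix` restricted to `labels`, in that order.
#' @export
subset_matrix <- function(m, labels) {
  missing <- setdiff(labels, m$labels)
  if (length(missing))
    gv_stop("labels not present in matrix: ", paste(missing, collapse = ", "))
  if (length(labels) < 1) gv_stop("at least one label required")
  labeled_matrix(m$values[labels, labels, drop = FALSE], kind = m$kind)
}
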