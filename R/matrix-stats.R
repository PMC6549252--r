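# Matrix correlation statistics: the standardized Mantel permutation
# test of genetic vs geographic distance, and the Spearman rank
# correlation of genetic similarity vs tectonic-plate sympatry.
#
# The Mantel statistic is
#   r_M = 1/(d-1) * sum_{i<j} stand(X)_ij * stand(Y)_ij,  d = n(n-1)/2,
# where stand() z-scores the d upper-triangle entries with the sample
# (d-1) standard deviation, so r_M is exactly the Pearson correlation of
# the two vectorized upper triangles. The permutation null jointly
# relabels rows and columns of one matrix; for n <= 7 (n! <= 5040) all
# relabelings are enumerated and the p-value is exact.

#' Z-score the upper-triangle entries of a labeled matrix
#'
#' Standardizes the d = n(n-1)/2 off-diagonal upper-triangle entries with
#' their mean and sample standard deviation (divisor d - 1), so that
#' `sum(stand(x) * stand(y)) / (d - 1)` is the Pearson sample correlation
#' of the two vectors.
#'
#' @param m a [labeled_matrix()] with n >= 3.
#' @return numeric vector of d standardized values (mean 0, sample
#'   variance 1).
#' @export
standardize_upper_triangle <- function(m) {
  if (length(m$labels) < 3) gv_stop("need n >= 3 labels")
  v <- upper_triangle(m)
  s <- sd(v)
  if (s == 0)
    gv_stop("degenerate matrix: all ", length(v),
            " upper-triangle entries are equal (", v[1],
            "); the statistic is undefined")
  (v - mean(v)) / s
}

# reorder y's labels to match x's; error on any mismatch
reconcile_labels <- function(x, y) {
  only_x <- setdiff(x$labels, y$labels)
  only_y <- setdiff(y$labels, x$labels)
  if (length(only_x) || length(only_y)) {
    parts <- c(
      if (length(only_x)) paste0("only in first: ",
                                 paste(only_x, collapse = ", ")),
      if (length(only_y)) paste0("only in second: ",
                                 paste(only_y, collapse = ", "))
    )
    gv_stop("label sets differ (", paste(parts, collapse = "; "),
            "); subset explicitly if intersection is intended")
  }
  subset_matrix(y, x$labels)
}

# upper triangle of values[perm, perm]
permuted_upper <- function(values, perm) {
  pv <- values[perm, perm]
  pv[upper.tri(pv)]
}

# shared permutation engine: stat_fun maps two upper-triangle vectors to
# a scalar statistic; y is relabeled under the null
perm_test <- function(xv, yvalues, stat_fun, n_perm, alternative, seed) {
  n <- nrow(yvalues)
  r_obs <- stat_fun(xv, yvalues[upper.tri(yvalues)])
  exhaustive <- FALSE
  if (n_perm <= 0 || n < 4)
    return(list(r = r_obs, p = NA_real_, n_perm = 0L, exhaustive = FALSE))
  nfact <- factorial(n)
  if (n <= 7 && n_perm >= nfact) {
    perms <- all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(k) {
      stat_fun(xv, permuted_upper(yvalues, perms[k, ]))
    }, numeric(1))
    exhaustive <- TRUE
    n_used <- nfact
    p_ge <- mean(r_perm >= r_obs - 1e-12)
    p_le <- mean(r_perm <= r_obs + 1e-12)
  } else {
    if (is.null(seed))
      gv_stop("a seed is required for Monte-Carlo permutations")
    set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(k) {
      stat_fun(xv, permuted_upper(yvalues, sample.int(n)))
    }, numeric(1))
    n_used <- as.integer(n_perm)
    # add-one convention: the observed statistic counts as one permutation
    p_ge <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    p_le <- (sum(r_perm <= r_obs + 1e-12) + 1) / (n_perm + 1)
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              `two-sided` = min(1, 2 * min(p_ge, p_le)))
  list(r = r_obs, p = p, n_perm = n_used, exhaustive = exhaustive)
}

#' Mantel permutation test between two distance matrices
#'
#' Computes the standardized Mantel statistic r_M (the Pearson
#' correlation of the vectorized upper triangles) between two distance
#' matrices with a common label set, and a permutation p-value obtained
#' by jointly permuting rows and columns of the second matrix. Label
#' order is reconciled by name; differing label sets are an error rather
#' than a silent intersection. For n <= 7 and `n_perm >= n!` the
#' permutation distribution is enumerated exhaustively.
#'
#' Both inputs must be distances (`distance_km` or `distance_percent`);
#' convert similarities with [similarity_to_distance()] first so that the
#' sign convention of r_M is fixed across analyses.
#'
#' @param x,y [labeled_matrix()] distance matrices, same label sets,
#'   n >= 3 (n >= 4 for a permutation p-value).
#' @param n_perm Monte-Carlo permutation count (default 9999).
#' @param alternative `"greater"` (default; isolation-by-distance
#'   predicts positive correlation), `"less"`, or `"two-sided"`
#'   (doubled tail).
#' @param seed RNG seed, required for Monte-Carlo permutations.
#' @return an object of class `mantel_result`: `r_m`, `n`, `d`,
#'   `p_value`, `n_perm`, `exhaustive`, `alternative`, `seed`.
#' @export
mantel <- function(x, y, n_perm = 9999,
                   alternative = c("greater", "less", "two-sided"),
                   seed = NULL) {
  alternative <- match.arg(alternative)
  for (m in list(x, y)) {
    if (!inherits(m, "labeled_matrix")) gv_stop("inputs must be labeled_matrix")
    if (!m$kind %in% c("distance_km", "distance_percent"))
      gv_stop("Mantel inputs must be distance matrices (got '", m$kind,
              "'); convert similarities with similarity_to_distance()")
  }
  y <- reconcile_labels(x, y)
  n <- length(x$labels)
  zx <- standardize_upper_triangle(x)
  zy <- standardize_upper_triangle(y)   # validates non-degeneracy
  d <- n * (n - 1) / 2
  stat <- function(uv, wv) {
    sw <- sd(wv)
    if (sw == 0) return(NA_real_)
    sum(uv * (wv - mean(wv)) / sw) / (d - 1)
  }
  res <- perm_test(zx, y$values, stat, n_perm, alternative, seed)
  structure(list(r_m = res$r, n = n, d = d, p_value = res$p,
                 n_perm = res$n_perm, exhaustive = res$exhaustive,
                 alternative = alternative, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r_M = %.4f (n = %d, d = %d)\n", x$r_m, x$n, x$d))
  if (is.na(x$p_value)) {
    cat("  no permutation p-value (n < 4 or n_perm = 0)\n")
  } else {
    cat(sprintf("  p = %.5g (%s; %d %s permutations)\n", x$p_value,
                x$alternative, x$n_perm,
                if (x$exhaustive) "exhaustive" else "Monte-Carlo"))
  }
  invisible(x)
}

#' Binary tectonic-plate sympatry matrix
#'
#' Entry (i, j) is 1 when isolates i and j were sampled from the same
#' tectonic plate, else 0; the diagonal is 1. Plate labels are taken
#' verbatim (the package never infers plate membership from coordinates —
#' boundary sites must be labeled by the user).
#'
#' @param x a [site_table()] with a `plate` column, or a named character
#'   vector of plate labels.
#' @return a [labeled_matrix()] of kind `sympatry_binary`.
#' @export
sympatry_matrix <- function(x) {
  if (inherits(x, "site_table")) {
    plates <- stats::setNames(x$plate, x$name)
  } else if (is.character(x) && !is.null(names(x))) {
    plates <- x
  } else {
    gv_stop("'x' must be a site_table or a named character vector of plates")
  }
  missing <- names(plates)[is.na(plates) | !nzchar(plates)]
  if (length(missing))
    gv_stop("sites lack a plate label: ", paste(missing, collapse = ", "))
  v <- outer(plates, plates, "==") * 1
  dimnames(v) <- list(names(plates), names(plates))
  labeled_matrix(v, kind = "sympatry_binary")
}

#' Spearman rank correlation of genetic similarity vs plate sympatry
#'
#' Ranks (average ranks for ties) the d upper-triangle genetic
#' similarities and the d binary sympatry indicators, and reports the
#' Pearson correlation of the two rank vectors — the covariance of the
#' rank variables over the product of their standard deviations. A
#' positive r_s means pairs on the same plate tend to be genetically
#' more similar. The permutation p-value jointly relabels the sympatry
#' matrix, exactly as in [mantel()].
#'
#' @param genetic a [labeled_matrix()] of genetic similarities (or any
#'   kind; ranking is monotone-invariant but the sign of r_s follows the
#'   input's orientation).
#' @param sympatry a `sympatry_binary` [labeled_matrix()] from
#'   [sympatry_matrix()].
#' @inheritParams mantel
#' @return an object of class `spearman_result`: `r_s`, `n`, `n_pairs`,
#'   `p_value`, `n_perm`, `exhaustive`, `alternative`, `seed`.
#' @export
spearman_sympatry <- function(genetic, sympatry, n_perm = 9999,
                              alternative = c("greater", "less", "two-sided"),
                              seed = NULL) {
  alternative <- match.arg(alternative)
  if (!inherits(genetic, "labeled_matrix") ||
      !inherits(sympatry, "labeled_matrix"))
    gv_stop("inputs must be labeled_matrix")
  if (sympatry$kind != "sympatry_binary")
    gv_stop("'sympatry' must be a sympatry_binary matrix")
  sympatry <- reconcile_labels(genetic, sympatry)
  n <- length(genetic$labels)
  if (n < 4) gv_stop("need n >= 4 for the sympatry correlation")
  gv <- upper_triangle(genetic)
  sv <- upper_triangle(sympatry)
  if (sd(gv) == 0)
    gv_stop("degenerate genetic matrix: zero rank variance")
  if (sd(sv) == 0)
    gv_stop("degenerate sympatry matrix: all pairs ",
            if (sv[1] == 1) "sympatric" else "allopatric",
            " (zero rank variance)")
  rg <- rank(gv)
  stat <- function(uv, wv) {
    rw <- rank(wv)
    if (sd(rw) == 0) return(NA_real_)
    cor(uv, rw)
  }
  res <- perm_test(rg, sympatry$values, stat, n_perm, alternative, seed)
  structure(list(r_s = res$r, n = n, n_pairs = length(gv),
                 p_value = res$p, n_perm = res$n_perm,
                 exhaustive = res$exhaustive, alternative = alternative,
                 seed = seed),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman sympatry test: r_s = %.4f (n = %d, %d pairs)\n",
              x$r_s, x$n, x$n_pairs))
  if (!is.na(x$p_value))
    cat(sprintf("  p = %.5g (%s; %d %s permutations)\n", x$p_value,
                x$alternative, x$n_perm,
                if (x$exhaustive) "exhaustive" else "Monte-Carlo"))
  invisible(x)
}
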