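#' Size factors by angular-based linear regression
#'
#' Finds the unit reference vector r that maximizes the summed cosines
#' between itself and every gene's expression vector,
#' L(r) = sum_i r . v_i / |v_i|, over the unit sphere. By Lagrange
#' multipliers the maximizer is r proportional to R, where
#' R_k = sum_i v_ik / |v_i|. Size factors are the components of r rescaled
#' so that identical libraries receive s_k = 1:
#' s_k = sqrt(m) * R_k / |R| (equivalently sum_k s_k^2 = m).
#'
#' Genes whose row is entirely zero contribute no direction and are excluded
#' from the sums with a warning; their ids are recorded in the result.
#'
#' @param m expression matrix (genes x samples), non-negative.
#' @param gene_subset optional character vector of gene ids to restrict the
#'   sums to (e.g. a stably expressed gene set); default all genes.
#' @return an object of class `size_factor_set`: list with components
#'   `s` (named size factors, sum of squares = number of samples),
#'   `R` (raw per-sample sums), `r` (unit reference vector),
#'   `contributing_genes`, `excluded_genes`, `convention_scale` (sqrt(m)).
#' @seealso [normalize_expression()] to apply the factors.
#' @export
compute_size_factors <- function(m, gene_subset = NULL) {
  validate_expression_matrix(m)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(m))
    if (length(missing))
      stop("gene_subset contains unknown gene(s): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    sub <- m[gene_subset, , drop = FALSE]
  } else {
    sub <- m
  }
  norms <- sqrt(rowSums(sub^2))
  zero <- norms == 0
  if (all(zero)) stop("all candidate genes have zero expression everywhere")
  if (any(zero))
    warning(sum(zero), " all-zero gene row(s) excluded from size-factor sums")
  contrib <- sub[!zero, , drop = FALSE] / norms[!zero]
  R <- colSums(contrib)
  r <- R / sqrt(sum(R^2))
  n_samples <- ncol(m)
  s <- sqrt(n_samples) * r
  names(s) <- names(R) <- names(r) <- colnames(m)
  structure(list(s = s, R = R, r = r,
                 contributing_genes = rownames(sub)[!zero],
                 excluded_genes = rownames(sub)[zero],
                 convention_scale = sqrt(n_samples)),
            class = "size_factor_set")
}

#' Evaluate the angular-regression objective L at a reference vector
#'
#' L(r) = sum over genes of the cosine between r and the gene's expression
#' vector. Exposed for diagnostics and for verifying that the closed-form
#' reference vector is the global maximizer.
#'
#' @param m expression matrix.
#' @param r numeric vector, one entry per sample (need not be unit length; it
#'   is normalized internally).
#' @param gene_subset optional gene-id restriction as in
#'   [compute_size_factors()].
#' @return scalar value of L.
#' @export
angular_objective <- function(m, r, gene_subset = NULL) {
  if (!is.null(gene_subset)) m <- m[gene_subset, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  keep <- norms > 0
  r <- r / sqrt(sum(r^2))
  sum((m[keep, , drop = FALSE] / norms[keep]) %*% r)
}

#' Divide an expression matrix by per-sample size factors
#'
#' @param m expression matrix.
#' @param sf a `size_factor_set` from [compute_size_factors()], or a named
#'   numeric vector of positive per-sample factors.
#' @return normalized expression matrix (same dimnames and attributes).
#' @export
normalize_expression <- function(m, sf) {
  validate_expression_matrix(m)
  s <- if (inherits(sf, "size_factor_set")) sf$s else sf
  if (is.null(names(s)) || !setequal(names(s), colnames(m)))
    stop("size-factor sample ids do not match the matrix")
  s <- s[colnames(m)]
  if (any(s <= 0)) stop("size factors must be positive")
  out <- sweep(m, 2L, s, "/")
  attributes(out)[c("sample_group", "sample_condition")] <-
    attributes(m)[c("sample_group", "sample_condition")]
  out
}

#' @export
print.size_factor_set <- function(x, ...) {
  cat("Angular-regression size factors (", length(x$s), " samples, ",
      length(x$contributing_genes), " contributing genes)\n", sep = "")
  print(round(x$s, 4L))
  if (length(x$excluded_genes))
    cat("Excluded all-zero genes:", length(x$excluded_genes), "\n")
  invisible(x)
}
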