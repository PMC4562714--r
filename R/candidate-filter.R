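#' Genes expressed in every sample
#'
#' Keeps genes whose value is at least `min_count` in every sample ("commonly
#' expressed" prefilter applied before dispersion statistics).
#'
#' @param m expression matrix.
#' @param min_count threshold, default 1; `>=` comparison, so a count exactly
#'   at the threshold is kept.
#' @return character vector of passing gene ids.
#' @export
common_expression_filter <- function(m, min_count = 1) {
  stopifnot(min_count >= 0)
  rownames(m)[rowSums(m >= min_count) == ncol(m)]
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Dimensionless and invariant to positive scaling.
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @return scalar CoV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("coefficient of variation undefined for non-positive mean")
  stats::sd(values) / m
}

#' Shapiro-Wilk and Kolmogorov-Smirnov normality p-values
#'
#' The KS test is one-sample against a Gaussian whose mean and standard
#' deviation are estimated from the same values (the common usage; the
#' resulting p-values are anti-conservative in the Lilliefors sense). Set
#' `lilliefors = TRUE` to use the Lilliefors-corrected test instead
#' (requires the `nortest` package).
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param lilliefors logical, default FALSE.
#' @return named numeric vector `c(shapiro_p = , ks_p = )`.
#' @export
normality_pvalues <- function(values, lilliefors = FALSE) {
  if (length(values) < 3L) stop("need at least three values")
  if (stats::sd(values) == 0)
    stop("normality tests undefined for constant input")
  shapiro_p <- stats::shapiro.test(values)$p.value
  ks_p <- if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("lilliefors = TRUE requires the 'nortest' package")
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                    stats::sd(values)))$p.value
  }
  c(shapiro_p = shapiro_p, ks_p = ks_p)
}

#' Per-gene, per-group dispersion and normality statistics
#'
#' Computes, for each gene within each sample group, the coefficient of
#' variation and the Shapiro-Wilk and KS normality p-values. Intended to run
#' on angular-normalized expression (the default in [run_pipeline()]); raw
#' counts can be supplied for diagnostics.
#'
#' @param m expression matrix (normally the normalized one).
#' @param groups character vector of group labels, one per sample (defaults
#'   to the matrix's `sample_group` attribute). Every group needs >= 3
#'   samples.
#' @param lilliefors passed to [normality_pvalues()].
#' @return data.frame with columns gene, group, cov, shapiro_p, ks_p,
#'   n_samples (one row per gene x group).
#' @export
compute_dispersion_stats <- function(m, groups = attr(m, "sample_group"),
                                     lilliefors = FALSE) {
  if (is.null(groups)) stop("sample group labels are required")
  stopifnot(length(groups) == ncol(m))
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 3L))
    stop("every group needs at least 3 samples; too small: ",
         paste(names(tab)[tab < 3L], collapse = ", "))
  out <- lapply(sort(unique(groups)), function(g) {
    sub <- m[, groups == g, drop = FALSE]
    stats_g <- t(apply(sub, 1L, function(v) {
      np <- normality_pvalues(v, lilliefors)
      c(cov = coefficient_of_variation(v), np)
    }))
    data.frame(gene = rownames(m), group = g, cov = stats_g[, "cov"],
               shapiro_p = stats_g[, "shapiro_p"], ks_p = stats_g[, "ks_p"],
               n_samples = ncol(sub), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Default two-group filter criteria
#'
#' The shipped thresholds: a gene passes a group when its CoV is strictly
#' below `cov_max` and at least one normality p-value is strictly above
#' `p_min`; it passes the filter when it passes every group. Defaults are
#' CoV < 0.2 with p > 0.6 for group "1" and CoV < 0.24 with p > 0.45 for
#' group "2".
#'
#' @param cov_max named numeric vector of per-group CoV caps.
#' @param p_min named numeric vector of per-group normality p floors.
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(cov_max = c("1" = 0.2, "2" = 0.24),
                            p_min = c("1" = 0.6, "2" = 0.45)) {
  stopifnot(all(cov_max > 0), all(p_min > 0), all(p_min < 1),
            setequal(names(cov_max), names(p_min)))
  structure(list(cov_max = cov_max, p_min = p_min), class = "filter_criteria")
}

#' Published soybean reference-gene evaluation statistics
#'
#' Loads the shipped table of per-gene dispersion statistics (CoV and the two
#' normality p-values, in sequencing-quality groups "1" and "2") for 7 new
#' candidate and 12 commonly-used soybean reference-gene loci, as evaluated
#' on 26 RNA-Seq libraries. Useful as a worked input for
#' [two_stage_filter()].
#'
#' @param long return the long per-(gene, group) format accepted by
#'   [two_stage_filter()] (default); `FALSE` returns the wide table with the
#'   `candidate` flag.
#' @return data.frame; in long form the `gene` column holds
#'   "<gene_name>|<gene_id>" so duplicated gene names at different loci stay
#'   distinct.
#' @export
published_candidate_stats <- function(long = TRUE) {
  path <- system.file("extdata", "rnaseq_candidate_stats.tsv",
                      package = "stableref")
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = TRUE, quote = "")
  if (!long) return(wide)
  key <- paste(wide$gene_name, wide$gene_id, sep = "|")
  do.call(rbind, lapply(c("1", "2"), function(g) {
    data.frame(gene = key, group = g,
               cov = wide[[paste0("cov_", g)]],
               shapiro_p = wide[[paste0("shapiro_p_", g)]],
               ks_p = wide[[paste0("ks_p_", g)]],
               candidate = wide$candidate)
  }))
}

#' Two-stage CoV + normality filter
#'
#' A gene passes iff, in every group g: cov_g < cov_max[g] AND
#' (shapiro_p_g > p_min[g] OR ks_p_g > p_min[g]). Inequalities are strict, so
#' boundary values fail.
#'
#' @param stats data.frame as from [compute_dispersion_stats()] (columns
#'   gene, group, cov, shapiro_p, ks_p).
#' @param criteria a [filter_criteria()] object.
#' @return character vector of passing gene ids (input order preserved).
#' @export
two_stage_filter <- function(stats, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  need <- names(criteria$cov_max)
  have <- split(stats, stats$gene)
  genes <- unique(stats$gene)
  pass <- vapply(genes, function(g) {
    rows <- have[[g]]
    if (!all(need %in% rows$group))
      stop("gene ", g, " missing statistics for group(s): ",
           paste(setdiff(need, rows$group), collapse = ", "))
    all(vapply(need, function(grp) {
      r <- rows[rows$group == grp, ][1L, ]
      r$cov < criteria$cov_max[[grp]] &&
        (r$shapiro_p > criteria$p_min[[grp]] || r$ks_p > criteria$p_min[[grp]])
    }, logical(1L)))
  }, logical(1L))
  genes[pass]
}
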