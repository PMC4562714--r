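#' Run the reference-gene discovery workflow end to end
#'
#' Executes the stages on the supplied inputs: stable-set selection and
#' normalization on the count matrix; the CoV/normality candidate filter on
#' the normalized expression (when sample groups are available); in-silico
#' PCR when primers and transcripts are given; and the four-method consensus
#' stability ranking when a replicate-level Ct table is given. Inputs may be
#' in-memory objects or file paths in the package's standard formats. When
#' `output_dir` is set, every stage writes its TSV outputs there along with a
#' JSON run summary; a stage failure aborts with the stage named, retaining
#' the outputs already written.
#'
#' @param counts expression matrix or path to a counts TSV (mandatory).
#' @param sample_groups per-sample group labels (or NULL to skip the filter
#'   stage; defaults to the matrix's `sample_group` attribute).
#' @param criteria [filter_criteria()] for the filter stage.
#' @param ct replicate-level Ct data.frame or CSV path (optional).
#' @param primers primer data.frame or TSV path (optional; needs
#'   `transcripts`).
#' @param transcripts transcript data.frame or FASTA path (optional).
#' @param output_dir directory for stage outputs (created if needed), or NULL
#'   to return results without writing.
#' @param min_count common-expression prefilter threshold, default 1.
#' @param ... further arguments passed to [select_stable_genes()].
#' @return list with elements `fit` (stable_set_fit), `normalized`,
#'   `common_genes`, `dispersion_stats`, `passing_genes`, `ispcr_hits`,
#'   `ispcr_classification`, `stability` (stability_report); absent stages
#'   are NULL.
#' @export
run_pipeline <- function(counts, sample_groups = NULL,
                         criteria = filter_criteria(), ct = NULL,
                         primers = NULL, transcripts = NULL,
                         output_dir = NULL, min_count = 1, ...) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(counts)) counts <- stage("read", read_expression_matrix(counts))
  if (is.null(sample_groups)) sample_groups <- attr(counts, "sample_group")
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(output_dir)) writer(file.path(output_dir, name))
  }

  res <- list(fit = NULL, normalized = NULL, common_genes = NULL,
              dispersion_stats = NULL, passing_genes = NULL,
              ispcr_hits = NULL, ispcr_classification = NULL,
              stability = NULL)

  res$common_genes <- stage("common_expression",
                            common_expression_filter(counts, min_count))
  if (!length(res$common_genes))
    stop("stage 'common_expression' failed: no gene passes min_count")
  expressed <- counts[res$common_genes, , drop = FALSE]

  res$fit <- stage("select", select_stable_genes(expressed, ...))
  res$normalized <- stage("normalize",
                          normalize_expression(expressed,
                                               res$fit$size_factors))
  emit("membership.tsv", function(p) utils::write.table(
    data.frame(gene = names(res$fit$membership),
               stable = res$fit$membership,
               per_gene_loglik = res$fit$per_gene_loglik),
    p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("trace.tsv", function(p) utils::write.table(
    res$fit$trace, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("size_factors.tsv", function(p) utils::write.table(
    data.frame(sample = names(res$fit$size_factors$s),
               R = res$fit$size_factors$R, s = res$fit$size_factors$s),
    p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("normalized.tsv", function(p) write_expression_matrix(res$normalized, p))

  if (!is.null(sample_groups)) {
    res$dispersion_stats <- stage("filter", compute_dispersion_stats(
      res$normalized, sample_groups))
    crit_groups <- names(criteria$cov_max)
    if (all(crit_groups %in% unique(as.character(sample_groups)))) {
      res$passing_genes <- stage("filter",
                                 two_stage_filter(res$dispersion_stats,
                                                  criteria))
    }
    emit("dispersion_stats.tsv", function(p) utils::write.table(
      res$dispersion_stats, p, sep = "\t", quote = FALSE, row.names = FALSE))
    if (!is.null(res$passing_genes))
      emit("passing_genes.tsv", function(p) utils::write.table(
        data.frame(gene = res$passing_genes), p, sep = "\t", quote = FALSE,
        row.names = FALSE))
  }

  if (!is.null(primers) && !is.null(transcripts)) {
    if (is.character(primers)) primers <- stage("ispcr", read_primer_table(primers))
    if (is.character(transcripts)) transcripts <- stage("ispcr", read_fasta(transcripts))
    res$ispcr_hits <- stage("ispcr", find_amplicons(primers, transcripts))
    res$ispcr_classification <- stage("ispcr", classify_primer_sets(
      res$ispcr_hits, primers$name))
    emit("ispcr_hits.tsv", function(p) utils::write.table(
      res$ispcr_hits, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("ispcr_classification.tsv", function(p) utils::write.table(
      res$ispcr_classification, p, sep = "\t", quote = FALSE,
      row.names = FALSE))
  }

  if (!is.null(ct)) {
    if (is.character(ct)) ct <- stage("rank", read_ct_table(ct))
    ctm <- stage("rank", aggregate_replicates(ct))
    res$stability <- stage("rank", rank_stability(ctm))
    emit("consensus.tsv", function(p) utils::write.table(
      res$stability$table, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("ct_summary.tsv", function(p) utils::write.table(
      data.frame(gene = names(res$stability$mean_ct),
                 mean_ct = res$stability$mean_ct,
                 mean_delta_ct = res$stability$mean_delta_ct),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (!is.null(output_dir)) {
    summary <- list(
      package_version = as.character(utils::packageVersion("stableref")),
      n_genes_input = nrow(counts), n_samples = ncol(counts),
      n_common = length(res$common_genes),
      n_stable = sum(res$fit$membership),
      mu = res$fit$mu, sigma = res$fit$sigma,
      likelihood = res$fit$likelihood,
      config = res$fit$config,
      n_passing = if (is.null(res$passing_genes)) NULL
                  else length(res$passing_genes),
      consensus_order = res$stability$consensus_order)
    jsonlite::write_json(summary, file.path(output_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  res
}
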