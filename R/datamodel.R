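#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes as rows, samples as
#' columns) with unique row and column names, holding non-negative read counts
#' or normalized expression values. Optional per-sample labels travel as
#' attributes so the matrix stays a first-class R matrix for arithmetic.
#'
#' @param values numeric matrix of non-negative values.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   existing rownames).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to existing colnames).
#' @param sample_group optional per-sample group label (e.g. sequencing-quality
#'   group "1"/"2"), recycled checks applied.
#' @param sample_condition optional per-sample condition label
#'   (tissue/treatment).
#' @return the validated matrix with dimnames and optional `sample_group` /
#'   `sample_condition` attributes.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              sample_group = NULL, sample_condition = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or set as dimnames)")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimnames lengths do not match matrix dimensions")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  validate_expression_matrix(values)
  if (!is.null(sample_group)) {
    stopifnot(length(sample_group) == ncol(values))
    attr(values, "sample_group") <- as.character(sample_group)
  }
  if (!is.null(sample_condition)) {
    stopifnot(length(sample_condition) == ncol(values))
    attr(values, "sample_condition") <- as.character(sample_condition)
  }
  values
}

validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene id: ", rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1L])
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  invisible(m)
}

#' Construct a validated Ct matrix
#'
#' Cycle-threshold values from RT-qPCR, genes as rows, samples as columns.
#' Values must be finite and positive; values outside the usual 10--40 cycle
#' range trigger a warning but are retained.
#'
#' @inheritParams expression_matrix
#' @return validated numeric matrix.
#' @export
ct_matrix <- function(values, gene_ids = rownames(values),
                      sample_ids = colnames(values),
                      sample_condition = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  validate_ct_matrix(values)
  if (!is.null(sample_condition)) {
    stopifnot(length(sample_condition) == ncol(values))
    attr(values, "sample_condition") <- as.character(sample_condition)
  }
  values
}

validate_ct_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("Ct matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("Ct matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate gene or sample id in Ct matrix")
  if (anyNA(m) || any(!is.finite(m))) stop("Ct values must be finite")
  if (any(m <= 0)) stop("Ct values must be positive")
  if (any(m < 10 | m > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  invisible(m)
}

#' Derive a gene locus id from a transcript id
#'
#' Transcript identifiers of the form `<locus>.<n>` (Phytozome style, e.g.
#' "Glyma.08G115100.1") are collapsed to their parent locus by stripping the
#' final ".<integer>" suffix. Identifiers without such a suffix are their own
#' locus.
#'
#' @param transcript_id character vector of transcript identifiers.
#' @return character vector of locus identifiers.
#' @examples
#' locus_id("Glyma.08G115100.1")  # "Glyma.08G115100"
#' locus_id("t1")                 # "t1"
#' @export
locus_id <- function(transcript_id) {
  sub("\\.[0-9]+$", "", as.character(transcript_id))
}
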