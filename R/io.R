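#' Read a gene-by-sample expression matrix from a delimited file
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (genes-as-rows orientation by default; set `orientation = "samples"` for
#' the transpose).
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @param orientation "genes" (rows are genes, default) or "samples".
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", quote = "")
  ids <- df[[1L]]
  vals <- df[-1L]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 as.matrix(vals)[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], names(vals)[bad[1L, 2L]]))
  }
  rownames(num) <- ids
  if (orientation == "samples") num <- t(num)
  expression_matrix(num)
}

#' Write an expression matrix as TSV
#'
#' Genes as rows; first column named `gene_id`, remaining columns are sample
#' ids in matrix order, so repeated runs are diffable.
#'
#' @param m expression (or Ct) matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ct_table_cols <- c("gene", "sample", "biological_rep", "technical_rep", "ct")

#' Read a replicate-level Ct table
#'
#' Long-format CSV with columns gene, sample, biological_rep, technical_rep,
#' ct. Unbalanced replicate designs are allowed; every record is retained.
#'
#' @param path CSV path.
#' @return data.frame with the five columns, `ct` numeric.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(ct_table_cols, names(df))
  if (length(missing))
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[ct_table_cols]
  ct <- suppressWarnings(as.numeric(df$ct))
  if (anyNA(ct)) {
    i <- which(is.na(ct))[1L]
    stop(sprintf("non-numeric Ct '%s' at record %d", df$ct[i], i))
  }
  df$ct <- ct
  df
}

#' Write a replicate-level Ct table as CSV
#' @param records data.frame as returned by [read_ct_table()].
#' @param path output path.
#' @export
write_ct_table <- function(records, path) {
  utils::write.csv(records[ct_table_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate replicate Ct records into a gene-by-sample Ct matrix
#'
#' Hierarchical mean: technical repeats are averaged within each biological
#' replicate first, then the biological-replicate means are averaged. On a
#' balanced design this equals the grand mean of all replicates; on an
#' unbalanced design it weights biological replicates equally.
#'
#' @param records replicate-level data.frame (gene, sample, biological_rep,
#'   technical_rep, ct).
#' @return Ct matrix, genes as rows, samples as columns.
#' @export
aggregate_replicates <- function(records) {
  stopifnot(all(ct_table_cols %in% names(records)))
  genes <- unique(records$gene)
  samples <- unique(records$sample)
  bio <- stats::aggregate(ct ~ gene + sample + biological_rep,
                          data = records, FUN = mean)
  cell <- stats::aggregate(ct ~ gene + sample, data = bio, FUN = mean)
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  out[cbind(match(cell$gene, genes), match(cell$sample, samples))] <- cell$ct
  if (anyNA(out)) {
    empty <- which(is.na(out), arr.ind = TRUE)
    stop("no Ct records for cell(s): ",
         paste(sprintf("(%s, %s)", genes[empty[, 1L]], samples[empty[, 2L]]),
               collapse = ", "))
  }
  validate_ct_matrix(out)
  out
}

#' Read transcript sequences from a FASTA file
#'
#' Sequences are upper-cased; the record id is the first whitespace-delimited
#' token of the header, and the parent locus is derived with [locus_id()].
#'
#' @param path FASTA path.
#' @return data.frame with columns id, locus_id, seq.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record: ", ids[!nzchar(seqs)][1L])
  data.frame(id = ids, locus_id = locus_id(ids), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#' @param records data.frame with columns id, seq.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$seq)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Read a primer table
#'
#' Three-column TSV: name, forward, reverse (both primers written 5'->3').
#' Sequences are upper-cased and checked against the IUPAC nucleotide
#' alphabet.
#'
#' @param path TSV path.
#' @return data.frame with columns name, forward, reverse.
#' @export
read_primer_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  stopifnot(all(c("name", "forward", "reverse") %in% names(df)))
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  for (col in c("forward", "reverse")) {
    seqs <- df[[col]]
    if (any(!nzchar(seqs)))
      stop("empty ", col, " primer for set: ", df$name[!nzchar(seqs)][1L])
    bad <- grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")), seqs)
    if (any(bad))
      stop("non-IUPAC character in ", col, " primer of set: ", df$name[bad][1L])
  }
  df[c("name", "forward", "reverse")]
}

#' Write a primer table as TSV
#' @param primers data.frame with columns name, forward, reverse.
#' @param path output path.
#' @export
write_primer_table <- function(primers, path) {
  utils::write.table(primers[c("name", "forward", "reverse")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
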