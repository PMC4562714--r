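#' Reverse complement of an IUPAC nucleotide string
#'
#' Handles the full degenerate alphabet (revcomp(revcomp(s)) == s).
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# IUPAC bitmasks (A=1, C=2, G=4, T=8); two codes are compatible when their
# masks intersect. Primer codes expand (N matches any template base); template
# codes are taken literally except that template ambiguity codes also match by
# intersection.
iupac_mask <- local({
  masks <- integer(128)
  defs <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L, W = 9L,
            K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
  masks[utf8ToInt(paste(names(defs), collapse = ""))] <- defs
  masks
})

encode_seq <- function(s) {
  codes <- iupac_mask[utf8ToInt(s)]
  if (any(codes == 0L)) stop("non-IUPAC character in sequence")
  codes
}

# All start positions (1-based) where `primer` anneals to the + strand of the
# encoded template with at most max_mm mismatches, the 3'-terminal `protect`
# bases matching exactly. `three_prime` gives which end of the footprint is
# the primer's 3' end on this strand ("right" for a forward primer, "left"
# for the reverse complement of a reverse primer). Returns a data.frame of
# start positions and mismatch counts.
scan_primer <- function(template_codes, primer_codes, max_mm, protect,
                        three_prime = c("right", "left")) {
  three_prime <- match.arg(three_prime)
  lp <- length(primer_codes)
  nt <- length(template_codes)
  if (lp > nt)
    return(data.frame(start = integer(0), mismatches = integer(0)))
  n_starts <- nt - lp + 1L
  mm <- integer(n_starts)
  protected_mm <- integer(n_starts)
  protect_idx <- if (protect <= 0L) integer(0)
  else if (three_prime == "right") seq(max(1L, lp - protect + 1L), lp)
  else seq_len(min(protect, lp))
  for (p in seq_len(lp)) {
    hit <- bitwAnd(template_codes[p:(p + n_starts - 1L)], primer_codes[p]) > 0L
    mm <- mm + !hit
    if (p %in% protect_idx) protected_mm <- protected_mm + !hit
  }
  ok <- mm <= max_mm & protected_mm == 0L
  data.frame(start = which(ok), mismatches = mm[ok])
}

#' Predict PCR amplicons of primer sets on transcript sequences
#'
#' For each primer set and transcript, reports every position where the
#' forward primer matches the sense strand and the reverse complement of the
#' reverse primer matches downstream within `max_product` bases (orientation
#' "A"), and, when `both_orientations`, symmetrically with the primer roles
#' swapped (orientation "B", covering primer pairs recorded against the
#' antisense strand). IUPAC ambiguity codes in primers match their expansions
#' in the template. At most `max_mismatches` mismatches are tolerated per
#' primer, with the 3'-terminal `three_prime_protect` bases required to match
#' exactly.
#'
#' Coordinates are 0-based half-open on the transcript sense strand and span
#' both primer footprints, so `length = end - start` includes both primers.
#'
#' @param primers data.frame with columns name, forward, reverse (5'->3').
#' @param transcripts data.frame with columns id, locus_id, seq (see
#'   [read_fasta()]).
#' @param max_mismatches per-primer mismatch cap, default 0 (exact matching).
#' @param three_prime_protect number of 3'-terminal bases that must match
#'   exactly, default 3.
#' @param max_product maximum amplicon length in bases, default 5000.
#' @param both_orientations search the swapped-role orientation too, default
#'   TRUE.
#' @return data.frame with columns primer_name, transcript_id, locus_id,
#'   start, end, length, orientation ("A"/"B"), mismatches_fwd,
#'   mismatches_rev.
#' @export
find_amplicons <- function(primers, transcripts, max_mismatches = 0,
                           three_prime_protect = 3, max_product = 5000,
                           both_orientations = TRUE) {
  stopifnot(max_mismatches >= 0, three_prime_protect >= 0, max_product >= 1)
  empty <- data.frame(primer_name = character(0), transcript_id = character(0),
                      locus_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0), mismatches_fwd = integer(0),
                      mismatches_rev = integer(0))
  hits <- list(empty)
  for (p in seq_len(nrow(primers))) {
    fwd <- primers$forward[p]
    rev <- primers$reverse[p]
    orientations <- list(A = c(left = fwd, right = revcomp(rev)))
    if (both_orientations)
      orientations$B <- c(left = rev, right = revcomp(fwd))
    for (t in seq_len(nrow(transcripts))) {
      tmpl <- encode_seq(transcripts$seq[t])
      for (ori in names(orientations)) {
        left <- encode_seq(orientations[[ori]][["left"]])
        right <- encode_seq(orientations[[ori]][["right"]])
        lsites <- scan_primer(tmpl, left, max_mismatches,
                              three_prime_protect, "right")
        if (!nrow(lsites)) next
        rsites <- scan_primer(tmpl, right, max_mismatches,
                              three_prime_protect, "left")
        if (!nrow(rsites)) next
        for (i in seq_len(nrow(lsites))) {
          l0 <- lsites$start[i] - 1L             # 0-based footprint start
          r_end <- rsites$start + length(right) - 1L  # 1-based = 0-based end
          valid <- rsites$start - 1L >= l0 + length(left) &
            r_end - l0 <= max_product
          for (j in which(valid)) {
            hits[[length(hits) + 1L]] <- data.frame(
              primer_name = primers$name[p],
              transcript_id = transcripts$id[t],
              locus_id = transcripts$locus_id[t],
              start = l0, end = r_end[j], length = r_end[j] - l0,
              orientation = ori,
              mismatches_fwd = if (ori == "A") lsites$mismatches[i]
                               else rsites$mismatches[j],
              mismatches_rev = if (ori == "A") rsites$mismatches[j]
                               else lsites$mismatches[i])
          }
        }
      }
    }
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$primer_name, out$transcript_id, out$start, out$end), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Classify primer sets by locus multiplicity and amplicon sizes
#'
#' Collapses transcript isoforms to their parent locus: identical-length
#' amplicons from different isoforms of one locus count once per
#' (locus, length). A primer set is multi-locus when it hits more than one
#' locus, has multiple sizes when its distinct amplicon lengths exceed one
#' (within or across loci), and is flagged `no_amplicon` when it produced no
#' hit at all.
#'
#' @param hits data.frame from [find_amplicons()].
#' @param primer_names character vector of all primer-set names (so sets with
#'   zero hits are reported too); defaults to those present in `hits`.
#' @return data.frame with columns primer_name, n_loci, loci_hit
#'   (comma-joined), amplicon_sizes (comma-joined, per (locus, length)),
#'   is_multi_locus, has_multiple_sizes, no_amplicon.
#' @export
classify_primer_sets <- function(hits, primer_names = unique(hits$primer_name)) {
  stopifnot(!is.null(hits$locus_id))
  out <- lapply(primer_names, function(nm) {
    h <- hits[hits$primer_name == nm, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(primer_name = nm, n_loci = 0L, loci_hit = "",
                        amplicon_sizes = "", is_multi_locus = FALSE,
                        has_multiple_sizes = FALSE, no_amplicon = TRUE))
    }
    per_locus <- unique(h[c("locus_id", "length")])
    loci <- sort(unique(per_locus$locus_id))
    sizes <- per_locus$length[order(per_locus$locus_id, per_locus$length)]
    data.frame(primer_name = nm, n_loci = length(loci),
               loci_hit = paste(loci, collapse = ","),
               amplicon_sizes = paste(sizes, collapse = ","),
               is_multi_locus = length(loci) > 1L,
               has_multiple_sizes = length(unique(sizes)) > 1L,
               no_amplicon = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
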