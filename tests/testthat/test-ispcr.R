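test_that("reverse complement is an involution over the IUPAC alphabet", {
  codes <- c("ACGT", "RYSWKMBDHVN", "GATTACA")
  expect_identical(revcomp(revcomp(codes)), codes)
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAGN"), "NCTT")
})

test_that("a constructed template yields exactly one amplicon of known size", {
  fwd <- "GTATGCTGATCGGGTGGAGA"
  rev <- "AGCTGGGGTTCATCATCCTC"
  tmpl <- paste0(strrep("C", 7), fwd, strrep("A", 50), revcomp(rev),
                 strrep("G", 5))
  tr <- data.frame(id = "t1.1", locus_id = "t1", seq = tmpl)
  pr <- data.frame(name = "p", forward = fwd, reverse = rev)
  hits <- find_amplicons(pr, tr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 7)
  expect_equal(hits$length, nchar(fwd) + 50 + nchar(rev))
  expect_equal(hits$end, hits$start + hits$length)
  expect_identical(hits$orientation, "A")

  # product cap: a 10 kb insert is rejected at max_product 5000
  big <- data.frame(id = "t2.1", locus_id = "t2",
                    seq = paste0(fwd, strrep("A", 10000), revcomp(rev)))
  expect_equal(nrow(find_amplicons(pr, big)), 0L)
  expect_equal(nrow(find_amplicons(pr, big, max_product = 11000)), 1L)
})

test_that("swapped primer roles are found in orientation B", {
  fwd <- "GTATGCTGATCGGGTGGAGA"
  rev <- "AGCTGGGGTTCATCATCCTC"
  tmpl <- paste0(rev, strrep("T", 30), revcomp(fwd))
  tr <- data.frame(id = "t1.1", locus_id = "t1", seq = tmpl)
  pr <- data.frame(name = "p", forward = fwd, reverse = rev)
  hits <- find_amplicons(pr, tr)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$orientation, "B")
  expect_equal(nrow(find_amplicons(pr, tr, both_orientations = FALSE)), 0L)
})

test_that("IUPAC ambiguity codes in primers match their template expansions", {
  fwd <- "GTATGNTGATCGGGTGGAGA"  # N at position 6
  rev <- "AGCTGGGGTTCATCATCCTC"
  tmpl <- paste0(sub("N", "G", fwd), strrep("A", 40), revcomp(rev))
  tr <- data.frame(id = "t1.1", locus_id = "t1", seq = tmpl)
  hits <- find_amplicons(data.frame(name = "p", forward = fwd, reverse = rev),
                         tr, max_mismatches = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches_fwd, 0L)
})

test_that("mismatch cap and 3'-protection are enforced per primer", {
  fwd <- "GTATGCTGATCGGGTGGAGA"
  rev <- "AGCTGGGGTTCATCATCCTC"
  mut_mid <- fwd
  substr(mut_mid, 5, 5) <- "A"  # template mismatch far from the 3' end
  tmpl_mid <- paste0(mut_mid, strrep("A", 40), revcomp(rev))
  tr_mid <- data.frame(id = "t1.1", locus_id = "t1", seq = tmpl_mid)
  pr <- data.frame(name = "p", forward = fwd, reverse = rev)
  expect_equal(nrow(find_amplicons(pr, tr_mid, max_mismatches = 0)), 0L)
  hits <- find_amplicons(pr, tr_mid, max_mismatches = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches_fwd, 1L)

  mut_end <- fwd
  substr(mut_end, 20, 20) <- "C"  # 3'-terminal mismatch: never tolerated
  tmpl_end <- paste0(mut_end, strrep("A", 40), revcomp(rev))
  tr_end <- data.frame(id = "t1.1", locus_id = "t1", seq = tmpl_end)
  expect_equal(nrow(find_amplicons(pr, tr_end, max_mismatches = 2)), 0L)
  expect_equal(nrow(find_amplicons(pr, tr_end, max_mismatches = 2,
                                   three_prime_protect = 0)), 1L)
})

test_that("planted synthetic transcriptomes are recovered exactly", {
  for (seed in c(2, 11)) {
    sim <- simulate_transcriptome(seed = seed)
    hits <- find_amplicons(sim$primers, sim$transcripts)
    got <- hits[c("primer_name", "transcript_id", "locus_id", "start", "end",
                  "length")]
    expect_identical(got, sim$truth_hits)
    expect_true(all(hits$mismatches_fwd == 0 & hits$mismatches_rev == 0))
    # input order of transcripts does not matter
    set.seed(seed)
    perm <- sample.int(nrow(sim$transcripts))
    hits2 <- find_amplicons(sim$primers, sim$transcripts[perm, , drop = FALSE])
    expect_identical(hits2, hits)
  }
})

test_that("classification collapses isoforms and sets all three flags", {
  sim <- simulate_transcriptome(seed = 2)
  hits <- find_amplicons(sim$primers, sim$transcripts)
  cls <- classify_primer_sets(hits, sim$primers$name)
  cls <- cls[match(c("single", "multilocus", "multisize", "decoy1"),
                   cls$primer_name), ]
  expect_identical(cls$is_multi_locus, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(cls$has_multiple_sizes, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(cls$no_amplicon, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(cls$amplicon_sizes[cls$primer_name == "multisize"],
                   "103,129")

  # duplicating a transcript under a second locus id flips multi-locus
  tr <- sim$transcripts
  hit1 <- hits[hits$primer_name == "single", ][1L, ]
  dup <- tr[tr$id == hit1$transcript_id, ]
  dup$id <- "Dup.99G.1"
  dup$locus_id <- "Dup.99G"
  hits_dup <- find_amplicons(sim$primers, rbind(tr, dup))
  expect_equal(sum(hits_dup$primer_name == "single"),
               2L * sum(hits$primer_name == "single"))
  cls_dup <- classify_primer_sets(hits_dup, sim$primers$name)
  expect_true(cls_dup$is_multi_locus[cls_dup$primer_name == "single"])

  # identical-length amplicons on two isoforms of one locus count once
  iso <- tr[tr$id == hit1$transcript_id, ]
  iso$id <- paste0(hit1$locus_id, ".9")
  cls_iso <- classify_primer_sets(find_amplicons(sim$primers, rbind(tr, iso)),
                                  sim$primers$name)
  expect_false(cls_iso$has_multiple_sizes[cls_iso$primer_name == "single"])
  expect_false(cls_iso$is_multi_locus[cls_iso$primer_name == "single"])
})

test_that("a primer longer than every transcript gives an empty result", {
  tr <- data.frame(id = "t1.1", locus_id = "t1", seq = "ACGTACGT")
  pr <- data.frame(name = "p", forward = strrep("A", 30),
                   reverse = strrep("C", 30))
  expect_equal(nrow(find_amplicons(pr, tr)), 0L)
})
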