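#' Simulate an RNA-Seq count matrix with planted size factors
#'
#' Generates continuous expression values under the model the stable-set
#' selector assumes. Stable genes follow
#' v_ik = mu_i * s_k * exp(e_ik), e ~ N(0, tau_s^2) (lognormal measurement
#' noise around a common per-sample scale). Unstable genes additionally
#' receive a directional fold effect: a per-gene random subset of samples is
#' multiplied by exp(d_i * |eta_ik|) with eta ~ N(0, tau_u^2) and d_i a
#' per-gene random sign, producing the skewed, sample-specific deviations the
#' model treats as outliers. Values are left continuous; set `integerize` for
#' rounded counts.
#'
#' @param n_genes,m_samples dimensions.
#' @param stable_fraction fraction of genes planted stable, default 0.8.
#' @param size_factors planted per-sample scales s*_k; default drawn
#'   lognormal(0, 0.3) and rescaled to sum of squares = m.
#' @param tau_s stable-gene lognormal noise SD (log scale), default 0.05.
#' @param tau_u unstable-gene fold-effect SD (log scale), default 0.7.
#' @param mean_range range of per-gene base means (log10-uniform), default
#'   c(10, 1e4).
#' @param integerize round to integer counts, default FALSE.
#' @param seed integer seed; the generator is fully reproducible.
#' @return list: `matrix` (expression matrix with gene/sample ids) and
#'   `truth` (list: size_factors, stable_mask, gene_means, tau_s, tau_u,
#'   seed).
#' @export
simulate_counts <- function(n_genes = 500, m_samples = 8,
                            stable_fraction = 0.8, size_factors = NULL,
                            tau_s = 0.05, tau_u = 0.7,
                            mean_range = c(10, 1e4), integerize = FALSE,
                            seed = 1) {
  stopifnot(stable_fraction >= 0, stable_fraction <= 1, tau_s >= 0, tau_u >= 0)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  if (is.null(size_factors)) {
    size_factors <- exp(stats::rnorm(m_samples, 0, 0.3))
  }
  stopifnot(length(size_factors) == m_samples, all(size_factors > 0))
  size_factors <- size_factors * sqrt(m_samples / sum(size_factors^2))
  n_stable <- round(stable_fraction * n_genes)
  stable_mask <- c(rep(TRUE, n_stable), rep(FALSE, n_genes - n_stable))
  gene_means <- 10^stats::runif(n_genes, log10(mean_range[1L]),
                                log10(mean_range[2L]))
  noise <- matrix(stats::rnorm(n_genes * m_samples, 0, tau_s),
                  n_genes, m_samples)
  v <- gene_means * outer(rep(1, n_genes), size_factors) * exp(noise)
  for (i in which(!stable_mask)) {
    k_aff <- sample.int(max(1L, m_samples - 1L), 1L)
    affected <- sample.int(m_samples, k_aff)
    d <- sample(c(-1, 1), 1L)
    v[i, affected] <- v[i, affected] *
      exp(d * abs(stats::rnorm(k_aff, 0, tau_u)))
  }
  if (integerize) v <- round(v)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  sample_ids <- sprintf("sample%02d", seq_len(m_samples))
  mat <- expression_matrix(v, gene_ids, sample_ids)
  names(size_factors) <- sample_ids
  names(stable_mask) <- names(gene_means) <- gene_ids
  list(matrix = mat,
       truth = list(size_factors = size_factors, stable_mask = stable_mask,
                    gene_means = gene_means, tau_s = tau_s, tau_u = tau_u,
                    seed = seed))
}

#' Simulate a replicate-level qPCR Ct table with planted stable genes
#'
#' Stable genes draw their per-sample Ct from N(c_i, stable_sd^2) everywhere;
#' unstable genes are additionally shifted by `effect_size` cycles (random
#' per-gene sign) in a random, non-empty proper subset of conditions. Each
#' (gene, sample) emits 2 biological x 3 technical replicates: biological
#' replicates add N(0, bio_sd^2), technical repeats N(0, tech_sd^2).
#'
#' @param n_stable,n_unstable gene counts.
#' @param samples_per_condition samples per condition, default 3.
#' @param conditions number of conditions, default 4 (12 samples in all).
#' @param base_ct_range per-gene baseline Ct range (uniform), default
#'   c(22, 30).
#' @param stable_sd biological per-sample Ct SD in cycles, default 0.2.
#' @param effect_size condition shift for unstable genes in cycles, default 2.
#' @param bio_sd,tech_sd replicate noise SDs, defaults 0.05 / 0.05.
#' @param seed integer seed.
#' @return list: `records` (long-format replicate data.frame: gene, sample,
#'   biological_rep, technical_rep, ct), `truth` (stable_mask, condition
#'   labels per sample, affected conditions per unstable gene, seed).
#' @export
simulate_ct <- function(n_stable = 4, n_unstable = 4,
                        samples_per_condition = 3, conditions = 4,
                        base_ct_range = c(22, 30), stable_sd = 0.2,
                        effect_size = 2, bio_sd = 0.05, tech_sd = 0.05,
                        seed = 1) {
  stopifnot(n_stable + n_unstable >= 1, conditions >= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n_genes <- n_stable + n_unstable
  genes <- c(sprintf("stable%02d", seq_len(n_stable)),
             sprintf("unstable%02d", seq_len(n_unstable)))
  stable_mask <- stats::setNames(rep(c(TRUE, FALSE), c(n_stable, n_unstable)),
                                 genes)
  m <- samples_per_condition * conditions
  cond <- rep(sprintf("cond%d", seq_len(conditions)),
              each = samples_per_condition)
  samples <- sprintf("s%02d", seq_len(m))
  base_ct <- stats::setNames(stats::runif(n_genes, base_ct_range[1L],
                                          base_ct_range[2L]), genes)
  affected <- list()
  true_ct <- matrix(0, n_genes, m, dimnames = list(genes, samples))
  for (i in seq_len(n_genes)) {
    mu <- rep(base_ct[i], m)
    if (!stable_mask[i] && conditions >= 2) {
      n_aff <- sample.int(conditions - 1L, 1L)
      aff <- sample(sprintf("cond%d", seq_len(conditions)), n_aff)
      affected[[genes[i]]] <- aff
      mu[cond %in% aff] <- mu[cond %in% aff] +
        sample(c(-1, 1), 1L) * effect_size
    }
    true_ct[i, ] <- stats::rnorm(m, mu, stable_sd)
  }
  recs <- expand.grid(technical_rep = 1:3, biological_rep = 1:2,
                      sample = samples, gene = genes,
                      stringsAsFactors = FALSE)[, 4:1]
  bio_key <- paste(recs$gene, recs$sample, recs$biological_rep)
  bio_shift <- stats::setNames(stats::rnorm(length(unique(bio_key)), 0, bio_sd),
                               unique(bio_key))
  recs$ct <- true_ct[cbind(match(recs$gene, genes), match(recs$sample, samples))] +
    bio_shift[bio_key] + stats::rnorm(nrow(recs), 0, tech_sd)
  list(records = recs,
       truth = list(stable_mask = stable_mask, condition =
                      stats::setNames(cond, samples),
                    affected_conditions = affected, base_ct = base_ct,
                    seed = seed))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy transcriptome with planted primer binding sites
#'
#' Builds random transcript sequences and plants forward/reverse primer
#' binding sites (forward primer then an insert then the reverse complement
#' of the reverse primer) at known coordinates, so every predicted amplicon
#' can be checked against construction. `plant` describes one primer set per
#' element: which loci it lands on and the amplicon size(s) per locus
#' (several sizes for one locus are planted on separate isoforms of that
#' locus). Decoy primer sets with no binding site anywhere are appended.
#'
#' @param n_loci number of background loci, each with `isoforms_per_locus`
#'   isoform transcripts named `<locus>.<n>`.
#' @param isoforms_per_locus isoforms per locus, default 2.
#' @param plant list of plant descriptions, each a list with `name`,
#'   `loci` (integer locus indices) and `sizes` (list parallel to `loci`:
#'   amplicon lengths in bases, one per isoform to plant on). Default plants
#'   one single-locus set, one two-locus set, and one two-size set.
#' @param n_decoys number of decoy primer sets, default 1.
#' @param primer_length planted primer length, default 20.
#' @param transcript_length background transcript length, default 600.
#' @param seed integer seed.
#' @return list: `transcripts` (data.frame id, locus_id, seq), `primers`
#'   (name, forward, reverse), `truth_hits` (expected [find_amplicons()]
#'   rows: primer_name, transcript_id, locus_id, start, end, length).
#' @export
simulate_transcriptome <- function(n_loci = 6, isoforms_per_locus = 2,
                                   plant = NULL, n_decoys = 1,
                                   primer_length = 20,
                                   transcript_length = 600, seed = 1) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  stopifnot(n_loci >= 1, isoforms_per_locus >= 1)
  if (is.null(plant)) {
    plant <- list(
      list(name = "single", loci = 1L, sizes = list(120L)),
      list(name = "multilocus", loci = c(2L, 3L), sizes = list(110L, 110L)),
      list(name = "multisize", loci = 4L, sizes = list(c(103L, 129L))))
  }
  loci <- sprintf("Locus.%02dG", seq_len(n_loci))
  ids <- as.vector(t(outer(loci, seq_len(isoforms_per_locus),
                           function(l, n) paste0(l, ".", n))))
  seqs <- stats::setNames(vapply(ids, function(i)
    random_dna(transcript_length), character(1L)), ids)
  primers <- list()
  truth <- list()
  for (ps in plant) {
    fwd <- random_dna(primer_length)
    rev <- random_dna(primer_length)
    primers[[length(primers) + 1L]] <-
      data.frame(name = ps$name, forward = fwd, reverse = rev)
    for (li in seq_along(ps$loci)) {
      locus <- loci[ps$loci[[li]]]
      sizes <- ps$sizes[[li]]
      stopifnot(length(sizes) <= isoforms_per_locus,
                all(sizes >= 2 * primer_length))
      for (si in seq_along(sizes)) {
        tid <- paste0(locus, ".", si)
        insert <- random_dna(sizes[si] - 2L * primer_length)
        site <- paste0(fwd, insert, revcomp(rev))
        pos <- sample.int(nchar(seqs[tid]) - 1L, 1L)  # insertion point
        seqs[tid] <- paste0(substr(seqs[tid], 1L, pos), site,
                            substr(seqs[tid], pos + 1L, nchar(seqs[tid])))
        truth[[length(truth) + 1L]] <- data.frame(
          primer_name = ps$name, transcript_id = tid, locus_id = locus,
          start = pos, end = pos + sizes[si], length = sizes[si])
      }
    }
  }
  for (d in seq_len(n_decoys)) {
    primers[[length(primers) + 1L]] <-
      data.frame(name = sprintf("decoy%d", d), forward = random_dna(primer_length),
                 reverse = random_dna(primer_length))
  }
  transcripts <- data.frame(id = ids, locus_id = locus_id(ids),
                            seq = unname(seqs[ids]))
  truth_hits <- do.call(rbind, truth)
  truth_hits <- truth_hits[order(truth_hits$primer_name,
                                 truth_hits$transcript_id, truth_hits$start), ]
  rownames(truth_hits) <- NULL
  list(transcripts = transcripts, primers = do.call(rbind, primers),
       truth_hits = truth_hits)
}

# Seed the RNG reproducibly and return a restorer for the caller's RNG state.
.Random.seed_guard <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  function() {
    if (is.null(prev)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
  }
}
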