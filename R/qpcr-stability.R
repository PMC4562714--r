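#' Convert Ct values to relative quantities
#'
#' q_ik = E^(Ct_min,i - Ct_ik), where Ct_min,i is the gene's lowest Ct across
#' samples and E the amplification efficiency (2 = perfect doubling per
#' cycle). Each gene's maximum quantity is exactly 1, attained at its Ct_min.
#'
#' @param ct Ct matrix (genes x samples).
#' @param efficiency amplification efficiency E > 1, default 2. May be a
#'   single value or a per-gene named vector.
#' @return list of class `quantity_matrix`: `q` (gene x sample quantities in
#'   (0, 1]) and `efficiency`.
#' @export
ct_to_quantities <- function(ct, efficiency = 2) {
  stopifnot(all(efficiency > 1))
  if (length(efficiency) > 1L) {
    stopifnot(!is.null(names(efficiency)),
              setequal(names(efficiency), rownames(ct)))
    E <- efficiency[rownames(ct)]
  } else {
    E <- rep(efficiency, nrow(ct))
  }
  dct <- ct - apply(ct, 1L, min)
  q <- E^(-dct)
  dimnames(q) <- dimnames(ct)
  structure(list(q = q, efficiency = efficiency), class = "quantity_matrix")
}

#' Per-gene mean delta-Ct
#'
#' Mean over samples of Ct_ik - Ct_min,i; a simple per-gene spread summary in
#' cycles (0 for a perfectly constant gene).
#'
#' @param ct Ct matrix.
#' @return named numeric vector.
#' @export
mean_delta_ct <- function(ct) {
  rowMeans(ct - apply(ct, 1L, min))
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (i, j), the per-sample Ct difference
#' d = Ct_i - Ct_j is formed and its sample standard deviation taken; gene
#' i's stability is the mean of those SDs over all j != i. Lower is more
#' stable. Invariant to per-sample additive shifts (sample effects cancel in
#' the differences).
#'
#' @param ct Ct matrix with >= 2 genes and >= 2 samples.
#' @return named numeric vector of stabilities (cycles).
#' @export
comparative_delta_ct <- function(ct) {
  n <- nrow(ct)
  stopifnot(n >= 2L, ncol(ct) >= 2L)
  sds <- matrix(0, n, n, dimnames = list(rownames(ct), rownames(ct)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- stats::sd(ct[i, ] - ct[j, ])
      sds[i, j] <- sds[j, i] <- s
    }
  }
  stats::setNames(rowSums(sds) / (n - 1L), rownames(ct))
}

#' BestKeeper descriptive stability statistics
#'
#' Per gene: the standard deviation and the mean absolute deviation of its
#' raw Ct values, plus the Pearson correlation with the BestKeeper index
#' (the per-sample arithmetic mean Ct across genes, i.e. the geometric mean
#' of quantities in Ct space). The conventional ranking metric is the SD.
#'
#' @param ct Ct matrix.
#' @return data.frame with columns gene, sd, mad, r (r is NA for a constant
#'   gene, whose correlation with the index is undefined).
#' @export
bestkeeper <- function(ct) {
  index <- colMeans(ct)
  sds <- apply(ct, 1L, stats::sd)
  mads <- apply(ct, 1L, function(v) mean(abs(v - mean(v))))
  rs <- apply(ct, 1L, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, index)
  })
  data.frame(gene = rownames(ct), sd = sds, mad = mads, r = rs,
             row.names = NULL)
}

#' NormFinder-style stability (group-free variant)
#'
#' Log2 quantities are centred per sample (subtracting the gene-average
#' profile), and a gene's stability is the sample standard deviation of its
#' centred values. This is the pooled-samples variant: the full intra/
#' intergroup variance decomposition over experimental groups is not
#' implemented here (a `groups` argument is reserved for it).
#'
#' @param quantities a `quantity_matrix` from [ct_to_quantities()].
#' @param groups reserved; must be NULL.
#' @return named numeric vector of stabilities (log2 units).
#' @export
normfinder <- function(quantities, groups = NULL) {
  if (!is.null(groups))
    stop("grouped NormFinder decomposition is not implemented")
  q <- quantities$q
  stopifnot(nrow(q) >= 3L, ncol(q) >= 2L)
  x <- log2(q)
  z <- sweep(x, 2L, colMeans(x))
  stats::setNames(apply(z, 1L, stats::sd), rownames(q))
}

#' geNorm expression-stability measure M with stepwise exclusion
#'
#' A_ij is the sample standard deviation of the pairwise log2 expression
#' ratio of genes i and j; M_i is the mean of A_ij over j != i. The gene with
#' the highest M is excluded and M recomputed on the survivors, down to the
#' final two genes, which cannot be distinguished and share ranks 1-2. The
#' pairwise-variation values V_n/V_{n+1} for the averaged best-n normalization
#' factors are reported for completeness but not used in ranking.
#'
#' @param quantities a `quantity_matrix`.
#' @return list: `M` (named initial M values on the full set), `exclusion_order`
#'   (worst first), `final_pair`, `rounds` (per-round M tables), `V`
#'   (pairwise variations, NULL when fewer than 4 genes).
#' @export
genorm <- function(quantities) {
  q <- quantities$q
  n <- nrow(q)
  stopifnot(n >= 3L, ncol(q) >= 2L)
  x <- log2(q)
  m_values <- function(xm) {
    k <- nrow(xm)
    A <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s <- stats::sd(xm[i, ] - xm[j, ])
        A[i, j] <- A[j, i] <- s
      }
    }
    stats::setNames(rowSums(A) / (k - 1L), rownames(xm))
  }
  rounds <- list()
  excl <- character(0)
  cur <- x
  M0 <- m_values(x)
  while (nrow(cur) > 2L) {
    M <- m_values(cur)
    rounds[[length(rounds) + 1L]] <- M
    worst <- names(M)[which.max(M)]
    excl <- c(excl, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  V <- NULL
  if (n >= 4L) {
    # ranking best-first: final pair, then reverse exclusion order
    ranking <- c(rownames(cur), rev(excl))
    V <- numeric(0)
    for (k in 2:(n - 1L)) {
      nf_k <- colMeans(x[ranking[seq_len(k)], , drop = FALSE])
      nf_k1 <- colMeans(x[ranking[seq_len(k + 1L)], , drop = FALSE])
      V <- c(V, stats::setNames(stats::sd(nf_k - nf_k1),
                                sprintf("V%d/%d", k, k + 1L)))
    }
  }
  list(M = M0, exclusion_order = excl, final_pair = rownames(cur),
       rounds = rounds, V = V)
}

# geNorm ranks: final pair shares average rank 1.5; remaining genes ranked by
# reverse exclusion order (last excluded = rank 3).
genorm_ranks <- function(gn) {
  genes <- c(gn$final_pair, rev(gn$exclusion_order))
  ranks <- c(1.5, 1.5, seq(3, length.out = length(gn$exclusion_order)))
  stats::setNames(ranks, genes)
}

#' Four-method consensus stability ranking
#'
#' Runs the comparative delta-Ct, BestKeeper (ranked on Ct SD), NormFinder
#' (group-free) and geNorm algorithms on an aggregated Ct matrix, ranks genes
#' within each method (1 = most stable, ties as average ranks; a gene with an
#' undefined statistic is ranked last), and aggregates by the geometric mean
#' of the four ranks. The consensus order sorts ascending geomean, residual
#' ties broken alphabetically by gene id.
#'
#' @param ct Ct matrix (use [aggregate_replicates()] for replicate-level
#'   data).
#' @param efficiency amplification efficiency for the Ct-to-quantity
#'   transform, default 2.
#' @param bestkeeper_metric rank BestKeeper on `"sd"` (default) or `"mad"`.
#' @param use_values aggregate per-method stability VALUES instead of ranks
#'   when TRUE (geomean of values; default FALSE, standard rank aggregation).
#' @return object of class `stability_report`: `table` (per-gene statistics,
#'   per-method ranks, geomean and consensus order), `consensus_order`,
#'   `genorm` (full geNorm output), `mean_ct`, `mean_delta_ct`.
#' @examples
#' sim <- simulate_ct(n_stable = 3, n_unstable = 2, seed = 1)
#' rep <- rank_stability(aggregate_replicates(sim$records))
#' rep
#' @export
rank_stability <- function(ct, efficiency = 2,
                           bestkeeper_metric = c("sd", "mad"),
                           use_values = FALSE) {
  bestkeeper_metric <- match.arg(bestkeeper_metric)
  validate_ct_matrix(ct)
  stopifnot(nrow(ct) >= 3L)
  genes <- rownames(ct)
  q <- ct_to_quantities(ct, efficiency)
  dct <- comparative_delta_ct(ct)
  bk <- bestkeeper(ct)
  nf <- normfinder(q)
  gn <- genorm(q)

  rank_stat <- function(v) {
    r <- rank(v, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- length(v)  # undefined statistic ranks last
    r
  }
  bk_metric <- stats::setNames(bk[[bestkeeper_metric]], bk$gene)[genes]
  ranks <- cbind(delta_ct = rank_stat(dct[genes]),
                 bestkeeper = rank_stat(bk_metric),
                 normfinder = rank_stat(nf[genes]),
                 genorm = genorm_ranks(gn)[genes])
  geo_in <- if (use_values) {
    cbind(dct[genes], bk_metric, nf[genes], gn$M[genes])
  } else {
    ranks
  }
  geomean <- exp(rowMeans(log(geo_in)))
  ord <- order(geomean, genes)
  tab <- data.frame(gene = genes,
                    delta_ct_stability = dct[genes],
                    bestkeeper_sd = stats::setNames(bk$sd, bk$gene)[genes],
                    bestkeeper_mad = stats::setNames(bk$mad, bk$gene)[genes],
                    bestkeeper_r = stats::setNames(bk$r, bk$gene)[genes],
                    normfinder_stability = nf[genes],
                    genorm_M = gn$M[genes],
                    rank_delta_ct = ranks[, "delta_ct"],
                    rank_bestkeeper = ranks[, "bestkeeper"],
                    rank_normfinder = ranks[, "normfinder"],
                    rank_genorm = ranks[, "genorm"],
                    geomean_rank = geomean,
                    mean_ct = rowMeans(ct),
                    mean_delta_ct = mean_delta_ct(ct),
                    row.names = NULL)
  tab$consensus_rank <- match(seq_len(nrow(tab)), ord)
  structure(list(table = tab, consensus_order = genes[ord], genorm = gn,
                 mean_ct = rowMeans(ct), mean_delta_ct = mean_delta_ct(ct),
                 efficiency = efficiency,
                 bestkeeper_metric = bestkeeper_metric,
                 use_values = use_values),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, n = 10L, ...) {
  cat("Consensus stability ranking (", nrow(x$table), " genes, E = ",
      x$efficiency, ")\n", sep = "")
  tab <- x$table[order(x$table$consensus_rank),
                 c("gene", "delta_ct_stability", "bestkeeper_sd",
                   "normfinder_stability", "genorm_M", "geomean_rank")]
  print(utils::head(`rownames<-`(tab, NULL), n), digits = 4L)
  if (nrow(tab) > n) cat("... and", nrow(tab) - n, "more genes\n")
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  cat("Most stable:", paste(utils::head(object$consensus_order, 3L),
                            collapse = ", "), "\n")
  cat("Least stable:", utils::tail(object$consensus_order, 1L), "\n")
  invisible(object$table)
}

#' @export
plot.stability_report <- function(x, ...) {
  tab <- x$table[order(x$table$consensus_rank), ]
  graphics::barplot(tab$geomean_rank, names.arg = tab$gene, las = 2L,
                    ylab = "geomean of method ranks",
                    main = "Consensus stability (lower = more stable)", ...)
  invisible(x)
}
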