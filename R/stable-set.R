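#' Rescale normalized expression by gene means
#'
#' Divides each gene's normalized expression by its mean across samples,
#' u_ik = w_ik / mean_k(w_ik), so every gene carries equal weight in the
#' pooled Gaussian model: each output row has mean exactly 1.
#'
#' @param w normalized expression matrix.
#' @return rescaled matrix u with unit row means.
#' @export
rescale_by_gene_mean <- function(w) {
  rm <- rowMeans(w)
  if (any(rm <= 0)) {
    stop("zero-mean row for gene: ", rownames(w)[rm <= 0][1L])
  }
  w / rm
}

#' Pooled mean and standard deviation of rescaled expression
#'
#' Pools every entry of the rescaled matrix u and returns the grand mean and
#' the sample standard deviation (denominator m*n - 1). Because each row of u
#' has mean 1 by construction, the pooled mean is always exactly 1.
#'
#' @param u rescaled expression matrix from [rescale_by_gene_mean()].
#' @return list with elements `mu` and `sigma`.
#' @export
pooled_moments <- function(u) {
  v <- as.vector(u)
  if (length(v) < 2L) stop("need at least two pooled values")
  mu <- mean(v)
  sigma <- stats::sd(v)
  if (sigma == 0)
    stop("pooled standard deviation is zero: degenerate (constant) model")
  list(mu = mu, sigma = sigma)
}

#' Per-gene log10 probability under the two-state Gaussian tail model
#'
#' A stably expressed gene's rescaled values are scored by the two-sided tail
#' probability P = 2 * Phi(-|z|) with z = (u - mu) / sigma; an unstably
#' expressed gene by the complement 1 - 2 * Phi(-|z|). Probabilities are
#' clamped to `[p_floor, 1]` before taking log10 (the unstable-state P is
#' exactly 0 at u = mu), and the per-sample logs are summed.
#'
#' @param u_row numeric vector: one gene's rescaled expression across samples.
#' @param mu,sigma pooled moments.
#' @param is_stable logical: score under the stable (TRUE) or unstable state.
#' @param p_floor lower clamp for probabilities, default 1e-12.
#' @return scalar log10 probability of the row.
#' @export
gene_log_probability <- function(u_row, mu, sigma, is_stable,
                                 p_floor = 1e-12) {
  stopifnot(sigma > 0, p_floor > 0, p_floor < 1)
  p_tail <- 2 * stats::pnorm(-abs((u_row - mu) / sigma))
  p <- if (is_stable) p_tail else 1 - p_tail
  sum(log10(pmin(pmax(p, p_floor), 1)))
}

# Vectorised two-state scores for all genes at once: returns an n x 2 matrix
# of per-gene log10 likelihood under (stable, unstable).
state_loglik_matrix <- function(u, mu, sigma, p_floor) {
  p_tail <- 2 * stats::pnorm(-abs((u - mu) / sigma))
  clamp <- function(p) pmin(pmax(p, p_floor), 1)
  cbind(stable = rowSums(log10(clamp(p_tail))),
        unstable = rowSums(log10(clamp(1 - p_tail))))
}

#' Total model likelihood for a given stable/unstable membership
#'
#' Size factors are computed from the stable genes only; the whole matrix is
#' then normalized, rescaled by gene means, pooled for mu and sigma, and each
#' gene scored under its assigned state. The total likelihood is the sum of
#' the per-gene log10 probabilities.
#'
#' @param m expression matrix (raw counts or expression values).
#' @param membership named logical vector over the genes of `m`; TRUE marks a
#'   stably expressed gene. At least one gene must be stable.
#' @param p_floor probability clamp, see [gene_log_probability()].
#' @param pool moments pooled over `"all"` genes (default, the literal model)
#'   or only the `"stable"` set.
#' @return list: `likelihood`, `per_gene_loglik` (named, under each gene's
#'   current state), `state_loglik` (n x 2 matrix), `size_factors`, `mu`,
#'   `sigma`.
#' @export
total_likelihood <- function(m, membership, p_floor = 1e-12,
                             pool = c("all", "stable")) {
  pool <- match.arg(pool)
  if (is.null(names(membership))) names(membership) <- rownames(m)
  membership <- membership[rownames(m)]
  if (anyNA(membership)) stop("membership must cover every gene of the matrix")
  if (!any(membership)) stop("at least one gene must be marked stable")
  sf <- compute_size_factors(m, rownames(m)[membership])
  w <- normalize_expression(m, sf)
  u <- rescale_by_gene_mean(w)
  mom <- pooled_moments(if (pool == "all") u else u[membership, , drop = FALSE])
  sl <- state_loglik_matrix(u, mom$mu, mom$sigma, p_floor)
  per_gene <- ifelse(membership, sl[, "stable"], sl[, "unstable"])
  names(per_gene) <- rownames(m)
  list(likelihood = sum(per_gene), per_gene_loglik = per_gene,
       state_loglik = sl, size_factors = sf, mu = mom$mu, sigma = mom$sigma)
}

#' Greedy elimination phase of stable-set selection
#'
#' Starts with every gene in the stable set. Each round recomputes size
#' factors from the current stable set and the per-gene log likelihoods, then
#' removes the stable gene with the smallest per-gene log likelihood (ties
#' broken by first occurrence in gene order), recording (set size, total
#' likelihood) per round until one gene remains eliminated to empty. The
#' membership at the best-likelihood round is returned.
#'
#' @inheritParams total_likelihood
#' @param drop_fraction optional accelerator: fraction of the stable set to
#'   drop per round (default 0 = faithful single elimination; at least one
#'   gene is always dropped).
#' @return list: `membership` (at the maximum-likelihood round), `trace`
#'   (data.frame round, size, likelihood), `best_likelihood`.
#' @export
greedy_elimination <- function(m, p_floor = 1e-12, pool = c("all", "stable"),
                               drop_fraction = 0) {
  pool <- match.arg(pool)
  n <- nrow(m)
  if (n < 2L) stop("need at least two genes")
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  membership <- stats::setNames(rep(TRUE, n), rownames(m))
  trace <- vector("list", n)
  best <- -Inf
  best_membership <- membership
  round <- 0L
  while (any(membership)) {
    round <- round + 1L
    tl <- total_likelihood(m, membership, p_floor, pool)
    trace[[round]] <- data.frame(round = round, size = sum(membership),
                                 likelihood = tl$likelihood)
    if (tl$likelihood > best) {
      best <- tl$likelihood
      best_membership <- membership
    }
    stable_idx <- which(membership)
    n_drop <- max(1L, floor(drop_fraction * length(stable_idx)))
    n_drop <- min(n_drop, length(stable_idx))
    worst <- stable_idx[order(tl$per_gene_loglik[stable_idx])[seq_len(n_drop)]]
    membership[worst] <- FALSE
  }
  list(membership = best_membership,
       trace = do.call(rbind, trace[seq_len(round)]),
       best_likelihood = best)
}

#' Flip-refinement phase of stable-set selection
#'
#' Starting from an initial membership, repeatedly flips the state of the
#' gene with the smallest per-gene log likelihood under its current state
#' (considering all genes, so eliminated genes can re-enter). A flip is kept
#' only if the total likelihood strictly increases; on the first rejected
#' flip the search stops (set `scan_all = TRUE` to instead try every gene in
#' ascending log-likelihood order before stopping).
#'
#' @inheritParams total_likelihood
#' @param membership initial named logical membership.
#' @param scan_all logical; see Description.
#' @return list: `membership`, `likelihood`, `flips_accepted`,
#'   `likelihood_path` (likelihood after each accepted flip, starting value
#'   first), plus the final `total_likelihood()` pieces (`mu`, `sigma`,
#'   `per_gene_loglik`, `size_factors`).
#' @export
refine_membership <- function(m, membership, p_floor = 1e-12,
                              pool = c("all", "stable"), scan_all = FALSE) {
  pool <- match.arg(pool)
  cur <- total_likelihood(m, membership, p_floor, pool)
  if (is.null(names(membership))) names(membership) <- rownames(m)
  membership <- membership[rownames(m)]
  flips <- 0L
  path <- cur$likelihood
  repeat {
    cand_order <- order(cur$per_gene_loglik)
    if (!scan_all) cand_order <- cand_order[1L]
    improved <- FALSE
    for (g in cand_order) {
      trial <- membership
      trial[g] <- !trial[g]
      if (!any(trial)) next  # cannot empty the stable set
      new <- total_likelihood(m, trial, p_floor, pool)
      if (new$likelihood > cur$likelihood) {
        membership <- trial
        cur <- new
        flips <- flips + 1L
        path <- c(path, cur$likelihood)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(membership = membership, likelihood = cur$likelihood,
       flips_accepted = flips, likelihood_path = path,
       per_gene_loglik = cur$per_gene_loglik, size_factors = cur$size_factors,
       mu = cur$mu, sigma = cur$sigma)
}

#' Select the maximally likely set of stably expressed genes
#'
#' Fits the two-state Gaussian tail-probability model to an expression matrix
#' by the two-phase search: greedy elimination from the all-stable model
#' (finding the best stable-set size), then single-flip refinement around it.
#' Both phases are deterministic for a fixed input.
#'
#' @inheritParams greedy_elimination
#' @param scan_all passed to [refine_membership()].
#' @return an object of class `stable_set_fit`: membership, pooled moments,
#'   likelihood, per-gene log likelihoods, size factors, greedy trace and
#'   refinement counters. Use `coef()` for the size factors, `summary()` for
#'   an overview, `plot()` for the likelihood trace.
#' @examples
#' sim <- simulate_counts(n_genes = 40, m_samples = 4, seed = 1)
#' fit <- select_stable_genes(sim$matrix)
#' fit
#' head(stable_genes(fit))
#' @export
select_stable_genes <- function(m, p_floor = 1e-12, pool = c("all", "stable"),
                                drop_fraction = 0, scan_all = FALSE) {
  pool <- match.arg(pool)
  validate_expression_matrix(m)
  greedy <- greedy_elimination(m, p_floor, pool, drop_fraction)
  ref <- refine_membership(m, greedy$membership, p_floor, pool, scan_all)
  structure(list(membership = ref$membership,
                 mu = ref$mu, sigma = ref$sigma,
                 likelihood = ref$likelihood,
                 per_gene_loglik = ref$per_gene_loglik,
                 size_factors = ref$size_factors,
                 trace = greedy$trace,
                 greedy_likelihood = greedy$best_likelihood,
                 flips_accepted = ref$flips_accepted,
                 config = list(p_floor = p_floor, pool = pool,
                               drop_fraction = drop_fraction,
                               scan_all = scan_all),
                 call = match.call()),
            class = "stable_set_fit")
}

#' Gene ids of the fitted stable set
#' @param fit a `stable_set_fit`.
#' @return character vector of stably expressed gene ids.
#' @export
stable_genes <- function(fit) {
  stopifnot(inherits(fit, "stable_set_fit"))
  names(fit$membership)[fit$membership]
}

#' @export
print.stable_set_fit <- function(x, ...) {
  cat("Stable-set model fit\n")
  cat(sprintf("  genes: %d (%d stable, %d unstable)\n",
              length(x$membership), sum(x$membership), sum(!x$membership)))
  cat(sprintf("  pooled mu = %.6f, sigma = %.6f\n", x$mu, x$sigma))
  cat(sprintf("  log10 likelihood = %.4f (greedy best %.4f, %d flips accepted)\n",
              x$likelihood, x$greedy_likelihood, x$flips_accepted))
  invisible(x)
}

#' @export
summary.stable_set_fit <- function(object, ...) {
  out <- list(n_stable = sum(object$membership),
              n_unstable = sum(!object$membership),
              mu = object$mu, sigma = object$sigma,
              likelihood = object$likelihood,
              flips_accepted = object$flips_accepted,
              size_factors = object$size_factors$s,
              trace = object$trace)
  class(out) <- "summary.stable_set_fit"
  out
}

#' @export
print.summary.stable_set_fit <- function(x, ...) {
  cat(sprintf("Stable-set model: %d stable / %d unstable genes, sigma = %.5f, log10 L = %.4f\n",
              x$n_stable, x$n_unstable, x$sigma, x$likelihood))
  cat("Size factors:\n")
  print(round(x$size_factors, 4L))
  best <- x$trace[which.max(x$trace$likelihood), ]
  cat(sprintf("Greedy phase: best size %d at likelihood %.4f; %d refinement flips\n",
              best$size, best$likelihood, x$flips_accepted))
  invisible(x)
}

#' @export
coef.stable_set_fit <- function(object, ...) object$size_factors$s

#' @export
plot.stable_set_fit <- function(x, ...) {
  plot(x$trace$size, x$trace$likelihood, type = "b", pch = 16,
       xlab = "stable-set size", ylab = "log10 likelihood",
       main = "Greedy elimination trace", ...)
  graphics::abline(v = sum(x$membership), lty = 2, col = "grey40")
  invisible(x)
}
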