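# Small builders shared across tests.

toy_matrix <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, genes, samples)
}

# Planted noiseless (or jittered) matrix v_ik = mu_i * s_k * exp(eps).
planted_matrix <- function(mu, s, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- outer(mu, s)
  if (jitter > 0) v <- v * exp(matrix(rnorm(length(v), 0, jitter),
                                      nrow(v), ncol(v)))
  toy_matrix(v)
}

# Planted instance for the stable-set search: n_stable clean genes plus
# outliers with a fold spike in one sample each.
planted_instance <- function(n_stable, n_outlier, m, spike = 4,
                             jitter = 1e-3, seed = 1) {
  set.seed(seed)
  n <- n_stable + n_outlier
  mat <- planted_matrix(runif(n, 5, 50), exp(rnorm(m, 0, 0.2)),
                        jitter = jitter)
  truth <- rep(c(TRUE, FALSE), c(n_stable, n_outlier))
  names(truth) <- rownames(mat)
  for (i in which(!truth)) {
    k <- sample.int(m, 1L)
    mat[i, k] <- mat[i, k] * spike
  }
  list(matrix = mat, truth = truth)
}

# Exhaustive maximum of the membership likelihood over all 2^n - 1
# non-empty stable sets (independent oracle for the two-phase search).
exhaustive_best_membership <- function(m, p_floor = 1e-12) {
  n <- nrow(m)
  stopifnot(n <= 14)
  best <- -Inf
  best_mem <- NULL
  for (k in seq_len(2^n - 1L)) {
    mem <- bitwAnd(k, 2^(seq_len(n) - 1L)) > 0
    names(mem) <- rownames(m)
    ll <- total_likelihood(m, mem, p_floor)$likelihood
    if (ll > best) {
      best <- ll
      best_mem <- mem
    }
  }
  list(likelihood = best, membership = best_mem)
}
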