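test_that("gene-mean rescaling forces unit row means", {
  m <- toy_matrix(rbind(c(2, 4, 6), c(5, 5, 5)))
  u <- rescale_by_gene_mean(m)
  expect_equal(u["g1", ], c(s1 = 0.5, s2 = 1, s3 = 1.5))
  expect_equal(u["g2", ], c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(unname(rowMeans(u)), c(1, 1), tolerance = 1e-15)
  bad <- m
  bad["g2", ] <- 0
  expect_error(rescale_by_gene_mean(bad), "zero-mean row.*g2")
})

test_that("pooled moments match hand arithmetic and reject degeneracy", {
  u <- rbind(c(1, 1), c(0.5, 1.5))
  mom <- pooled_moments(u)
  expect_equal(mom$mu, 1, tolerance = 1e-12)
  expect_equal(mom$sigma, sqrt(0.5 / 3), tolerance = 1e-12) # 0.40825
  expect_error(pooled_moments(matrix(1, 2, 3)), "degenerate")
  # mu is analytically 1 for any rescaled matrix
  set.seed(3)
  u2 <- rescale_by_gene_mean(toy_matrix(matrix(runif(40, 1, 9), 8, 5)))
  expect_equal(pooled_moments(u2)$mu, 1, tolerance = 1e-9)
})

test_that("two-state log probabilities follow the Gaussian tail model", {
  # at u = mu the stable state is certain, the unstable state is floored
  expect_equal(gene_log_probability(rep(2, 4), 2, 0.3, TRUE), 0)
  expect_equal(gene_log_probability(rep(2, 4), 2, 0.3, FALSE,
                                    p_floor = 1e-12), 4 * -12)
  # z = 1.959964 gives the textbook two-sided 0.05 tail
  expect_equal(gene_log_probability(1.959964, 0, 1, TRUE), log10(0.05),
               tolerance = 1e-6)
  expect_equal(gene_log_probability(1.959964, 0, 1, FALSE), log10(0.95),
               tolerance = 1e-6)
  expect_error(gene_log_probability(1, 0, 0, TRUE), "sigma")
})

test_that("total likelihood is self-consistent and maximal at planted truth", {
  inst <- planted_instance(n_stable = 5, n_outlier = 1, m = 3, seed = 1)
  fit <- select_stable_genes(inst$matrix)
  # stored likelihood is reproduced from scratch for the stored membership
  re <- total_likelihood(inst$matrix, fit$membership)
  expect_equal(re$likelihood, fit$likelihood, tolerance = 1e-9)
  expect_equal(sum(fit$per_gene_loglik), fit$likelihood, tolerance = 1e-6)
  # exhaustive oracle over all 2^6 - 1 memberships
  oracle <- exhaustive_best_membership(inst$matrix)
  expect_equal(fit$likelihood, oracle$likelihood, tolerance = 1e-9)
  expect_identical(fit$membership, oracle$membership)
  expect_identical(fit$membership, inst$truth)
})

test_that("greedy elimination removes the planted spike first, traces fully", {
  inst <- planted_instance(n_stable = 5, n_outlier = 1, m = 3, seed = 2)
  g <- greedy_elimination(inst$matrix)
  expect_equal(nrow(g$trace), 6L)
  expect_equal(g$trace$size, 6:1)
  # the spiked gene has the smallest stable-state likelihood at round 1,
  # so it is the one missing from the size-5 membership
  tl0 <- total_likelihood(inst$matrix,
                          setNames(rep(TRUE, 6), rownames(inst$matrix)))
  expect_identical(names(which.min(tl0$per_gene_loglik)),
                   names(which(!inst$truth)))
  # best-trace likelihood is at least the all-stable (round 1) likelihood
  expect_gte(g$best_likelihood, g$trace$likelihood[1L])
})

test_that("refinement only accepts strict improvements and can re-enter genes", {
  inst <- planted_instance(n_stable = 6, n_outlier = 2, m = 4, seed = 3)
  g <- greedy_elimination(inst$matrix)
  ref <- refine_membership(inst$matrix, g$membership)
  expect_true(all(diff(ref$likelihood_path) > 0))
  expect_gte(ref$likelihood, g$best_likelihood)
  # a local optimum is returned unchanged
  again <- refine_membership(inst$matrix, ref$membership)
  expect_identical(again$membership, ref$membership)
  expect_identical(again$flips_accepted, 0L)
})

test_that("the two-phase search matches the exhaustive oracle on planted instances", {
  set.seed(10)
  sizes <- cbind(n = c(6, 7, 8), m = c(3, 4, 3))
  for (i in seq_len(nrow(sizes))) {
    inst <- planted_instance(n_stable = sizes[i, "n"] - 1L, n_outlier = 1L,
                             m = sizes[i, "m"], seed = 100 + i)
    fit <- select_stable_genes(inst$matrix)
    oracle <- exhaustive_best_membership(inst$matrix)
    expect_equal(fit$likelihood, oracle$likelihood, tolerance = 1e-9)
  }
})

test_that("membership recovery is invariant to gene order (no exact ties)", {
  inst <- planted_instance(n_stable = 7, n_outlier = 2, m = 4, seed = 5)
  fit1 <- select_stable_genes(inst$matrix)
  set.seed(99)
  perm <- sample.int(nrow(inst$matrix))
  fit2 <- select_stable_genes(inst$matrix[perm, , drop = FALSE])
  expect_identical(fit1$membership[rownames(inst$matrix)[perm]],
                   fit2$membership)
  expect_equal(fit1$likelihood, fit2$likelihood, tolerance = 1e-9)
})

test_that("parameter recovery holds at realistic scale", {
  sim <- simulate_counts(n_genes = 500, m_samples = 8, stable_fraction = 0.8,
                         tau_s = 0.05, tau_u = 0.7, seed = 7)
  fit <- select_stable_genes(sim$matrix)
  pred <- fit$membership
  truth <- sim$truth$stable_mask
  precision <- sum(pred & truth) / sum(pred)
  recall <- sum(pred & truth) / sum(truth)
  expect_gte(precision, 0.90)
  expect_gte(recall, 0.90)
  rel_err <- abs(coef(fit) - sim$truth$size_factors) / sim$truth$size_factors
  expect_lte(max(rel_err), 0.05)
})

test_that("fit object accessors and methods are coherent", {
  inst <- planted_instance(n_stable = 5, n_outlier = 1, m = 3, seed = 8)
  fit <- select_stable_genes(inst$matrix)
  expect_s3_class(fit, "stable_set_fit")
  expect_identical(stable_genes(fit), names(which(fit$membership)))
  expect_identical(coef(fit), fit$size_factors$s)
  expect_equal(fit$mu, 1, tolerance = 1e-9)
  expect_output(print(fit), "Stable-set model fit")
  expect_output(print(summary(fit)), "Size factors")
})

test_that("stable-only moment pooling is available behind the switch", {
  inst <- planted_instance(n_stable = 5, n_outlier = 1, m = 3, seed = 9)
  fit_all <- select_stable_genes(inst$matrix, pool = "all")
  fit_stable <- select_stable_genes(inst$matrix, pool = "stable")
  # the stable-only pool concentrates sigma on the fitted set
  expect_lte(fit_stable$sigma, fit_all$sigma)
  expect_gte(length(stable_genes(fit_stable)), 1L)
  re <- total_likelihood(inst$matrix, fit_stable$membership, pool = "stable")
  expect_equal(re$likelihood, fit_stable$likelihood, tolerance = 1e-9)
})
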