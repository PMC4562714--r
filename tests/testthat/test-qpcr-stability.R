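toy_ct <- function() {
  ct_matrix(rbind(g1 = c(20, 21, 22), g2 = c(20, 21, 22), g3 = c(20, 22, 21)),
            sample_ids = c("a", "b", "c"))
}

test_that("Ct-to-quantity transform follows the efficiency model", {
  ct <- toy_ct()
  q <- ct_to_quantities(ct, efficiency = 2)
  expect_equal(unname(q$q["g1", ]), c(1, 0.5, 0.25))
  expect_equal(apply(q$q, 1, max), c(g1 = 1, g2 = 1, g3 = 1))
  const <- ct_matrix(matrix(25, 1, 3, dimnames = list("g", c("a", "b", "c"))))
  expect_equal(unname(ct_to_quantities(const)$q[1, ]), rep(1, 3))
  q19 <- ct_to_quantities(ct, efficiency = 1.9)
  expect_equal(q19$q["g1", "b"], 1 / 1.9, ignore_attr = TRUE)
  expect_error(ct_to_quantities(ct, efficiency = 1), "efficiency > 1")
})

test_that("mean delta-Ct summarises spread in cycles", {
  ct <- toy_ct()
  expect_equal(unname(mean_delta_ct(ct)), c(1, 1, 1))
  expect_equal(unname(mean_delta_ct(ct[, c(3, 1, 2)])), c(1, 1, 1))
  const <- ct_matrix(matrix(25, 1, 3, dimnames = list("g", c("a", "b", "c"))))
  expect_equal(unname(mean_delta_ct(const)), 0)
})

test_that("comparative delta-Ct matches the hand oracle and cancels sample shifts", {
  ct <- toy_ct()
  st <- comparative_delta_ct(ct)
  expect_equal(unname(st), c(0.5, 0.5, 1.0)) # SD(g1-g3) = SD(0,-1,1) = 1
  shifted <- ct + matrix(rep(c(3, -1, 0.5), each = 3), 3, 3)
  expect_equal(comparative_delta_ct(ct_matrix(shifted)), st,
               tolerance = 1e-12)
})

test_that("BestKeeper descriptive statistics match hand arithmetic", {
  bk <- bestkeeper(toy_ct())
  g3 <- bk[bk$gene == "g3", ]
  expect_equal(g3$sd, 1)
  expect_equal(g3$mad, 2 / 3)
  const <- ct_matrix(rbind(g1 = c(20, 21, 22), flat = c(25, 25, 25)),
                     sample_ids = c("a", "b", "c"))
  bk2 <- bestkeeper(const)
  expect_equal(bk2$sd[bk2$gene == "flat"], 0)
  expect_true(is.na(bk2$r[bk2$gene == "flat"]))
  # per-gene additive shifts leave sd and mad unchanged
  shifted <- toy_ct() + c(5, 0, -3)
  expect_equal(bestkeeper(ct_matrix(shifted))[c("sd", "mad")],
               bestkeeper(toy_ct())[c("sd", "mad")], tolerance = 1e-12)
})

test_that("NormFinder stability is zero for an average-profile gene and shift-invariant", {
  q <- ct_to_quantities(toy_ct())
  nf <- normfinder(q)
  expect_true(all(nf >= 0))
  # g1 and g2 are identical, so their centred profiles coincide
  expect_equal(nf[["g1"]], nf[["g2"]], tolerance = 1e-12)
  # per-sample additive Ct shifts (global sample effects) cancel
  shifted <- ct_matrix(toy_ct() + matrix(rep(c(2, -1, 4), each = 3), 3, 3))
  expect_equal(normfinder(ct_to_quantities(shifted)), nf, tolerance = 1e-12)
  # a gene equal to the per-sample average profile has stability 0
  ct4 <- ct_matrix(rbind(g1 = c(20, 21, 22), g2 = c(22, 21, 20),
                         avg = c(21, 21, 21)), sample_ids = c("a", "b", "c"))
  expect_equal(normfinder(ct_to_quantities(ct4))[["avg"]], 0,
               tolerance = 1e-12)
})

test_that("geNorm M is scale-invariant and excludes the noisiest gene first", {
  ct <- toy_ct()
  q <- ct_to_quantities(ct)
  gn <- genorm(q)
  # g1 and g2 track each other exactly: A_12 = 0
  expect_equal(gn$M[["g1"]], gn$M[["g2"]], tolerance = 1e-12)
  expect_lt(gn$M[["g1"]], gn$M[["g3"]])
  expect_identical(gn$exclusion_order, "g3")
  expect_setequal(gn$final_pair, c("g1", "g2"))
  # multiplicative rescaling of one gene's quantities leaves M unchanged
  q2 <- q
  q2$q["g1", ] <- q2$q["g1", ] * 0.37
  expect_equal(genorm(q2)$M, gn$M, tolerance = 1e-12)

  # planted noise ladder: the noisiest genes are excluded first (majority
  # vote over seeded replicates)
  set.seed(17)
  worst_first <- replicate(20, {
    x <- rbind(a = rep(0, 8), b = rep(0, 8),
               c = rnorm(8, 0, 0.2), d = rnorm(8, 0, 0.6))
    ctm <- ct_matrix(25 + x, sample_ids = sprintf("s%d", 1:8))
    genorm(ct_to_quantities(ctm))$exclusion_order[1L]
  })
  expect_gt(mean(worst_first == "d"), 0.5)
})

test_that("consensus ranking aggregates by geomean with documented tie rules", {
  sim <- simulate_ct(seed = 2)
  ctm <- aggregate_replicates(sim$records)
  rep_ <- rank_stability(ctm)
  tab <- rep_$table
  # geomean equals direct arithmetic on the four rank columns
  direct <- exp(rowMeans(log(tab[, c("rank_delta_ct", "rank_bestkeeper",
                                     "rank_normfinder", "rank_genorm")])))
  expect_equal(tab$geomean_rank, direct, tolerance = 1e-9)
  # each method's ranks are a permutation allowing average ties
  for (col in c("rank_delta_ct", "rank_bestkeeper", "rank_normfinder",
                "rank_genorm")) {
    expect_equal(sum(tab[[col]]), sum(seq_len(nrow(tab))))
  }
  # consensus order sorts ascending geomean
  expect_identical(rep_$consensus_order,
                   tab$gene[order(tab$geomean_rank, tab$gene)])

  # duplicated identical genes tie and fall back to alphabetical order
  ct_dup <- ct_matrix(rbind(zz = c(20, 21, 22), aa = c(20, 21, 22),
                            g3 = c(20, 25, 21)),
                      sample_ids = c("a", "b", "c"))
  rep_dup <- rank_stability(ct_dup)
  ga <- rep_dup$table[rep_dup$table$gene == "aa", "geomean_rank"]
  gz <- rep_dup$table[rep_dup$table$gene == "zz", "geomean_rank"]
  expect_equal(ga, gz, tolerance = 1e-12)
  expect_lt(match("aa", rep_dup$consensus_order),
            match("zz", rep_dup$consensus_order))

  expect_error(rank_stability(ctm[1:2, ]), "nrow")
})

test_that("all four methods separate planted stable from unstable genes", {
  sim <- simulate_ct(n_stable = 4, n_unstable = 4, stable_sd = 0.2,
                     effect_size = 2, seed = 1)
  ctm <- aggregate_replicates(sim$records)
  rep_ <- rank_stability(ctm)
  tab <- rep_$table
  truth <- sim$truth$stable_mask[tab$gene]
  for (metric in c("delta_ct_stability", "bestkeeper_sd",
                   "normfinder_stability", "genorm_M")) {
    expect_lt(max(tab[[metric]][truth]), min(tab[[metric]][!truth]))
  }
  # and the consensus puts every stable gene ahead of every unstable one
  expect_identical(sort(utils::head(rep_$consensus_order, 4)),
                   sort(names(which(sim$truth$stable_mask))))
})
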