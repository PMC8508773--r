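test_that("pairwise variation matches closed forms and the brute-force oracle", {
  # constant ratio (parallel genes in Ct) -> V = 0
  ct <- make_ct(rbind(c(24, 25, 26), c(26, 27, 28), c(25, 25, 25)))
  q <- relative_quantities(ct)
  expect_equal(pairwise_variation(q, "g1", "g2"), 0)

  # A = {0, -1, -2} -> sample SD 1
  expect_equal(pairwise_variation(q, "g1", "g3"), 1.0)
  # symmetry
  expect_equal(pairwise_variation(q, "g3", "g1"),
               pairwise_variation(q, "g1", "g3"))

  # random 2x6 panel equals elementwise log-ratio SD
  ct2 <- random_ct(2, 6, sigma = c(0.4, 0.7), seed = 21)
  q2 <- relative_quantities(ct2)
  expect_equal(pairwise_variation(q2, "g1", "g2"),
               sd(log2(q2["g1", ] / q2["g2", ])))

  expect_error(pairwise_variation(relative_quantities(make_ct(
    rbind(c(24, 25), c(23, 23)))), "g1", "g2"), "3 samples")
})

test_that("M values match the brute-force double-loop oracle", {
  for (seed in c(2, 7, 13)) {
    ct <- random_ct(5, 8, sigma = runif(5, 0.1, 1), seed = seed)
    q <- relative_quantities(ct)
    got <- genorm_m(q)
    want <- oracle_m_values(unclass(q))
    expect_equal(setNames(got$m, got$gene), want, tolerance = 1e-12)
  }
  # symmetry: two offset-parallel genes share M, a noisy third exceeds it
  set.seed(1)
  base <- 25 + rnorm(10, 0, 0.3)
  ct <- make_ct(rbind(base, base + 2, 25 + rnorm(10, 0, 1.5)))
  m <- genorm_m(relative_quantities(ct))
  expect_equal(m$m[1], m$m[2])
  expect_gt(m$m[3], m$m[1])
  # identical genes -> all M = 0
  ct0 <- make_ct(matrix(rep(c(24, 25, 26, 24), each = 3), nrow = 3, byrow = FALSE))
  expect_equal(genorm_m(relative_quantities(ct0))$m, rep(0, 3))
})

test_that("stepwise elimination ranks genes and keeps a shared rank-1 pair", {
  # 3-gene panel: one elimination step, ranks {1,1,2}
  ct <- random_ct(3, 10, sigma = c(0.1, 0.1, 1.0), seed = 4)
  fit <- genorm(relative_quantities(ct))
  expect_equal(sort(fit$ranks$rank), c(1L, 1L, 2L))
  expect_equal(fit$ranks$rank[fit$ranks$gene == "g3"], 2L)
  expect_equal(sort(fit$final_pair), c("g1", "g2"))

  # a group-confounded gene is eliminated first
  set.seed(9)
  k <- 5; n <- 12
  m <- 25 + matrix(rnorm(k * n, 0, 0.2), k, n)
  m[5, 1:6] <- m[5, 1:6] + 3   # large shift confined to half the samples
  fit2 <- genorm(relative_quantities(make_ct(m)))
  expect_equal(fit2$elimination$gene[1], "g5")

  # initial M equals full-panel M exactly; ranks are dense 1..k-1
  q <- relative_quantities(random_ct(6, 9, sigma = runif(6, 0.2, 0.9), seed = 5))
  fit3 <- genorm(q)
  expect_equal(fit3$initial_m$m, genorm_m(q)$m)
  expect_setequal(fit3$ranks$rank, 1:5)
  expect_equal(sum(fit3$ranks$rank == 1L), 2L)
})

test_that("V series and optimal_n behave on degenerate and designed panels", {
  # three identical genes: V2/3 = 0, optimal n = 2
  ct <- make_ct(matrix(rep(c(24, 25, 26, 27), each = 3), nrow = 3))
  fit <- genorm(relative_quantities(ct))
  expect_equal(fit$v_series$v[fit$v_series$n == 2], 0)
  expect_equal(fit$optimal_n, 2L)

  # two clean genes plus one very noisy: V2/3 above the cutoff
  set.seed(31)
  m <- rbind(25 + rnorm(20, 0, 0.05), 24 + rnorm(20, 0, 0.05),
             26 + rnorm(20, 0, 1.5))
  fit2 <- genorm(relative_quantities(make_ct(m)))
  v23 <- fit2$v_series$v[fit2$v_series$n == 2]
  # direct evaluation of the same quantity
  q <- unclass(relative_quantities(make_ct(m)))
  ord <- fit2$stability_order
  nf2 <- apply(q[ord[1:2], ], 2, function(x) exp(mean(log(x))))
  nf3 <- apply(q[ord[1:3], ], 2, function(x) exp(mean(log(x))))
  expect_equal(v23, sd(log2(nf2 / nf3)))
  expect_gt(v23, 0.15)
  expect_true(is.na(fit2$optimal_n) || fit2$optimal_n > 2)
})

test_that("geNorm is invariant to per-gene scaling and sample permutation", {
  ct <- random_ct(5, 10, sigma = runif(5, 0.2, 1), seed = 17)
  q <- relative_quantities(ct)
  fit <- genorm(q)

  # shifting one gene's Ct by a constant (scales its Q) changes nothing
  m2 <- unclass(ct); m2[2, ] <- m2[2, ] + 3
  fit2 <- genorm(relative_quantities(make_ct(m2)))
  expect_equal(fit2$initial_m$m, fit$initial_m$m)
  expect_equal(fit2$v_series$v, fit$v_series$v)
  expect_equal(fit2$ranks, fit$ranks)

  # permuting samples changes nothing
  perm <- sample(ncol(ct))
  m3 <- unclass(ct)[, perm]
  fit3 <- genorm(relative_quantities(make_ct(m3, samples = colnames(ct)[perm])))
  expect_equal(fit3$initial_m$m, fit$initial_m$m)
  expect_equal(fit3$v_series$v, fit$v_series$v)
})

test_that("a 5x noise-inflated gene is eliminated first across seeds", {
  hits <- 0L
  for (seed in 1:100) {
    ct <- random_ct(5, 12, sigma = c(0.2, 0.2, 0.2, 0.2, 1.0), seed = seed)
    fit <- genorm(relative_quantities(ct))
    hits <- hits + (fit$elimination$gene[1] == "g5")
  }
  expect_gte(hits, 95L)
})
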