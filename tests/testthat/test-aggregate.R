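test_that("rank sums reproduce the published worked example", {
  for (block in c("all_samples", "three_raspberries")) {
    ex <- published_rank_example(block)
    rs <- rank_sum(ex)
    got <- rs$rank_sum[match(ex$gene, rs$gene)]
    expect_equal(got, ex$published_sum)
  }
  # spot checks on the extreme rows
  rs <- rank_sum(published_rank_example("all_samples"))
  expect_equal(rs$rank_sum[rs$gene == "RuEEF1A"], 4L)
  expect_equal(rs$rank_sum[rs$gene == "RuPGK"], 34L)
})

test_that("rank_sum aggregation is coherent", {
  # perfect agreement: final ranks equal each input ranking
  ranks <- tibble::tibble(gene = letters[1:5], genorm = 1:5,
                          normfinder = 1:5, bestkeeper = 1:5)
  rs <- rank_sum(ranks)
  expect_equal(rs$final_rank, rs$genorm)

  # worst-everywhere gene: sum 3k, final rank k
  ranks$genorm[5] <- ranks$normfinder[5] <- ranks$bestkeeper[5] <- 5L
  rs <- rank_sum(ranks)
  expect_equal(rs$rank_sum[rs$gene == "e"], 15L)
  expect_equal(rs$final_rank[rs$gene == "e"], 5L)

  # permutation equivariance over gene labels
  perm <- c(3, 1, 5, 2, 4)
  rs_perm <- rank_sum(ranks[perm, ])
  expect_equal(dplyr::arrange(rs_perm, .data$gene),
               dplyr::arrange(rs, .data$gene))

  # improving one method's rank never worsens the final rank
  base <- tibble::tibble(gene = letters[1:4], genorm = c(1L, 2L, 3L, 4L),
                         normfinder = c(2L, 1L, 3L, 4L),
                         bestkeeper = c(1L, 3L, 2L, 4L))
  before <- rank_sum(base)
  improved <- base
  improved$bestkeeper[improved$gene == "b"] <- 1L
  after <- rank_sum(improved)
  expect_lte(after$final_rank[after$gene == "b"],
             before$final_rank[before$gene == "b"])

  # gene-set mismatch across methods is a hard error naming the difference
  sim <- simulate_ct(default_ct_spec(seed = 1))
  q <- relative_quantities(sim$ct)
  expect_error(
    refstab:::check_gene_sets(c("a", "b"), c("a", "c"), "geNorm", "BestKeeper"),
    "only in geNorm: b")
  expect_error(rank_sum(tibble::tibble(gene = "a", genorm = 1L,
                                       normfinder = NA_integer_,
                                       bestkeeper = 1L)),
               "missing ranks")
})

test_that("analyze_group bundles the three methods consistently", {
  sim <- simulate_ct(default_ct_spec(seed = 4))
  sub <- subset_ct(sim$ct, sim$annotation, cultivar == "blackberry",
                   name = "blackberry_tissues")
  fit <- analyze_group(sub)
  expect_s3_class(fit, "stability_analysis")
  expect_equal(nrow(fit$ranking), 12)
  expect_equal(fit$ranking$rank_sum,
               fit$ranking$genorm + fit$ranking$normfinder + fit$ranking$bestkeeper)
  # ranks come straight from the member fits
  expect_equal(setNames(fit$ranking$genorm, fit$ranking$gene)[fit$genorm$ranks$gene],
               setNames(fit$genorm$ranks$rank, fit$genorm$ranks$gene))
  expect_equal(glance(fit)$group, "blackberry_tissues")

  # 3-gene group: all outputs have k = 3 rows
  small <- ct_matrix(unclass(sim$ct)[c("RuEEF1A", "Ru18S", "RuPGK"), ])
  fit3 <- analyze_group(small, sim$annotation)
  expect_equal(nrow(fit3$ranking), 3)
  expect_equal(nrow(fit3$genorm$initial_m), 3)
  expect_equal(nrow(fit3$normfinder$stability), 3)
  expect_equal(nrow(fit3$bestkeeper$stats), 3)
})

test_that("the twelve standard study groups are produced and analyzable", {
  sim <- simulate_ct(default_ct_spec(seed = 2))
  groups <- standard_groups(sim$annotation)
  expect_length(groups, 12)
  expect_equal(lengths(groups)[["all_samples"]], 72L)
  expect_equal(lengths(groups)[["three_raspberries"]], 54L)
  expect_equal(lengths(groups)[["raspberry_fruit_stages"]], 27L)
  expect_equal(lengths(groups)[["blackberry_fruit_stages"]], 9L)

  res <- analyze_groups(sim$ct, sim$annotation, groups = groups)
  expect_length(res$errors, 0)
  expect_equal(nrow(res$summary), 12)
  # schema-identical ranking tables across groups
  cols <- lapply(res$fits, function(f) names(f$ranking))
  expect_true(all(vapply(cols, identical, logical(1), cols[[1]])))

  # a failing group does not abort the others
  groups$bad <- c(groups$all_samples[1], "not_a_sample")
  res2 <- analyze_groups(sim$ct, sim$annotation, groups = groups)
  expect_named(res2$errors, "bad")
  expect_equal(nrow(res2$summary), 12)
})

test_that("the designed-stable gene wins the comprehensive ranking across seeds", {
  hits <- 0L
  for (seed in 1:40) {
    sim <- simulate_ct(default_ct_spec(seed = 400 + seed))
    fit <- analyze_group(sim$ct, sim$annotation)
    top <- fit$ranking$gene[fit$ranking$final_rank == 1L]
    hits <- hits + (fit$ranking$gene[1] %in% c("RuEEF1A", "Ru18S"))
  }
  expect_gte(hits, 38L)
})
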