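test_that("ct_matrix enforces its invariants", {
  m <- matrix(c(24, 25, 26, 23, 23.5, 24), nrow = 2, byrow = TRUE)
  expect_s3_class(make_ct(m), "ct_matrix")
  expect_error(make_ct(matrix(c(24, NA, 25, 26), 2)), "out-of-range|non-finite")
  expect_error(make_ct(matrix(c(24, 46, 25, 26), 2)), "0, 45")
  expect_error(make_ct(matrix(c(24, -1, 25, 26), 2)), "0, 45")
  expect_error(make_ct(m, genes = c("a", "a")), "duplicate gene")
  expect_error(make_ct(m[, 1:2], samples = c("s", "s")), "duplicate sample")
  expect_error(ct_matrix(matrix(25, 1, 3, dimnames = list("g", c("a", "b", "c")))),
               "at least 2 genes")
})

test_that("read/write round-trips a Ct table and rejects bad cells", {
  ct <- random_ct(3, 4, sigma = rep(1, 3), seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ct, path)
  back <- read_ct_table(path, orientation = "genes-as-rows")
  expect_identical(unclass(back), unclass(ct))

  # samples-as-rows orientation is honoured, never guessed
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::as_tibble(t(unclass(ct)), rownames = "sample")
  readr::write_tsv(df, path2)
  back2 <- read_ct_table(path2, orientation = "samples-as-rows")
  expect_equal(unclass(back2), unclass(ct))

  # missing cells are a hard error naming the offending cell by default
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2,s3", "g1,24,NA,26", "g2,23,23,23"), path3)
  expect_error(read_ct_table(path3), "g1.*s2|\\(g1, s2\\)")

  # non-numeric cells name the column
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,24,oops", "g2,23,23"), path4)
  expect_error(read_ct_table(path4), "non-numeric")
})

test_that("missing-Ct imputation fills from replicates of the same cell", {
  ann <- tiny_annotation(r = 3)  # 12 samples
  path <- withr::local_tempfile(fileext = ".csv")
  vals <- rbind(g1 = c(24, 25, NA, rep(24, 9)), g2 = rep(23, 12))
  df <- data.frame(gene = rownames(vals), vals)
  colnames(df) <- c("gene", ann$sample_id)
  readr::write_csv(df, path, na = "NA")
  ct <- read_ct_table(path, missing = "impute", annotation = ann)
  # s3 shares (blackberry, green_fruit) with s1 and s2 -> mean(24, 25)
  expect_equal(unclass(ct)["g1", "s3"], 24.5)
})

test_that("subsetting respects predicates, order and composition", {
  sim <- simulate_ct(default_ct_spec(seed = 3))
  sub <- subset_ct(sim$ct, sim$annotation, cultivar != "blackberry")
  expect_equal(ncol(sub), 54)  # 3 cultivars x 6 classes x 3 reps
  expect_equal(colnames(sub),
               intersect(colnames(sim$ct), colnames(sub)))  # input order

  frt <- subset_ct(sim$ct, sim$annotation, cultivar == "blackberry",
                   sample_class %in% c("green_fruit", "immature_fruit", "mature_fruit"))
  expect_equal(ncol(frt), 9)   # 3 stages x 3 reps

  # identity subset
  all_s <- subset_ct(sim$ct, sim$annotation)
  expect_identical(unclass(all_s)[, ], unclass(sim$ct)[, ])

  # nested subsets equal the conjunction
  a <- subset_ct(sim$ct, sim$annotation, cultivar == "blackberry")
  ab <- subset_ct(a, attr(a, "annotation"), sample_class == "leaf")
  both <- subset_ct(sim$ct, sim$annotation,
                    cultivar == "blackberry", sample_class == "leaf")
  expect_identical(unclass(ab)[, ], unclass(both)[, ])

  expect_error(subset_ct(sim$ct, sim$annotation, cultivar == "nope"),
               "matched no samples")
})

test_that("relative quantities follow Q = E^(minCt - Ct) with per-gene max 1", {
  ct <- make_ct(rbind(c(24, 25, 26), c(25, 25, 25)))
  q <- relative_quantities(ct)
  expect_equal(unname(q["g1", ]), c(1, 0.5, 0.25))
  expect_equal(unname(q["g2", ]), c(1, 1, 1))

  # non-default efficiency, direct evaluation
  ct2 <- make_ct(rbind(c(24, 25), c(20, 21)))
  q2 <- relative_quantities(ct2, efficiency = 1.9)
  expect_equal(unname(q2["g1", ]), c(1, 1 / 1.9))

  expect_error(relative_quantities(ct, efficiency = 1.2), "1.5, 2.2")

  # log2(Q) recovers Ct differences exactly for E = 2
  sim <- simulate_ct(default_ct_spec(seed = 5))
  q3 <- relative_quantities(sim$ct)
  m <- unclass(sim$ct)
  expect_equal(log2(unclass(q3)), apply(m, 1, min)[row(m)] - m,
               ignore_attr = TRUE)
  expect_true(all(apply(unclass(q3), 1, max) == 1))
})

test_that("describe_ct summarises per gene and globally", {
  ct <- make_ct(rbind(c(22, 24), c(26, 28)))
  g <- describe_ct(ct, scope = "global")
  expect_equal(c(g$min, g$max, g$mean), c(22, 28, 25))
  pg <- describe_ct(ct)
  expect_equal(pg$sd[pg$gene == "g1"], sd(c(22, 24)))
  expect_equal(pg$range_width, c(2, 2))

  # seeded 12x72 fixture: global mean near the generator's mean baseline
  spec <- default_ct_spec(seed = 2)
  sim <- simulate_ct(spec)
  expect_lt(abs(describe_ct(sim$ct, "global")$mean -
                  mean(spec$genes$baseline)), 0.2)
  # per-gene means match baselines within 3 sigma / sqrt(72)
  pg2 <- describe_ct(sim$ct)
  tr <- sim$truth[match(pg2$gene, sim$truth$gene), ]
  tol <- 3 * sqrt(tr$sigma^2 + 0.3^2) / sqrt(72) + abs(tr$max_abs_delta) / 6 + 1e-9
  expect_true(all(abs(pg2$mean - tr$baseline) <= tol + 0.3))
})
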