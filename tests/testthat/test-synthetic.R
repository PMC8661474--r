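test_that("an empty edge request yields the identity precision", {
  truth <- make_ground_truth(n_lipids = 6, n_mediators = 3, core_size = 0,
                             n_planted_cross_edges = 0, seed = 1)
  expect_equal(unname(truth$precision), diag(9), tolerance = 1e-10)
  expect_equal(nrow(truth$planted_edges), 0L)
})

test_that("planted precision matrices are positive-definite with the stated pattern", {
  for (s in 1:5) {
    truth <- make_ground_truth(n_lipids = 30, n_mediators = 10, core_size = 5,
                               n_planted_cross_edges = 6, seed = s)
    ev <- eigen(truth$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # planted edges are exactly the off-diagonal nonzero pattern
    om <- truth$precision
    ids <- truth$catalog$feature_id
    planted <- paste(pmin(truth$planted_edges$feature_a, truth$planted_edges$feature_b),
                     pmax(truth$planted_edges$feature_a, truth$planted_edges$feature_b))
    idx <- which(upper.tri(om) & abs(om) > 1e-8, arr.ind = TRUE)
    found <- paste(pmin(ids[idx[, 1]], ids[idx[, 2]]),
                   pmax(ids[idx[, 1]], ids[idx[, 2]]))
    expect_setequal(found, planted)
    # core is positively intercorrelated, cross signs as drawn
    core <- truth$planted_edges[truth$planted_edges$kind == "mediator-mediator", ]
    expect_true(all(core$partial_correlation > 0))
  }
})

test_that("the default emulation has the study's structure", {
  truth <- make_ground_truth(seed = 4)
  expect_equal(sum(truth$catalog$role == "lipid"), 185L)
  expect_equal(sum(truth$catalog$role != "lipid"), 20L)
  expect_equal(sum(truth$catalog$role == "mediator_plasma"), 11L)
  expect_equal(sum(truth$catalog$role == "mediator_gene"), 9L)
  core <- truth$planted_edges[truth$planted_edges$kind == "mediator-mediator", ]
  expect_equal(nrow(core), choose(6, 2))
  cross <- truth$planted_edges[truth$planted_edges$kind == "mediator-lipid", ]
  expect_equal(nrow(cross), 7L)
})

test_that("cohorts regenerate bit-for-bit under the same seed", {
  truth <- make_ground_truth(n_lipids = 12, n_mediators = 4, core_size = 2,
                             n_planted_cross_edges = 2, seed = 3)
  a <- simulate_cohort(truth, n_pairs = 8, seed = 10)
  b <- simulate_cohort(truth, n_pairs = 8, seed = 10)
  expect_identical(a$table, b$table)
  expect_identical(a$metadata, b$metadata)
  d <- simulate_cohort(truth, n_pairs = 8, seed = 11)
  expect_false(identical(a$table, d$table))
})

test_that("censoring controls the missingness pattern", {
  truth0 <- make_ground_truth(n_lipids = 10, n_mediators = 4, core_size = 0,
                              n_planted_cross_edges = 0,
                              censoring_quantile = 0, seed = 6)
  co0 <- simulate_cohort(truth0, n_pairs = 15, seed = 6)
  expect_false(anyNA(co0$table))
  truth1 <- make_ground_truth(n_lipids = 10, n_mediators = 4, core_size = 0,
                              n_planted_cross_edges = 0,
                              censoring_quantile = 0.1, seed = 6)
  co1 <- simulate_cohort(truth1, n_pairs = 50, seed = 6)
  expect_gt(mean(is.na(co1$table)), 0.05)
  expect_lt(mean(is.na(co1$table)), 0.15)
  expect_error(simulate_cohort(truth1, n_pairs = 1), "n_pairs")
})

test_that("a planted partial correlation is recovered from the fold-change matrix", {
  truth <- make_ground_truth(n_lipids = 10, n_mediators = 4, core_size = 0,
                             n_planted_cross_edges = 1,
                             negative_fraction = 0,
                             cross_partial_range = c(0.6, 0.6),
                             censoring_quantile = 0,
                             effect_features = numeric(0), seed = 8)
  edge <- truth$planted_edges
  expect_equal(abs(edge$partial_correlation), 0.6, tolerance = 1e-6)
  co <- simulate_cohort(truth, n_pairs = 200, seed = 8)
  fc <- preprocess_cohort(co$table, co$metadata)$fold_change
  i <- match(edge$feature_a, colnames(fc))
  j <- match(edge$feature_b, colnames(fc))
  Q <- setdiff(seq_len(ncol(fc)), c(i, j))[1:4]
  expect_lt(abs(partial_correlation(fc, i, j, Q) - edge$partial_correlation),
            0.1)
})

test_that("pairing removes shared variance from fold changes", {
  truth <- make_ground_truth(n_lipids = 8, n_mediators = 4, core_size = 0,
                             n_planted_cross_edges = 0,
                             censoring_quantile = 0,
                             effect_features = numeric(0), seed = 9)
  set.seed(123)
  wins <- replicate(8, {
    co <- simulate_cohort(truth, n_pairs = 40, pair_effect_sd = 1,
                          seed = sample.int(1e6, 1))
    sc <- preprocess_cohort(co$table, co$metadata)$scaled
    pat <- sc[grep("^PAT", rownames(sc)), ]
    ctl <- sc[grep("^CTL", rownames(sc)), ]
    paired_var <- mean(apply(pat - ctl, 2, var))
    shuffled_var <- mean(apply(pat - ctl[sample(nrow(ctl)), ], 2, var))
    paired_var < shuffled_var
  })
  expect_gt(mean(wins), 0.8)
})

test_that("null cohorts stay null: group tests reject at the nominal rate", {
  truth <- make_ground_truth(n_lipids = 12, n_mediators = 4, core_size = 0,
                             n_planted_cross_edges = 0,
                             censoring_quantile = 0,
                             effect_features = numeric(0), seed = 13)
  set.seed(321)
  rates <- replicate(50, {
    co <- simulate_cohort(truth, n_pairs = 20, seed = sample.int(1e6, 1))
    lg <- log2(co$table)
    pat <- lg[grep("^PAT", rownames(lg)), ]
    ctl <- lg[grep("^CTL", rownames(lg)), ]
    mean(vapply(seq_len(ncol(lg)), function(j)
      t.test(pat[, j], ctl[, j])$p.value < 0.01, logical(1)))
  })
  expect_lt(abs(mean(rates) - 0.01), 0.012)
})

test_that("written cohorts read back into the same analysis inputs", {
  truth <- make_ground_truth(n_lipids = 6, n_mediators = 3, core_size = 2,
                             n_planted_cross_edges = 1, seed = 14)
  co <- simulate_cohort(truth, n_pairs = 5, seed = 14)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_feature_table(paths[["features"]])
  expect_identical(unname(back), unname(co$table))
  md <- read_metadata(paths[["metadata"]])
  expect_equal(md$pair_id, co$metadata$pair_id)
  truth_json <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth_json$planted_edges), nrow(truth$planted_edges))
})
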