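make_toy_matrices <- function() {
  ids <- c("LPC(18:1)", "TG(50:1)", "P-OPN", "CASP1")
  rho <- matrix(0, 4, 4, dimnames = list(ids, ids))
  rho[upper.tri(rho)] <- c(0.6, -0.52, 0.3, 0.55, -0.45, 0.7)
  rho <- rho + t(rho); diag(rho) <- 1
  nrr <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  nrr[upper.tri(nrr)] <- c(0.05, 0.2, 0.09, 0.5, 0.11, 0.01)
  nrr[lower.tri(nrr)] <- t(nrr)[lower.tri(nrr)]
  cat_df <- toy_catalog(lipids = ids[1:2], plasma = "P-OPN", genes = "CASP1")
  list(rho = rho, nrr = nrr, catalog = cat_df)
}

test_that("NRR filtering is inclusive and counts edges exactly", {
  tm <- make_toy_matrices()
  edges <- filter_nonspurious(tm$rho, tm$nrr, tm$catalog, 0.1)
  # nrr values {0.05, 0.2, 0.09, 0.5, 0.11, 0.01}: exactly 3 pass <= 0.1
  expect_equal(nrow(edges), 3L)
  expect_true(all(edges$nrr <= 0.1))
  # boundary: nrr exactly at the threshold is retained
  nrr2 <- tm$nrr
  nrr2["LPC(18:1)", "TG(50:1)"] <- nrr2["TG(50:1)", "LPC(18:1)"] <- 0.1
  edges2 <- filter_nonspurious(tm$rho, nrr2, tm$catalog, 0.1)
  expect_true(any(edges2$feature_a == "LPC(18:1)" &
                  edges2$feature_b == "TG(50:1)"))
  # threshold 0 with all positive NRRs -> empty
  expect_equal(nrow(filter_nonspurious(tm$rho, tm$nrr, tm$catalog, 0)), 0L)
  # mismatched feature lists -> validation error
  rho_bad <- tm$rho[c(2, 1, 3, 4), c(2, 1, 3, 4)]
  expect_error(filter_nonspurious(rho_bad, tm$nrr, tm$catalog, 0.1),
               "same feature order")
})

test_that("lipid-lipid pruning leaves a mediator-centric edge set", {
  tm <- make_toy_matrices()
  edges <- filter_nonspurious(tm$rho, tm$nrr, tm$catalog, 0.5)
  pruned <- prune_lipid_lipid(edges, tm$catalog)
  expect_false(any(pruned$kind == "lipid-lipid"))
  expect_true(all(pruned$kind %in% c("mediator-lipid", "mediator-mediator")))
  # every retained edge has a mediator endpoint
  roles_a <- tm$catalog$role[match(pruned$feature_a, tm$catalog$feature_id)]
  roles_b <- tm$catalog$role[match(pruned$feature_b, tm$catalog$feature_id)]
  expect_true(all(roles_a != "lipid" | roles_b != "lipid"))
  # only lipid-lipid edges -> empty result
  ll <- edges[edges$kind == "lipid-lipid", ]
  expect_equal(nrow(prune_lipid_lipid(ll, tm$catalog)), 0L)
  # mixed synthetic list: counts are conserved
  mixed <- edges[rep(seq_len(nrow(edges)), 2), ]
  expect_equal(nrow(prune_lipid_lipid(mixed, tm$catalog)),
               sum(mixed$kind != "lipid-lipid"))
})

test_that("the network carries roles, signs and magnitudes", {
  tm <- make_toy_matrices()
  edges <- prune_lipid_lipid(
    filter_nonspurious(tm$rho, tm$nrr, tm$catalog, 0.2), tm$catalog)
  net <- build_network(edges, tm$catalog)
  expect_equal(igraph::vcount(net),
               length(unique(c(edges$feature_a, edges$feature_b))))
  expect_equal(igraph::ecount(net), nrow(edges))
  expect_equal(sort(abs(igraph::E(net)$rho)), sort(igraph::E(net)$weight))
  expect_true(all(igraph::E(net)$sign %in% c(-1, 1)))
  # empty edge list -> empty network
  empty <- build_network(edges[0L, ], tm$catalog)
  expect_equal(igraph::vcount(empty), 0L)
  # a fully connected positive mediator core renders complete
  core_ids <- c("NLRP3", "PYCARD", "CASP1", "IL1RN")
  core_cat <- toy_catalog(genes = core_ids)
  pairs <- t(combn(core_ids, 2))
  core_edges <- data.frame(feature_a = pmin(pairs[, 1], pairs[, 2]),
                           feature_b = pmax(pairs[, 1], pairs[, 2]),
                           rho = 0.6, nrr = 0, kind = "mediator-mediator",
                           stringsAsFactors = FALSE)
  core_net <- build_network(core_edges, core_cat)
  expect_equal(igraph::ecount(core_net), choose(4, 2))
  expect_equal(igraph::vcount(core_net), 4L)
})

test_that("strong candidates honour the inclusive rho threshold", {
  cat_df <- toy_catalog(lipids = c("PC(O-34:3)", "TG(56:4)", "LPC(22:5)"),
                        plasma = c("P-IL1Ra", "P-CXCL8", "P-IL6"))
  edges <- data.frame(
    feature_a = c("P-IL1Ra", "P-CXCL8", "LPC(22:5)", "P-CXCL8"),
    feature_b = c("PC(O-34:3)", "TG(56:4)", "P-IL6", "P-IL6"),
    rho = c(-0.512, 0.523, -0.499, 0.8),
    nrr = c(0, 0.02, 0.05, 0.01),
    kind = c("mediator-lipid", "mediator-lipid", "mediator-lipid",
             "mediator-mediator"),
    stringsAsFactors = FALSE)
  cands <- strong_candidates(edges, cat_df, 0.5)
  # -0.512 and 0.523 retained; 0.499 magnitude excluded; mediator-mediator
  # excluded from the default report
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$lipid, c("PC(O-34:3)", "TG(56:4)"))
  expect_true(all(abs(cands$rho) >= 0.5))
  # flag brings mediator-mediator pairs in
  both <- strong_candidates(edges, cat_df, 0.5, include_mediator_mediator = TRUE)
  expect_equal(nrow(both), 3L)
  expect_true(any(both$kind == "mediator-mediator" & is.na(both$lipid)))
  # candidate list is a subset of the edge list
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cand_lipids <- cands$lipid
  expect_true(all(key(cands$mediator, cand_lipids) %in%
                  key(edges$feature_a, edges$feature_b)))
})

test_that("filter -> prune -> candidates is monotone in both thresholds", {
  set.seed(21)
  truth <- make_ground_truth(n_lipids = 20, n_mediators = 8, core_size = 3,
                             n_planted_cross_edges = 4, seed = 21)
  co <- simulate_cohort(truth, n_pairs = 25, seed = 21)
  fc <- preprocess_cohort(co$table, co$metadata)$fold_change
  rho <- spearman_matrix(fc)
  nrr <- nrr_matrix(fc, nrr_config(n_tests = 40, seed = 21))
  key <- function(df) paste(df$feature_a, df$feature_b)
  ckey <- function(df) paste(df$mediator, df$lipid)
  prev_edges <- character(0)
  for (thr in c(0.05, 0.1, 0.3)) {
    ed <- prune_lipid_lipid(filter_nonspurious(rho, nrr, co$catalog, thr),
                            co$catalog)
    expect_true(all(prev_edges %in% key(ed)))
    prev_edges <- key(ed)
  }
  ed <- prune_lipid_lipid(filter_nonspurious(rho, nrr, co$catalog, 0.1),
                          co$catalog)
  prev_cands <- character(0)
  for (rthr in c(0.6, 0.5, 0.3)) {
    ca <- strong_candidates(ed, co$catalog, rthr)
    expect_true(all(prev_cands %in% ckey(ca)))
    prev_cands <- ckey(ca)
  }
})
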