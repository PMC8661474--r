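# name pools for synthetic mediators; extended generically when more are
# requested than the pools hold
gene_name_pool <- function(n) {
  base <- c("NLRP3", "PYCARD", "CASP1", "IL1RN", "IL18", "IL1B",
            "AIM2", "NLRC4", "TLR4")
  c(base, sprintf("GENE%02d", seq_len(max(0, n - length(base)))))[seq_len(n)]
}

plasma_name_pool <- function(n) {
  base <- c("P-OPN", "P-IL6", "P-CXCL8", "P-CXCL10", "P-IL1Ra", "P-TNF",
            "P-IL10", "P-IFNG", "P-CCL2", "P-IL17A", "P-VEGFA")
  c(base, sprintf("P-MED%02d", seq_len(max(0, n - length(base)))))[seq_len(n)]
}

# deterministic pool of plausible lipid shorthand names per class, shuffled
# under the active RNG; always contains the three showcase lipids
synthetic_lipid_names <- function(n_lipids) {
  pool <- c("TG(50:1)", "TG(16:0/18:0/18:1)", "PC(O-34:3)")
  classes <- list(
    TG  = as.vector(outer(seq(42, 60, 2), 0:8,
                          function(c, d) sprintf("TG(%d:%d)", c, d))),
    PC  = c(as.vector(outer(30:40, 0:6,
                            function(c, d) sprintf("PC(%d:%d)", c, d))),
            as.vector(outer(seq(32, 40, 2), 0:5,
                            function(c, d) sprintf("PC(O-%d:%d)", c, d)))),
    LPC = as.vector(outer(14:22, 0:5,
                          function(c, d) sprintf("LPC(%d:%d)", c, d))),
    PE  = c(as.vector(outer(32:42, 0:7,
                            function(c, d) sprintf("PE(%d:%d)", c, d))),
            as.vector(outer(seq(34, 40, 2), 0:5,
                            function(c, d) sprintf("PE(O-%d:%d)", c, d)))),
    PI  = as.vector(outer(32:40, 0:6,
                          function(c, d) sprintf("PI(%d:%d)", c, d))),
    Cer = sprintf("Cer(d18:1/%d:0)", 16:26),
    SM  = as.vector(outer(14:24, 0:2,
                          function(c, d) sprintf("SM(d18:1/%d:%d)", c, d))),
    ChoE = as.vector(outer(14:22, 0:6,
                           function(c, d) sprintf("ChoE(%d:%d)", c, d))))
  weights <- c(TG = 0.33, PC = 0.18, LPC = 0.08, PE = 0.12, PI = 0.06,
               Cer = 0.08, SM = 0.08, ChoE = 0.07)
  remaining <- n_lipids - length(pool)
  counts <- round(weights * remaining)
  counts[counts < 0] <- 0
  for (cls in names(classes)) {
    avail <- setdiff(classes[[cls]], pool)
    take <- min(counts[[cls]], length(avail))
    if (take > 0) pool <- c(pool, sample(avail, take))
  }
  # top up (or trim) to the requested count from whatever is left
  leftover <- setdiff(unlist(classes), pool)
  if (length(pool) < n_lipids)
    pool <- c(pool, sample(leftover, n_lipids - length(pool)))
  if (length(pool) < n_lipids)
    pool <- c(pool, sprintf("TG(%d:9)", seq_len(n_lipids - length(pool)) + 40))
  pool[seq_len(n_lipids)]
}

#' Plant a sparse conditional-dependence structure
#'
#' Builds the ground truth for a synthetic cohort: a feature catalog
#' (lipids across classes plus plasma and gene-expression inflammatory
#' mediators), a sparse positive-definite precision matrix whose off-diagonal
#' pattern is exactly the planted edge list, per-feature group effects and a
#' detection-limit censoring level.
#'
#' Two kinds of edges are planted.  A tightly, positively intercorrelated
#' "inflammasome core" of `core_size` gene mediators receives all pairwise
#' edges with partial correlation `core_partial` (default `0.9 / (core_size
#' - 1)`, just inside the positive-definiteness bound so the implied marginal
#' correlations are strong).  `n_planted_cross_edges` mediator-lipid edges
#' are assigned round-robin over the non-core mediators to distinct lipids,
#' with target partial-correlation magnitudes drawn from
#' `cross_partial_range` and negative sign with probability
#' `negative_fraction`.  Keeping each cross pair near-isolated makes its
#' marginal correlation essentially equal to the planted partial correlation.
#'
#' Positive-definiteness is enforced by shrinking all off-diagonals by 5%
#' per round (at most 60 rounds); an infeasible request errors out.  The
#' final precision matrix is rescaled so the implied covariance has unit
#' diagonal, and the achieved partial correlations are recorded per edge.
#'
#' @param n_lipids,n_mediators feature counts (defaults mirror a cohort of
#'   185 lipids and 20 mediators).
#' @param core_size number of gene mediators in the inflammasome-like core.
#' @param n_planted_cross_edges number of mediator-lipid edges.
#' @param negative_fraction probability a cross edge is negative.
#' @param effect_features named numeric vector of per-feature patient shifts
#'   (log scale, units of feature SD); `NULL` uses the default showcase:
#'   +1 on TG(50:1) and TG(16:0/18:0/18:1), -1 on PC(O-34:3).
#' @param censoring_quantile per-feature fraction of values pushed below the
#'   detection limit, in \[0, 1).
#' @param seed integer seed.
#' @param n_plasma number of plasma mediators (rest are gene-expression);
#'   default keeps the 11:9 plasma:gene ratio.
#' @param cross_partial_range magnitude range for cross-edge partial
#'   correlations.
#' @param core_partial partial correlation of each core edge.
#' @return object of class `ground_truth`: `catalog`, `precision`, `sigma`,
#'   `planted_edges`, `group_effects`, `censoring_quantile`, `seed`.
#' @export
make_ground_truth <- function(n_lipids = 185L, n_mediators = 20L,
                              core_size = 6L, n_planted_cross_edges = 7L,
                              negative_fraction = 0.73,
                              effect_features = NULL,
                              censoring_quantile = 0.05, seed = 1L,
                              n_plasma = NULL,
                              cross_partial_range = c(0.6, 0.75),
                              core_partial = NULL) {
  stopifnot(n_lipids >= 1L, n_mediators >= 0L, core_size >= 0L,
            core_size <= n_mediators, n_planted_cross_edges >= 0L,
            negative_fraction >= 0, negative_fraction <= 1,
            censoring_quantile >= 0, censoring_quantile < 1)
  set.seed(seed)
  n_gene <- if (is.null(n_plasma)) round(n_mediators * 9 / 20)
            else n_mediators - n_plasma
  n_gene <- max(n_gene, core_size)
  n_plasma <- n_mediators - n_gene
  lipid_ids <- synthetic_lipid_names(n_lipids)
  gene_ids <- gene_name_pool(n_gene)
  plasma_ids <- plasma_name_pool(n_plasma)
  ids <- c(lipid_ids, gene_ids, plasma_ids)
  catalog <- validate_catalog(data.frame(
    feature_id = ids,
    role = c(rep("lipid", n_lipids), rep("mediator_gene", n_gene),
             rep("mediator_plasma", n_plasma)),
    display_name = ids, stringsAsFactors = FALSE))

  p <- length(ids)
  omega <- diag(p)
  edge_a <- integer(0); edge_b <- integer(0); edge_sign <- numeric(0)
  # inflammasome-like core: all pairs among the first core_size gene
  # mediators, positive partial correlations
  core_idx <- n_lipids + seq_len(core_size)
  if (is.null(core_partial))
    core_partial <- if (core_size > 1L) 0.9 / (core_size - 1L) else 0
  if (core_size >= 2L) {
    for (a in core_idx) for (b in core_idx) if (a < b) {
      omega[a, b] <- omega[b, a] <- -core_partial
      edge_a <- c(edge_a, a); edge_b <- c(edge_b, b)
    }
  }
  # mediator-lipid cross edges, round-robin over non-core mediators
  if (n_planted_cross_edges > 0L) {
    non_core <- setdiff(n_lipids + seq_len(n_mediators), core_idx)
    if (!length(non_core)) non_core <- core_idx
    meds <- rep(non_core, length.out = n_planted_cross_edges)
    lips <- sample(n_lipids, min(n_planted_cross_edges, n_lipids))
    lips <- rep(lips, length.out = n_planted_cross_edges)
    mags <- stats::runif(n_planted_cross_edges,
                         cross_partial_range[1L], cross_partial_range[2L])
    signs <- ifelse(stats::runif(n_planted_cross_edges) < negative_fraction,
                    -1, 1)
    for (k in seq_len(n_planted_cross_edges)) {
      a <- min(meds[k], lips[k]); b <- max(meds[k], lips[k])
      omega[a, b] <- omega[b, a] <- -mags[k] * signs[k]
      edge_a <- c(edge_a, a); edge_b <- c(edge_b, b)
    }
  }
  # enforce positive-definiteness by shrinking off-diagonals
  rounds <- 0L
  while (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) < 1e-4) {
    rounds <- rounds + 1L
    if (rounds > 60L)
      stop("generation error: requested edge signs/magnitudes cannot be made positive-definite")
    off <- omega; diag(off) <- 0
    omega <- diag(diag(omega)) + off * 0.95
  }
  sigma <- solve(omega)
  d <- 1 / sqrt(diag(sigma))
  sigma <- diag(d) %*% sigma %*% diag(d)
  dimnames(sigma) <- list(ids, ids)
  omega <- solve(sigma)
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- list(ids, ids)

  planted <- data.frame(
    feature_a = ids[edge_a], feature_b = ids[edge_b],
    partial_correlation = -omega[cbind(edge_a, edge_b)] /
      sqrt(diag(omega)[edge_a] * diag(omega)[edge_b]),
    kind = mapply(edge_kind, catalog$role[edge_a], catalog$role[edge_b]),
    stringsAsFactors = FALSE)

  effects <- stats::setNames(numeric(p), ids)
  if (is.null(effect_features)) {
    showcase <- c("TG(50:1)" = 1, "TG(16:0/18:0/18:1)" = 1, "PC(O-34:3)" = -1)
    effect_features <- showcase[names(showcase) %in% ids]
  }
  if (length(effect_features)) {
    unknown <- setdiff(names(effect_features), ids)
    if (length(unknown))
      stop("effect feature(s) not in catalog: ", paste(unknown, collapse = ", "))
    effects[names(effect_features)] <- effect_features
  }
  structure(list(catalog = catalog, precision = omega, sigma = sigma,
                 planted_edges = planted, group_effects = effects,
                 censoring_quantile = censoring_quantile, seed = seed),
            class = "ground_truth")
}

#' Simulate a matched patient-control cohort
#'
#' Draws, per pair, a shared pair-level latent shift (modelling age/sex
#' matching) plus individual multivariate-normal draws with covariance equal
#' to the inverse of the planted precision matrix; patients additionally
#' receive the per-feature group effects.  Latent log2 abundances (baseline
#' `baseline_log2`) are exponentiated base 2 to a lognormal concentration
#' scale.  Per feature, values below the censoring quantile of that
#' feature's marginal are replaced by missing, emulating a detection limit.
#'
#' @param truth a [make_ground_truth()] object.
#' @param n_pairs number of patient-control pairs, >= 2.
#' @param pair_effect_sd SD of the shared pair-level shift (feature-SD
#'   units).
#' @param seed integer seed.
#' @param antipsychotic_fraction fraction of patients flagged as medicated.
#' @param baseline_log2 baseline log2 abundance added to every latent value.
#' @return object of class `synthetic_cohort`: `table` (concentration-scale
#'   feature table with `NA` for censored cells), `metadata`, `catalog`,
#'   `truth`.
#' @export
simulate_cohort <- function(truth, n_pairs = 39L, pair_effect_sd = 0.5,
                            seed = 1L, antipsychotic_fraction = 18 / 39,
                            baseline_log2 = 10) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_pairs < 2L) stop("n_pairs must be >= 2 (no variance estimable otherwise)")
  set.seed(seed)
  ids <- truth$catalog$feature_id
  p <- length(ids)
  ch <- chol(truth$sigma)
  pad <- function(k) formatC(k, width = max(2L, nchar(n_pairs)), flag = "0")
  sample_ids <- c(sprintf("PAT%s", pad(seq_len(n_pairs))),
                  sprintf("CTL%s", pad(seq_len(n_pairs))))
  pair_ids <- sprintf("pair%s", pad(seq_len(n_pairs)))

  pair_shift <- matrix(rnorm(n_pairs * p, sd = pair_effect_sd), n_pairs, p)
  z_pat <- matrix(rnorm(n_pairs * p), n_pairs, p) %*% ch
  z_ctl <- matrix(rnorm(n_pairs * p), n_pairs, p) %*% ch
  lat_pat <- baseline_log2 + pair_shift + z_pat +
    matrix(truth$group_effects, n_pairs, p, byrow = TRUE)
  lat_ctl <- baseline_log2 + pair_shift + z_ctl
  conc <- 2^rbind(lat_pat, lat_ctl)
  dimnames(conc) <- list(sample_ids, ids)

  cq <- truth$censoring_quantile
  if (cq > 0) {
    for (j in seq_len(p)) {
      thr <- quantile(conc[, j], cq, names = FALSE)
      conc[conc[, j] < thr, j] <- NA_real_
    }
  }
  n_flag <- round(antipsychotic_fraction * n_pairs)
  flagged <- sample(n_pairs, n_flag)
  metadata <- data.frame(
    sample_id = sample_ids,
    group = rep(c("patient", "control"), each = n_pairs),
    pair_id = rep(pair_ids, 2L),
    antipsychotic_flag = c(seq_len(n_pairs) %in% flagged,
                           rep(FALSE, n_pairs)),
    stringsAsFactors = FALSE)
  structure(list(table = conc, metadata = metadata,
                 catalog = truth$catalog, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the same TSV formats the readers accept (`features.tsv`,
#' `metadata.tsv`, `catalog.tsv`) plus `ground_truth.json` with the planted
#' edge list, group effects, censoring level and seed.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(features = file.path(dir, "features.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             catalog = file.path(dir, "catalog.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_feature_table(cohort$table, paths[["features"]])
  write_metadata(cohort$metadata, paths[["metadata"]])
  write_catalog(cohort$catalog, paths[["catalog"]])
  tr <- cohort$truth
  jsonlite::write_json(
    list(planted_edges = tr$planted_edges,
         group_effects = as.list(tr$group_effects[tr$group_effects != 0]),
         censoring_quantile = tr$censoring_quantile, seed = tr$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
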