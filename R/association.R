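#' Pairwise Spearman correlation matrix
#'
#' Spearman rho for every pair of features of the fold-change matrix, i.e.
#' the Pearson correlation of average-ranked columns (ties get average
#' ranks).  Constant columns have no rank variation; their correlations are
#' set to 0 with a warning.
#'
#' @param fc pairs x features numeric matrix, >= 3 rows.
#' @return features x features symmetric matrix, unit diagonal.
#' @export
spearman_matrix <- function(fc) {
  if (nrow(fc) < 3L) stop("need >= 3 rows for a correlation matrix")
  constant <- apply(fc, 2, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(cor(fc, method = "spearman"))
  if (any(constant)) {
    warning("constant column(s), correlations set to 0: ",
            paste(colnames(fc)[constant], collapse = ", "))
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rho
}

#' Sample q-order partial correlation
#'
#' Correlation between columns `i` and `j` after removing the linear effect
#' of the conditioning columns `Q`, computed by inverting the sample
#' covariance of the submatrix on `{i, j} union Q`:
#' `r = -Omega_ij / sqrt(Omega_ii * Omega_jj)`.  With empty `Q` this is the
#' plain Pearson correlation.
#'
#' @param data numeric matrix (observations x variables).
#' @param i,j column indices, distinct and not in `Q`.
#' @param Q integer vector of conditioning column indices (possibly empty).
#' @return the partial correlation coefficient.
#' @export
partial_correlation <- function(data, i, j, Q = integer(0)) {
  if (i == j || i %in% Q || j %in% Q)
    stop("i, j must be distinct and disjoint from Q")
  if (nrow(data) <= length(Q) + 3L)
    stop("need more than |Q| + 3 observations")
  cov_partial_correlation(cov(data[, c(i, j, Q), drop = FALSE]), 1L, 2L,
                          seq_len(length(Q)) + 2L)
}

#' Partial correlation from a covariance (or correlation) matrix
#'
#' Same quantity as [partial_correlation()] but starting from a covariance
#' matrix, so population (closed-form) values can be computed directly.
#'
#' @param S covariance or correlation matrix.
#' @param i,j variable indices.
#' @param Q conditioning indices.
#' @return the partial correlation coefficient.
#' @export
cov_partial_correlation <- function(S, i, j, Q = integer(0)) {
  idx <- c(i, j, Q)
  sub <- S[idx, idx, drop = FALSE]
  om <- tryCatch(solve(sub), error = function(e)
    stop("singular covariance submatrix for conditioning set {",
         paste(idx, collapse = ","), "}"))
  -om[1L, 2L] / sqrt(om[1L, 1L] * om[2L, 2L])
}

#' Non-rejection-rate configuration
#'
#' Bundles the parameters of the NRR estimator: significance level of the
#' Fisher-z partial-correlation test, number of Monte-Carlo tests per feature
#' pair, the conditioning-order policy (a fixed `q` or `q` drawn uniformly
#' from `1..q_max`) and the sampling mode.  `q_max = NULL` resolves at use
#' time to `min(p - 2, n - 4, 20)`, which keeps the Fisher-z degrees of
#' freedom `n - q - 3` positive.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param n_tests Monte-Carlo tests per pair.
#' @param q_policy `"uniform"` (q ~ uniform on 1..q_max) or `"fixed"`.
#' @param q fixed conditioning order (required when `q_policy = "fixed"`).
#' @param q_max largest conditioning order for the uniform policy.
#' @param mode `"monte_carlo"` or `"exhaustive"` (enumerate all conditioning
#'   subsets of every configured order).
#' @param seed master seed; per-pair substreams are derived from it keyed by
#'   the sorted pair indices, so results do not depend on evaluation order.
#' @return object of class `nrr_config`.
#' @export
nrr_config <- function(alpha = 0.05, n_tests = 100L,
                       q_policy = c("uniform", "fixed"), q = NULL,
                       q_max = NULL, mode = c("monte_carlo", "exhaustive"),
                       seed = 1L) {
  q_policy <- match.arg(q_policy)
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  if (q_policy == "fixed" && is.null(q))
    stop("q_policy = 'fixed' requires q")
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 q_policy = q_policy, q = if (!is.null(q)) as.integer(q),
                 q_max = if (!is.null(q_max)) as.integer(q_max),
                 mode = mode, seed = as.integer(seed)),
            class = "nrr_config")
}

# resolve q_max against the data dimensions and check feasibility
resolve_q <- function(config, n, p) {
  q_max <- config$q_max
  if (is.null(q_max)) q_max <- min(p - 2L, n - 4L, 20L)
  if (config$q_policy == "fixed") {
    qs <- config$q
    q_max <- config$q
  } else qs <- seq_len(q_max)
  if (q_max > min(p - 2L, n - 4L) || q_max < 1L)
    stop(sprintf("infeasible conditioning order: q_max = %d with p = %d, n = %d (need q_max <= min(p - 2, n - 4))",
                 q_max, p, n))
  list(qs = qs, q_max = q_max)
}

# Fisher-z non-rejection decision; |r| >= 1 counts as rejection
fisher_z_nonreject <- function(r, n, q, crit) {
  if (!is.finite(r) || abs(r) >= 1) return(FALSE)
  abs(sqrt(n - q - 3) * atanh(r)) <= crit
}

# exhaustive enumeration over all conditioning subsets of the given orders,
# pooled with equal weight per subset
nrr_exhaustive_pair <- function(S, n, i, j, qs, crit) {
  p <- nrow(S)
  others <- setdiff(seq_len(p), c(i, j))
  # a perfectly collinear (i, j) pair makes every submatrix singular; the
  # partial correlation is then +-1 and every test rejects
  pair_r <- S[i, j] / sqrt(S[i, i] * S[j, j])
  decisions <- unlist(lapply(qs, function(q) {
    subs <- combn(others, q)
    apply(subs, 2, function(Q) {
      r <- tryCatch(cov_partial_correlation(S, i, j, Q), error = function(e) {
        if (abs(pair_r) >= 1 - 1e-12) return(1)
        stop(e)
      })
      fisher_z_nonreject(r, n, q, crit)
    })
  }))
  mean(decisions)
}

#' Non-rejection rate of one feature pair
#'
#' Repeats `n_tests` conditional-independence tests: draw a conditioning
#' order `q` per the policy, draw a conditioning set `Q` of that size
#' uniformly without replacement from the remaining features, compute the
#' q-order partial correlation, and test `H0: r = 0` with the Fisher-z
#' statistic `z = sqrt(n - q - 3) * atanh(r)` against the two-sided normal
#' critical value at `alpha`.  The NRR is the fraction of tests that fail to
#' reject; a low NRR means the association persists after conditioning and
#' is unlikely to be spurious.
#'
#' In exhaustive mode — and in Monte-Carlo mode with a fixed `q` whenever
#' `n_tests` covers all `choose(p - 2, q)` subsets — every conditioning set
#' is enumerated exactly once.
#'
#' @param data observations x variables matrix.
#' @param i,j column indices of the pair.
#' @param config an [nrr_config()].
#' @return the non-rejection rate in \[0, 1\].
#' @export
nonrejection_rate <- function(data, i, j, config = nrr_config()) {
  m <- nrr_matrix_impl(data, config, pairs = cbind(min(i, j), max(i, j)))
  m[1L]
}

# shared driver: computes NRRs for the requested (i < j) pairs
nrr_matrix_impl <- function(data, config, pairs) {
  n <- nrow(data)
  p <- ncol(data)
  if (p < 2L) stop("need >= 2 features")
  rq <- resolve_q(config, n, p)
  crit <- qnorm(1 - config$alpha / 2)
  S <- cov(data)
  if (config$mode == "exhaustive") {
    vapply(seq_len(nrow(pairs)), function(k)
      nrr_exhaustive_pair(S, n, pairs[k, 1L], pairs[k, 2L], rq$qs, crit),
      numeric(1))
  } else if (config$q_policy == "fixed" &&
             choose(p - 2L, config$q) <= config$n_tests) {
    # all subsets covered: enumerate instead of sampling with duplicates
    vapply(seq_len(nrow(pairs)), function(k)
      nrr_exhaustive_pair(S, n, pairs[k, 1L], pairs[k, 2L], rq$qs, crit),
      numeric(1))
  } else {
    q_fixed <- if (config$q_policy == "fixed") config$q else 0L
    nrr_pairs_mc(S, n, pairs - 1L, crit, config$n_tests,
                 q_fixed, rq$q_max, config$seed)
  }
}

#' Non-rejection-rate matrix
#'
#' Fills every unordered feature pair via [nonrejection_rate()], with
#' independent seed-derived substreams per pair so the matrix is reproducible
#' and independent of evaluation order.  The diagonal is undefined (`NA`).
#'
#' @param data observations x variables matrix (typically the fold-change
#'   matrix).
#' @param config an [nrr_config()].
#' @return symmetric features x features matrix of NRRs, `NA` diagonal.
#' @export
nrr_matrix <- function(data, config = nrr_config()) {
  p <- ncol(data)
  pairs <- t(combn(p, 2L))
  vals <- nrr_matrix_impl(data, config, pairs)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(data), colnames(data)))
  out[pairs] <- vals
  out[pairs[, 2:1, drop = FALSE]] <- vals
  out
}

#' Histogram of non-rejection rates
#'
#' Bins the off-diagonal upper-triangle NRRs into uniform bins on \[0, 1\];
#' used to judge a conservative retention threshold.  Counts sum to
#' `p * (p - 1) / 2`.
#'
#' @param nrr NRR matrix from [nrr_matrix()].
#' @param n_bins number of bins, >= 1.
#' @return data.frame with `bin_low`, `bin_high`, `count`.
#' @export
nrr_histogram <- function(nrr, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  vals <- nrr[upper.tri(nrr)]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1L],
             count = tabulate(idx, nbins = n_bins))
}
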