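# shared fixture builders; everything is generated in code

# samples x features matrix with names
named_matrix <- function(vals, nrow, ncol,
                         samples = sprintf("S%02d", seq_len(nrow)),
                         features = sprintf("F%02d", seq_len(ncol))) {
  matrix(vals, nrow, ncol, dimnames = list(samples, features))
}

# minimal matched metadata for n pairs
toy_metadata <- function(n_pairs, flagged = integer(0)) {
  data.frame(
    sample_id = c(sprintf("PAT%02d", seq_len(n_pairs)),
                  sprintf("CTL%02d", seq_len(n_pairs))),
    group = rep(c("patient", "control"), each = n_pairs),
    pair_id = rep(sprintf("pair%02d", seq_len(n_pairs)), 2),
    antipsychotic_flag = c(seq_len(n_pairs) %in% flagged, rep(FALSE, n_pairs)),
    stringsAsFactors = FALSE)
}

# catalog for a mixed toy feature set
toy_catalog <- function(lipids = character(0), plasma = character(0),
                        genes = character(0)) {
  validate_catalog(data.frame(
    feature_id = c(lipids, plasma, genes),
    role = c(rep("lipid", length(lipids)),
             rep("mediator_plasma", length(plasma)),
             rep("mediator_gene", length(genes))),
    display_name = c(lipids, plasma, genes),
    stringsAsFactors = FALSE))
}

# independent partial-correlation oracle: correlation of the residuals from
# regressing columns i and j on the conditioning columns
pcor_residual_oracle <- function(data, i, j, Q) {
  if (!length(Q)) return(cor(data[, i], data[, j]))
  ri <- resid(lm(data[, i] ~ data[, Q, drop = FALSE]))
  rj <- resid(lm(data[, j] ~ data[, Q, drop = FALSE]))
  cor(ri, rj)
}

# brute-force NRR oracle: enumerate every conditioning subset of the given
# orders, decide each Fisher-z test, pool all decisions with equal weight
nrr_bruteforce_oracle <- function(data, i, j, qs, alpha) {
  n <- nrow(data)
  crit <- qnorm(1 - alpha / 2)
  others <- setdiff(seq_len(ncol(data)), c(i, j))
  decisions <- logical(0)
  for (q in qs) {
    subs <- combn(others, q)
    for (k in seq_len(ncol(subs))) {
      r <- pcor_residual_oracle(data, i, j, subs[, k])
      z <- sqrt(n - q - 3) * atanh(r)
      decisions <- c(decisions, is.finite(z) && abs(z) <= crit)
    }
  }
  mean(decisions)
}
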