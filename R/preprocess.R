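#' Replace missing and negative measurements with zero
#'
#' First cleaning step for detection-limit-censored data: any missing cell or
#' negative value becomes exactly 0; everything else is untouched.  The
#' operation is idempotent.
#'
#' @param x feature table (samples x features numeric matrix, `NA` = missing).
#' @return matrix of the same shape with no `NA` and no negatives.
#' @export
clean_nonpositive <- function(x) {
  validate_feature_table(x)
  x[is.na(x) | x < 0] <- 0
  x
}

#' Half-minimum imputation of zeros
#'
#' Per feature, every zero is replaced by half the smallest strictly positive
#' value observed for that feature — the standard left-censoring surrogate.
#' Features that are zero everywhere carry no information about a detection
#' limit and are dropped with a warning.
#'
#' @param x cleaned feature table (no `NA`, no negatives).
#' @return matrix with strictly positive entries; dropped feature ids, if
#'   any, are attached as attribute `"dropped_features"`.
#' @export
impute_half_minimum <- function(x) {
  validate_feature_table(x)
  if (anyNA(x) || any(x < 0))
    stop("impute_half_minimum expects a cleaned table (no missing, no negatives)")
  all_zero <- colSums(x > 0) == 0L
  dropped <- colnames(x)[all_zero]
  if (length(dropped)) {
    warning("dropping all-zero feature(s): ", paste(dropped, collapse = ", "))
    x <- x[, !all_zero, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    z <- x[, j] == 0
    if (any(z)) x[z, j] <- min(x[x[, j] > 0, j]) / 2
  }
  attr(x, "dropped_features") <- dropped
  x
}

#' Log2 transform and autoscale
#'
#' Takes log2 of every (strictly positive) value, then standardizes each
#' feature to zero mean and unit variance across all samples jointly —
#' patients and controls together, before pairing.  Zero-variance features
#' cannot be scaled and are dropped with a warning.
#'
#' @param x imputed feature table, all values > 0.
#' @param sd_method `"sample"` (divide by the n-1 standard deviation, the
#'   default, matching [scale()]) or `"population"` (divide by n).  The
#'   choice rescales values but leaves all downstream correlations unchanged.
#' @return scaled matrix; dropped ids in attribute `"dropped_features"`.
#' @export
log2_autoscale <- function(x, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  validate_feature_table(x)
  if (anyNA(x) || any(x <= 0))
    stop("log2_autoscale expects strictly positive values (impute first)")
  lg <- log2(x)
  n <- nrow(lg)
  mu <- colMeans(lg)
  s <- apply(lg, 2, sd)
  if (sd_method == "population") s <- s * sqrt((n - 1) / n)
  zero_var <- !is.finite(s) | s == 0
  dropped <- colnames(lg)[zero_var]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
    lg <- lg[, !zero_var, drop = FALSE]
    mu <- mu[!zero_var]
    s <- s[!zero_var]
  }
  out <- sweep(sweep(lg, 2, mu, "-"), 2, s, "/")
  attr(out, "dropped_features") <- dropped
  attr(out, "sd_method") <- sd_method
  out
}

#' Matched-pair fold-change matrix
#'
#' One row per patient-control pair: the patient's scaled value minus the
#' matched control's.  This pairs x features matrix is the substrate of all
#' association analysis.
#'
#' @param scaled autoscaled feature table.
#' @param metadata validated metadata data.frame (see [read_metadata()]).
#' @return pairs x features numeric matrix, rownames = pair ids (sorted).
#' @export
paired_fold_change <- function(scaled, metadata) {
  validate_feature_table(scaled)
  metadata <- validate_metadata(metadata)
  missing_samples <- setdiff(metadata$sample_id, rownames(scaled))
  if (length(missing_samples))
    stop("pairing error: sample(s) absent from table: ",
         paste(missing_samples, collapse = ", "))
  pair_ids <- sort(unique(metadata$pair_id))
  fc <- matrix(NA_real_, nrow = length(pair_ids), ncol = ncol(scaled),
               dimnames = list(pair_ids, colnames(scaled)))
  for (p in pair_ids) {
    rows <- metadata[metadata$pair_id == p, ]
    pat <- rows$sample_id[rows$group == "patient"]
    ctl <- rows$sample_id[rows$group == "control"]
    fc[p, ] <- scaled[pat, ] - scaled[ctl, ]
  }
  fc
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: clean, half-minimum impute, log2 + autoscale, then
#' matched-pair fold change.
#'
#' @inheritParams paired_fold_change
#' @param x raw feature table.
#' @param sd_method autoscaling SD convention, see [log2_autoscale()].
#' @return list with `scaled`, `fold_change` and `dropped_features`.
#' @export
preprocess_cohort <- function(x, metadata, sd_method = "sample") {
  cleaned <- clean_nonpositive(x)
  imputed <- impute_half_minimum(cleaned)
  scaled <- log2_autoscale(imputed, sd_method = sd_method)
  dropped <- c(attr(imputed, "dropped_features"),
               attr(scaled, "dropped_features"))
  list(scaled = scaled,
       fold_change = paired_fold_change(scaled, metadata),
       dropped_features = dropped)
}
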