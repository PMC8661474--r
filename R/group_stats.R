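#' Tukey HSD pairwise comparisons
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#' over all group pairs, via [stats::aov()] and [stats::TukeyHSD()].  For
#' two groups the studentized-range statistic satisfies `q = sqrt(2) * |t|`,
#' so the Tukey p-value equals the pooled two-sample t-test p-value.
#'
#' If every group has zero within-group variance the error mean square is 0;
#' pairs with unequal means are then reported as p = 0 with a warning, and
#' identical pairs as p = 1.
#'
#' @param groups named list of numeric vectors, >= 2 groups of >= 2 values.
#' @return data.frame with `group_a`, `group_b`, `diff` (mean difference,
#'   b - a) and `p`.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  pairs <- t(combn(names(groups), 2L))
  means <- vapply(groups, mean, numeric(1))
  diffs <- means[pairs[, 2L]] - means[pairs[, 1L]]
  ss_res <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  if (ss_res == 0) {
    pvals <- ifelse(diffs == 0, 1, 0)
    if (any(pvals == 0))
      warning("zero within-group variance with unequal means: p = 0 reported")
  } else if (length(groups) == 2L) {
    # exact identity q = sqrt(2) * |t|: Tukey p = pooled two-sample t p
    n1 <- lengths(groups)[1L]; n2 <- lengths(groups)[2L]
    mse <- ss_res / (n1 + n2 - 2L)
    t_stat <- diffs / sqrt(mse * (1 / n1 + 1 / n2))
    pvals <- 2 * pt(-abs(t_stat), n1 + n2 - 2L)
  } else {
    tk <- TukeyHSD(aov(value ~ group, data = df))$group
    key <- paste(pairs[, 2L], pairs[, 1L], sep = "-")
    pvals <- tk[match(key, rownames(tk)), "p adj"]
  }
  data.frame(group_a = pairs[, 1L], group_b = pairs[, 2L],
             diff = unname(diffs), p = unname(pvals),
             stringsAsFactors = FALSE)
}

#' Per-feature patient-vs-control group test
#'
#' For every feature, compares patients with controls by ANOVA/Tukey HSD
#' (equivalently the pooled t-test for two groups).  Tested on the log2
#' scale by default (variance-stabilized); the report carries group means on
#' the tested scale.  The raw table is cleaned and half-minimum imputed
#' first.
#'
#' @param table raw feature table (concentration scale).
#' @param metadata validated metadata.
#' @param scale `"log2"` (default) or `"concentration"`.
#' @param alpha significance level, default 0.05.
#' @return data.frame sorted by p: `feature_id`, `mean_patient`,
#'   `mean_control`, `p_value`, `significant`.
#' @export
per_feature_group_test <- function(table, metadata,
                                   scale = c("log2", "concentration"),
                                   alpha = 0.05) {
  scale <- match.arg(scale)
  metadata <- validate_metadata(metadata)
  x <- impute_half_minimum(clean_nonpositive(table))
  if (scale == "log2") x <- log2(x)
  pat <- metadata$sample_id[metadata$group == "patient"]
  ctl <- metadata$sample_id[metadata$group == "control"]
  if (!length(pat) || !length(ctl)) stop("both groups must be non-empty")
  res <- lapply(colnames(x), function(f) {
    tk <- tukey_hsd(list(patient = x[pat, f], control = x[ctl, f]))
    data.frame(feature_id = f,
               mean_patient = mean(x[pat, f]),
               mean_control = mean(x[ctl, f]),
               p_value = tk$p[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$feature_id), , drop = FALSE]
}

#' Antipsychotic-medication confounder scan
#'
#' Within the patient stratum (controls are unmedicated by design), fits per
#' feature an ordinary least-squares model of the processed value on the
#' binary medication flag — a Gaussian identity-link GLM — and reports the
#' flag coefficient, its raw t-test p-value, and both Benjamini-Hochberg and
#' Bonferroni adjusted p-values across all features.  For a binary
#' predictor, coefficient and p coincide with a pooled two-sample t-test.
#'
#' @param table raw feature table.
#' @param metadata validated metadata.
#' @param scale `"log2"` (default) or `"concentration"`.
#' @param stratum `"patients"` (default) or `"all"` samples.
#' @param alpha significance level for the `flagged` column.
#' @return data.frame: `feature_id`, `coefficient`, `p_raw`, `p_bh`,
#'   `p_bonferroni`, `flagged`.
#' @export
confounder_scan <- function(table, metadata,
                            scale = c("log2", "concentration"),
                            stratum = c("patients", "all"), alpha = 0.05) {
  scale <- match.arg(scale)
  stratum <- match.arg(stratum)
  metadata <- validate_metadata(metadata)
  x <- impute_half_minimum(clean_nonpositive(table))
  if (scale == "log2") x <- log2(x)
  md <- if (stratum == "patients") metadata[metadata$group == "patient", ]
        else metadata
  flag <- md$antipsychotic_flag
  if (length(unique(flag)) < 2L)
    stop("scan error: medication flag is constant within the stratum")
  xs <- x[md$sample_id, , drop = FALSE]
  res <- lapply(colnames(xs), function(f) {
    fit <- summary(lm(xs[, f] ~ flag))$coefficients
    data.frame(feature_id = f, coefficient = fit["flagTRUE", "Estimate"],
               p_raw = fit["flagTRUE", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- adjust_pvalues(out$p_raw, "bh")
  out$p_bonferroni <- adjust_pvalues(out$p_raw, "bonferroni")
  out$flagged <- out$p_bh < alpha | out$p_bonferroni < alpha
  out
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up FDR adjustment or Bonferroni family-wise
#' correction (via [stats::p.adjust()]); adjusted values are capped at 1 and
#' returned in the input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"bonferroni"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
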