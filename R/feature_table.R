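#' Validate a feature table
#'
#' A feature table is a numeric matrix with samples in rows and features in
#' columns; `NA` marks a measurement that is missing (e.g. below the
#' detection limit).  Row and column names must be unique sample and feature
#' identifiers.
#'
#' @param x numeric matrix, samples x features.
#' @return the validated matrix, invisibly usable downstream.
#' @export
validate_feature_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("feature table must be a numeric matrix (samples x features)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature table must carry sample (row) and feature (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  x
}

#' Read a feature table from TSV/CSV
#'
#' First column holds sample ids, the header row feature ids.  Cells must
#' parse as real numbers or as a missing token (empty, `NA`, `NaN`,
#' case-insensitive).  Negative values are retained at read time; they are
#' zeroed later by [clean_nonpositive()] so that cleaning remains an explicit,
#' audited step.
#'
#' @param path file path.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @param missing_tokens character vector of tokens read as missing.
#' @return numeric matrix with `NA` for missing cells.
#' @export
read_feature_table <- function(path, sep = "\t",
                               missing_tokens = c("", "na", "nan")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("feature table needs a sample-id column plus >= 1 feature")
  sample_ids <- trimws(raw[[1]])
  feature_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(feature_ids),
                 dimnames = list(sample_ids, feature_ids))
  for (j in seq_along(feature_ids)) {
    cell <- trimws(raw[[j + 1L]])
    is_missing <- tolower(cell) %in% missing_tokens | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(num))
    if (length(bad))
      stop(sprintf("malformed numeric cell '%s' at row '%s', column '%s' in %s",
                   cell[bad[1L]], sample_ids[bad[1L]], feature_ids[j], path))
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }
  validate_feature_table(vals)
}

#' Write a feature table to TSV
#'
#' Serializes with 17 significant digits so that a write-then-read round trip
#' reproduces finite values exactly; missing values are written as empty
#' cells.
#'
#' @param x numeric matrix, samples x features.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_feature_table <- function(x, path, sep = "\t") {
  validate_feature_table(x)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  header <- paste(c("sample_id", colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt(x[i, ])), collapse = sep), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects TSV columns `sample_id`, `group` (patient/control), `pair_id` and
#' `antipsychotic_flag` (TRUE/FALSE or 1/0).  Verifies the matched design:
#' every `pair_id` must map to exactly one patient and one control.  The flag
#' is forced to `FALSE` for controls (unmedicated by design).
#'
#' @param path file path.
#' @return data.frame of validated metadata rows.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(md)
}

#' Validate sample metadata
#' @param md data.frame with columns `sample_id`, `group`, `pair_id`,
#'   `antipsychotic_flag`.
#' @return the validated (and normalized) data.frame.
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "group", "pair_id", "antipsychotic_flag")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$group <- as.character(md$group)
  md$pair_id <- as.character(md$pair_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  if (!all(md$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  flag <- md$antipsychotic_flag
  if (is.character(flag)) flag <- toupper(trimws(flag)) %in% c("TRUE", "T", "1")
  md$antipsychotic_flag <- as.logical(flag) & md$group == "patient"
  bad <- Filter(function(p) {
    g <- md$group[md$pair_id == p]
    !(sum(g == "patient") == 1L && sum(g == "control") == 1L)
  }, unique(md$pair_id))
  if (length(bad))
    stop("pairing error: pair(s) without exactly one patient and one control: ",
         paste(bad, collapse = ", "))
  md
}

#' Write sample metadata to TSV
#' @param md metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(md, path) {
  write.table(md[, c("sample_id", "group", "pair_id", "antipsychotic_flag")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature catalog
#'
#' TSV with columns `feature_id`, `role` (lipid / mediator_plasma /
#' mediator_gene) and `display_name`.  Lipid rows are annotated by parsing
#' their display name with [parse_lipid_name()]; mediators carry no lipid
#' annotation.  The plasma display prefix "P-" is presentation only: role
#' always comes from the catalog column.
#'
#' @param path file path.
#' @return data.frame with annotation columns `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `ether_flag` (NA for mediators).
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cat_df <- read.delim(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE)
  validate_catalog(cat_df)
}

#' Validate (and annotate) a feature catalog
#' @param cat_df data.frame with `feature_id`, `role`, `display_name`.
#' @return annotated catalog data.frame.
#' @export
validate_catalog <- function(cat_df) {
  need <- c("feature_id", "role", "display_name")
  miss <- setdiff(need, colnames(cat_df))
  if (length(miss)) stop("catalog lacks columns: ", paste(miss, collapse = ", "))
  cat_df$feature_id <- as.character(cat_df$feature_id)
  if (anyDuplicated(cat_df$feature_id))
    stop("duplicate feature ids in catalog: ",
         paste(unique(cat_df$feature_id[duplicated(cat_df$feature_id)]),
               collapse = ", "))
  ok_roles <- c("lipid", "mediator_plasma", "mediator_gene")
  if (!all(cat_df$role %in% ok_roles))
    stop("role must be one of: ", paste(ok_roles, collapse = ", "))
  ann <- lapply(seq_len(nrow(cat_df)), function(i) {
    if (cat_df$role[i] == "lipid") parse_lipid_name(cat_df$display_name[i])
    else list(lipid_class = NA_character_, total_carbons = NA_integer_,
              total_double_bonds = NA_integer_, ether_flag = NA_character_)
  })
  cat_df$lipid_class <- vapply(ann, function(a) a$lipid_class, character(1))
  cat_df$total_carbons <- vapply(ann, function(a) as.integer(a$total_carbons), integer(1))
  cat_df$total_double_bonds <- vapply(ann, function(a) as.integer(a$total_double_bonds), integer(1))
  cat_df$ether_flag <- vapply(ann, function(a) a$ether_flag, character(1))
  cat_df
}

#' Write a feature catalog to TSV
#' @param cat_df catalog data.frame.
#' @param path output path.
#' @export
write_catalog <- function(cat_df, path) {
  write.table(cat_df[, c("feature_id", "role", "display_name")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# role lookup keyed by feature id; errors on unknown ids
catalog_roles <- function(ids, cat_df) {
  m <- match(ids, cat_df$feature_id)
  if (anyNA(m))
    stop("feature id(s) not in catalog: ",
         paste(unique(ids[is.na(m)]), collapse = ", "))
  cat_df$role[m]
}
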