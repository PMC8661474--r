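#' Write an edge list to TSV
#'
#' Deterministic layout: columns `feature_a`, `feature_b`, `rho`, `nrr`,
#' `kind`; rows sorted by `|rho|` descending, ties broken by feature ids
#' lexicographically.  An empty edge list produces a header-only file.
#'
#' @param edges edge data.frame (see [filter_nonspurious()]).
#' @param path output path.
#' @param catalog optional catalog; when given, endpoints are validated
#'   against it.
#' @export
write_edge_list <- function(edges, path, catalog = NULL) {
  if (!is.null(catalog))
    catalog_roles(unique(c(edges$feature_a, edges$feature_b)), catalog)
  ord <- order(-abs(edges$rho), edges$feature_a, edges$feature_b)
  write_records(edges[ord, c("feature_a", "feature_b", "rho", "nrr", "kind"),
                      drop = FALSE], path)
}

#' Write a candidate table to TSV
#'
#' Columns `mediator`, `lipid`, `rho`, `nrr`; rows sorted by `|rho|`
#' descending (the Table-3 layout).
#'
#' @param candidates candidate data.frame (see [strong_candidates()]).
#' @param path output path.
#' @param catalog optional catalog for endpoint validation.
#' @export
write_candidates <- function(candidates, path, catalog = NULL) {
  if (!is.null(catalog)) {
    ids <- c(candidates$mediator, candidates$lipid)
    catalog_roles(unique(ids[!is.na(ids)]), catalog)
  }
  ord <- order(-abs(candidates$rho), candidates$mediator, candidates$lipid)
  write_records(candidates[ord, c("mediator", "lipid", "rho", "nrr"),
                           drop = FALSE], path)
}

#' Export a network as GraphML
#'
#' Nodes carry `role` and `lipid_class` attributes; edges carry `rho`,
#' `nrr` and `sign` (see [build_network()]).
#'
#' @param network an igraph object.
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back
#' @param path GraphML file.
#' @return an igraph object.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

# deterministic TSV serialization: 17 significant digits, no quoting
write_records <- function(df, path) {
  fmt <- function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "", sprintf("%.17g", col))
    else ifelse(is.na(col), "", as.character(col))
  }
  header <- paste(colnames(df), collapse = "\t")
  if (nrow(df) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  cols <- lapply(df, fmt)
  writeLines(c(header, do.call(paste, c(cols, sep = "\t"))), path)
  invisible(path)
}
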