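# edge kind from the two endpoint roles
edge_kind <- function(role_a, role_b) {
  n_lipid <- (role_a == "lipid") + (role_b == "lipid")
  c("mediator-mediator", "mediator-lipid", "lipid-lipid")[n_lipid + 1L]
}

#' Retain non-spurious associations by NRR threshold
#'
#' Keeps every unordered feature pair whose non-rejection rate is at or below
#' the threshold (inclusive, NRR <= threshold) and attaches the Spearman
#' coefficient and the edge kind derived from the catalog roles.  Edges are
#' canonical: `feature_a < feature_b` lexicographically.
#'
#' @param rho Spearman correlation matrix (see [spearman_matrix()]).
#' @param nrr NRR matrix over the same features in the same order.
#' @param catalog annotated feature catalog (see [read_catalog()]).
#' @param threshold NRR retention threshold in \[0, 1\], default 0.1.
#' @return data.frame of edge records: `feature_a`, `feature_b`, `rho`,
#'   `nrr`, `kind`.
#' @export
filter_nonspurious <- function(rho, nrr, catalog, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!identical(colnames(rho), colnames(nrr)))
    stop("rho and nrr matrices must share the same feature order")
  ids <- colnames(rho)
  roles <- catalog_roles(ids, catalog)
  keep <- which(upper.tri(nrr) & nrr <= threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      rho = numeric(0), nrr = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  a <- ids[keep[, 1L]]
  b <- ids[keep[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(
    feature_a = a, feature_b = b,
    rho = rho[keep], nrr = nrr[keep],
    kind = mapply(edge_kind, roles[match(a, ids)], roles[match(b, ids)]),
    stringsAsFactors = FALSE)
  edges[order(-abs(edges$rho), edges$feature_a, edges$feature_b), ,
        drop = FALSE]
}

#' Prune lipid-lipid edges
#'
#' Removes, for clarity, every association between two lipids: the retained
#' network is mediator-centric, every edge having at least one inflammatory
#' mediator endpoint.  All other edges pass through in order.
#'
#' @param edges edge data.frame from [filter_nonspurious()].
#' @param catalog annotated feature catalog.
#' @return edge data.frame with no `lipid-lipid` edges.
#' @export
prune_lipid_lipid <- function(edges, catalog) {
  catalog_roles(unique(c(edges$feature_a, edges$feature_b)), catalog)
  edges[edges$kind != "lipid-lipid", , drop = FALSE]
}

#' Assemble the mediator-centric association network
#'
#' Builds an undirected igraph object: nodes are all features incident to at
#' least one retained edge (isolated features are omitted), attributed with
#' their role and lipid class; edges carry the Spearman coefficient, its
#' sign, the NRR, and `weight = |rho|` so the correlation magnitude can
#' drive edge thickness in a viewer.
#'
#' @param edges edge data.frame (NRR-filtered, usually pruned).
#' @param catalog annotated feature catalog.
#' @return an [igraph::graph] object.
#' @export
build_network <- function(edges, catalog) {
  ids <- sort(unique(c(edges$feature_a, edges$feature_b)))
  m <- match(ids, catalog$feature_id)
  if (anyNA(m))
    stop("feature id(s) not in catalog: ", paste(ids[is.na(m)], collapse = ", "))
  vertices <- data.frame(
    name = ids,
    role = catalog$role[m],
    lipid_class = ifelse(is.na(catalog$lipid_class[m]), "",
                         catalog$lipid_class[m]),
    display_name = catalog$display_name[m],
    stringsAsFactors = FALSE)
  ed <- data.frame(from = edges$feature_a, to = edges$feature_b,
                   rho = edges$rho, nrr = edges$nrr,
                   sign = sign(edges$rho), weight = abs(edges$rho),
                   kind = edges$kind, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vertices)
}

#' Extract strong consistent candidates
#'
#' Refines the NRR-filtered, mediator-centric edge list to the strongest
#' associations: `|rho| >= rho_threshold` (inclusive, default 0.5).  By
#' default only mediator-lipid pairs are reported (the Table-3-style
#' candidate list); mediator-mediator pairs can be included with a flag.
#' Candidates are sorted by `|rho|` descending.
#'
#' @param edges NRR-filtered and pruned edge data.frame.
#' @param catalog annotated feature catalog.
#' @param rho_threshold minimum absolute Spearman coefficient.
#' @param include_mediator_mediator also report mediator-mediator pairs.
#' @return data.frame of candidate records: `mediator`, `lipid` (NA for
#'   mediator-mediator pairs), `rho`, `nrr`, `kind`.
#' @export
strong_candidates <- function(edges, catalog, rho_threshold = 0.5,
                              include_mediator_mediator = FALSE) {
  kinds <- "mediator-lipid"
  if (include_mediator_mediator) kinds <- c(kinds, "mediator-mediator")
  sel <- edges[edges$kind %in% kinds & abs(edges$rho) >= rho_threshold, ,
               drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(mediator = character(0), lipid = character(0),
                      rho = numeric(0), nrr = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  roles_a <- catalog_roles(sel$feature_a, catalog)
  a_is_mediator <- roles_a != "lipid"
  out <- data.frame(
    mediator = ifelse(a_is_mediator, sel$feature_a, sel$feature_b),
    lipid = ifelse(sel$kind == "mediator-lipid",
                   ifelse(a_is_mediator, sel$feature_b, sel$feature_a),
                   NA_character_),
    rho = sel$rho, nrr = sel$nrr, kind = sel$kind,
    stringsAsFactors = FALSE)
  out[order(-abs(out$rho), out$mediator, out$lipid), , drop = FALSE]
}
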