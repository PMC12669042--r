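#' Extract the localized subgraph where molecule and disease both diffuse
#'
#' Mechanism-of-action view: keeps the interactome nodes that are in the
#' top `top_fraction` of the molecule's diffusion profile AND in the top
#' `top_fraction` of the disease's, adds both seed sets, induces the
#' interactome edges among the retained nodes, and prunes connected
#' components containing no seed. The "top" sets are the
#' `ceiling(top_fraction * N)` highest-scoring nodes of each profile
#' (ties resolved by node-index order), which makes the retained set
#' monotone non-decreasing in `top_fraction`.
#'
#' @param interactome an `interactome`.
#' @param dp_m,dp_d molecule / disease `diffusion_profile`s over
#'   `interactome`.
#' @param seeds_m,seeds_d the corresponding `seed_vector`s.
#' @param top_fraction quantile fraction in (0, 1]; on realistically
#'   sized interactomes values around 0.001 give figure-sized subgraphs,
#'   on toy graphs use 0.25 or larger.
#' @return object of class `localized_subgraph`: list with `nodes` (data
#'   frame `node_id`, `node_type`, `dp_molecule`, `dp_disease`,
#'   `is_seed_molecule`, `is_seed_disease`), `edges` (subset of
#'   interactome edges), `n_components` (kept), `n_dropped_components`.
#' @export
localized_subgraph <- function(interactome, dp_m, dp_d, seeds_m, seeds_d,
                               top_fraction = 0.25) {
  if (!(is.numeric(top_fraction) && length(top_fraction) == 1L &&
        top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- interactome$n_nodes
  vm <- profile_values(dp_m)
  vd <- profile_values(dp_d)
  stopifnot(length(vm) == n, length(vd) == n,
            length(seeds_m$values) == n, length(seeds_d$values) == n)

  n_keep <- ceiling(top_fraction * n)
  top_set <- function(v) sort(order(-v, method = "radix")[seq_len(n_keep)])
  joint <- intersect(top_set(vm), top_set(vd))
  seed_idx <- which(seeds_m$values > 0 | seeds_d$values > 0)
  keep <- sort(union(joint, seed_idx))

  ids <- interactome$nodes$node_id[keep]
  e <- interactome$edges
  in_keep <- e$from %in% ids & e$to %in% ids
  sub_edges <- e[in_keep, , drop = FALSE]

  # component pruning: keep only components holding at least one seed
  g <- igraph::graph_from_data_frame(
    sub_edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  seed_ids <- interactome$nodes$node_id[seed_idx]
  seeded <- unique(comp$membership[names(comp$membership) %in% seed_ids])
  keep_ids <- names(comp$membership)[comp$membership %in% seeded]
  dropped <- comp$no - length(seeded)

  final <- keep[ids %in% keep_ids]
  ids <- interactome$nodes$node_id[final]
  sub_edges <- sub_edges[sub_edges$from %in% ids & sub_edges$to %in% ids, ,
                         drop = FALSE]
  rownames(sub_edges) <- NULL

  nodes <- data.frame(node_id = ids,
                      node_type = interactome$nodes$node_type[final],
                      dp_molecule = vm[final],
                      dp_disease = vd[final],
                      is_seed_molecule = seeds_m$values[final] > 0,
                      is_seed_disease = seeds_d$values[final] > 0,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = sub_edges,
                 n_components = length(seeded),
                 n_dropped_components = dropped),
            class = "localized_subgraph")
}

#' @exportS3Method base::print
print.localized_subgraph <- function(x, ...) {
  cat("localized subgraph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges in ", x$n_components, " seed-containing component(s)",
      if (x$n_dropped_components > 0)
        paste0(" (", x$n_dropped_components, " seedless dropped)"),
      "\n", sep = "")
  invisible(x)
}

# build the annotated igraph used by both exporters
subgraph_igraph <- function(subgraph) {
  igraph::graph_from_data_frame(
    subgraph$edges[, c("from", "to", "edge_type")], directed = FALSE,
    vertices = data.frame(name = subgraph$nodes$node_id,
                          type = subgraph$nodes$node_type,
                          dp_molecule = subgraph$nodes$dp_molecule,
                          dp_disease = subgraph$nodes$dp_disease,
                          seed_molecule = as.integer(
                            subgraph$nodes$is_seed_molecule),
                          seed_disease = as.integer(
                            subgraph$nodes$is_seed_disease),
                          stringsAsFactors = FALSE))
}

#' Export a localized subgraph
#'
#' `write_subgraph_graphml()` writes GraphML with node attributes (type,
#' both diffusion values, seed flags); `write_subgraph_dot()` writes a
#' DOT file for rendering; `write_subgraph_table()` writes the node
#' table as TSV.
#'
#' @param subgraph a `localized_subgraph`.
#' @param path output file path.
#' @export
write_subgraph_graphml <- function(subgraph, path) {
  igraph::write_graph(subgraph_igraph(subgraph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_subgraph_graphml
#' @export
write_subgraph_dot <- function(subgraph, path) {
  igraph::write_graph(subgraph_igraph(subgraph), path, format = "dot")
  invisible(path)
}

#' @rdname write_subgraph_graphml
#' @export
write_subgraph_table <- function(subgraph, path) {
  utils::write.table(subgraph$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
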