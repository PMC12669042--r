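#' Node and edge types of the multiscale interactome
#'
#' @name interactome-types
#' @keywords internal
NULL

.node_types <- c("protein", "biological_function")
.edge_types <- c("protein_protein", "protein_function", "function_function")

# expected (node_1_type, node_2_type) for each edge type; protein_function
# rows may come in either orientation and are normalized protein-first
.edge_endpoint_types <- list(
  protein_protein   = c("protein", "protein"),
  protein_function  = c("protein", "biological_function"),
  function_function = c("biological_function", "biological_function")
)

#' Read a typed edge list from a tab-separated file
#'
#' Expects a header `node_1<TAB>node_1_type<TAB>node_2<TAB>node_2_type`, the
#' layout of the public multiscale-interactome release files. Rows whose
#' node types contradict `edge_type` are rejected with their row numbers.
#' Self-loops are dropped (with a message) and duplicate edges collapsed.
#' `protein_function` rows are accepted in either orientation and stored
#' protein-first; `function_function` rows are directed child-to-parent in
#' the order given.
#'
#' @param path path to a TSV file.
#' @param edge_type one of `"protein_protein"`, `"protein_function"`,
#'   `"function_function"`.
#' @return a data frame with columns `from`, `to`, `edge_type`.
#' @export
read_edge_list <- function(path,
                           edge_type = c("protein_protein", "protein_function",
                                         "function_function")) {
  edge_type <- match.arg(edge_type)
  if (!file.exists(path)) {
    stop("edge list file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE)
  required <- c("node_1", "node_1_type", "node_2", "node_2_type")
  if (!all(required %in% names(df))) {
    stop("malformed header in ", path, ": expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("edge list ", path, " has no data rows", call. = FALSE)
  }
  make_edge_df(df$node_1, df$node_1_type, df$node_2, df$node_2_type,
               edge_type = edge_type, source = path)
}

# Validate endpoint types, drop self-loops, canonicalize orientation and
# collapse duplicates. Shared by read_edge_list() and the synthetic generator.
make_edge_df <- function(from, from_type, to, to_type, edge_type,
                         source = "<edges>") {
  want <- .edge_endpoint_types[[edge_type]]
  ok_fwd <- from_type == want[1] & to_type == want[2]
  ok_rev <- from_type == want[2] & to_type == want[1]
  ok <- if (want[1] == want[2]) ok_fwd else (ok_fwd | ok_rev)
  if (any(!ok)) {
    bad <- which(!ok)
    stop("in ", source, ": ", length(bad), " row(s) contradict edge type '",
         edge_type, "' (rows ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", ")", call. = FALSE)
  }
  # normalize protein_function to protein-first
  if (edge_type == "protein_function" && any(ok_rev)) {
    tmp <- from[ok_rev]
    from[ok_rev] <- to[ok_rev]
    to[ok_rev] <- tmp
  }
  self <- from == to
  if (any(self)) {
    message("dropping ", sum(self), " self-loop(s) from ", source)
    from <- from[!self]
    to <- to[!self]
  }
  if (length(from) == 0L) {
    stop("no usable edges in ", source, call. = FALSE)
  }
  # undirected edge types collapse regardless of orientation
  if (edge_type == "protein_protein") {
    a <- pmin(from, to)
    b <- pmax(from, to)
    from <- a
    to <- b
  }
  keep <- !duplicated(paste(from, to, sep = "\r"))
  data.frame(from = from[keep], to = to[keep],
             edge_type = rep(edge_type, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Write a typed edge list to a tab-separated file
#'
#' Inverse of [read_edge_list()]: a read-back reproduces the edges up to row
#' order and duplicate collapse.
#'
#' @param edges data frame with columns `from`, `to`, `edge_type` (one
#'   edge type throughout).
#' @param path output file path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("from", "to", "edge_type") %in% names(edges)))
  et <- unique(edges$edge_type)
  if (length(et) != 1L) {
    stop("write_edge_list() expects a single edge type, got: ",
         paste(et, collapse = ", "), call. = FALSE)
  }
  want <- .edge_endpoint_types[[et]]
  out <- data.frame(node_1 = edges$from, node_1_type = want[1],
                    node_2 = edges$to, node_2_type = want[2],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a multiscale interactome from typed edge collections
#'
#' Takes the three typed edge collections (as returned by
#' [read_edge_list()]) and assembles the heterogeneous graph. Node ids must
#' be used with a single node type across all collections. Node positions
#' are assigned deterministically: nodes are sorted lexicographically (C
#' locale) by `(node_type, node_id)`, so vector positions are reproducible
#' across runs and input orderings.
#'
#' `protein_protein` and `protein_function` edges are undirected;
#' `function_function` edges are directed child-to-parent (a hierarchy) but
#' traversable both ways with distinct bias weights during propagation.
#'
#' @param protein_protein edge data frame (required, at least one edge).
#' @param protein_function,function_function optional edge data frames.
#' @return an object of class `interactome`: list with `nodes` (data frame
#'   `node_id`, `node_type` in index order), `edges` (data frame `from`,
#'   `to`, `edge_type`), and `n_nodes`.
#' @export
build_interactome <- function(protein_protein,
                              protein_function = NULL,
                              function_function = NULL) {
  if (is.null(protein_protein) || nrow(protein_protein) == 0L) {
    stop("at least one protein_protein edge is required", call. = FALSE)
  }
  parts <- list(protein_protein, protein_function, function_function)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  edges <- do.call(rbind, parts)
  if (!all(edges$edge_type %in% .edge_types)) {
    stop("unknown edge type(s): ",
         paste(setdiff(unique(edges$edge_type), .edge_types), collapse = ", "),
         call. = FALSE)
  }

  # type assignment per endpoint, from the edge-type contract
  end_types <- t(vapply(edges$edge_type,
                        function(et) .edge_endpoint_types[[et]],
                        character(2)))
  ids <- c(edges$from, edges$to)
  types <- c(end_types[, 1], end_types[, 2])
  tab <- unique(data.frame(node_id = ids, node_type = types,
                           stringsAsFactors = FALSE))
  dup <- tab$node_id[duplicated(tab$node_id)]
  if (length(dup) > 0L) {
    stop("node id(s) used with two different node types: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  ord <- order(tab$node_type, tab$node_id, method = "radix")
  nodes <- tab[ord, , drop = FALSE]
  rownames(nodes) <- NULL

  # cross-collection dedup (protein_protein already canonically oriented)
  keep <- !duplicated(paste(edges$from, edges$to, edges$edge_type, sep = "\r"))
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges, n_nodes = nrow(nodes)),
            class = "interactome")
}

#' @exportS3Method base::print
print.interactome <- function(x, ...) {
  cat("multiscale interactome: ", x$n_nodes, " nodes (",
      sum(x$nodes$node_type == "protein"), " proteins, ",
      sum(x$nodes$node_type == "biological_function"), " functions), ",
      nrow(x$edges), " edges\n", sep = "")
  print(table(x$edges$edge_type))
  invisible(x)
}

#' Map node ids to interactome positions
#'
#' @param interactome an `interactome`.
#' @param ids character vector of node ids.
#' @return integer positions (NA for absent ids).
#' @export
node_index <- function(interactome, ids) {
  match(ids, interactome$nodes$node_id)
}

#' Read an entity-to-target table
#'
#' Reads a TSV with columns `entity_id`, `entity_name`, `protein_id` (one
#' row per entity/target pair), groups rows by entity and deduplicates each
#' entity's target set. Targets are resolved against an interactome later
#' with [resolve_targets()].
#'
#' @param path path to the TSV.
#' @param entity_class `"bioactive_molecule"` or `"drug"`.
#' @return named list of `entity_targets` objects (fields `entity_id`,
#'   `entity_name`, `entity_class`, `target_ids`, `unresolved_ids`).
#' @export
read_entity_targets <- function(path,
                                entity_class = c("bioactive_molecule", "drug")) {
  entity_class <- match.arg(entity_class)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE)
  required <- c("entity_id", "entity_name", "protein_id")
  if (!all(required %in% names(df))) {
    stop("malformed header in ", path, ": expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("entity target table ", path, " is empty",
                           call. = FALSE)
  if (any(!nzchar(df$entity_id))) {
    stop("entity with blank id in ", path, call. = FALSE)
  }
  entity_targets_from_df(df, entity_class)
}

# group a (entity_id, entity_name, protein_id) data frame into a collection
entity_targets_from_df <- function(df, entity_class) {
  split_idx <- split(seq_len(nrow(df)), df$entity_id)
  out <- lapply(split_idx, function(i) {
    structure(list(entity_id = df$entity_id[i[1]],
                   entity_name = df$entity_name[i[1]],
                   entity_class = entity_class,
                   target_ids = sort(unique(df$protein_id[i])),
                   unresolved_ids = character(0)),
              class = "entity_targets")
  })
  out[order(names(out), method = "radix")]
}

#' Resolve entity target sets against an interactome
#'
#' Restricts each entity's targets to protein nodes present in the
#' interactome; ids that do not resolve are recorded in `unresolved_ids`,
#' never silently dropped. Entities left with zero resolved targets are
#' retained (a warning lists them) and are excluded later from ranking.
#'
#' @param targets collection from [read_entity_targets()].
#' @param interactome an `interactome`.
#' @return the collection with `target_ids` resolved and `unresolved_ids`
#'   filled in.
#' @export
resolve_targets <- function(targets, interactome) {
  proteins <- interactome$nodes$node_id[interactome$nodes$node_type == "protein"]
  out <- lapply(targets, function(e) {
    hit <- e$target_ids %in% proteins
    e$unresolved_ids <- e$target_ids[!hit]
    e$target_ids <- e$target_ids[hit]
    e
  })
  empty <- names(out)[vapply(out, function(e) length(e$target_ids) == 0L,
                             logical(1))]
  if (length(empty) > 0L) {
    warning(length(empty), " entit(y/ies) with zero resolvable targets: ",
            paste(utils::head(empty, 10L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a disease gene list
#'
#' Plain text, one gene id per line; an optional second tab-separated
#' column gives an evidence tier (used for gene-subset robustness runs).
#'
#' @param path file path.
#' @return data frame with columns `gene_id` and (possibly all-`NA`)
#'   `evidence_tier`.
#' @export
read_disease_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("disease gene list ", path, " is empty",
                                call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, character(1), 1L),
             evidence_tier = vapply(parts, function(p)
               if (length(p) >= 2L) p[2] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' Build a binary seed vector over interactome nodes
#'
#' Sets 1 exactly at the requested ids that are present as protein nodes.
#' Requested ids absent from the interactome (or present only as
#' biological-function nodes) are reported in `missing_ids` and the
#' analysis proceeds with the available subset; it is an error only when no
#' id resolves at all.
#'
#' @param interactome an `interactome`.
#' @param gene_ids character vector of protein/gene ids (non-empty).
#' @return object of class `seed_vector`: list with `values` (0/1 numeric of
#'   length `n_nodes`), `n_seeds`, `missing_ids`.
#' @export
make_seed_vector <- function(interactome, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0L) stop("gene_ids is empty", call. = FALSE)
  is_protein <- interactome$nodes$node_type == "protein"
  pos <- node_index(interactome, gene_ids)
  hit <- !is.na(pos) & is_protein[pmax(pos, 1L)]
  hit[is.na(pos)] <- FALSE
  if (!any(hit)) {
    stop("no seeds resolved: none of the requested ids are protein nodes",
         call. = FALSE)
  }
  values <- numeric(interactome$n_nodes)
  values[pos[hit]] <- 1
  structure(list(values = values,
                 n_seeds = sum(hit),
                 missing_ids = gene_ids[!hit]),
            class = "seed_vector")
}

#' @exportS3Method base::print
print.seed_vector <- function(x, ...) {
  cat("seed vector: ", x$n_seeds, " seed(s) over ", length(x$values),
      " nodes", sep = "")
  if (length(x$missing_ids) > 0L) {
    cat("; ", length(x$missing_ids), " requested id(s) not resolved", sep = "")
  }
  cat("\n")
  invisible(x)
}
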