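#' Parameters of the synthetic interactome benchmark
#'
#' Defines a desk-scale heterogeneous interactome with planted structure:
#' a scale-free (preferential-attachment) protein layer, a balanced-tree
#' biological-function hierarchy (directed child-to-parent), random
#' protein-to-function memberships, a disease gene set concentrated in
#' one graph neighborhood, and a cohort of planted "beneficial"
#' molecules whose targets are drawn from that neighborhood while
#' background molecules target uniformly at random.
#'
#' Defaults mirror the structure of the real analysis at desk scale: 13
#' disease genes, 15 planted molecules among 100 candidates, and target
#' sets of 13 proteins per molecule, all of a planted molecule's targets
#' drawn from the disease neighborhood with affinity decaying in graph
#' distance (see `planted_distance_weights`). Beneficial molecules in the
#' emulated biology act on the disease module itself, so planted draws
#' are weighted towards the disease genes and their immediate
#' interactors; this is what concentrates planted similarity scores into
#' a tight top cohort separated from the background by a visible elbow.
#'
#' @param n_proteins,n_functions,n_molecules layer and cohort sizes.
#' @param ppi_attachment edges added per node in the preferential
#'   attachment model (graph stays connected; 1 gives a scale-free
#'   tree-like layer with well-localized neighborhoods).
#' @param function_branching arity of the balanced function hierarchy.
#' @param membership_rate mean number of function memberships per protein
#'   (Poisson).
#' @param n_disease_genes disease gene count (sampled from one
#'   breadth-first ball).
#' @param n_planted number of planted beneficial molecules.
#' @param planted_overlap fraction in (0, 1] of a planted molecule's
#'   targets drawn from the disease neighborhood (within radius 2 of the
#'   disease genes); the remainder are uniform over all proteins.
#' @param targets_per_molecule targets per molecule.
#' @param planted_distance_weights positive length-3 vector: relative
#'   sampling weight of neighborhood proteins at graph distance 0
#'   (disease genes), 1, and 2 when drawing planted targets.
#' @param rng_seed integer seed; every stage derives its own stream from
#'   it, so generation is fully deterministic.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 500, n_functions = 40, n_molecules = 100,
                       ppi_attachment = 1, function_branching = 3,
                       membership_rate = 2, n_disease_genes = 13,
                       n_planted = 15, planted_overlap = 1,
                       targets_per_molecule = 13,
                       planted_distance_weights = c(32, 8, 1),
                       rng_seed = 1) {
  p <- list(n_proteins = as.integer(n_proteins),
            n_functions = as.integer(n_functions),
            n_molecules = as.integer(n_molecules),
            ppi_attachment = as.integer(ppi_attachment),
            function_branching = as.integer(function_branching),
            membership_rate = membership_rate,
            n_disease_genes = as.integer(n_disease_genes),
            n_planted = as.integer(n_planted),
            planted_overlap = planted_overlap,
            targets_per_molecule = as.integer(targets_per_molecule),
            planted_distance_weights = as.numeric(planted_distance_weights),
            rng_seed = as.integer(rng_seed))
  counts <- c("n_proteins", "n_functions", "n_molecules", "ppi_attachment",
              "function_branching", "n_disease_genes",
              "targets_per_molecule")
  if (any(vapply(p[counts], function(v) is.na(v) || v < 1L, logical(1)))) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (p$n_planted < 0L || p$n_planted > p$n_molecules) {
    stop("n_planted must be in 0..n_molecules", call. = FALSE)
  }
  if (!(p$planted_overlap > 0 && p$planted_overlap <= 1)) {
    stop("planted_overlap must be in (0, 1]", call. = FALSE)
  }
  if (p$n_disease_genes > p$n_proteins ||
      p$targets_per_molecule > p$n_proteins) {
    stop("more disease genes or targets than proteins", call. = FALSE)
  }
  if (length(p$planted_distance_weights) != 3L ||
      any(p$planted_distance_weights <= 0)) {
    stop("planted_distance_weights must be 3 positive values", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

# per-stage RNG stream derived from the top-level seed (kept < 2^31)
stage_seed <- function(params, offset) {
  (params$rng_seed * 11L + offset) %% 2147483629L
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))
function_ids <- function(n) sprintf("F%04d", seq_len(n))
molecule_ids <- function(n) sprintf("M%04d", seq_len(n))

#' Generate a synthetic heterogeneous interactome
#'
#' Protein layer: connected undirected preferential-attachment graph
#' (degree-heterogeneous, like a protein-protein interaction network).
#' Function layer: balanced rooted tree of the configured arity, edges
#' directed child-to-parent (a hierarchy in the style of an ontology).
#' Memberships: each protein is linked to `Poisson(membership_rate)`
#' distinct functions chosen uniformly. Deterministic given
#' `params$rng_seed`.
#'
#' @param params a `sim_params`.
#' @return an `interactome`.
#' @export
generate_interactome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params, 0L))

  pid <- protein_ids(params$n_proteins)
  g <- igraph::sample_pa(params$n_proteins, m = params$ppi_attachment,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  pp <- make_edge_df(pid[el[, 1]], "protein", pid[el[, 2]], "protein",
                     edge_type = "protein_protein", source = "<synthetic ppi>")

  fid <- function_ids(params$n_functions)
  ff <- NULL
  if (params$n_functions >= 2L) {
    tr <- igraph::make_tree(params$n_functions,
                            children = params$function_branching,
                            mode = "in")  # edges point child -> parent
    tel <- igraph::as_edgelist(tr, names = FALSE)
    ff <- make_edge_df(fid[tel[, 1]], "biological_function",
                       fid[tel[, 2]], "biological_function",
                       edge_type = "function_function",
                       source = "<synthetic hierarchy>")
  }

  n_links <- stats::rpois(params$n_proteins, params$membership_rate)
  n_links <- pmin(n_links, params$n_functions)
  pf_from <- rep(pid, n_links)
  pf_to <- unlist(lapply(n_links, function(k)
    if (k > 0) sample(fid, k) else character(0)))
  pf <- NULL
  if (length(pf_from) > 0L) {
    pf <- make_edge_df(pf_from, "protein", pf_to, "biological_function",
                       edge_type = "protein_function",
                       source = "<synthetic memberships>")
  }

  build_interactome(pp, pf, ff)
}

#' Plant a disease gene set and molecule target table
#'
#' Samples `n_disease_genes` proteins from one breadth-first ball around
#' a random center (growing the radius until the ball is large enough),
#' defines the disease neighborhood as all proteins within graph
#' distance 2 of a disease gene, and draws molecule target sets:
#' planted molecules take `round(planted_overlap * targets_per_molecule)`
#' targets from the neighborhood — weighted by
#' `params$planted_distance_weights` so that the disease genes
#' themselves are the most likely targets, their direct interactors
#' next, and the distance-2 fringe least — and the rest uniformly;
#' background molecules draw all targets uniformly. Planted molecules
#' are labeled benefit category `a`, background ones `d`. Deterministic
#' given `params$rng_seed`.
#'
#' @param interactome interactome from [generate_interactome()].
#' @param params the same `sim_params`.
#' @return list with `disease_genes` (character), `targets`
#'   (`entity_targets` collection), `labels` (named category vector,
#'   `entity_id -> a/d`), `planted_ids`.
#' @export
plant_disease_and_molecules <- function(interactome, params = sim_params()) {
  stopifnot(inherits(interactome, "interactome"),
            inherits(params, "sim_params"))
  set.seed(stage_seed(params, 1L))

  pp <- interactome$edges[interactome$edges$edge_type == "protein_protein", ]
  proteins <- interactome$nodes$node_id[
    interactome$nodes$node_type == "protein"]
  g <- igraph::graph_from_data_frame(pp[, c("from", "to")], directed = FALSE,
                                     vertices = proteins)

  center <- sample(proteins, 1)
  radius <- 1L
  repeat {
    ball <- names(igraph::ego(g, order = radius, nodes = center)[[1]])
    if (length(ball) >= params$n_disease_genes) break
    if (radius > length(proteins)) {
      stop("graph too small for the requested disease gene count",
           call. = FALSE)
    }
    radius <- radius + 1L
  }
  disease_genes <- sort(sample(ball, params$n_disease_genes))

  # neighborhood shells at graph distance 0 / 1 / 2 from the disease genes
  d1 <- setdiff(unique(unlist(lapply(
    igraph::ego(g, order = 1L, nodes = disease_genes), names))),
    disease_genes)
  d2 <- setdiff(unique(unlist(lapply(
    igraph::ego(g, order = 2L, nodes = disease_genes), names))),
    c(disease_genes, d1))
  nbhd <- c(disease_genes, d1, d2)
  nbhd_w <- rep(params$planted_distance_weights,
                c(length(disease_genes), length(d1), length(d2)))

  n_in <- round(params$planted_overlap * params$targets_per_molecule)
  n_in <- max(1L, min(n_in, params$targets_per_molecule, length(nbhd)))
  mid <- molecule_ids(params$n_molecules)
  planted_ids <- mid[seq_len(params$n_planted)]

  draw_targets <- function(is_planted) {
    if (is_planted) {
      inside <- sample(nbhd, n_in, prob = nbhd_w)
      rest <- params$targets_per_molecule - n_in
      outside <- if (rest > 0)
        sample(setdiff(proteins, inside), rest) else character(0)
      sort(c(inside, outside))
    } else {
      sort(sample(proteins, params$targets_per_molecule))
    }
  }
  target_sets <- lapply(seq_along(mid),
                        function(i) draw_targets(i <= params$n_planted))

  targets <- lapply(seq_along(mid), function(i) {
    structure(list(entity_id = mid[i],
                   entity_name = paste0("molecule_", mid[i]),
                   entity_class = "bioactive_molecule",
                   target_ids = target_sets[[i]],
                   unresolved_ids = character(0)),
              class = "entity_targets")
  })
  names(targets) <- mid

  labels <- structure(ifelse(mid %in% planted_ids, "a", "d"), names = mid)
  list(disease_genes = disease_genes, targets = targets,
       labels = labels, planted_ids = planted_ids)
}

#' Generate a complete synthetic benchmark instance
#'
#' Convenience wrapper: [generate_interactome()] plus
#' [plant_disease_and_molecules()].
#'
#' @param params a `sim_params`.
#' @return list with `interactome`, `disease_genes`, `targets`, `labels`,
#'   `planted_ids`, `params`.
#' @export
simulate_benchmark <- function(params = sim_params()) {
  interactome <- generate_interactome(params)
  planted <- plant_disease_and_molecules(interactome, params)
  c(list(interactome = interactome, params = params), planted)
}

#' Write a benchmark instance as the on-disk fixture bundle
#'
#' Writes the exact TSV dialects the readers consume: the three typed
#' edge lists, the entity-target table, the disease gene list, and the
#' benefit categorization table. A fresh pipeline run on the bundle
#' reproduces the in-memory objects exactly.
#'
#' @param bench list from [simulate_benchmark()] (or the same pieces
#'   assembled by hand).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- bench$interactome$edges
  paths <- c(ppi = file.path(dir, "protein_protein.tsv"),
             pf = file.path(dir, "protein_function.tsv"),
             ff = file.path(dir, "function_function.tsv"),
             targets = file.path(dir, "targets.tsv"),
             disease = file.path(dir, "disease_genes.txt"),
             categories = file.path(dir, "categories.tsv"))
  for (et in .edge_types) {
    sub <- e[e$edge_type == et, , drop = FALSE]
    if (nrow(sub) > 0L) {
      key <- c(protein_protein = "ppi", protein_function = "pf",
               function_function = "ff")[[et]]
      write_edge_list(sub, paths[[key]])
    }
  }
  rows <- do.call(rbind, lapply(bench$targets, function(x)
    data.frame(entity_id = x$entity_id, entity_name = x$entity_name,
               protein_id = x$target_ids, stringsAsFactors = FALSE)))
  utils::write.table(rows, paths[["targets"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(bench$disease_genes, paths[["disease"]])
  utils::write.table(
    data.frame(entity_id = names(bench$labels),
               category = unname(bench$labels), stringsAsFactors = FALSE),
    paths[["categories"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a fixture bundle back into benchmark objects
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `interactome`, `targets`, `disease_genes`, `labels`.
#' @export
read_fixture <- function(dir) {
  pp <- read_edge_list(file.path(dir, "protein_protein.tsv"),
                       "protein_protein")
  pf_path <- file.path(dir, "protein_function.tsv")
  ff_path <- file.path(dir, "function_function.tsv")
  pf <- if (file.exists(pf_path)) read_edge_list(pf_path, "protein_function")
  ff <- if (file.exists(ff_path)) read_edge_list(ff_path, "function_function")
  interactome <- build_interactome(pp, pf, ff)
  targets <- read_entity_targets(file.path(dir, "targets.tsv"))
  disease <- read_disease_genes(file.path(dir, "disease_genes.txt"))
  labels <- read_benefit_categories(file.path(dir, "categories.tsv"))
  list(interactome = interactome, targets = targets,
       disease_genes = disease$gene_id, labels = labels)
}
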