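#' Run the full propagation-and-ranking pipeline
#'
#' Builds the disease seed vector and one seed vector per entity,
#' propagates all of them in one batch to diffusion profiles, and ranks
#' entities by cosine similarity to the disease profile. Entities with
#' zero resolved targets are excluded from the ranking and reported via
#' a warning (from [resolve_targets()]) and the `excluded` field.
#'
#' @param interactome an `interactome`.
#' @param targets `entity_targets` collection (resolved or not; targets
#'   are resolved against `interactome` here).
#' @param disease_genes character vector (or data frame from
#'   [read_disease_genes()]) of disease gene ids.
#' @param params a `walk_params`.
#' @param keep_profiles if `TRUE`, the returned object carries the dense
#'   profile matrix (one column per entity) for downstream explanation.
#' @return list with `ranked` (a `ranked_list`), `disease_profile`,
#'   `disease_seed`, `elbow` (the [detect_elbow()] result on the sorted
#'   similarity curve, or `NULL` if the curve has no positive drop),
#'   `excluded` (entity ids with no resolvable target), and optionally
#'   `profiles` / `seeds`.
#' @export
rank_molecules <- function(interactome, targets, disease_genes,
                           params = walk_params(), keep_profiles = FALSE) {
  if (is.data.frame(disease_genes)) disease_genes <- disease_genes$gene_id
  targets <- suppressWarnings(resolve_targets(targets, interactome))
  n_targets <- vapply(targets, function(e) length(e$target_ids), integer(1))
  excluded <- names(targets)[n_targets == 0L]
  if (length(excluded) > 0L) {
    warning("excluding ", length(excluded),
            " entit(y/ies) with no resolvable target: ",
            paste(utils::head(excluded, 10L), collapse = ", "),
            call. = FALSE)
  }
  usable <- targets[n_targets > 0L]
  if (length(usable) == 0L) stop("no entity has a resolvable target",
                                 call. = FALSE)

  disease_seed <- make_seed_vector(interactome, disease_genes)
  seeds <- lapply(usable, function(e)
    make_seed_vector(interactome, e$target_ids))

  op <- build_transition_operator(interactome, params)
  n <- interactome$n_nodes
  P0 <- vapply(c(list(disease = disease_seed), seeds),
               function(s) s$values / s$n_seeds, numeric(n))
  P <- propagate_matrix(op, P0, params)
  dp_d <- P[, 1]
  PM <- P[, -1, drop = FALSE]

  sims <- as.vector(crossprod(PM, dp_d)) /
    (sqrt(colSums(PM^2)) * sqrt(sum(dp_d^2)))
  sims <- pmin(pmax(sims, 0), 1)

  ranked <- make_ranked_list(names(usable), sims, usable)
  elbow <- tryCatch(detect_elbow(ranked$similarity),
                    error = function(e) NULL)

  out <- list(ranked = ranked,
              disease_profile = new_diffusion_profile(dp_d,
                                                      op$node_ids,
                                                      disease_seed),
              disease_seed = disease_seed,
              elbow = elbow,
              excluded = excluded)
  if (keep_profiles) {
    colnames(PM) <- names(usable)
    out$profiles <- PM
    out$seeds <- seeds
    out$operator <- op
  }
  out
}
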