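#' Rank entities by similarity to a disease diffusion profile
#'
#' Computes the cosine similarity of every entity's diffusion profile to
#' the disease profile and sorts descending. Exact ties are broken
#' lexicographically by `entity_id` (C locale), so the ranking is fully
#' deterministic and invariant to input order.
#'
#' @param profiles named list of `diffusion_profile` objects (names are
#'   entity ids), all over the same interactome.
#' @param disease_profile the disease `diffusion_profile`.
#' @param entities optional collection of `entity_targets` supplying
#'   `entity_name` / `entity_class` per id; defaults to the id itself and
#'   `"bioactive_molecule"`.
#' @param disease_id label stored on the result.
#' @return object of class `ranked_list`: data frame with columns `rank`,
#'   `entity_id`, `entity_name`, `entity_class`, `similarity`, plus
#'   attribute `disease_id`.
#' @export
rank_entities <- function(profiles, disease_profile, entities = NULL,
                          disease_id = "disease") {
  if (length(profiles) == 0L) stop("empty profile map", call. = FALSE)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("profiles must be a named list (entity ids)", call. = FALSE)
  }
  sims <- vapply(profiles, cosine_similarity, numeric(1),
                 dp_d = disease_profile)
  make_ranked_list(names(profiles), sims, entities, disease_id)
}

# internal constructor shared with the pipeline (which computes similarities
# in one matrix product rather than per-profile)
make_ranked_list <- function(entity_ids, similarities, entities = NULL,
                             disease_id = "disease") {
  name_of <- function(id) {
    e <- entities[[id]]
    if (is.null(e)) id else e$entity_name
  }
  class_of <- function(id) {
    e <- entities[[id]]
    if (is.null(e)) "bioactive_molecule" else e$entity_class
  }
  ord <- order(-similarities, entity_ids, method = "radix")
  out <- data.frame(rank = seq_along(ord),
                    entity_id = entity_ids[ord],
                    entity_name = vapply(entity_ids[ord], name_of, character(1)),
                    entity_class = vapply(entity_ids[ord], class_of, character(1)),
                    similarity = unname(similarities[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "disease_id") <- disease_id
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Detect the elbow in a sorted similarity curve
#'
#' Locates the cutoff separating top candidates from the remainder of a
#' non-increasing score sequence. The default `"max_gap"` method returns
#' the position of the largest successive drop (`argmax_i s_i - s_{i+1}`,
#' first index on ties), directly operationalizing a substantial drop in
#' the similarity curve. The `"chord"` method (kneedle-style) returns the
#' point of maximum vertical distance below the chord joining the first
#' and last scores, for sensitivity analysis on smoother curves.
#'
#' @param scores non-increasing numeric vector, length >= 3.
#' @param method `"max_gap"` (default) or `"chord"`.
#' @return object of class `elbow_result`: list with `cut_index` (1-based
#'   rank after which the drop occurs), `drop_magnitude`, `method`.
#' @export
detect_elbow <- function(scores, method = c("max_gap", "chord")) {
  method <- match.arg(method)
  n <- length(scores)
  if (n < 3L) stop("need at least 3 scores", call. = FALSE)
  gaps <- -diff(scores)
  if (any(gaps < -1e-12)) {
    stop("scores must be non-increasing", call. = FALSE)
  }
  gaps <- pmax(gaps, 0)
  if (all(gaps == 0)) stop("no elbow: constant score sequence", call. = FALSE)
  if (method == "max_gap") {
    cut <- which.max(gaps)  # first index on ties
    drop <- gaps[cut]
  } else {
    chord <- scores[1] + (scores[n] - scores[1]) *
      (seq_len(n) - 1) / (n - 1)
    below <- chord - scores
    knee <- which.max(below)
    # the knee point sits just past a cliff; the cut is the last rank kept,
    # i.e. whichever side of the knee carries the larger drop
    cut <- if (knee > 1L && gaps[knee - 1L] >= gaps[min(knee, n - 1L)])
      knee - 1L else min(knee, n - 1L)
    if (gaps[cut] == 0) {  # flat around the knee: fall back to the max gap
      cut <- which.max(gaps)
    }
    drop <- gaps[cut]
  }
  structure(list(cut_index = as.integer(cut), drop_magnitude = drop,
                 method = method),
            class = "elbow_result")
}

#' @exportS3Method base::print
print.elbow_result <- function(x, ...) {
  cat("elbow (", x$method, "): cut after rank ", x$cut_index,
      ", drop ", format(x$drop_magnitude), "\n", sep = "")
  invisible(x)
}

#' Group ranked entities into classes by identical target sets
#'
#' Pharmacological agents that target exactly the same proteins have the
#' same seed vector, hence the same diffusion profile and similarity
#' score; they form one class. Classes are ordered by shared similarity
#' descending (ties by first member id).
#'
#' @param entities collection of resolved `entity_targets`.
#' @param ranked a `ranked_list` covering the entities.
#' @return data frame with columns `class_id`, `member_count`, `members`
#'   (comma-joined entity ids), `target_set` (comma-joined protein ids),
#'   `similarity`.
#' @export
group_by_target_set <- function(entities, ranked) {
  ids <- ranked$entity_id
  missing <- ids[!ids %in% names(entities)]
  if (length(missing) > 0L) {
    stop("ranked entities without a target set: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  keys <- vapply(ids, function(id)
    paste(sort(entities[[id]]$target_ids), collapse = ","), character(1))
  sims <- ranked$similarity
  names(sims) <- ids
  groups <- split(ids, keys)
  cls <- lapply(groups, function(members) {
    members <- sort(members)
    s <- sims[members]
    if (diff(range(s)) > 1e-12) {
      warning("members of one target-set class differ in similarity by ",
              format(diff(range(s))), call. = FALSE)
    }
    list(members = members, similarity = unname(s[1]),
         target_set = paste(sort(entities[[members[1]]]$target_ids),
                            collapse = ","))
  })
  ord <- order(-vapply(cls, `[[`, numeric(1), "similarity"),
               vapply(cls, function(g) g$members[1], character(1)),
               method = "radix")
  cls <- cls[ord]
  data.frame(class_id = seq_along(cls),
             member_count = vapply(cls, function(g) length(g$members),
                                   integer(1)),
             members = vapply(cls, function(g)
               paste(g$members, collapse = ","), character(1)),
             target_set = vapply(cls, `[[`, character(1), "target_set"),
             similarity = vapply(cls, `[[`, numeric(1), "similarity"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a ranking to CSV
#'
#' Columns `rank,entity_id,entity_name,entity_class,similarity`, with the
#' similarity printed to 6 decimal places.
#'
#' @param ranked a `ranked_list`.
#' @param path output path.
#' @export
write_ranking <- function(ranked, path) {
  out <- as.data.frame(ranked)
  out$similarity <- sprintf("%.6f", out$similarity)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
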