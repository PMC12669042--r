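#' Read a benefit categorization table
#'
#' TSV with columns `entity_id`, `category`, where the category is one of
#' the four literature-review classes: `a` (potential therapeutic
#' benefit), `b` (found in food items showing potential therapeutic
#' benefit), `c` (harmful / not beneficial), `d` (no supporting
#' literature). Categories `a` and `b` count as beneficial in the
#' enrichment test; `c` and `d` as not beneficial.
#'
#' @param path file path.
#' @return named character vector: `entity_id -> category`.
#' @export
read_benefit_categories <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("entity_id", "category") %in% names(df))) {
    stop("malformed header in ", path,
         ": expected columns entity_id, category", call. = FALSE)
  }
  bad <- !df$category %in% c("a", "b", "c", "d")
  if (any(bad)) {
    stop("invalid categor(y/ies) in ", path, ": ",
         paste(unique(df$category[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$entity_id)) {
    stop("duplicate entity_id in ", path, call. = FALSE)
  }
  structure(df$category, names = df$entity_id)
}

beneficial_categories <- c("a", "b")

#' Build the 2x2 benefit contingency table at a ranking cut
#'
#' Row 1 counts beneficial / not-beneficial entities among ranks
#' `1..cut`; row 2 among ranks `cut+1..cut+window`. Beneficial means
#' category `a` or `b` in the categorization.
#'
#' @param ranked a `ranked_list`.
#' @param categories named character vector from
#'   [read_benefit_categories()] (or equivalent).
#' @param cut number of top ranks in the first group.
#' @param window number of ranks in the comparison group.
#' @return 2x2 integer matrix with dimnames
#'   `list(c("top", "next"), c("beneficial", "not_beneficial"))`.
#' @export
build_contingency <- function(ranked, categories, cut, window) {
  cut <- as.integer(cut)
  window <- as.integer(window)
  if (cut < 1L || window < 1L) stop("cut and window must be >= 1",
                                    call. = FALSE)
  if (cut + window > nrow(ranked)) {
    stop("cut + window (", cut + window, ") exceeds ranking length (",
         nrow(ranked), ")", call. = FALSE)
  }
  ids <- ranked$entity_id[seq_len(cut + window)]
  cats <- categories[ids]
  if (any(is.na(cats))) {
    stop("uncategorized entit(y/ies) in ranks 1..", cut + window, ": ",
         paste(utils::head(ids[is.na(cats)], 10L), collapse = ", "),
         call. = FALSE)
  }
  ben <- cats %in% beneficial_categories
  top <- seq_len(cut)
  tab <- matrix(c(sum(ben[top]), sum(!ben[top]),
                  sum(ben[-top]), sum(!ben[-top])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("top", "next"),
                                c("beneficial", "not_beneficial")))
  storage.mode(tab) <- "integer"
  tab
}

#' Exact Fisher test for benefit enrichment in the top group
#'
#' Exact hypergeometric computation on a 2x2 table with rows (top group,
#' next group) and columns (beneficial, not beneficial), conditioning on
#' the margins. `"greater"` returns the upper-tail probability of at
#' least the observed top-group beneficial count; `"two_sided"` sums the
#' probabilities of all outcomes no more likely than the observed one
#' (with the conventional 1e-7 relative tolerance on "no more likely").
#' Hypergeometric terms are evaluated in log-gamma form (via
#' [stats::dhyper()]), with no asymptotic approximation.
#'
#' @param table 2x2 nonnegative integer matrix (both row sums > 0).
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return the p-value, a number in (0, 1].
#' @export
fisher_exact <- function(table, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0)) stop("both row sums must be > 0", call. = FALSE)
  if (any(colSums(tab) == 0)) {
    warning("degenerate margins (a zero column): p = 1", call. = FALSE)
    return(1)
  }
  a <- tab[1, 1]                 # beneficial in top group
  m <- sum(tab[, 1])             # total beneficial
  n <- sum(tab[, 2])             # total not beneficial
  k <- sum(tab[1, ])             # top-group size
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  if (alternative == "greater") {
    p <- sum(probs[support >= a])
  } else {
    p_obs <- stats::dhyper(a, m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Direct gene-overlap baseline similarity
#'
#' The standard propagation-free baseline: cosine similarity of the two
#' binary indicator vectors, `|T intersect D| / sqrt(|T| * |D|)`. Zero
#' exactly when the target set and the disease gene set do not intersect,
#' so "non-zero baseline similarity" means "targets at least one disease
#' gene directly".
#'
#' @param targets set (character vector) of protein ids.
#' @param disease_genes set (character vector) of disease gene ids.
#' @return score in \[0, 1\].
#' @export
overlap_similarity <- function(targets, disease_genes) {
  targets <- unique(targets)
  disease_genes <- unique(disease_genes)
  if (length(targets) == 0L || length(disease_genes) == 0L) {
    stop("empty input set", call. = FALSE)
  }
  length(intersect(targets, disease_genes)) /
    sqrt(length(targets) * length(disease_genes))
}

#' Count shared entities between the tops of two rankings
#'
#' @param ranking_a,ranking_b `ranked_list` objects.
#' @param k_a,k_b how deep to look into each ranking.
#' @return the number of entity ids appearing in both top segments.
#' @export
top_k_overlap <- function(ranking_a, ranking_b, k_a, k_b) {
  if (k_a > nrow(ranking_a) || k_b > nrow(ranking_b)) {
    stop("k exceeds ranking length", call. = FALSE)
  }
  length(intersect(ranking_a$entity_id[seq_len(k_a)],
                   ranking_b$entity_id[seq_len(k_b)]))
}

#' Ranking AUC of a positive set by exhaustive pair counting
#'
#' Probability that a uniformly chosen positive entity outranks
#' (strictly higher similarity than) a uniformly chosen negative one,
#' with ties counted 1/2 — the Wilcoxon/Mann-Whitney statistic computed
#' by exhaustive pair counting over the ranking.
#'
#' @param ranked a `ranked_list`.
#' @param positive_ids entity ids of the positive (e.g. planted) set.
#' @return AUC in \[0, 1\].
#' @export
ranking_auc <- function(ranked, positive_ids) {
  pos <- ranked$entity_id %in% positive_ids
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative entity", call. = FALSE)
  }
  # midranks on similarity handle exact ties at 1/2
  r <- rank(ranked$similarity, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compare rankings from the full disease gene list and a subset
#'
#' Runs the whole propagation + ranking pipeline twice — once seeded with
#' the full disease gene list, once with a subset (e.g. only the
#' well-evidenced genes) — and reports top-k overlaps between the two
#' rankings plus, for each gene list, how many molecules retain a
#' non-zero direct-overlap baseline score.
#'
#' @param interactome an `interactome`.
#' @param targets resolved `entity_targets` collection.
#' @param full_gene_list,subset_gene_list character vectors of disease
#'   gene ids; the subset must be contained in the full list (after
#'   resolution).
#' @param params a `walk_params`.
#' @param k_pairs list of `c(k_full, k_subset)` pairs for
#'   [top_k_overlap()].
#' @return list with `ranked_full`, `ranked_subset`, `overlaps` (data
#'   frame `k_full`, `k_subset`, `overlap`), and `baseline_nonzero`
#'   (named counts of molecules with non-zero overlap similarity under
#'   each gene list).
#' @export
subset_robustness <- function(interactome, targets, full_gene_list,
                              subset_gene_list, params = walk_params(),
                              k_pairs = list(c(10, 10), c(20, 10))) {
  full_res <- make_seed_vector(interactome, full_gene_list)
  sub_res <- make_seed_vector(interactome, subset_gene_list)
  full_resolved <- setdiff(full_gene_list, full_res$missing_ids)
  sub_resolved <- setdiff(subset_gene_list, sub_res$missing_ids)
  if (!all(sub_resolved %in% full_resolved)) {
    stop("subset gene list is not contained in the full list after resolution",
         call. = FALSE)
  }
  ranked_full <- rank_molecules(interactome, targets, full_gene_list,
                                params)$ranked
  ranked_subset <- rank_molecules(interactome, targets, subset_gene_list,
                                  params)$ranked
  overlaps <- do.call(rbind, lapply(k_pairs, function(ks) {
    data.frame(k_full = ks[1], k_subset = ks[2],
               overlap = top_k_overlap(ranked_full, ranked_subset,
                                       ks[1], ks[2]))
  }))
  nz <- function(genes) {
    sum(vapply(targets, function(e) {
      length(e$target_ids) > 0L &&
        overlap_similarity(e$target_ids, genes) > 0
    }, logical(1)))
  }
  list(ranked_full = ranked_full,
       ranked_subset = ranked_subset,
       overlaps = overlaps,
       baseline_nonzero = c(full = nz(full_resolved),
                            subset = nz(sub_resolved)))
}
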