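# In-code fixtures shared across test files.

edge_df <- function(from, to, edge_type) {
  data.frame(from = from, to = to, edge_type = edge_type,
             stringsAsFactors = FALSE)
}

# undirected path graph P1 - P2 - ... - Pn of protein nodes
path_interactome <- function(n) {
  ids <- sprintf("P%d", seq_len(n))
  build_interactome(edge_df(ids[-n], ids[-1], "protein_protein"))
}

# small mixed interactome: proteins P1-P2-P3 (path), functions F1 -> F2
# (child -> parent), membership P2 - F1
mixed_interactome <- function() {
  build_interactome(
    edge_df(c("P1", "P2"), c("P2", "P3"), "protein_protein"),
    edge_df("P2", "F1", "protein_function"),
    edge_df("F1", "F2", "function_function"))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

edge_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("node_1\tnode_1_type\tnode_2\tnode_2_type", rows), path)
  path
}

# independent Fisher oracle: exhaustive hypergeometric enumeration with
# plain binomial coefficients (no dhyper)
fisher_oracle <- function(tab, alternative = "greater") {
  a <- tab[1, 1]
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# small random interactome for propagation property tests
random_interactome <- function(n_proteins = 40, n_functions = 8, seed = 1) {
  generate_interactome(sim_params(
    n_proteins = n_proteins, n_functions = n_functions,
    n_molecules = 1, n_planted = 0, n_disease_genes = min(5, n_proteins),
    targets_per_molecule = min(5, n_proteins), rng_seed = seed))
}
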