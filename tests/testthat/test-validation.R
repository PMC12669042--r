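ranked_fixture <- function(categories) {
  n <- length(categories)
  out <- data.frame(rank = seq_len(n),
                    entity_id = sprintf("m%02d", seq_len(n)),
                    entity_name = sprintf("m%02d", seq_len(n)),
                    entity_class = "bioactive_molecule",
                    similarity = seq(0.9, 0.1, length.out = n),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  list(ranked = out,
       categories = stats::setNames(categories, out$entity_id))
}

test_that("build_contingency counts beneficial molecules per rank window", {
  # 13 of the top 15 beneficial, 2 of the next 15
  cats <- c(rep("a", 10), rep("b", 3), rep("c", 2),
            rep("d", 13), rep("a", 2))[c(1:13, 14:15, 16:28, 29:30)]
  fx <- ranked_fixture(c(rep("a", 13), "c", "c", rep("d", 13), "a", "b"))
  tab <- build_contingency(fx$ranked, fx$categories, cut = 15, window = 15)
  expect_equal(unname(tab), matrix(c(13L, 2L, 2L, 13L), 2, byrow = TRUE))

  # all beneficial
  fx2 <- ranked_fixture(rep("a", 10))
  tab2 <- build_contingency(fx2$ranked, fx2$categories, 5, 5)
  expect_equal(unname(tab2), matrix(c(5L, 0L, 5L, 0L), 2, byrow = TRUE))

  expect_error(build_contingency(fx2$ranked, fx2$categories, 6, 5),
               "exceeds")
  # uncategorized entity in range is an error naming it
  cats <- fx2$categories[-3]
  expect_error(build_contingency(fx2$ranked, cats, 5, 5), "m03")
})

test_that("fisher_exact reproduces hand-enumerated tail probabilities", {
  # (C(15,13)C(15,2) + C(15,14)C(15,1) + C(15,15)C(15,0)) / C(30,15)
  tab <- matrix(c(13, 2, 2, 13), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab, "greater"), 11251 / 155117520,
               tolerance = 1e-12)
  expect_lt(fisher_exact(tab, "greater"), 1e-4)

  expect_equal(fisher_exact(matrix(c(0, 15, 15, 0), 2, byrow = TRUE),
                            "greater"), 1)
  expect_equal(fisher_exact(matrix(c(15, 0, 0, 15), 2, byrow = TRUE),
                            "greater"), 1 / 155117520, tolerance = 1e-12)

  expect_warning(p <- fisher_exact(matrix(c(0, 3, 0, 3), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 3), 2, byrow = TRUE)),
               "row sums")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("fisher_exact agrees with enumeration over all margins, N <= 40", {
  # exhaustive brute-force oracle over every feasible table; one relative
  # error bound per total so the check stays fast
  for (N in c(8, 17, 26, 33, 40)) {
    worst <- 0
    for (k in 1:(N - 1)) {        # top-group size
      for (m in 1:(N - 1)) {      # beneficial column total
        n <- N - m
        support <- max(0, k - n):min(k, m)
        for (a in support) {
          tab <- matrix(c(a, k - a, m - a, n - (k - a)), 2, byrow = TRUE)
          p <- fisher_exact(tab, "greater")
          q <- fisher_oracle(tab, "greater")
          worst <- max(worst, abs(p - q) / q)
        }
      }
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("two-sided fisher_exact matches stats::fisher.test", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + c(1, 0, 0, 1), 2)
    if (any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab, "two_sided"),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact(tab, "greater"),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("two-sided p is invariant to simultaneous row and column swaps", {
  set.seed(11)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact(tab, "two_sided"),
                 fisher_exact(swapped, "two_sided"), tolerance = 1e-12)
  }
})

test_that("hypergeometric outcome probabilities sum to one", {
  for (N in c(10, 25, 40)) {
    m <- N %/% 3; n <- N - m; k <- N %/% 2
    support <- max(0, k - n):min(k, m)
    expect_lt(abs(sum(stats::dhyper(support, m, n, k)) - 1), 1e-12)
  }
})

test_that("overlap similarity is the binary cosine of the two sets", {
  expect_equal(overlap_similarity(c("g1", "g2"), c("g2", "g3")), 1 / 2)
  expect_equal(overlap_similarity(c("g1"), c("g2")), 0)
  expect_equal(overlap_similarity(c("g1", "g2"), c("g1", "g2")), 1)
  expect_error(overlap_similarity(character(0), "g1"), "empty")
  # positive exactly when the sets intersect
  set.seed(5)
  pool <- sprintf("g%d", 1:30)
  for (i in 1:50) {
    a <- sample(pool, sample(1:8, 1))
    b <- sample(pool, sample(1:8, 1))
    expect_identical(overlap_similarity(a, b) > 0,
                     length(intersect(a, b)) > 0)
  }
})

test_that("top_k_overlap counts shared ids between ranking heads", {
  fx <- ranked_fixture(rep("a", 10))
  expect_equal(top_k_overlap(fx$ranked, fx$ranked, 10, 10), 10L)
  other <- fx$ranked
  other$entity_id <- sprintf("q%02d", 1:10)
  expect_equal(top_k_overlap(fx$ranked, other, 5, 5), 0L)
  mixed <- fx$ranked
  mixed$entity_id <- c("m03", "q1", "q2", sprintf("q%02d", 3:9))
  expect_equal(top_k_overlap(fx$ranked, mixed, 3, 2), 1L)
  expect_error(top_k_overlap(fx$ranked, fx$ranked, 11, 5), "exceeds")
})

test_that("subset_robustness with subset == full reproduces the ranking", {
  b <- simulate_benchmark(sim_params(n_proteins = 150, n_molecules = 30,
                                     rng_seed = 21))
  res <- subset_robustness(b$interactome, b$targets, b$disease_genes,
                           b$disease_genes, walk_params(k = 300),
                           k_pairs = list(c(5, 5), c(10, 10)))
  expect_equal(res$overlaps$overlap, c(5L, 10L))
  expect_equal(res$ranked_full$entity_id, res$ranked_subset$entity_id)
  expect_equal(res$baseline_nonzero[["full"]],
               res$baseline_nonzero[["subset"]])

  expect_error(
    subset_robustness(b$interactome, b$targets, b$disease_genes[1:7],
                      b$disease_genes, walk_params(k = 100)),
    "not contained")
})

test_that("rankings stay stable under random disease-gene subsetting", {
  hits <- vapply(1:10, function(s) {
    b <- simulate_benchmark(sim_params(n_proteins = 250, rng_seed = 400 + s))
    set.seed(900 + s)
    subset <- sample(b$disease_genes, 7)
    res <- subset_robustness(b$interactome, b$targets, b$disease_genes,
                             subset, walk_params(k = 300),
                             k_pairs = list(c(10, 10)))
    res$overlaps$overlap[1] >= 5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("benefit categorization tables read and validate", {
  f <- write_tsv_lines(c("entity_id\tcategory", "m1\ta", "m2\td"))
  cats <- read_benefit_categories(f)
  expect_equal(cats[["m1"]], "a")
  bad <- write_tsv_lines(c("entity_id\tcategory", "m1\tx"))
  expect_error(read_benefit_categories(bad), "invalid")
  dup <- write_tsv_lines(c("entity_id\tcategory", "m1\ta", "m1\tb"))
  expect_error(read_benefit_categories(dup), "duplicate")
})

test_that("ranking AUC counts discordant pairs exhaustively", {
  fx <- ranked_fixture(rep("a", 6))
  # positives at ranks 1-2 of 6: AUC = 1
  expect_equal(ranking_auc(fx$ranked, c("m01", "m02")), 1)
  # positive at the bottom: AUC = 0
  expect_equal(ranking_auc(fx$ranked, "m06"), 0)
  # hand-counted mixed case: positives at ranks 1 and 4 of 6
  # pairs won: rank1 beats all 4 negatives, rank4 beats 2 -> 6/8
  expect_equal(ranking_auc(fx$ranked, c("m01", "m04")), 6 / 8)
  expect_error(ranking_auc(fx$ranked, "zz"), "at least one")
})
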