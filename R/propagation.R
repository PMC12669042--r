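#' Random-walk parameters
#'
#' Parameters of the biased random walk with restarts. `weights` sets one
#' positive bias per traversal type; the unnormalized weight of every
#' allowed move i -> j is the weight of its traversal type, and rows of the
#' transition operator are then normalized to sum to one. Traversal types:
#' `pp` (protein to protein), `pf` (protein into the function layer), `fp`
#' (function back to protein), `ff_up` (function child to parent in the
#' hierarchy), `ff_down` (parent to child).
#'
#' Defaults are neutral (all weights 1, restart 0.15, 1000 steps); optimized
#' per-type probabilities from an external calibration can be supplied when
#' reproducing real-data rankings.
#'
#' @param r restart probability in (0, 1].
#' @param k number of propagation steps (>= 1).
#' @param weights named positive numeric with names `pp`, `pf`, `fp`,
#'   `ff_up`, `ff_down`.
#' @param dangling what a walker at a node with no outgoing edge does:
#'   `"restart"` (teleport to the seed distribution, the default) or
#'   `"self_loop"` (stay in place).
#' @return object of class `walk_params`.
#' @export
walk_params <- function(r = 0.15, k = 1000,
                        weights = c(pp = 1, pf = 1, fp = 1,
                                    ff_up = 1, ff_down = 1),
                        dangling = c("restart", "self_loop")) {
  dangling <- match.arg(dangling)
  if (!(is.numeric(r) && length(r) == 1L && r > 0 && r <= 1)) {
    stop("r must be a single probability in (0, 1]", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  need <- c("pp", "pf", "fp", "ff_up", "ff_down")
  if (!all(need %in% names(weights))) {
    stop("weights must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(weights[need])) || any(weights[need] <= 0)) {
    stop("all bias weights must be positive and finite", call. = FALSE)
  }
  structure(list(r = r, k = k, weights = weights[need], dangling = dangling),
            class = "walk_params")
}

#' Build the type-biased row-stochastic transition operator
#'
#' Expands each interactome edge into its allowed traversals (undirected
#' edges both ways; hierarchy edges both ways with distinct up/down
#' weights), weights each traversal by its type, and row-normalizes.
#' Rows with no outgoing mass (isolated nodes) are flagged as dangling and
#' left all-zero; [propagate()] handles them per `params$dangling`.
#'
#' @param interactome an `interactome`.
#' @param params a `walk_params`.
#' @return object of class `transition_operator`: list with `W` (sparse
#'   row-stochastic N x N `dgCMatrix` aligned to the interactome node
#'   index), `dangling` (integer positions), `node_ids`.
#' @export
build_transition_operator <- function(interactome, params = walk_params()) {
  stopifnot(inherits(interactome, "interactome"),
            inherits(params, "walk_params"))
  w <- params$weights
  e <- interactome$edges
  i_from <- node_index(interactome, e$from)
  i_to <- node_index(interactome, e$to)

  trav_w <- function(et) {
    switch(et,
           protein_protein   = c(w[["pp"]], w[["pp"]]),
           protein_function  = c(w[["pf"]], w[["fp"]]),  # stored protein-first
           function_function = c(w[["ff_up"]], w[["ff_down"]]))  # child-first
  }
  ww <- t(vapply(e$edge_type, trav_w, numeric(2)))
  ii <- c(i_from, i_to)
  jj <- c(i_to, i_from)
  xx <- c(ww[, 1], ww[, 2])

  n <- interactome$n_nodes
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  rs <- Matrix::rowSums(A)
  dangling <- which(rs == 0)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(n, inv) %*% A
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  structure(list(W = W, dangling = dangling,
                 node_ids = interactome$nodes$node_id),
            class = "transition_operator")
}

# internal: pull a plain values vector out of profile-like input
profile_values <- function(x) {
  if (inherits(x, c("diffusion_profile", "seed_vector"))) x$values
  else as.numeric(x)
}

#' Propagate seed mass to a diffusion profile
#'
#' Runs the biased random walk with restarts for a fixed number of steps
#' `k`: starting from the uniform distribution over the seed nodes
#' (`p0`), iterates `p <- (1 - r) * step(p) + r * p0`, where `step`
#' applies the transition operator and redirects mass sitting on dangling
#' nodes according to `params$dangling`. The result is the entity's
#' diffusion profile: a probability distribution over all interactome
#' nodes recording where the walk spends its time. Convergence to the
#' stationary profile is geometric with rate `1 - r`, so `k = 1000` is far
#' beyond convergence for any practical restart probability.
#'
#' @param operator a `transition_operator`.
#' @param seed a `seed_vector` over the same interactome.
#' @param params a `walk_params`.
#' @return object of class `diffusion_profile`: list with `values`
#'   (nonnegative, sums to 1), `node_ids`, `source` (the seed).
#' @export
propagate <- function(operator, seed, params = walk_params()) {
  stopifnot(inherits(operator, "transition_operator"),
            inherits(seed, "seed_vector"))
  n <- nrow(operator$W)
  if (length(seed$values) != n) {
    stop("operator/seed dimension mismatch: ", n, " vs ",
         length(seed$values), call. = FALSE)
  }
  p0 <- seed$values / seed$n_seeds
  P <- propagate_matrix(operator, matrix(p0, ncol = 1), params)
  new_diffusion_profile(as.vector(P), operator$node_ids, seed)
}

# internal workhorse: propagate many seed columns at once.
# P0: dense N x M matrix, one seed distribution per column.
propagate_matrix <- function(operator, P0, params) {
  W <- operator$W
  dang <- operator$dangling
  r <- params$r
  P <- P0
  for (t in seq_len(params$k)) {
    Q <- as.matrix(Matrix::crossprod(W, P))
    if (length(dang) > 0L) {
      if (params$dangling == "restart") {
        dm <- colSums(P[dang, , drop = FALSE])
        Q <- Q + P0 * rep(dm, each = nrow(P0))
      } else {
        Q[dang, ] <- Q[dang, , drop = FALSE] + P[dang, , drop = FALSE]
      }
    }
    P <- (1 - r) * Q + r * P0
  }
  P
}

new_diffusion_profile <- function(values, node_ids, source = NULL) {
  structure(list(values = values, node_ids = node_ids, source = source),
            class = "diffusion_profile")
}

#' @exportS3Method base::print
print.diffusion_profile <- function(x, ...) {
  cat("diffusion profile over ", length(x$values), " nodes (sum = ",
      format(sum(x$values)), ")\n", sep = "")
  invisible(x)
}

#' Exact stationary profile by dense linear solve
#'
#' Independent oracle for [propagate()]: solves the fixed-point system
#' `p = (1 - r) * step(p) + r * p0` directly with a dense LU
#' factorization, including the same dangling-node redirection. Intended
#' for verification on small graphs (a dense N x N solve), capped at
#' 2000 nodes.
#'
#' @inheritParams propagate
#' @param r restart probability; `dangling` policy is taken from `params`
#'   if supplied.
#' @param params optional `walk_params` (only `r` and `dangling` are used).
#' @return a `diffusion_profile` holding the exact fixed point.
#' @export
stationary_oracle <- function(operator, seed, r = 0.15,
                              params = NULL) {
  stopifnot(inherits(operator, "transition_operator"),
            inherits(seed, "seed_vector"))
  dangling_policy <- "restart"
  if (!is.null(params)) {
    r <- params$r
    dangling_policy <- params$dangling
  }
  n <- nrow(operator$W)
  if (n > 2000L) stop("stationary_oracle is a dense solve; N <= 2000 only",
                      call. = FALSE)
  if (length(seed$values) != n) {
    stop("operator/seed dimension mismatch", call. = FALSE)
  }
  p0 <- seed$values / seed$n_seeds
  M <- t(as.matrix(operator$W))
  if (length(operator$dangling) > 0L) {
    if (dangling_policy == "restart") {
      M[, operator$dangling] <- M[, operator$dangling, drop = FALSE] + p0
    } else {
      M[cbind(operator$dangling, operator$dangling)] <- 1
    }
  }
  A <- diag(n) - (1 - r) * M
  p <- tryCatch(solve(A, r * p0),
                error = function(e) stop("singular stationary system: ",
                                         conditionMessage(e), call. = FALSE))
  new_diffusion_profile(as.vector(p), operator$node_ids, seed)
}

#' Cosine similarity of two diffusion profiles
#'
#' Returns `sum(x * y) / (||x|| * ||y||)`. For valid (nonnegative)
#' diffusion profiles the score lies in \[0, 1\]: 1 when the two walks
#' visit the interactome identically, 0 when their supports are disjoint.
#'
#' @param dp_m,dp_d `diffusion_profile` objects or plain nonnegative
#'   numeric vectors of equal length.
#' @return similarity score in \[0, 1\].
#' @export
cosine_similarity <- function(dp_m, dp_d) {
  x <- profile_values(dp_m)
  y <- profile_values(dp_d)
  if (length(x) != length(y)) {
    stop("profile length mismatch: ", length(x), " vs ", length(y),
         call. = FALSE)
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm profile", call. = FALSE)
  min(max(sum(x * y) / (nx * ny), 0), 1)
}

#' Export / import a diffusion profile as TSV
#'
#' Writes `node_id<TAB>value` in node-index order with full precision
#' (17 significant digits), so a read-back is bit-exact.
#'
#' @param profile a `diffusion_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "diffusion_profile"))
  out <- data.frame(node_id = profile$node_ids,
                    value = sprintf("%.17g", profile$values),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param path path to a profile TSV.
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character"))
  new_diffusion_profile(as.numeric(df$value), df$node_id)
}
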