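#' Third-order adjacency tensor of a multiplex network
#'
#' Stacks the L symmetric layer weight matrices into a sparse representation of
#' the n x n x L tensor T with t_ijk = e^k(i,j) for layer edges and 0
#' elsewhere. Stored as one sparse matrix per layer; absent pairs are not
#' stored.
#'
#' @param net A \code{multiplex_network}.
#' @return Object of class \code{adjacency_tensor} with fields \code{mats}
#'   (list of L symmetric \code{dgCMatrix}), \code{n}, \code{L},
#'   \code{universe}.
#' @export
build_adjacency_tensor <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  mats <- lapply(net$layers, layer_matrix)
  structure(list(mats = mats, n = n_proteins(net$universe),
                 L = length(mats), universe = net$universe),
            class = "adjacency_tensor")
}

#' @export
print.adjacency_tensor <- function(x, ...) {
  nz <- vapply(x$mats, function(m) length(m@x), integer(1))
  cat("adjacency_tensor: n =", x$n, ", L =", x$L,
      ", stored entries per layer:", paste(nz, collapse = ", "), "\n")
  invisible(x)
}

#' Probability transition tensors of the higher-order walk
#'
#' Builds the two fiber-normalized tensors driving the coupled walk:
#' \itemize{
#'   \item T(1): for each (j, k), t1_ijk = t_ijk / sum_i t_ijk, giving the
#'     probability of stepping to node i from node j through layer k. Fibers
#'     with zero sum (node j isolated in layer k) fall back to the uniform
#'     1/n distribution; these "dangling" fibers are stored as a flag per
#'     (j, k), never densified.
#'   \item T(2): for each (i, j), t2_ijk = t_ijk / sum_k t_ijk, giving the
#'     probability of the pair (i, j) being linked through layer k. Pairs
#'     adjacent in no layer (including the diagonal) fall back to uniform 1/L,
#'     handled in closed form via the complement of the union adjacency
#'     pattern.
#' }
#' Both families of fibers sum to 1 exactly by construction.
#'
#' @param tensor An \code{adjacency_tensor}.
#' @return Object of class \code{transition_tensors}: \code{t1} (list of L
#'   column-stochastic-on-support \code{dgCMatrix}), \code{dangling} (list of L
#'   logical vectors over columns), \code{t2} (list of L triplet data.frames
#'   i, j, p over each layer's support), \code{adj_pairs} (two-column integer
#'   matrix: all (i, j) with an edge in some layer, both orientations),
#'   \code{n}, \code{L}.
#' @export
build_transition_tensors <- function(tensor) {
  stopifnot(inherits(tensor, "adjacency_tensor"))
  n <- tensor$n; L <- tensor$L
  t1 <- vector("list", L); dangling <- vector("list", L)
  for (k in seq_len(L)) {
    M <- tensor$mats[[k]]
    s <- Matrix::colSums(M)
    dangling[[k]] <- s == 0
    inv <- ifelse(s > 0, 1 / s, 0)
    t1[[k]] <- M %*% Matrix::Diagonal(n, inv)
  }
  # sum over layers per pair, support = union adjacency
  S <- Reduce(`+`, tensor$mats)
  St <- methods::as(S, "TsparseMatrix")
  adj_pairs <- cbind(i = St@i + 1L, j = St@j + 1L)
  pair_sum <- St@x
  key <- (adj_pairs[, "i"] - 1) * n + adj_pairs[, "j"]
  t2 <- vector("list", L)
  for (k in seq_len(L)) {
    Mt <- methods::as(tensor$mats[[k]], "TsparseMatrix")
    ik <- Mt@i + 1L; jk <- Mt@j + 1L
    pos <- match((ik - 1) * n + jk, key)
    t2[[k]] <- data.frame(i = ik, j = jk, p = Mt@x / pair_sum[pos])
  }
  structure(list(t1 = t1, dangling = dangling, t2 = t2,
                 adj_pairs = adj_pairs, n = n, L = L),
            class = "transition_tensors")
}

#' One step of the coupled random walk with restart
#'
#' Applies the two-stage update of the coupled walk:
#' \deqn{x_i \leftarrow \alpha \sum_{j,k} t^{(1)}_{ijk} x_j y_k + (1-\alpha) rv_i}
#' \deqn{y_k \leftarrow \sum_{i,j} t^{(2)}_{ijk} x_i x_j}
#' with y computed from the freshly updated x. Uniform fallback fibers
#' contribute in closed form: for T(1), the mass on dangling columns of layer
#' k spreads as y_k * (dangling mass)/n to every node; for T(2), pairs with no
#' edge in any layer contribute (1/L)((sum x)^2 - sum over adjacent pairs of
#' x_i x_j) to every layer.
#'
#' @param x Node-score vector (length n, nonnegative, sums to 1).
#' @param y Layer-score vector (length L, nonnegative, sums to 1).
#' @param tt A \code{transition_tensors}.
#' @param rv Restart vector (length n, nonnegative, sums to 1).
#' @param alpha Walk probability in (0, 1); 1 - alpha is the restart mass.
#' @return List with updated \code{x} and \code{y}.
#' @export
walk_step <- function(x, y, tt, rv, alpha) {
  stopifnot(inherits(tt, "transition_tensors"))
  n <- tt$n; L <- tt$L
  if (length(rv) != n || any(rv < 0) || abs(sum(rv) - 1) > 1e-8)
    stop("restart vector must be a length-n probability vector")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  xs <- numeric(n)
  for (k in seq_len(L)) {
    xs <- xs + y[k] * as.numeric(tt$t1[[k]] %*% x)
    dm <- sum(x[tt$dangling[[k]]])
    if (dm > 0) xs <- xs + y[k] * dm / n
  }
  x_new <- alpha * xs + (1 - alpha) * rv
  s_adj <- sum(x_new[tt$adj_pairs[, "i"]] * x_new[tt$adj_pairs[, "j"]])
  compl <- sum(x_new)^2 - s_adj
  y_new <- numeric(L)
  for (k in seq_len(L)) {
    tr <- tt$t2[[k]]
    y_new[k] <- sum(tr$p * x_new[tr$i] * x_new[tr$j]) + compl / L
  }
  list(x = x_new, y = y_new)
}

#' Coupled random walk with restart on a multiplex network
#'
#' Iterates \code{\link{walk_step}} from the uniform state X0 = 1/n,
#' Y0 = 1/L until the L1 residual ||X_t - X_{t-1}||_1 + ||Y_t - Y_{t-1}||_1
#' drops below \code{threshold}, or \code{max_iter} is reached. Probability
#' mass is conserved analytically at every step (sum x = sum y = 1), so no
#' renormalization is applied.
#'
#' @param net A \code{multiplex_network} (or a prebuilt
#'   \code{transition_tensors}).
#' @param rv Restart probability vector over the universe (sums to 1).
#' @param alpha Walk probability in (0, 1). Default 0.3.
#' @param threshold L1 stopping threshold. Default 1e-9.
#' @param max_iter Maximum iterations. Default 1000. Non-convergence yields a
#'   warning, not an error: the partial ranking is still returned.
#' @return Object of class \code{walk_result}: \code{x} (named node scores),
#'   \code{y} (layer importances), \code{iterations}, \code{converged},
#'   \code{residual_trace}.
#' @export
run_rwr <- function(net, rv, alpha = 0.3, threshold = 1e-9, max_iter = 1000L) {
  if (inherits(net, "multiplex_network")) {
    ids <- as.character(net$universe)
    tt <- build_transition_tensors(build_adjacency_tensor(net))
  } else if (inherits(net, "transition_tensors")) {
    ids <- NULL
    tt <- net
  } else stop("net must be a multiplex_network or transition_tensors")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (threshold <= 0) stop("threshold must be positive")
  n <- tt$n; L <- tt$L
  x <- rep(1 / n, n); y <- rep(1 / L, L)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    st <- walk_step(x, y, tt, rv, alpha)
    res <- sum(abs(st$x - x)) + sum(abs(st$y - y))
    trace <- c(trace, res)
    x <- st$x; y <- st$y
    if (res < threshold) { converged <- TRUE; break }
  }
  if (!converged)
    warning("random walk did not converge in ", max_iter,
            " iterations (residual ", signif(trace[length(trace)], 3), ")")
  if (!is.null(ids)) names(x) <- ids
  structure(list(x = x, y = y, iterations = it, converged = converged,
                 residual_trace = trace),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat("walk_result:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      "(final residual", signif(x$residual_trace[length(x$residual_trace)], 3),
      ")\n  layer importances y:", paste(signif(x$y, 4), collapse = ", "), "\n")
  invisible(x)
}
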