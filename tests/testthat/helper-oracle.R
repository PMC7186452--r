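# Independent dense oracles for the tensor walk, written as literal
# triple-loop evaluations of the defining sums. Deliberately naive: these
# share no code with the sparse implementation they check.

dense_tensor <- function(net) {
  n <- length(as.character(net$universe))
  L <- length(net$layers)
  Tarr <- array(0, c(n, n, L))
  for (k in seq_len(L)) {
    e <- net$layers[[k]]$edges
    for (r in seq_len(nrow(e))) {
      Tarr[e$i[r], e$j[r], k] <- e$w[r]
      Tarr[e$j[r], e$i[r], k] <- e$w[r]
    }
  }
  Tarr
}

dense_transitions <- function(Tarr) {
  n <- dim(Tarr)[1L]; L <- dim(Tarr)[3L]
  T1 <- array(0, dim(Tarr)); T2 <- array(0, dim(Tarr))
  for (k in seq_len(L)) for (j in seq_len(n)) {
    s <- sum(Tarr[, j, k])
    T1[, j, k] <- if (s > 0) Tarr[, j, k] / s else rep(1 / n, n)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- sum(Tarr[i, j, ])
    T2[i, j, ] <- if (s > 0) Tarr[i, j, ] / s else rep(1 / L, L)
  }
  list(T1 = T1, T2 = T2)
}

dense_walk_step <- function(x, y, T1, T2, rv, alpha) {
  n <- length(x); L <- length(y)
  x_new <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) for (k in seq_len(L))
      acc <- acc + T1[i, j, k] * x[j] * y[k]
    x_new[i] <- alpha * acc + (1 - alpha) * rv[i]
  }
  y_new <- numeric(L)
  for (k in seq_len(L)) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      acc <- acc + T2[i, j, k] * x_new[i] * x_new[j]
    y_new[k] <- acc
  }
  list(x = x_new, y = y_new)
}

dense_rwr <- function(net, rv, alpha, threshold = 1e-9, max_iter = 1000L) {
  Tarr <- dense_tensor(net)
  tt <- dense_transitions(Tarr)
  n <- dim(Tarr)[1L]; L <- dim(Tarr)[3L]
  x <- rep(1 / n, n); y <- rep(1 / L, L)
  for (it in seq_len(max_iter)) {
    st <- dense_walk_step(x, y, tt$T1, tt$T2, rv, alpha)
    res <- sum(abs(st$x - x)) + sum(abs(st$y - y))
    x <- st$x; y <- st$y
    if (res < threshold) break
  }
  list(x = x, y = y)
}

# classical single-matrix RWR: power iteration on the column-normalized
# weight matrix (dangling columns uniform), x <- alpha P x + (1-alpha) rv
classical_rwr <- function(W, rv, alpha, threshold = 1e-12, max_iter = 5000L) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- sum(W[, j])
    P[, j] <- if (s > 0) W[, j] / s else rep(1 / n, n)
  }
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- alpha * as.numeric(P %*% x) + (1 - alpha) * rv
    if (sum(abs(x_new - x)) < threshold) { x <- x_new; break }
    x <- x_new
  }
  x
}

# two-pass brute-force Pearson, the textbook sum formula
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# random multiplex over n nodes, L layers, with weights in (0, 1]
random_multiplex <- function(n, L, density = 0.4, seed = 1) {
  set.seed(seed)
  u <- protein_universe(sprintf("n%03d", seq_len(n)))
  layers <- lapply(seq_len(L), function(k) {
    pairs <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pairs)) < density
    weighted_layer(u, pairs[1L, keep], pairs[2L, keep],
                   stats::runif(sum(keep)), name = paste0("L", k))
  })
  assemble_multiplex(layers)
}

# small deterministic PIN fixtures used across test files
toy_triangle <- function() pin_graph(cbind(c("a", "a", "b"), c("b", "c", "c")))
toy_path <- function() pin_graph(cbind(c("a", "b"), c("b", "c")))
toy_paw <- function() pin_graph(cbind(c("a", "a", "a", "b"), c("b", "c", "d", "c")))

toy_domain_map <- function() {
  # p1: d1 (NP=1) + d2 (NP=2); p2: d2; p3: none
  domain_map(cbind(c("p1", "p1", "p2"), c("d1", "d2", "d2")))
}
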