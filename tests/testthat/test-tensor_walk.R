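test_that("adjacency tensor stores symmetrized layer weights and nothing else", {
  tri <- build_co_neighbor(toy_triangle())
  net1 <- assemble_multiplex(list(tri))
  tens <- build_adjacency_tensor(net1)
  expect_equal(tens$n, 3L); expect_equal(tens$L, 1L)
  M <- tens$mats[[1L]]
  expect_equal(length(M@x), 6L)            # 3 undirected pairs, 2 orientations
  expect_true(all(M@x == 1.0))
  expect_equal(as.matrix(M), t(as.matrix(M)))
  expect_true(all(Matrix::diag(M) == 0))

  # the co-structure toy value carries through to layer 2 of a 3-layer net
  pin <- pin_graph(cbind(c("p1", "p2"), c("p2", "p3")))
  ex <- rbind(p1 = c(1, 2, 3), p2 = c(1, 2, 4), p3 = c(3, 1, 2))
  net3 <- build_multiplex(pin, toy_domain_map(), expression_profile(ex))
  t3 <- build_adjacency_tensor(net3)
  i1 <- universe_index(pin$universe, "p1"); i2 <- universe_index(pin$universe, "p2")
  expect_equal(t3$mats[[2L]][i1, i2], 1/3)

  # empty multiplex -> empty tensor
  u <- protein_universe(c("a", "b"))
  t0 <- build_adjacency_tensor(assemble_multiplex(list(weighted_layer(u))))
  expect_equal(length(t0$mats[[1L]]@x), 0L)
})

test_that("transition tensor fibers are exactly stochastic (hand cases + random nets)", {
  # hand case: column j with weights 0.2 and 0.6 normalizes to 0.25 / 0.75
  u <- protein_universe(c("i1", "i2", "j"))
  lay <- weighted_layer(u, c(1, 2), c(3, 3), c(0.2, 0.6))
  tt <- build_transition_tensors(build_adjacency_tensor(assemble_multiplex(list(lay))))
  jcol <- as.numeric(tt$t1[[1L]][, 3L])
  expect_equal(jcol, c(0.25, 0.75, 0))
  # node with no edges in the layer dangles -> uniform handled via flag
  expect_false(tt$dangling[[1L]][3L])

  # isolated node: its column is flagged uniform
  u2 <- protein_universe(c("a", "b", "c"))
  lay2 <- weighted_layer(u2, 1, 2, 0.5)
  tt2 <- build_transition_tensors(build_adjacency_tensor(assemble_multiplex(list(lay2))))
  expect_true(tt2$dangling[[1L]][3L])

  # pair present in layers 1 and 3 with equal weight splits 0.5 / 0 / 0.5
  l1 <- weighted_layer(u2, 1, 2, 0.5); l3 <- weighted_layer(u2, 1, 2, 0.5)
  l2 <- weighted_layer(u2)
  tt3 <- build_transition_tensors(build_adjacency_tensor(
    assemble_multiplex(list(l1, l2, l3))))
  p12 <- vapply(tt3$t2, function(tr) {
    v <- tr$p[tr$i == 1L & tr$j == 2L]
    if (length(v)) v else 0
  }, numeric(1))
  expect_equal(p12, c(0.5, 0, 0.5))

  # Eq-style stochasticity on random multiplexes, exact to 1e-12
  for (s in 1:8) {
    net <- random_multiplex(n = sample(5:50, 1), L = 3, density = 0.25, seed = s)
    tens <- build_adjacency_tensor(net)
    tt <- build_transition_tensors(tens)
    for (k in 1:3) {
      cs <- Matrix::colSums(tt$t1[[k]])
      cs[tt$dangling[[k]]] <- 1            # uniform fibers sum to n * 1/n
      expect_true(all(abs(cs - 1) < 1e-12))
      expect_true(all(tt$t1[[k]]@x >= 0 & tt$t1[[k]]@x <= 1))
      expect_true(all(tt$t2[[k]]$p >= 0 & tt$t2[[k]]$p <= 1))
    }
    # per adjacent pair, t2 sums to 1 across layers
    key <- paste(tt$adj_pairs[, 1L], tt$adj_pairs[, 2L])
    acc <- setNames(numeric(length(key)), key)
    for (k in 1:3) {
      kk <- paste(tt$t2[[k]]$i, tt$t2[[k]]$j)
      acc[kk] <- acc[kk] + tt$t2[[k]]$p
    }
    expect_true(all(abs(acc - 1) < 1e-12))
  }
})

test_that("walk_step fixed points and symmetries", {
  # n = 1, L = 1: the only distribution is a fixed point
  u1 <- protein_universe("solo")
  tt1 <- build_transition_tensors(build_adjacency_tensor(
    assemble_multiplex(list(weighted_layer(u1)))))
  st <- walk_step(1, 1, tt1, 1, alpha = 0.7)
  expect_equal(st$x, 1); expect_equal(st$y, 1)

  # two identical layers of a symmetric graph keep y = (1/2, 1/2)
  u <- protein_universe(sprintf("p%d", 1:4))
  ring <- weighted_layer(u, c(1, 2, 3, 4), c(2, 3, 4, 1), rep(0.8, 4))
  tt <- build_transition_tensors(build_adjacency_tensor(
    assemble_multiplex(list(ring, ring))))
  x <- rep(0.25, 4); y <- c(0.5, 0.5)
  for (i in 1:5) {
    st <- walk_step(x, y, tt, rep(0.25, 4), alpha = 0.4)
    x <- st$x; y <- st$y
    expect_equal(y, c(0.5, 0.5))
  }

  expect_error(walk_step(x, y, tt, c(1, 1, 1, 1), alpha = 0.4), "probability")
})

test_that("walk_step matches the dense triple-loop oracle to 1e-12", {
  for (s in 1:6) {
    net <- random_multiplex(n = 5, L = 3, density = 0.4, seed = s)
    tens <- build_adjacency_tensor(net)
    tt <- build_transition_tensors(tens)
    dt <- dense_transitions(dense_tensor(net))
    set.seed(s + 100)
    x <- runif(5); x <- x / sum(x)
    y <- runif(3); y <- y / sum(y)
    rv <- runif(5); rv <- rv / sum(rv)
    sp <- walk_step(x, y, tt, rv, alpha = 0.3)
    de <- dense_walk_step(x, y, dt$T1, dt$T2, rv, alpha = 0.3)
    expect_equal(sp$x, de$x, tolerance = 1e-12)
    expect_equal(sp$y, de$y, tolerance = 1e-12)
  }
})

test_that("run_rwr conserves probability mass at every iterate", {
  for (s in 1:5) {
    net <- random_multiplex(n = 12, L = 3, density = 0.3, seed = s)
    tt <- build_transition_tensors(build_adjacency_tensor(net))
    set.seed(s)
    rv <- runif(12); rv <- rv / sum(rv)
    x <- rep(1 / 12, 12); y <- rep(1 / 3, 3)
    for (it in 1:30) {
      st <- walk_step(x, y, tt, rv, alpha = 0.3)
      x <- st$x; y <- st$y
      expect_true(abs(sum(x) - 1) < 1e-9)
      expect_true(abs(sum(y) - 1) < 1e-9)
      expect_true(all(x >= 0) && all(y >= 0))
    }
  }
})

test_that("run_rwr matches the dense oracle end-to-end on small instances", {
  for (s in 1:4) {
    n <- sample(4:8, 1)
    net <- random_multiplex(n = n, L = 3, density = 0.35, seed = s)
    set.seed(s + 50)
    rv <- runif(n); rv <- rv / sum(rv)
    sp <- run_rwr(net, rv, alpha = 0.3, threshold = 1e-12, max_iter = 2000L)
    de <- dense_rwr(net, rv, alpha = 0.3, threshold = 1e-12, max_iter = 2000L)
    expect_true(sp$converged)
    expect_equal(unname(sp$x), de$x, tolerance = 1e-10)
    expect_equal(sp$y, de$y, tolerance = 1e-10)
  }
})

test_that("restart-dominated limit: alpha near 0 drives x to rv", {
  net <- random_multiplex(n = 10, L = 3, density = 0.3, seed = 3)
  set.seed(3)
  rv <- runif(10); rv <- rv / sum(rv)
  res <- run_rwr(net, rv, alpha = 1e-9, threshold = 1e-12)
  expect_true(res$converged)
  expect_equal(unname(res$x), rv, tolerance = 1e-6)
})

test_that("L = 1 multiplex reduces to classical single-matrix RWR", {
  for (s in 1:3) {
    n <- 9L
    net <- random_multiplex(n = n, L = 1, density = 0.3, seed = s)
    set.seed(s + 7)
    rv <- runif(n); rv <- rv / sum(rv)
    res <- run_rwr(net, rv, alpha = 0.3, threshold = 1e-12, max_iter = 5000L)
    W <- as.matrix(dense_tensor(net)[, , 1L])
    xc <- classical_rwr(W, rv, alpha = 0.3)
    expect_equal(res$y, 1)
    expect_equal(unname(res$x), xc, tolerance = 1e-8)
  }
})

test_that("converged state is a fixed point of walk_step", {
  net <- random_multiplex(n = 15, L = 3, density = 0.25, seed = 11)
  tt <- build_transition_tensors(build_adjacency_tensor(net))
  set.seed(11)
  rv <- runif(15); rv <- rv / sum(rv)
  thr <- 1e-9
  res <- run_rwr(net, rv, alpha = 0.3, threshold = thr)
  expect_true(res$converged)
  st <- walk_step(unname(res$x), res$y, tt, rv, alpha = 0.3)
  expect_lt(sum(abs(st$x - unname(res$x))) + sum(abs(st$y - res$y)), thr)
})

test_that("walk is deterministic and reports non-convergence without raising", {
  net <- random_multiplex(n = 10, L = 3, density = 0.3, seed = 5)
  rv <- rep(0.1, 10)
  a <- run_rwr(net, rv, alpha = 0.3)
  b <- run_rwr(net, rv, alpha = 0.3)
  expect_identical(a$x, b$x); expect_identical(a$y, b$y)

  expect_warning(bad <- run_rwr(net, rv, alpha = 0.9, threshold = 1e-15,
                                max_iter = 3L),
                 "did not converge")
  expect_false(bad$converged)
  expect_equal(length(bad$residual_trace), 3L)
})
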