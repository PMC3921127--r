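# Criterion algebra, local moving, sample-and-seed, sequential extraction

test_that("criterion W matches hand-computed and boundary values", {
  net <- triangle_isolate_net()
  expect_equal(criterion_w(net, c("1", "2", "3")), 2)
  expect_equal(criterion_w(net, character(0)), 0)
  expect_equal(criterion_w(net, net$nodes), 0)

  net2 <- two_k4_net()
  expect_equal(criterion_w(net2, paste0("a", 1:4)), 18)
  # exhaustive check: one K4 is the global optimum over all 2^10 subsets
  expect_equal(exhaustive_max_w(adj_matrix(net2)), 18)
})

test_that("criterion W agrees with the full recompute on random states", {
  set.seed(101)
  for (rep in 1:20) {
    net <- er_network(18, 0.25)
    A <- adj_matrix(net)
    x <- random_membership(18)
    expect_equal(criterion_w(net, x), w_recompute(A, x), tolerance = 1e-12)
  }
})

test_that("incremental delta-W equals the recompute difference", {
  net <- triangle_isolate_net()
  expect_equal(delta_w(net, c("1", "2", "3"), "4"), -2)

  set.seed(7)
  for (rep in 1:50) {
    net <- er_network(30, 0.2)
    A <- adj_matrix(net)
    x <- random_membership(30, runif(1, 0.1, 0.9))
    for (v in seq_len(30)) {
      x2 <- x; x2[v] <- 1L - x2[v]
      expect_equal(delta_w(net, x, v),
                   w_recompute(A, x2) - w_recompute(A, x),
                   tolerance = 1e-9)
      # antisymmetry of a difference
      expect_equal(delta_w(net, x2, v), -delta_w(net, x, v),
                   tolerance = 1e-9)
    }
  }
})

test_that("local moving reaches a 1-flip optimum and never lowers W", {
  net <- two_k4_net()
  # a full K4 is already locally optimal
  res <- local_moving(net, paste0("a", 1:4))
  expect_setequal(res$members, paste0("a", 1:4))
  expect_equal(res$W, 18)
  # one member short: converges back to the full K4
  res2 <- local_moving(net, paste0("a", 1:3))
  expect_setequal(res2$members, paste0("a", 1:4))
  expect_equal(res2$W, 18)
  # empty stays empty (adding any node can only lose boundary edges)
  res3 <- local_moving(net, integer(10))
  expect_equal(sum(res3$x), 0)
  expect_equal(res3$W, 0)
})

test_that("local moving is monotone in W and idempotent", {
  set.seed(23)
  for (rep in 1:15) {
    net <- er_network(25, 0.2)
    x0 <- random_membership(25)
    w0 <- criterion_w(net, x0)
    res <- local_moving(net, x0)
    expect_gte(res$W, w0)
    expect_equal(res$W, criterion_w(net, res$x), tolerance = 1e-9)
    # no single flip improves further; rerun is a no-op
    dws <- vapply(seq_len(25), function(v) delta_w(net, res$x, v),
                  numeric(1))
    expect_true(all(dws <= 1e-9))
    res2 <- local_moving(net, res$x)
    expect_identical(res2$x, res$x)
  }
})

test_that("sampling stage never includes isolated nodes in its optima", {
  net <- two_k4_net()
  set.seed(11)
  sam <- sample_stage(net, K = 20, keep_solutions = TRUE)
  expect_equal(unname(sam$f[c("i1", "i2")]), c(0L, 0L))
  expect_equal(dim(sam$solutions), c(20L, 10L))
  # frequencies count membership across the positive-W optima
  expect_equal(unname(sam$f),
               unname(colSums(sam$solutions[sam$W > 0, , drop = FALSE])))
})

test_that("seed probabilities normalise frequencies into a PMF", {
  sp <- seed_probabilities(c(2, 1, 1))
  expect_equal(sp$P, c(0.5, 0.25, 0.25))
  expect_equal(sum(seed_probabilities(rep(3, 7))$P), 1, tolerance = 1e-12)
  sp0 <- seed_probabilities(c(0, 2, 0, 2))
  expect_identical(sp0$P[c(1, 3)], c(0, 0))
  expect_error(seed_probabilities(c(0, 0)), "no module signal")
})

test_that("single-module extraction finds the planted optimum, deterministically", {
  net <- two_k4_net()
  res <- extract_module(net, extraction_config(M = 50, seed = 1))
  expect_equal(res$W, 18)
  expect_true(setequal(res$members, paste0("a", 1:4)) ||
                setequal(res$members, paste0("b", 1:4)))
  res2 <- extract_module(net, extraction_config(M = 50, seed = 1))
  expect_identical(res$x, res2$x)

  edgeless <- module_network(matrix(character(), ncol = 2),
                             nodes = letters[1:5])
  res3 <- extract_module(edgeless, extraction_config(M = 10, seed = 3))
  expect_equal(res3$W, 0)
  expect_length(res3$members, 0)
})

test_that("sequential extraction peels both cliques then stops", {
  net <- two_k4_net()
  ms <- extract_all(net, extraction_config(M = 50, seed = 4))
  expect_equal(length(ms), 2L)
  got <- lapply(ms$modules, sort)
  expect_true(setequal(got[[1]], paste0("a", 1:4)) ||
                setequal(got[[1]], paste0("b", 1:4)))
  expect_true(setequal(sort(unlist(got)), sort(c(paste0("a", 1:4),
                                                 paste0("b", 1:4)))))
  expect_equal(ms$W, c(18, 6))
  expect_true(all(ms$connected))

  edgeless <- module_network(matrix(character(), ncol = 2),
                             nodes = letters[1:6])
  expect_equal(length(extract_all(edgeless,
                                  extraction_config(M = 10, seed = 5))), 0L)
})

test_that("extracted modules are disjoint subsets of the input nodes", {
  set.seed(9)
  for (rep in 1:5) {
    net <- er_network(40, 0.15)
    ms <- extract_all(net, extraction_config(M = 30))
    members <- unlist(ms$modules, use.names = FALSE)
    expect_equal(anyDuplicated(members), 0L)
    expect_true(all(members %in% net$nodes))
    expect_true(all(ms$W > 0))
    expect_true(all(lengths(ms$modules) >= 3L))
  }
})
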