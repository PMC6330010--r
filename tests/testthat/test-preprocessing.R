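test_that("flux variability reproduces the bounded toy polyhedron", {
  toy <- with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10))
  fva <- flux_variability(toy)
  expect_equal(fva$max[fva$reaction == "R2"], 30)
  expect_equal(fva$min[fva$reaction == "R3"], -5)
  expect_equal(fva$max[fva$reaction == "R4"], 10)
  expect_equal(fva$min[fva$reaction == "R5"], -10)
  # the internal cycle is unconstrained by the uptake bounds
  expect_equal(fva$min[fva$reaction == "R4"], -Inf)
  expect_equal(fva$max[fva$reaction == "R5"], Inf)
  expect_equal(fva$max[fva$reaction == "R6"], Inf)
  # unbounded cone
  fva0 <- flux_variability(toy_model())
  expect_equal(fva0$max[fva0$reaction == "R1"], Inf)
})

test_that("flux variability honors an extra equality constraint", {
  toy <- with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10))
  fva <- flux_variability(toy, extra_eq = list(a = c(0, 1, 0, 0, 0, 0), b = 30))
  expect_equal(fva$min[fva$reaction == "R1"], 10)
  expect_equal(fva$max[fva$reaction == "R1"], 10)
  expect_equal(fva$min[fva$reaction == "R3"], 10, tolerance = 1e-6)
})

test_that("make_consistent is idempotent and leaves the toy network unchanged", {
  toy <- toy_model()
  res <- make_consistent(toy)
  expect_length(res$report$removed, 0)
  expect_length(res$report$fixed_forward, 0)
  expect_length(res$report$fixed_backward, 0)
  expect_equal(res$network$N, toy$N)
  res2 <- make_consistent(res$network)
  expect_identical(res2$network, res$network)
})

test_that("dead-end reactions are removed by consistency preprocessing", {
  net <- toy_with_dead_end()
  res <- make_consistent(net)
  expect_identical(res$report$removed, "R7")
  expect_equal(ncol(res$network$N), 6)
  expect_true(is_consistent(res$network))
})

test_that("direction-fixing converts one-way reversible reactions", {
  # A is produced by irreversible R1 and by reversible R2 (written as -> A):
  # mass balance forces R2 backward, so its column is negated and flagged
  # irreversible
  N <- matrix(c(1, 1), 1, 2, dimnames = list("A", c("R1", "R2")))
  net <- metabolic_network(N, reversible = c(FALSE, TRUE))
  res <- make_consistent(net)
  expect_identical(res$report$fixed_backward, "R2")
  expect_false(any(res$network$reversible))
  expect_equal(unname(res$network$N["A", "R2"]), -1)
  expect_equal(res$network$orientation, c(1L, -1L))
  # forward-fix: reversible R2 in a forward-only chain
  N2 <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("R1", "R2")))
  net2 <- metabolic_network(N2, reversible = c(FALSE, TRUE))
  res2 <- make_consistent(net2)
  expect_identical(res2$report$fixed_forward, "R2")
  expect_false(any(res2$network$reversible))
  # topes of re-oriented networks are reported in original orientation
  res_t <- enumerate_topes(res$network)
  expect_identical(tope_pattern_set(res_t$topes), "+-")
})

test_that("nullspace basis is exact with selectable pivot rows", {
  toy <- toy_model()
  K <- nullspace_basis(toy$N, pivots = c(1, 2, 4))
  expect_equal(max(abs(toy$N %*% K)), 0)
  expect_equal(unname(K[c(1, 2, 4), ]), diag(3))
  K_pub <- matrix(c(1, 0, 0, 0, 1, 0, -1/2, 1/2, 0,
                    0, 0, 1, 0, 1, -1, 1, 0, -1), ncol = 3, byrow = TRUE)
  expect_equal(max(abs(K - K_pub)), 0)
  expect_true(attr(nullspace_basis(toy$N), "exact"))
  # trivial nullspace errors
  expect_error(nullspace_basis(diag(3)), "no nonzero flux")
})

test_that("reaction dependencies partition nullspace rows by proportionality", {
  K_toy <- nullspace_basis(toy_model()$N)
  deps <- reaction_dependencies(K_toy)
  expect_equal(deps$r_ind, 6)
  expect_equal(nrow(deps$dependent), 0)
  # unbranched chain: second reaction depends on the first with sign +
  ch <- chain_network()
  deps_ch <- reaction_dependencies(nullspace_basis(ch$N))
  expect_equal(deps_ch$r_ind, 1)
  expect_equal(deps_ch$dependent$rep, 1L)
  expect_equal(deps_ch$dependent$sign, 1L)
  # constructed negative multiple
  K <- rbind(c(1, 0), c(0, 1), c(-2, 0))
  deps_k <- reaction_dependencies(K)
  expect_equal(deps_k$dependent$index, 3L)
  expect_equal(deps_k$dependent$rep, 1L)
  expect_equal(deps_k$dependent$sign, -1L)
  expect_error(reaction_dependencies(rbind(c(1, 0), c(0, 0))), "zero row")
})

test_that("the initial tope of the toy network is all-plus with no flips", {
  root <- initial_tope(toy_model())
  expect_identical(root$tau, rep(1L, 6))
  expect_length(root$flips, 0)
  expect_true(all(root$witness > 0))
  expect_equal(max(abs(toy_model()$N %*% root$witness)), 0, tolerance = 1e-8)
})

test_that("initial topes of random consistent networks certify feasibility", {
  for (s in 1:5) {
    net <- random_network(4, 9, 4, seed = s)
    root <- initial_tope(net)
    expect_true(check_tope_feasible(net, root$tau)$feasible)
    expect_identical(sign_of(root$witness), root$tau)
    # FVA bounds bracket the witness
    fva <- flux_variability(net)
    expect_true(all(root$witness >= fva$min - 1e-8))
    expect_true(all(root$witness <= fva$max + 1e-8))
  }
})

test_that("inconsistent networks are rejected with a pointer to preprocessing", {
  net <- toy_with_dead_end()
  expect_error(initial_tope(net), "make_consistent")
  expect_error(enumerate_topes(net), "consistent")
})
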