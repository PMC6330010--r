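test_that("tope feasibility LP matches the published toy cases", {
  toy <- toy_model()
  chk <- check_tope_feasible(toy, rep(1L, 6))
  expect_true(chk$feasible)
  expect_true(all(chk$witness >= 1e-6 - 1e-12))
  # (R3,R4,R5) = (+,+,-) is not a flux tope
  expect_false(check_tope_feasible(toy, c(1L, 1L, 1L, 1L, -1L, 1L))$feasible)
  # (R3,R4,R5) = (-,-,+) is
  chk2 <- check_tope_feasible(toy, c(1L, 1L, -1L, -1L, 1L, 1L))
  expect_true(chk2$feasible)
  expect_identical(sign_of(chk2$witness), c(1L, 1L, -1L, -1L, 1L, 1L))
  expect_error(check_tope_feasible(toy, c(-1L, 1L, 1L, 1L, 1L, 1L)),
               "irreversible")
  expect_error(check_tope_feasible(toy, c(0L, 1L, 1L, 1L, 1L, 1L)), "full sign")
})

test_that("children flip one independent reversible reaction at a time", {
  toy <- toy_model()
  deps <- reaction_dependencies(nullspace_basis(toy$N))
  kids <- children(rep(1L, 6), deps, toy$reversible)
  expect_length(kids, 3)
  for (k in kids) {
    expect_equal(sum(k < 0), 1)
    expect_true(which(k < 0) %in% c(3, 4, 5))
  }
  # all reversibles already minus: nothing to flip
  expect_length(children(c(1L, 1L, -1L, -1L, -1L, 1L), deps, toy$reversible), 0)
  # dependents flip in lockstep with their representative's coupling sign
  K <- rbind(c(1, 0), c(0, 1), c(-2, 0))
  deps_k <- reaction_dependencies(K)
  kids_k <- children(c(1L, 1L, -1L), deps_k, rep(TRUE, 3))
  flipped_first <- kids_k[[which(vapply(kids_k, function(x) x[1] == -1L, TRUE))]]
  expect_identical(flipped_first, c(-1L, 1L, 1L)) # reaction 3 flips along
})

test_that("the toy flux cone decomposes into exactly the five published topes", {
  res <- enumerate_topes(toy_model())
  expect_equal(nrow(res$topes), 5)
  expect_identical(tope_pattern_set(res$topes), TOY_TOPES)
  # incremental counts by minus level, verified by exhaustive enumeration
  expect_equal(unname(res$incremental_counts[c("0", "1", "2")]), c(1L, 2L, 2L))
  expect_true(res$complete)
  # every witness conforms to its tope
  for (t in seq_len(5)) {
    expect_true(conforms(sign_of(res$witnesses[t, ]),
                         as.integer(res$topes[t, ])))
  }
  # BFS soundness: every non-root tope has a feasible parent one level down
  for (t in which(res$levels > 0)) {
    p <- res$parents[t]
    expect_equal(res$levels[p], res$levels[t] - 1L)
    expect_true(are_adjacent(res$topes[t, ], res$topes[p, ], res$indrev))
  }
})

test_that("adjacency counts positions among independent reversible reactions", {
  res <- enumerate_topes(toy_model())
  pat <- apply(res$topes, 1, function(s) sign_to_string(as.integer(s)))
  i <- function(p) which(pat == p)
  expect_true(are_adjacent(res$topes[i("++++++"), ], res$topes[i("++-+++"), ],
                           res$indrev))
  expect_false(are_adjacent(res$topes[i("++++++"), ], res$topes[i("++-+-+"), ],
                            res$indrev))
  # the two optimal topes are adjacent, separated by the R4 hyperplane
  expect_true(are_adjacent(res$topes[i("+++-++"), ], res$topes[i("++++++"), ],
                           res$indrev))
  expect_error(are_adjacent(c(1L, 1L), c(1L, 1L, -1L)), "length")
})

test_that("BFS equals exhaustive enumeration on random consistent networks", {
  for (s in 1:6) {
    net <- random_network(3 + s %% 3, 8 + s %% 3, 4, seed = 100 + s)
    bfs <- enumerate_topes(net, check_consistent = FALSE)
    oracle <- brute_force_topes(net)
    expect_identical(tope_pattern_set(bfs$topes), tope_pattern_set(oracle))
    expect_true(nrow(bfs$topes) <= tope_upper_bound(length(bfs$indrev)))
    expect_true(bfs$complete)
  }
})

test_that("the tope set is invariant under reaction permutation and column flips", {
  toy <- toy_model()
  # permutation
  perm <- c(4, 1, 6, 3, 2, 5)
  netp <- metabolic_network(toy$N[, perm], reversible = toy$reversible[perm])
  resp <- enumerate_topes(netp)
  expect_equal(nrow(resp$topes), 5)
  back <- resp$topes[, match(toy$reaction_ids, colnames(resp$topes))]
  expect_identical(tope_pattern_set(back), TOY_TOPES)
  # pre-flipping a reversible column re-orients the same five topes
  N2 <- toy$N; N2[, "R5"] <- -N2[, "R5"]
  net2 <- metabolic_network(N2, reversible = toy$reversible)
  res2 <- enumerate_topes(net2)
  expect_equal(nrow(res2$topes), 5)
  M <- res2$topes
  M[, "R5"] <- -M[, "R5"] # undo the flip: same sign patterns
  expect_identical(tope_pattern_set(M), TOY_TOPES)
})

test_that("deterministic output for any thread count and canonical TSV order", {
  toy <- toy_model()
  r1 <- enumerate_topes(toy, threads = 1)
  r2 <- enumerate_topes(toy, threads = 2)
  expect_identical(tope_pattern_set(r1$topes), tope_pattern_set(r2$topes))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_topes(r1, f1); write_topes(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("max_level and limit produce flagged partial results", {
  res <- enumerate_topes(toy_model(), max_level = 1)
  expect_false(res$complete)
  expect_equal(nrow(res$topes), 3) # root + two level-1 topes
  res2 <- enumerate_topes(toy_model(), limit = 2)
  expect_false(res2$complete)
  expect_true(nrow(res2$topes) >= 2)
  # termination is monotone: last recorded level is empty or the search
  # exhausted all independent reversible reactions
  res3 <- enumerate_topes(toy_model())
  last <- res3$incremental_counts[length(res3$incremental_counts)]
  expect_true(last == 0 ||
                as.integer(names(last)) == length(res3$indrev))
})
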