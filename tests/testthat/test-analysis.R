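toy_enum <- function() enumerate_topes(toy_model())

test_that("toy adjacency structure has one central and one peripheral tope", {
  hist <- adjacency_histogram(toy_enum())
  expect_equal(hist$count[hist$neighbors == 3], 1) # most central tope
  expect_equal(hist$count[hist$neighbors == 1], 1) # most peripheral tope
  expect_equal(sum(hist$count), 5) # conservation
  deg <- attr(hist, "per_tope")
  expect_equal(sort(deg), c(1L, 2L, 2L, 2L, 3L))
  # partial enumerations have no defined adjacency structure
  expect_error(adjacency_histogram(enumerate_topes(toy_model(), max_level = 1)),
               "partial")
  # a single-tope network has the degenerate histogram {0: 1}
  h1 <- adjacency_histogram(enumerate_topes(random_network(3, 7, 0, seed = 5)))
  expect_equal(h1$neighbors, 0L)
  expect_equal(h1$count, 1L)
})

test_that("direction frequencies count forward topes per reversible reaction", {
  freq <- direction_frequencies(toy_enum())
  expect_equal(freq$forward_fraction[freq$reaction == "R4"], 3 / 5)
  expect_equal(freq$forward_fraction[freq$reaction == "R3"], 2 / 5)
  expect_equal(freq$forward_fraction[freq$reaction == "R5"], 4 / 5)
  expect_true(all(freq$forward_fraction[!freq$reversible] == 1))
  expect_true(all(freq$forward_fraction >= 0 & freq$forward_fraction <= 1))
  # invariant under reaction relabeling
  toy <- toy_model()
  perm <- c(6, 5, 4, 3, 2, 1)
  netp <- metabolic_network(toy$N[, perm], reversible = toy$reversible[perm])
  freqp <- direction_frequencies(enumerate_topes(netp))
  expect_equal(freqp$forward_fraction[freqp$reaction == "R4"], 3 / 5)
})

test_that("pair-direction counts are conserved and match direct tabulation", {
  res <- toy_enum()
  pd <- pair_direction_matrix(res)
  # for each pair the four combinations partition the five topes
  sums <- tapply(pd$count, paste(pd$reaction_a, pd$reaction_b), sum)
  expect_true(all(sums == 5))
  # direct tabulation over the enumerated topes
  M <- res$topes
  cell <- function(a, b, da, db) {
    pd$count[pd$reaction_a == a & pd$reaction_b == b &
               pd$dir_a == da & pd$dir_b == db]
  }
  expect_equal(cell("R4", "R5", "-", "-"), sum(M[, "R4"] < 0 & M[, "R5"] < 0))
  expect_equal(cell("R4", "R5", "-", "-"), 0L) # infeasible combination
  expect_true(pd$infeasible[pd$reaction_a == "R4" & pd$reaction_b == "R5" &
                              pd$dir_a == "-" & pd$dir_b == "-"])
  expect_equal(cell("R3", "R4", "-", "+"), 2L)
  expect_equal(cell("R3", "R5", "-", "-"), 1L)
  # number of signed pairs among n reversible reactions
  expect_equal(signed_pair_count(27), 1431)
  expect_equal(nrow(pd), 4 * choose(3, 2))
})

test_that("Gaussian extrapolation recovers truncated tope-count totals", {
  a <- 1e6; mu <- 20; sigma <- 4; n_rev <- 40
  counts <- round(a * exp(-((0:n_rev) - mu)^2 / (2 * sigma^2)))
  truth <- sum(counts)
  errs <- vapply(c(12, 16, 20), function(cut) {
    fit <- fit_incremental_gaussian(counts[1:(cut + 1)], levels = 0:cut,
                                    n_total = n_rev)
    abs(fit$total_estimate - truth) / truth
  }, 1)
  expect_true(all(errs < 0.5))
  expect_true(errs[3] <= errs[1])
  # full information: estimate matches the observed total
  fit_full <- fit_incremental_gaussian(counts, n_total = n_rev)
  expect_equal(fit_full$total_estimate, truth, tolerance = 0.01)
  expect_gte(fit_full$total_estimate, fit_full$observed_total)
  expect_gt(fit_full$sigma, 0)
})

test_that("degenerate count profiles are flagged or rejected", {
  expect_error(fit_incremental_gaussian(c(5, 3, 1)), "at least 4")
  flat <- tryCatch(fit_incremental_gaussian(rep(7, 10)), error = function(e) e)
  if (inherits(flat, "error")) {
    expect_match(conditionMessage(flat), "fit|converge|degenerate")
  } else {
    expect_gt(flat$sigma, 10) # flagged by an implausibly wide curve
  }
})

test_that("parameter recovery improves with the number of observed levels", {
  set.seed(99)
  rel_err <- function(cut, noisy) {
    fit <- tryCatch(fit_incremental_gaussian(noisy[1:(cut + 1)],
                                             levels = 0:cut, n_total = 30),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$total_estimate - sum(noisy)) / sum(noisy)
  }
  errs <- replicate(20, {
    counts <- round(1e4 * exp(-((0:30) - 15)^2 / (2 * 3^2)))
    noisy <- pmax(0, round(counts * exp(stats::rnorm(31, 0, 0.1))))
    c(rel_err(10, noisy), rel_err(18, noisy))
  })
  expect_lt(stats::median(errs[2, ], na.rm = TRUE),
            stats::median(errs[1, ], na.rm = TRUE))
})

test_that("plot builders return ggplot objects", {
  res <- toy_enum()
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  counts <- round(50 * exp(-((0:10) - 5)^2 / 4))
  expect_s3_class(ggplot2::autoplot(fit_incremental_gaussian(counts)), "ggplot")
  expect_s3_class(plot_pair_directions(pair_direction_matrix(res)), "ggplot")
})

test_that("tidiers summarize enumerations and fits as tibbles", {
  res <- toy_enum()
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_true(all(nchar(td$pattern) == 6))
  gl <- glance(res)
  expect_equal(gl$n_topes, 5)
  expect_equal(gl$upper_bound, 8)
  es <- enumerate_efms_via_topes(toy_model())
  te <- tidy(es)
  expect_equal(nrow(te), 6)
  expect_true("n_topes" %in% names(te))
  fit <- fit_incremental_gaussian(round(50 * exp(-((0:10) - 5)^2 / 4)))
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(nrow(glance(fit)), 1)
})
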