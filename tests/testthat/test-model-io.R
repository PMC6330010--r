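test_that("toy network has the published stoichiometry and nullspace", {
  toy <- toy_model()
  expect_equal(dim(toy$N), c(3, 6))
  expect_equal(unname(toy$N[, "R3"]), c(0, 0, 2))
  expect_equal(sum(toy$reversible), 3)
  expect_identical(toy$reaction_ids[toy$reversible], c("R3", "R4", "R5"))
  # published nullspace basis (identity at rows R1, R2, R4)
  K_pub <- matrix(c(1, 0, 0,
                    0, 1, 0,
                    -1/2, 1/2, 0,
                    0, 0, 1,
                    0, 1, -1,
                    1, 0, -1), ncol = 3, byrow = TRUE)
  expect_equal(max(abs(toy$N %*% K_pub)), 0)
  K <- nullspace_basis(toy$N)
  expect_equal(ncol(K), 3)
  expect_equal(qr(cbind(K, K_pub))$rank, 3) # same column space
})

test_that("models round-trip through JSON and TSV", {
  toy <- with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10))
  toy$objective <- c(0, 1, 0, 0, 0, 0)
  for (fmt in c("json", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_model(toy, f, fmt)
    back <- read_model(f, fmt)
    expect_equal(unname(back$N[toy$metabolite_ids, toy$reaction_ids]),
                 unname(toy$N))
    expect_identical(back$reversible, toy$reversible)
    expect_equal(back$lb, toy$lb)
    expect_equal(back$ub, toy$ub)
    expect_equal(back$objective, toy$objective)
  }
})

test_that("SBML models are read with boundary species dropped", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="mini">
  <listOfSpecies>
   <species id="A" boundaryCondition="false"/>
   <species id="B" boundaryCondition="false"/>
   <species id="X" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <listOfReactants><speciesReference species="X" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R2" reversible="true">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
   </reaction>
   <reaction id="R3" reversible="false">
    <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  net <- read_model(f, "sbml")
  expect_identical(net$metabolite_ids, c("A", "B"))
  expect_identical(net$reaction_ids, c("R1", "R2", "R3"))
  expect_equal(unname(net$N), matrix(c(1, 0, -1, 2, 0, -1), 2, 3))
  expect_identical(net$reversible, c(FALSE, TRUE, FALSE))
})

test_that("degenerate model files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list("A"), reactions = list()), f)
  expect_error(read_model(f, "json"), "empty reaction list")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list("A"),
    reactions = list(list(id = "R1", stoich = list(A = 1), reversible = FALSE),
                     list(id = "R1", stoich = list(A = -1), reversible = FALSE))),
    f2, auto_unbox = TRUE)
  expect_error(read_model(f2, "json"), "duplicate reaction id")
})

test_that("random networks are reproducible, consistent and integer-valued", {
  n1 <- random_network(3, 8, 3, seed = 42)
  n2 <- random_network(3, 8, 3, seed = 42)
  expect_identical(n1, n2)
  n3 <- random_network(3, 8, 3, seed = 43)
  expect_false(identical(n1, n3))
  for (s in 1:5) {
    net <- random_network(3 + s %% 3, 8 + s %% 4, 3, seed = s)
    expect_true(all(net$N == round(net$N)))
    expect_true(max(abs(net$N)) <= 3)
    expect_true(is_consistent(net))
    expect_true(all(colSums(net$N != 0) > 0))
  }
})

test_that("a network without reversible reactions has exactly one tope", {
  net <- random_network(3, 7, 0, seed = 5)
  res <- enumerate_topes(net)
  expect_equal(nrow(res$topes), 1)
  expect_equal(res$levels, 0L)
})

test_that("topes and EFMs round-trip through their TSV dialects", {
  res <- enumerate_topes(toy_model())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topes(res, f)
  back <- read_topes(f)
  expect_equal(nrow(back), 5)
  expect_identical(colnames(back), paste0("R", 1:6))
  expect_setequal(tope_pattern_set(back), tope_pattern_set(res$topes))
  # empty set: header only
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_topes(matrix(integer(0), 0, 6,
                     dimnames = list(NULL, paste0("R", 1:6))), f2)
  expect_length(readLines(f2), 1)
  expect_equal(nrow(read_topes(f2)), 0)
  # canonical row order: byte-identical regardless of input row order
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_topes(res$topes[5:1, ], f3)
  expect_identical(readLines(f), readLines(f3))
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_efms(enumerate_efms_via_topes(toy_model()), fe)
  lines <- readLines(fe)
  expect_length(lines, 7)
  expect_identical(lines[1], paste(paste0("R", 1:6), collapse = "\t"))
})
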