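two_step_chain <- function() {
  data.frame(reaction_id = c("r1", "r2"), ec = c("e1", "e2"),
             substrates = I(list("A", "B")), products = I(list("B", "C")),
             reversible = FALSE, stringsAsFactors = FALSE)
}

test_that("the EIN follows the +1 product / -1 substrate convention", {
  M <- build_ein(two_step_chain())
  expect_equal(unclass(M)[c("A", "B", "C"), c("e1", "e2")],
               matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
                      dimnames = list(c("A", "B", "C"), c("e1", "e2"))),
               ignore_attr = TRUE)

  # additivity: two reactions of one function both producing B
  rx <- data.frame(reaction_id = c("r1", "r2"), ec = "e1",
                   substrates = I(list("A", "C")), products = I(list("B", "B")),
                   reversible = FALSE)
  expect_equal(unclass(build_ein(rx))["B", "e1"], 2)

  # substrate equal to product cancels (and leaves an all-zero column)
  rx2 <- data.frame(reaction_id = "r1", ec = "e1",
                    substrates = I(list("A")), products = I(list("A")),
                    reversible = FALSE)
  expect_warning(M2 <- build_ein(rx2), "all-zero")
  expect_equal(unclass(M2)["A", "e1"], 0)
})

test_that("EIN construction is additive over reaction-list unions and
           antisymmetric under side swapping", {
  set.seed(21)
  funs <- paste0("e", 1:5); mets <- paste0("C", 1:8)
  for (rep in 1:5) {
    r1 <- random_reactions(6, funs, mets)
    r2 <- random_reactions(5, funs, mets)
    r2$reaction_id <- paste0(r2$reaction_id, "b")
    both <- rbind(r1, r2)
    M <- suppressWarnings(build_ein(both))
    M1 <- suppressWarnings(build_ein(r1))
    M2 <- suppressWarnings(build_ein(r2))
    acc <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
    acc[rownames(M1), colnames(M1)] <- acc[rownames(M1), colnames(M1)] + M1
    acc[rownames(M2), colnames(M2)] <- acc[rownames(M2), colnames(M2)] + M2
    expect_equal(unclass(M), acc, ignore_attr = TRUE)

    swapped <- both
    swapped$substrates <- both$products
    swapped$products <- both$substrates
    expect_equal(unclass(suppressWarnings(build_ein(swapped))),
                 -unclass(M), ignore_attr = TRUE)

    # against the naive per-reaction loop oracle
    expect_equal(unclass(M), ein_oracle(both), ignore_attr = TRUE)
  }
})

test_that("per-function normalization divides columns by their nonzero count", {
  M0 <- build_ein(two_step_chain())
  Mn <- build_ein(two_step_chain(), normalize = "per_function")
  nz <- colSums(unclass(M0) != 0)
  expect_equal(unclass(Mn), sweep(unclass(M0), 2, nz, "/"),
               ignore_attr = TRUE)
})

test_that("reversible reactions can be mirrored", {
  rx <- data.frame(reaction_id = "r1", ec = "e1",
                   substrates = I(list("A")), products = I(list("B")),
                   reversible = TRUE)
  Mf <- build_ein(rx, reversible = "forward")
  expect_equal(unclass(Mf)[, "e1"], c(A = -1, B = 1))
  expect_warning(Mb <- build_ein(rx, reversible = "both"), "all-zero")
  expect_equal(unclass(Mb)[, "e1"], c(A = 0, B = 0))
})

test_that("restricting to an allowed function set matches a brute-force filter
           and commutes with EIN construction", {
  set.seed(31)
  funs <- paste0("e", 1:4); mets <- paste0("C", 1:6)
  rx <- random_reactions(10, funs, mets)
  allowed <- c("e1", "e3")

  sub <- subset_network(rx, allowed)
  expect_equal(nrow(sub), sum(rx$ec %in% allowed))

  expect_identical(subset_network(rx, funs), rx)
  expect_warning(empty <- subset_network(rx, character(0)), "no reactions")
  expect_equal(nrow(empty), 0L)

  # equivalence: subset-then-build equals column-select + row-prune
  M_full <- suppressWarnings(build_ein(rx))
  M_sub <- suppressWarnings(build_ein(sub))
  sel <- unclass(M_full)[, intersect(colnames(M_full), allowed), drop = FALSE]
  sel <- sel[rownames(sel) %in% rownames(M_sub), , drop = FALSE]
  expect_equal(unclass(M_sub), sel[rownames(M_sub), colnames(M_sub)],
               ignore_attr = TRUE)
})

test_that("transporter-ligand matrices validate and round-trip", {
  toy <- generate_worked_example()
  f <- tempfile()
  write_interaction_matrix(toy$transportome, f)
  back <- load_transportome(f)
  expect_equal(unclass(back), unclass(toy$transportome), ignore_attr = TRUE)
  expect_identical(attr(back, "mode_tag"), "transportome")

  # ligands A and B are moved by t1
  expect_equal(unclass(back)[c("A", "B"), "t1"], c(A = 1, B = 1))
  expect_equal(sum(unclass(back)["A", ]), 1)

  bad <- unclass(toy$transportome)
  bad["A", "t1"] <- 2
  f2 <- tempfile()
  write_interaction_matrix(bad, f2)
  expect_error(load_transportome(f2), "row 'A', column 't1'")

  # duplicate row ids are fatal
  txt <- readLines(f)
  writeLines(c(txt, txt[2]), f2)
  expect_error(load_transportome(f2), "duplicate")
})

test_that("reaction lists round-trip through the five-column dialect", {
  set.seed(41)
  rx <- random_reactions(8, paste0("e", 1:3), paste0("C", 1:5))
  f <- tempfile()
  write_reactions(rx, f)
  back <- read_reactions(f)
  expect_equal(back$reaction_id, rx$reaction_id)
  expect_equal(back$ec, rx$ec)
  expect_equal(unclass(back$substrates), unclass(rx$substrates),
               ignore_attr = TRUE)
  expect_equal(unclass(back$products), unclass(rx$products),
               ignore_attr = TRUE)
  expect_equal(back$reversible, rx$reversible)

  # a reaction with no metabolites at all is fatal for EIN construction
  rx$substrates[[1]] <- character(0)
  rx$products[[1]] <- character(0)
  expect_error(suppressWarnings(build_ein(rx)), "no metabolites")
})
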