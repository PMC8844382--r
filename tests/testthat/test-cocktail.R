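test_that("heuristic search seeds unique lysers then greedily extends by EI", {
  # a generalist covering everything wins alone
  cells <- cbind(G = rep(1, 5), n1 = c(1, 0, 0, 0, 0), n2 = c(0, 1, 0, 0, 0),
                 n3 = c(0, 0, 1, 0, 0))
  rownames(cells) <- paste0("b", 1:5)
  h <- heuristic_cocktail(build_pbin(cells))
  expect_identical(h$phages, "G")
  expect_true(h$complete)

  # identity: every bacterium has a unique lyser, all phages are mandatory
  id3 <- build_pbin(structure(diag(3), dimnames = list(paste0("b", 1:3),
                                                       paste0("p", 1:3))))
  h3 <- heuristic_cocktail(id3)
  expect_setequal(h3$phages, paste0("p", 1:3))
  expect_identical(h3$size, 3L)

  # worked matrix: no unique lysers; greedy takes A, then B (adds b5),
  # then C (adds b6)
  hw <- heuristic_cocktail(build_pbin(worked_matrix()))
  expect_identical(hw$phages, c("A", "B", "C"))
  expect_identical(hw$size, 3L)
  expect_true(hw$complete)
})

test_that("exhaustive search returns the MCS with a non-decreasing trace", {
  e <- exhaustive_cocktail(build_pbin(worked_matrix()))
  expect_identical(e$size, 2L)
  expect_true(e$complete)
  expect_identical(e$n_covered, 6L)
  expect_identical(e$per_size_trace$best_coverage, c(4L, 6L))
  expect_true(all(diff(e$per_size_trace$best_coverage) >= 0))

  id4 <- build_pbin(structure(diag(4), dimnames = list(paste0("b", 1:4),
                                                       paste0("p", 1:4))))
  expect_identical(exhaustive_cocktail(id4)$size, 4L)

  nested <- build_pbin(nested_matrix(10, 5, fill = 0.4, seed = 3))
  en <- exhaustive_cocktail(nested)
  expect_identical(en$size, 1L)
  expect_identical(oracle_mcs(nested$matrix$binary), 1L)
})

test_that("equal-coverage ties resolve to the lexicographically first subset", {
  # on the worked matrix both {A,D} and {B,C} cover all six bacteria at
  # size 2; standard combination order visits (A,D) before (B,C)
  e <- exhaustive_cocktail(build_pbin(worked_matrix()))
  expect_identical(e$phages, c("A", "D"))
})

test_that("the admissible bound never changes the result", {
  for (seed in 1:20) {
    pbin <- build_pbin(random_matrix(7, 7, fill = 0.15 + 0.03 * seed,
                                     seed = 1000 + seed))
    ep <- exhaustive_cocktail(pbin, prune = TRUE)
    eu <- exhaustive_cocktail(pbin, prune = FALSE)
    expect_identical(ep$size, eu$size)
    expect_identical(ep$phages, eu$phages)
    expect_identical(ep$per_size_trace, eu$per_size_trace)
  }
})

test_that("the size cap yields the best incomplete cocktail", {
  id5 <- build_pbin(structure(diag(5), dimnames = list(paste0("b", 1:5),
                                                       paste0("p", 1:5))))
  e <- exhaustive_cocktail(id5, max_size = 3)
  expect_false(e$complete)
  expect_identical(e$size, 3L)
  expect_identical(e$n_covered, 3L)
  expect_error(exhaustive_cocktail(id5, max_size = 0), "positive")
})

test_that("method comparison reports a non-negative size gap", {
  cmp <- compare_methods(build_pbin(worked_matrix()))
  expect_identical(cmp$gap, 1L)
  expect_true(cmp$both_complete)

  nested <- build_pbin(nested_matrix(8, 4, fill = 0.5, seed = 5))
  expect_identical(compare_methods(nested)$gap, 0L)

  zero <- build_pbin(matrix(0, 3, 3, dimnames = list(paste0("b", 1:3),
                                                     paste0("p", 1:3))))
  cz <- compare_methods(zero)
  expect_identical(cz$heuristic_size, 0L)
  expect_identical(cz$exhaustive_size, 0L)
  expect_identical(cz$gap, 0L)
  expect_true(cz$both_complete)
})

test_that("MCS matches the brute-force oracle and bounds the heuristic", {
  for (seed in 1:40) {
    fill <- 0.1 + 0.8 * (seed %% 8) / 8
    hrm <- random_matrix(2 + seed %% 7, 2 + (seed * 3) %% 7, fill = fill,
                         seed = 5000 + seed)
    pbin <- build_pbin(hrm)
    e <- exhaustive_cocktail(pbin)
    h <- heuristic_cocktail(pbin)
    expect_identical(e$size, oracle_mcs(hrm$binary))
    expect_true(h$size >= e$size)
    expect_true(h$complete && e$complete)
    if (e$complete)
      expect_setequal(e$covered_bacteria,
                      bacteria_ids(pbin)[pbin$in_degree >= 1])
  }
})

test_that("MCS is permutation invariant and monotone under added coverage", {
  for (seed in 1:10) {
    hrm <- random_matrix(6, 6, fill = 0.35, seed = 300 + seed)
    bin <- hrm$binary
    mcs <- exhaustive_cocktail(build_pbin(hrm))$size
    perm <- bin[sample(6), sample(6)] * 1
    expect_identical(exhaustive_cocktail(build_pbin(perm))$size, mcs)

    # adding a lytic cell on an already-susceptible bacterium cannot make
    # the cover harder
    susc <- which(rowSums(bin) > 0)
    open <- which(bin[susc, , drop = FALSE] == 0, arr.ind = TRUE)
    if (length(susc) && nrow(open)) {
      bin2 <- bin
      bin2[susc[open[1, 1]], open[1, 2]] <- 1L
      expect_lte(exhaustive_cocktail(build_pbin(bin2 * 1))$size, mcs)
    }
  }
})
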