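test_that("PCN extraction counts cocktail indegrees over susceptible bacteria", {
  pbin <- build_pbin(worked_matrix())
  pcn_bc <- extract_pcn(pbin, c("B", "C"))
  expect_identical(sort(pcn_bc$bacteria), paste0("b", 1:6))
  expect_true(all(pcn_bc$cocktail_indegree == 1))

  pcn_abc <- extract_pcn(pbin, c("A", "B", "C"))
  expect_equal(unname(pcn_abc$cocktail_indegree[paste0("b", 1:6)]),
               c(2, 2, 2, 2, 1, 1))

  # single-phage cocktail: every covered bacterium has exactly one lyser
  single <- extract_pcn(pbin, "A")
  expect_true(all(single$cocktail_indegree[c("b1", "b2", "b3", "b4")] == 1))

  expect_error(extract_pcn(pbin, c("A", "Z")), "not in the network")

  # resistant bacteria stay out of the PCN
  cells <- rbind(worked_matrix()$cells, b7 = c(0, 0, 0, 0))
  pbin7 <- build_pbin(cells)
  expect_false("b7" %in% extract_pcn(pbin7, c("A", "D"))$bacteria)
})

test_that("efficacy is the covered share of all bacteria, resistant included", {
  cells <- cbind(A = c(1, 1, 1, 1, 0), B = c(0, 0, 1, 1, 0))
  rownames(cells) <- paste0("b", 1:5)  # b5 resistant
  pbin <- build_pbin(cells)
  expect_equal(efficacy(pbin, c("A", "B")), 80)
  expect_equal(efficacy(pbin, "A"), 80)

  wk <- build_pbin(worked_matrix())
  expect_equal(efficacy(wk, exhaustive_cocktail(wk)), 100)

  zero <- build_pbin(matrix(0, 3, 2, dimnames = list(paste0("b", 1:3),
                                                     paste0("p", 1:2))))
  expect_equal(efficacy(zero, heuristic_cocktail(zero)), 0)
})

test_that("coinfection distributions are per-MCS percentages summing to 100", {
  pbin <- build_pbin(worked_matrix())
  d_bc <- coinfection_distribution(list(extract_pcn(pbin, c("B", "C"))))
  expect_equal(d_bc$k1, 100)
  expect_equal(d_bc$k2, 0)

  d_abc <- coinfection_distribution(list(extract_pcn(pbin, c("A", "B", "C"))))
  expect_equal(d_abc$k1, 100 * 2 / 6)
  expect_equal(d_abc$k2, 100 * 4 / 6)
  expect_equal(d_abc$k3, 0)

  # a complete single-phage cocktail puts every bacterium at k = 1
  nested <- build_pbin(nested_matrix(8, 4, fill = 0.5, seed = 2))
  pcn1 <- extract_pcn(nested, exhaustive_cocktail(nested))
  expect_identical(pcn1$mcs, 1L)
  expect_equal(coinfection_distribution(list(pcn1))$k1, 100)

  # mixed sizes: one row per MCS group, each summing to 100
  both <- coinfection_distribution(list(extract_pcn(pbin, c("B", "C")),
                                        pcn1,
                                        extract_pcn(pbin, c("A", "D"))))
  expect_equal(both$mcs, c(1, 2))
  kcols <- grep("^k", names(both))
  expect_equal(rowSums(both[, kcols]), rep(100, nrow(both)))
})

test_that("redundancy variation follows its closed form and bounds", {
  rec <- redundancy_variation(in_d = 4, in_dc = 1, n_phages = 10, mcs = 2)
  expect_equal(rec$rv, log10(1.25))
  expect_equal(rec$rv_min, log10(1.25))
  expect_equal(rec$rv_max, log10(5))

  # unchanged redundancy: every phage lyses the host and all are selected
  expect_equal(redundancy_variation(6, 3, 6, 3)$rv, 0)
  expect_equal(redundancy_variation(2, 1, 4, 2)$rv, 0)

  expect_error(redundancy_variation(0, 1, 4, 2), "resistant")
  expect_error(redundancy_variation(2, 3, 4, 2), "in_dc")
  expect_error(redundancy_variation(2, 1, 1, 2), "n_phages")
})

test_that("rv bounds and the log10(in_d) width hold on generated PCNs", {
  for (seed in 1:12) {
    hrm <- random_matrix(8, 6, fill = 0.2 + 0.05 * (seed %% 6),
                         seed = 700 + seed)
    pbin <- build_pbin(hrm)
    if (n_susceptible(pbin) == 0) next
    e <- exhaustive_cocktail(pbin)
    rec <- redundancy_records(extract_pcn(pbin, e))
    expect_true(all(rec$rv >= rec$rv_min - 1e-12))
    expect_true(all(rec$rv <= rec$rv_max + 1e-12))
    expect_equal(rec$rv_max - rec$rv_min, log10(rec$in_d))
    if (e$size == 1)  # in_dc forced to 1, rv pinned at its minimum
      expect_equal(rec$rv, rec$rv_min)
  }
})

test_that("rv grouping preserves records and uses midpoint medians", {
  rec <- data.frame(bacterium_id = letters[1:6], mcs = c(2, 2, 2, 3, 3, 3),
                    in_d = 2, in_dc = c(1, 1, 2, 1, 2, 2),
                    rv = c(0.1, 0.3, 0.5, 0, 0, 0))
  by_mcs <- rv_by_group(rec, "mcs")
  expect_equal(sum(by_mcs$n), nrow(rec))
  expect_equal(by_mcs$median_rv[by_mcs$group == 2], 0.3)
  expect_equal(by_mcs$median_rv[by_mcs$group == 3], 0)

  by_k <- rv_by_group(rec, "n_lysing_phages")
  expect_equal(sum(by_k$n), nrow(rec))
  expect_equal(by_k$median_rv[by_k$group == 1], stats::median(c(0.1, 0.3, 0)))

  # even-count midpoint convention
  expect_equal(rv_by_group(data.frame(mcs = 1, in_dc = 1,
                                      rv = c(0.2, 0.4)), "mcs")$median_rv, 0.3)
})

test_that("rv converts to fold change on the log10 scale", {
  expect_equal(rv_to_fold(0), 1)
  expect_equal(rv_to_fold(1), 10)
  expect_equal(rv_to_fold(log10(1.25)), 1.25)
})
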