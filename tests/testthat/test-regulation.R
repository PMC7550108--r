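test_that("channel factors equalize summed intensities", {
  map <- channel_map(c("c1", "c2"), c("wt", "mut"), c(1, 1))
  tab <- tibble::tibble(protein_id = c("a", "b"), n_unique_peptides = 2L,
    c1 = c(40, 60), c2 = c(150, 50))
  fac <- compute_channel_factors(tab, map)
  expect_equal(fac$factor, c(1.5, 0.75))
  norm <- normalize_channels(tab, map, fac)
  expect_equal(sum(norm$c1), sum(norm$c2))
  expect_equal(sum(norm$c1), 150)

  tab$c2 <- 0
  expect_error(compute_channel_factors(tab, map), "zero total")
})

test_that("normalization makes ratios invariant to rescaling a raw channel", {
  map <- two_strain_map()
  base <- toy_protein_table(map)
  base$c3 <- c(120, 300, 60)
  base$c4 <- c(90, 150, 45)
  scaled <- base
  scaled$c3 <- scaled$c3 * 10

  ratios_of <- function(tab) {
    norm <- normalize_channels(tab, map)
    condition_log2_ratios(norm, map, conditions = "mut")$log2_ratio
  }
  expect_equal(ratios_of(scaled), ratios_of(base), tolerance = 1e-12)

  # channel sums equal to machine precision after normalization
  norm <- normalize_channels(scaled, map)
  sums <- vapply(map$channel, function(ch) sum(norm[[ch]]), numeric(1))
  expect_equal(unname(diff(range(sums))), 0, tolerance = 1e-9)
})

test_that("log2 ratios average replicates and respect missing values", {
  map <- two_strain_map()
  tab <- tibble::tibble(
    protein_id = c("same", "double", "halfmiss"),
    n_unique_peptides = 2L,
    c1 = c(100, 100, 100), c2 = c(100, 100, 100),   # wt
    c3 = c(100, 200, NA),  c4 = c(100, 200, 300)    # mut
  )
  r <- condition_log2_ratios(tab, map, conditions = "mut")
  expect_equal(r$log2_ratio[r$feature_id == "same"], 0)
  expect_equal(r$log2_ratio[r$feature_id == "double"], 1)
  # missing replicate -> mean over the remaining one
  expect_equal(r$log2_ratio[r$feature_id == "halfmiss"], log2(3))

  tab$c1[1] <- 0; tab$c2[1] <- 0
  expect_warning(r0 <- condition_log2_ratios(tab, map, conditions = "mut"),
    "zero reference")
  expect_true(is.na(r0$log2_ratio[r0$feature_id == "same"]))
})

test_that("condition SD matches the sample standard deviation", {
  r <- tibble::tibble(feature_id = letters[1:3], condition = "mut",
    log2_ratio = c(-1, 0, 1))
  s <- estimate_condition_sd(r)
  expect_equal(s$sd, 1)
  expect_equal(s$threshold, 2)

  const <- dplyr::mutate(r, log2_ratio = 0.5)
  expect_equal(estimate_condition_sd(const)$sd, 0)

  expect_error(estimate_condition_sd(r[1, ]), "fewer than 2")
})

test_that("scores and calls reproduce the published worked values", {
  sds <- published_sds()
  r <- tibble::tibble(
    feature_id = c("S180_pep2", "S510_pep2", "null"),
    condition = c("pro11", "pp2Ac1pro22", "pro11pro22"),
    log2_ratio = c(1.35, 1.17, 0)
  )
  calls <- score_and_call(r, sds)
  expect_equal(round(calls$score[1], 2), 2.18)  # 1.35 / 0.62
  expect_true(calls$regulated[1])
  expect_equal(round(calls$score[2], 2), 1.75)  # 1.17 / 0.67
  expect_false(calls$regulated[2])
  expect_equal(calls$score[3], 0)
  expect_false(calls$regulated[3])
})

test_that("a score printing as exactly 2.00 is called regulated", {
  r <- tibble::tibble(feature_id = c("edge", "justbelow"), condition = "c",
    log2_ratio = c(1.998, 1.99) / 1)
  s <- tibble::tibble(condition = "c", sd = 1)
  calls <- score_and_call(r, s)
  expect_true(calls$regulated[1])    # 1.998 rounds to 2.00
  expect_false(calls$regulated[2])  # 1.99 stays below
})

test_that("calling is monotone in |log2 ratio| and flags degenerate SD", {
  s <- tibble::tibble(condition = "c", sd = 0.5)
  grid <- tibble::tibble(feature_id = paste0("f", 1:200), condition = "c",
    log2_ratio = seq(-4, 4, length.out = 200))
  calls <- score_and_call(grid, s)
  up <- calls$regulated[order(abs(calls$log2_ratio))]
  expect_false(is.unsorted(up))  # FALSE...TRUE, never back

  degen <- score_and_call(grid[1:3, ], tibble::tibble(condition = "c", sd = 0))
  expect_true(all(degen$degenerate_sd))
  expect_true(all(is.na(degen$regulated)))
})

test_that("cross-omic gating keeps, demotes and flags unanchored peptides", {
  phospho <- tibble::tibble(
    feature_id = c("keep", "demote", "orphan", "quiet"),
    protein_id = c("P1", "P2", "P9", "P1"),
    condition = "mut",
    log2_ratio = c(2, 2, 2, 0.1),
    sd = 0.5, degenerate_sd = FALSE,
    score = c(4, 4, 4, 0.2), regulated = c(TRUE, TRUE, TRUE, FALSE)
  )
  protein <- tibble::tibble(
    feature_id = c("P1", "P2"), protein_id = c("P1", "P2"), condition = "mut",
    log2_ratio = c(0, 2), sd = 0.5, degenerate_sd = FALSE,
    score = c(0, 4), regulated = c(FALSE, TRUE)
  )
  gated <- gate_phospho_by_global(phospho, protein)
  expect_equal(gated$gate_status,
    c("regulated", "protein_level", "unanchored", "not_regulated"))
  expect_equal(gated$regulated_gated, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("identical phospho and protein behaviour is demoted, not double-counted", {
  # a peptide whose protein changed the same way carries no phospho information
  phospho <- tibble::tibble(feature_id = "pep", protein_id = "P", condition = "m",
    log2_ratio = 1.5, sd = 0.5, degenerate_sd = FALSE, score = 3, regulated = TRUE)
  protein <- tibble::tibble(feature_id = "P", protein_id = "P", condition = "m",
    log2_ratio = 1.5, sd = 0.5, degenerate_sd = FALSE, score = 3, regulated = TRUE)
  expect_equal(gate_phospho_by_global(phospho, protein)$gate_status, "protein_level")
})
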