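test_that("site aggregation uses the any-supporting-peptide rule", {
  sites <- tibble::tibble(
    feature_id = c("pep1", "pep2"),
    protein_id = "P", site = "S10", position = 10L, residue = "S"
  )
  calls <- tibble::tibble(
    feature_id = rep(c("pep1", "pep2"), each = 2),
    condition = rep(c("A", "B"), times = 2),
    regulated = c(TRUE, FALSE, FALSE, FALSE)  # pep1 regulated in A only
  )
  agg <- aggregate_sites(calls, sites)
  expect_equal(agg$regulated[agg$condition == "A"], TRUE)
  expect_equal(agg$regulated[agg$condition == "B"], FALSE)
  expect_equal(agg$n_peptides, c(2L, 2L))

  none <- aggregate_sites(dplyr::mutate(calls, regulated = FALSE), sites)
  expect_false(any(none$regulated))
})

test_that("a regulated site always has a regulated supporting peptide", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n_pep <- sample(3:8, 1)
      sites <- tibble::tibble(
        feature_id = paste0("pep", seq_len(n_pep)),
        protein_id = sample(c("P1", "P2"), n_pep, replace = TRUE),
        site = paste0("S", sample(5:9, n_pep, replace = TRUE))
      ) |>
        dplyr::mutate(position = as.integer(sub("S", "", site)), residue = "S")
      calls <- tidyr::expand_grid(feature_id = sites$feature_id,
        condition = c("A", "B")) |>
        dplyr::mutate(regulated = runif(dplyr::n()) < 0.4)
      agg <- aggregate_sites(calls, sites)
      for (i in which(agg$regulated)) {
        peps <- strsplit(agg$supporting_peptides[i], ";")[[1]]
        reg_peps <- calls$feature_id[calls$condition == agg$condition[i] & calls$regulated]
        expect_true(any(peps %in% reg_peps))
      }
      expect_equal(agg$n_regulated_peptides > 0, agg$regulated)
    }
  })
})

test_that("multi-site peptides fan out their call to each site", {
  map <- two_strain_map()
  phos <- toy_phospho_table(map)  # third peptide has sites 7 (S) and 8 (Y)
  calls <- tibble::tibble(
    feature_id = phospho_sites(phos)$feature_id[3],
    condition = "mut", regulated = TRUE
  )
  agg <- aggregate_sites(calls, phos)
  expect_setequal(agg$site, c("S7", "Y8"))
  expect_true(all(agg$regulated))
})

test_that("Venn regions are exhaustive and sum to the union", {
  calls <- tibble::tibble(
    feature_id = c("a", "b", "b", "c", "b"),
    condition = c("X", "X", "Y", "Y", "Z"),
    regulated = TRUE
  )
  ov <- cross_strain_overlap(calls, conditions = c("X", "Y", "Z"))
  expect_equal(sum(ov$n), attr(ov, "union"))
  expect_equal(attr(ov, "union"), 3)
  triple <- ov$n[ov$X & ov$Y & ov$Z]
  expect_equal(triple, 1L)  # only b
  only_x <- ov$n[ov$X & !ov$Y & !ov$Z]
  expect_equal(only_x, 1L)  # only a

  # brute-force oracle over random 3-set systems
  withr::with_seed(99, {
    for (rep in 1:25) {
      sets <- lapply(1:3, function(i) sample(letters, sample(0:10, 1)))
      longc <- purrr::imap_dfr(sets, function(s, i) {
        tibble::tibble(feature_id = s, condition = paste0("c", i), regulated = TRUE)
      })
      if (nrow(longc) == 0) longc <- tibble::tibble(feature_id = character(),
        condition = character(), regulated = logical())
      ov <- cross_strain_overlap(longc, conditions = c("c1", "c2", "c3"))
      uni <- unique(unlist(sets))
      expect_equal(attr(ov, "union"), length(uni))
      expect_equal(sum(ov$n), length(uni))
      # every element lands in exactly the region of its membership pattern
      for (el in uni) {
        memb <- vapply(sets, function(s) el %in% s, logical(1))
        row <- ov[ov$c1 == memb[1] & ov$c2 == memb[2] & ov$c3 == memb[3], ]
        expect_gte(row$n, 1L)
      }
    }
  })

  empty <- cross_strain_overlap(
    tibble::tibble(feature_id = "a", condition = c("X", "Y"), regulated = FALSE),
    conditions = c("X", "Y"))
  expect_equal(sum(empty$n), 0)
})

test_that("identical regulated sets fall entirely in the full intersection", {
  calls <- tidyr::expand_grid(feature_id = c("f1", "f2"),
    condition = c("A", "B", "C")) |>
    dplyr::mutate(regulated = TRUE)
  ov <- cross_strain_overlap(calls)
  expect_equal(ov$n[ov$A & ov$B & ov$C], 2L)
  expect_equal(sum(ov$n), 2L)
})

test_that("residue distribution counts unique sites once", {
  sites <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P2", "P1"),
    position = c(10L, 10L, 4L, 9L, 22L),      # P1:10 covered twice
    residue = c("S", "S", "S", "T", "Y"),
    site = paste0(c("S", "S", "S", "T", "Y"), c(10, 10, 4, 9, 22))
  )
  d <- residue_distribution(sites)
  expect_equal(d$fraction, c(0.5, 0.25, 0.25))  # S,S,T,Y over 4 unique sites
  expect_equal(sum(d$fraction), 1)

  all_s <- dplyr::filter(sites, residue == "S")
  expect_equal(residue_distribution(all_s)$fraction, c(1, 0, 0))

  bad <- dplyr::mutate(sites, residue = "B", site = "B1")
  expect_error(residue_distribution(bad), "S, T, Y")
})

test_that("flank windows are centred, padded, and coordinate-checked", {
  proteome <- c(P = "ABCDEFGHIKLMNPQRSTVW")  # 20-mer
  mk_site <- function(pos) tibble::tibble(protein_id = "P", site = paste0("S", pos),
    position = as.integer(pos), residue = "S")

  full <- extract_flank_windows(mk_site(8), proteome)
  expect_equal(nchar(full$window), 15)
  expect_equal(full$window, "ABCDEFGHIKLMNPQ")
  expect_equal(substr(full$window, 8, 8), "H")  # centre = residue 8

  # position 3 has two upstream residues, so 7 - 2 = 5 leading pads
  lead <- extract_flank_windows(mk_site(3), proteome)
  expect_equal(lead$window, paste0(strrep("_", 5), "ABCDEFGHIK"))
  expect_equal(nchar(lead$window), 15)

  # final residue: nothing downstream, 7 trailing pads
  trail <- extract_flank_windows(mk_site(20), proteome)
  expect_equal(trail$window, paste0("NPQRSTVW", strrep("_", 7)))
  expect_equal(nchar(trail$window), 15)

  expect_error(extract_flank_windows(mk_site(25), proteome), "outside protein P")
})

test_that("ratio-set comparison reports overlap and Pearson correlation", {
  a <- tibble::tibble(feature_id = paste0("f", 1:5), log2_ratio = c(1, 2, 3, 4, 5))
  ident <- compare_ratio_sets(a, a)
  expect_equal(ident$overlap, 1)
  expect_equal(ident$pearson, 1)

  anti <- compare_ratio_sets(a, dplyr::mutate(a, log2_ratio = -log2_ratio))
  expect_equal(anti$pearson, -1)

  b <- tibble::tibble(feature_id = c("f1", "f2", "f3", "x1", "x2"),
    log2_ratio = c(2, 1, 4, 0, 0))
  res <- compare_ratio_sets(a, b)
  expect_equal(res$overlap, 0.6)
  # hand-computed Pearson over shared pairs (1,2),(2,1),(3,4)
  x <- c(1, 2, 3); y <- c(2, 1, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson, r_hand)

  expect_message(small <- compare_ratio_sets(a[1:2, ], a[1:2, ]), "fewer than 3")
  expect_true(is.na(small$pearson))
})
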