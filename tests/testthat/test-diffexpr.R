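# SAM statistic, Rank Product, PPLR and signature intersection.

test_that("SAM d matches the pooled-SE formula and its symmetries", {
  # one probe, groups {1,2,3} vs {4,5,6}: with s0 = 0,
  # d = (1-sqrt(2/3)*0) ... hand: r = 2 - 5 = -3, s = sqrt(2/3)
  st <- pdblood:::sam_stat(matrix(c(1, 2, 3, 4, 5, 6), 1, 6),
                           c("case", "case", "case",
                             "control", "control", "control"))
  expect_equal(st$r, -3)
  expect_equal(st$s, sqrt((1 / 3 + 1 / 3) * (2 + 2) / 4))
  expect_equal(st$r / st$s, -3 / sqrt(2 / 3), tolerance = 1e-12)

  # equal group means -> d = 0
  st0 <- pdblood:::sam_stat(matrix(c(1, 2, 3, 3, 2, 1), 1, 6),
                            c("case", "case", "case",
                              "control", "control", "control"))
  expect_equal(st0$r, 0)

  # label swap flips the statistic
  ds <- simulate_cohort(cohort_spec(n_probes = 100, n_spiked = 10, seed = 6))
  swapped <- ds
  swapped$samples$class <- ifelse(ds$samples$class == "case",
                                  "control", "case")
  perm <- permutation_spec(n_permutations = 25, seed = 1)
  d1 <- sam_test(ds, perm)$statistic
  d2 <- sam_test(swapped, perm)$statistic
  expect_equal(d1, -d2, tolerance = 1e-10)
})

test_that("rank product equals the geometric mean of per-comparison ranks", {
  # 8 probes, 2 comparisons: target probe at descending ranks 2 and 8
  up1 <- c(8, 9, 6, 5, 4, 3, 2, 1)   # ratios comparison 1 (rank 2 for p01)
  up2 <- c(0.5, 8, 7, 6, 5, 4, 3, 2) # comparison 2 (rank 8 for p01)
  ds <- make_ratio_dataset(cbind(up1, up2))
  rp <- rank_product_test(ds, permutation_spec(n_permutations = 10))
  tbl <- attr(rp, "rp_table")
  expect_equal(tbl$rp_up[1], sqrt(2 * 8))

  # rank 1 everywhere -> RP = 1, the minimum
  best <- make_ratio_dataset(cbind(c(9, 1:7), c(9, 1:7)))
  tbl_best <- attr(rank_product_test(best,
                                     permutation_spec(n_permutations = 10)),
                   "rp_table")
  expect_equal(tbl_best$rp_up[1], 1)
  expect_true(all(tbl_best$rp_up >= 1))

  # global sign flip swaps the up and down lists
  ds_flip <- make_ratio_dataset(-cbind(up1, up2))
  tbl_flip <- attr(rank_product_test(ds_flip,
                                     permutation_spec(n_permutations = 10)),
                   "rp_table")
  expect_equal(tbl_flip$rp_down, tbl$rp_up)
  expect_equal(tbl_flip$rp_up, tbl$rp_down)
})

test_that("rank product permutation p matches exhaustive enumeration", {
  # 3 probes x 2 comparisons: (3!)^2 = 36 assignments enumerated exactly
  ratios <- cbind(c(3, 2, 1), c(2.5, 0.5, 1.5))
  ds <- make_ratio_dataset(ratios)
  rp <- rank_product_test(ds, permutation_spec(n_permutations = 5))

  null_vals <- oracle_rp_null(3, 2)
  rank_desc <- apply(-ratios, 2, rank)
  rp_up <- exp(rowMeans(log(rank_desc)))
  p_oracle <- vapply(rp_up, function(v) mean(null_vals <= v + 1e-12),
                     numeric(1))
  up_rows <- rp$direction == "up"
  expect_true(all(up_rows))
  expect_equal(rp$p_like, p_oracle, tolerance = 1e-12)
})

test_that("PPLR follows the Gaussian closed form and its symmetry", {
  # identical class means and variances -> PPLR = 1/2
  le <- rbind(p1 = c(1, 2, 1, 2))
  ds <- make_dataset(le, c("case", "case", "control", "control"))
  expect_equal(pplr_test(ds)$statistic, 0.5)

  # delta = 1 with combined posterior sd 1 -> PPLR = pnorm(1)
  a <- sqrt(2) / 2
  le2 <- rbind(p1 = c(1 - a, 1 + a, -a, a) + 10)  # vars 1, n = 2 each
  ds2 <- make_dataset(le2, c("case", "case", "control", "control"))
  res2 <- pplr_test(ds2)
  expect_equal(res2$statistic, pnorm(1), tolerance = 1e-12)
  expect_identical(res2$direction, "up")
  expect_equal(res2$p_like, 1 - pnorm(1), tolerance = 1e-12)

  # class swap: PPLR + PPLR_swapped = 1
  ds_swap <- ds2
  ds_swap$samples$class <- c("control", "control", "case", "case")
  expect_equal(res2$statistic + pplr_test(ds_swap)$statistic, 1,
               tolerance = 1e-12)

  # raising the threshold never shrinks the significant set
  ds_big <- simulate_cohort(cohort_spec(n_probes = 300, n_spiked = 30,
                                        seed = 14))
  sizes <- vapply(c(0.001, 0.01, 0.05, 0.2),
                  function(th) sum(pplr_test(ds_big, th)$significant),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("signature intersection is set algebra with direction handling", {
  mk <- function(genes, dirs) {
    tibble::tibble(probe_id = paste0(genes, "_at"), gene_id = genes,
                   statistic = 1, direction = dirs,
                   p_like = 0.001, fdr = 0.01, significant = TRUE,
                   method = "SAM")
  }
  a <- mk(c("A", "B", "C"), c("up", "up", "down"))
  b <- mk(c("B", "C", "D"), c("up", "down", "down"))
  out <- intersect_signatures(list(a, b))
  expect_setequal(out$id, c("B", "C"))

  # identical lists intersect to themselves
  expect_setequal(intersect_signatures(list(a, a))$id, c("A", "B", "C"))

  # discordant directions removed when requested
  b2 <- mk(c("B", "C"), c("down", "down"))
  out2 <- intersect_signatures(list(a, b2), direction_consistent = TRUE)
  expect_identical(out2$id, "C")

  # character vectors join in (the cross-species comparison path)
  out3 <- intersect_signatures(list(a, c("B", "Z")))
  expect_identical(out3$id, "B")

  expect_warning(res <- intersect_signatures(list(a, mk(character(0),
                                                        character(0)))),
                 "empty")
  expect_equal(nrow(res), 0)
  expect_error(intersect_signatures(list(a)), "at least 2",
               class = "pdblood_validation_error")
})

test_that("intersection precision is at least every single method's", {
  ds <- simulate_cohort(cohort_spec(n_probes = 400, n_spiked = 40,
                                    fold_change_range = c(1.4, 1.5),
                                    seed = 19))
  perm <- permutation_spec(n_permutations = 40, seed = 2)
  res <- list(sam = sam_test(ds, perm),
              rp = rank_product_test(ds, perm, max_pairs = 100),
              pplr = pplr_test(ds))
  truth <- setNames(ds$probes$truth != "null", ds$probes$gene_id)
  precision <- function(ids) if (!length(ids)) NA else mean(truth[ids])
  single <- vapply(res, function(r) precision(r$gene_id[r$significant]),
                   numeric(1))
  inter <- intersect_signatures(unname(res))
  expect_true(precision(inter$id) >= max(single, na.rm = TRUE) - 1e-9)
})
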