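# Probe filters, between-array normalization and the probe-to-gene collapse.

toy_dataset <- function() {
  le <- rbind(
    p1 = c(8, 9, 8.5),            # bright, Present
    p2 = log2(c(50, 50, 50)),     # below floor everywhere
    p3 = c(7, 8, 9)               # bright, Present
  )
  colnames(le) <- c("PD1", "PD2", "HC1")
  calls <- matrix("P", 3, 3, dimnames = dimnames(le))
  expression_dataset(le, calls = calls,
                     class_labels = c("case", "case", "control"))
}

test_that("filter_probes removes all-below-floor and all-non-Present probes", {
  ds <- toy_dataset()
  out <- suppressMessages(filter_probes(ds))
  expect_identical(rownames(out$log_exprs), c("p1", "p3"))
  expect_equal(attr(out, "filter_counts")[["removed"]], 1)

  # non-Present in every sample is dropped even when bright
  ds2 <- toy_dataset()
  ds2$calls["p1", ] <- "A"
  out2 <- suppressMessages(filter_probes(ds2))
  expect_identical(rownames(out2$log_exprs), "p3")

  # identity case: everything Present and above floor somewhere
  ds3 <- toy_dataset()[c("p1", "p3"), ]
  out3 <- suppressMessages(filter_probes(ds3))
  expect_identical(out3$log_exprs, ds3$log_exprs)
})

test_that("filter_probes is monotone in the intensity floor", {
  ds <- simulate_cohort(cohort_spec(n_probes = 300, n_spiked = 0, seed = 8))
  kept <- lapply(c(50, 100, 400, 1600), function(floor) {
    rownames(suppressMessages(
      filter_probes(ds, filter_spec(intensity_floor = floor)))$log_exprs)
  })
  for (i in seq_len(length(kept) - 1L)) {
    expect_true(all(kept[[i + 1L]] %in% kept[[i]]))
  }
})

test_that("sam_prefilter applies the smaller-class Present-and->floor rule", {
  # smaller class: 2 controls among 5 samples; fraction 0.5 -> need 1 array
  le <- rbind(p1 = c(8, 8, 8, 8, 8), p2 = c(8, 8, 8, 6, 6),
              p3 = c(8, 8, 8, 6, 8))
  colnames(le) <- c("PD1", "PD2", "PD3", "HC1", "HC2")
  calls <- matrix("P", 3, 5, dimnames = dimnames(le))
  calls["p1", c("HC1", "HC2")] <- "A"
  ds <- expression_dataset(le, calls = calls,
                           class_labels = c("case", "case", "case",
                                            "control", "control"))
  out <- suppressMessages(sam_prefilter(ds))
  # p1 Absent in both smaller-class arrays -> removed; p2 below 100 in both
  # (2^6 = 64) -> removed; p3 passes in HC2 (2^8 = 256 > 100) -> retained
  expect_identical(rownames(out$log_exprs), "p3")

  # boundary: exactly half of the smaller group passes
  ds_half <- expression_dataset(
    rbind(p1 = c(8, 8, 8, 8, 6)),
    class_labels = c("case", "case", "case", "control", "control"))
  expect_identical(
    rownames(suppressMessages(sam_prefilter(ds_half))$log_exprs), "p1")

  # fraction 1: failing a single smaller-class array removes the probe
  out_strict <- suppressMessages(
    sam_prefilter(ds_half, filter_spec(sam_prefilter_min_fraction = 1)))
  expect_equal(nrow(out_strict$log_exprs), 0)
})

test_that("quantile normalization matches the hand oracle and its invariants", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2, ignore_attr = TRUE)

  # columns share one empirical distribution; within-column ranks preserved
  set.seed(1)
  m3 <- matrix(rnorm(60), 20, 3)
  qn3 <- quantile_normalize(m3)
  expect_equal(sort(qn3[, 1]), sort(qn3[, 2]))
  expect_equal(sort(qn3[, 2]), sort(qn3[, 3]))
  for (j in 1:3) expect_equal(order(qn3[, j]), order(m3[, j]))

  m3[1, 1] <- NA
  expect_error(quantile_normalize(m3), "missing",
               class = "pdblood_validation_error")
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "2 columns",
               class = "pdblood_validation_error")
})

test_that("median scaling shifts columns to the global median, idempotently", {
  m <- cbind(c(4, 5, 6), c(6, 7, 8))  # medians 5 and 7, global median 6
  ms <- median_scale(m)
  expect_equal(unname(ms[, 1]), c(5, 6, 7))  # +1
  expect_equal(unname(ms[, 2]), c(5, 6, 7))  # -1
  expect_equal(median_scale(ms), ms)
  # columns already sharing the global median are untouched
  m2 <- cbind(c(1, 6, 9), c(2, 6, 7))
  expect_equal(median_scale(m2), m2)
})

test_that("collapse_to_genes keeps the brightest probe per gene", {
  le <- rbind(pA = rep(8, 3), pB = rep(6, 3), pC = rep(7, 3))
  colnames(le) <- c("PD1", "PD2", "HC1")
  ds <- expression_dataset(le, class_labels = c("case", "case", "control"),
                           gene_ids = c("G1", "G1", "G2"))
  out <- collapse_to_genes(ds)
  expect_setequal(out$probes$gene_id, c("G1", "G2"))
  expect_identical(
    out$probes$probe_id[out$probes$gene_id == "G1"], "pA")

  # ties break to the lexicographically smallest probe id
  ds_tie <- expression_dataset(le[c("pA", "pB"), ],
                               class_labels = c("case", "case", "control"),
                               gene_ids = c("G1", "G1"))
  ds_tie$log_exprs["pB", ] <- 8
  expect_identical(collapse_to_genes(ds_tie)$probes$probe_id, "pA")

  # all-distinct genes: row count unchanged, gene ids unique
  ds_id <- expression_dataset(le, class_labels = c("case", "case", "control"),
                              gene_ids = c("G1", "G2", "G3"))
  out_id <- collapse_to_genes(ds_id)
  expect_equal(nrow(out_id$log_exprs), 3)
  expect_false(anyDuplicated(out_id$probes$gene_id) > 0)

  # unannotated probes survive under their own id, with a warning
  ds_na <- expression_dataset(le, class_labels = c("case", "case", "control"),
                              gene_ids = c("G1", NA, "G2"))
  expect_warning(out_na <- collapse_to_genes(ds_na), "annotation")
  expect_true("pB" %in% out_na$probes$gene_id)
})
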