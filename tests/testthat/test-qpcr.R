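# geNorm / NormFinder stability, relative quantification and the per-gene
# group comparison.

zero_noise_plate <- function() {
  simulate_qpcr_plate(
    n_cases = 6, n_controls = 6,
    gene_specs = data.frame(gene = "T1", group_shift_cq = -1, noise_sd = 0),
    ref_stabilities = data.frame(gene = c("R1", "R2", "R3"),
                                 noise_sd = c(0, 0, 0.7)),
    loading_sd = 0.5, seed = 31)
}

test_that("geNorm M matches the 3-gene hand computation", {
  # 3 genes x 4 samples with known pairwise ratio SDs (efficiency 2:
  # log2 ratio of genes j,k in a sample is Cq_k - Cq_j)
  cq <- tibble::tibble(
    gene = rep(c("A", "B", "C"), each = 4),
    sample = rep(sprintf("s%d", 1:4), 3),
    group = rep(c("case", "case", "control", "control"), 3),
    cq = c(20.0, 21.0, 20.5, 22.0,
           25.0, 26.2, 25.4, 27.1,
           30.0, 30.5, 31.5, 30.2)
  )
  plate <- qpcr_plate(cq, reference_genes = c("A", "B", "C"))
  gn <- genorm_rank(plate)

  m_oracle <- function(g, others, cqw) {
    mean(vapply(others, function(k) sd(cqw[k, ] - cqw[g, ]), numeric(1)))
  }
  cqw <- matrix(cq$cq, 3, 4, byrow = TRUE, dimnames = list(c("A", "B", "C")))
  # first exclusion round: highest M leaves; survivors share the final M
  m0 <- vapply(c("A", "B", "C"),
               function(g) m_oracle(g, setdiff(c("A", "B", "C"), g), cqw),
               numeric(1))
  worst <- names(which.max(m0))
  expect_identical(gn$gene[3], worst)
  expect_equal(gn$stability[3], unname(m0[worst]), tolerance = 1e-12)
  pair <- setdiff(c("A", "B", "C"), worst)
  expect_equal(gn$stability[1], sd(cqw[pair[1], ] - cqw[pair[2], ]),
               tolerance = 1e-12)
})

test_that("geNorm excludes the noisy gene and finds the zero-variance pair", {
  plate <- zero_noise_plate()
  gn <- genorm_rank(plate, candidates = c("R1", "R2", "R3"))
  expect_setequal(selected_pair(gn), c("R1", "R2"))
  expect_equal(gn$stability[1], 0, tolerance = 1e-12)  # perfect pair: M = 0
  expect_identical(gn$gene[3], "R3")
  expect_error(genorm_rank(plate, candidates = c("R1", "R2")),
               "at least 3", class = "pdblood_validation_error")
})

test_that("geNorm M is invariant to rescaling one gene's quantities", {
  plate <- simulate_qpcr_plate(
    4, 4,
    gene_specs = data.frame(gene = "T1", group_shift_cq = 0, noise_sd = 0.2),
    ref_stabilities = data.frame(gene = c("R1", "R2", "R3"),
                                 noise_sd = c(0.1, 0.2, 0.3)), seed = 13)
  gn1 <- genorm_rank(plate, c("R1", "R2", "R3"))
  # multiplying R1's quantities by a constant = subtracting constant cycles
  shifted <- plate
  shifted$cq[shifted$gene == "R1"] <- shifted$cq[shifted$gene == "R1"] - 3
  gn2 <- genorm_rank(shifted, c("R1", "R2", "R3"))
  expect_equal(gn1$stability, gn2$stability, tolerance = 1e-12)
  expect_identical(gn1$gene, gn2$gene)
})

test_that("NormFinder ranks by combined bias and noise", {
  plate <- zero_noise_plate()
  nf <- normfinder_rank(plate, candidates = c("R1", "R2", "R3"))
  expect_setequal(selected_pair(nf), c("R1", "R2"))
  expect_identical(nf$gene[3], "R3")

  # a pure group shift dominates equal-noise genes
  shifted <- simulate_qpcr_plate(
    8, 8,
    gene_specs = data.frame(gene = "T1", group_shift_cq = 0, noise_sd = 0.1),
    ref_stabilities = data.frame(gene = c("R1", "R2", "R3"),
                                 noise_sd = c(0.1, 0.1, 0.1)), seed = 17)
  biased <- shifted
  case_rows <- biased$gene == "R3" & biased$group == "case"
  biased$cq[case_rows] <- biased$cq[case_rows] + 1.5
  nf2 <- normfinder_rank(biased, candidates = c("R1", "R2", "R3"))
  expect_identical(nf2$gene[3], "R3")
})

test_that("relative expression honours the calibrator and cancels loading", {
  plate <- zero_noise_plate()
  rq <- relative_expression(plate, targets = "T1",
                            references = c("R1", "R2"))
  # control samples average to the calibrator -> mean ln rq of controls ~ 0
  expect_equal(mean(rq$log_rq[rq$group == "control"]), 0, tolerance = 1e-9)
  # -1 cycle at efficiency 2 -> case quantities exactly doubled
  expect_equal(unique(round(rq$rq[rq$group == "case"] /
                              mean(rq$rq[rq$group == "control"]), 9)), 2)

  # plate-wide additive Cq shift changes nothing
  shifted <- plate
  shifted$cq <- shifted$cq + 2.5
  rq2 <- relative_expression(shifted, targets = "T1",
                             references = c("R1", "R2"))
  expect_equal(rq$rq, rq2$rq, tolerance = 1e-9)

  # doubling both reference quantities leaves group differences unchanged
  ref_scaled <- plate
  ref_rows <- ref_scaled$gene %in% c("R1", "R2")
  ref_scaled$cq[ref_rows] <- ref_scaled$cq[ref_rows] - 1
  rq3 <- relative_expression(ref_scaled, targets = "T1",
                             references = c("R1", "R2"))
  diff1 <- mean(rq$log_rq[rq$group == "case"]) -
    mean(rq$log_rq[rq$group == "control"])
  diff3 <- mean(rq3$log_rq[rq3$group == "case"]) -
    mean(rq3$log_rq[rq3$group == "control"])
  expect_equal(diff1, diff3, tolerance = 1e-9)
})

test_that("group comparison bands p-values and has power at a planted shift", {
  # identical groups -> p = 1, no stars
  rq_flat <- tibble::tibble(gene = "G", group = rep(c("case", "control"),
                                                    each = 3),
                            log_rq = rep(c(0.1, 0.2, 0.3), 2))
  cmp <- group_compare(rq_flat)
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$stars, "")

  # planted ln-ratio 0.5, sd 0.3, 12 v 12: rejections in >= 80 % of seeds
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    rq <- tibble::tibble(
      gene = "G",
      group = rep(c("case", "control"), each = 12),
      log_rq = c(rnorm(12, 0.5, 0.3), rnorm(12, 0, 0.3))
    )
    group_compare(rq)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_error(group_compare(tibble::tibble(gene = "G",
                                            group = c("case", "control"),
                                            log_rq = c(1, 2))),
               "at least 2", class = "pdblood_validation_error")
})
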