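# PLS-DA preselection, Ranking-PCA, LDA forward selection and Mahalanobis
# diagnostics.

test_that("first PLS component weight is proportional to X'y on a toy fit", {
  x <- matrix(c(1.0, 2.0, 0.5,
                1.5, 1.0, 0.2,
                3.0, 2.5, 0.9,
                2.5, 3.5, 0.4), 4, 3, byrow = TRUE)
  labels <- c("control", "control", "case", "case")
  fit <- plsda_fit_select(x, labels, max_components = 1, keep = 3)
  y <- c(-1, -1, 1, 1)
  w_oracle <- crossprod(scale(x, scale = FALSE), y - mean(y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(as.vector(fit$weights[, 1])), abs(as.vector(w_oracle)),
               tolerance = 1e-10)
})

test_that("VIP separates informative from noise variables and is normalized", {
  set.seed(11)
  n <- 30
  labels <- rep(c("case", "control"), each = n / 2)
  signal <- ifelse(labels == "case", 1, -1) + rnorm(n, 0, 0.1)
  x <- cbind(sep = signal, matrix(rnorm(n * 20), n, 20))
  colnames(x) <- c("sep", sprintf("noise%02d", 1:20))
  fit <- plsda_fit_select(x, labels, keep = 5)
  v <- setNames(fit$vip$vip, fit$vip$variable)
  expect_gt(v["sep"], max(v[names(v) != "sep"]))
  expect_equal(mean(fit$vip$vip^2), 1, tolerance = 1e-8)
  expect_true("sep" %in% fit$selected)

  # constant variables are excluded with a warning; one class is an error
  x_const <- cbind(x, const = rep(1, n))
  expect_warning(plsda_fit_select(x_const, labels, keep = 5), "constant")
  expect_error(plsda_fit_select(x, rep("case", n), keep = 2),
               class = "pdblood_validation_error")
})

test_that("rpca_rank puts a perfectly separating variable first", {
  set.seed(5)
  n <- 24
  labels <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 100), n, 100)
  colnames(x) <- sprintf("v%03d", 1:100)
  x[, 37] <- ifelse(labels == "case", 2, -2) + rnorm(n, 0, 0.05)
  rk <- rpca_rank(x, labels, max_rank = 5)
  expect_identical(rk$ranking$variable[1], "v037")
  expect_equal(rk$ranking$criterion[1], 100)

  # deterministic, and permutation-equivariant up to tie-broken positions
  rk2 <- rpca_rank(x, labels, max_rank = 5)
  expect_identical(rk$ranking, rk2$ranking)
  perm <- sample(ncol(x))
  rk3 <- rpca_rank(x[, perm], labels, max_rank = 5)
  expect_identical(rk3$ranking$variable[1], "v037")

  expect_warning(rpca_rank(x[, 1:4], labels, max_rank = 10), "truncated")
})

test_that("lda_forward entry p-value matches the closed-form partial F", {
  set.seed(2)
  s <- cbind(PC1 = c(-2.1, -1.9, -2.0, -1.8, 2.0, 1.9, 2.2, 1.7),
             PC2 = rnorm(8, 0, 0.5))
  labels <- rep(c("control", "case"), each = 4)
  rep_ <- lda_forward(s, labels, alpha = 0.05)
  expect_identical(rep_$selected_pcs$pc[1], "PC1")

  # oracle: one-variable Wilks lambda = SSW/SST, F = (1/L - 1)(n - 2)
  v <- s[, "PC1"]
  ssw <- sum((v[1:4] - mean(v[1:4]))^2) + sum((v[5:8] - mean(v[5:8]))^2)
  sst <- sum((v - mean(v))^2)
  f <- (sst / ssw - 1) * (8 - 2)
  p_oracle <- pf(f, 1, 6, lower.tail = FALSE)
  expect_equal(rep_$selected_pcs$p_level[1], p_oracle, tolerance = 1e-12)
})

test_that("separable data give NER 100 and selection is monotone in alpha", {
  set.seed(3)
  n <- 40
  labels <- rep(c("case", "control"), each = n / 2)
  s <- cbind(PC1 = ifelse(labels == "case", 1.5, -1.5) + rnorm(n, 0, 0.3),
             PC2 = rnorm(n), PC3 = rnorm(n))
  rep_ <- lda_forward(s, labels, alpha = 0.01)
  expect_identical(rep_$selected_pcs$pc[1], "PC1")
  expect_equal(rep_$ner_percent, 100)
  expect_true(rep_$ner_percent >= 0 && rep_$ner_percent <= 100)
  expect_equal(rep_$ner_percent,
               100 * mean(rep_$samples$correct))

  n_sel <- vapply(c(0, 0.01, 0.5, 0.999999), function(a) {
    r <- suppressWarnings(lda_forward(s, labels, alpha = a))
    nrow(r$selected_pcs)
  }, numeric(1))
  expect_true(all(diff(n_sel) >= 0))
  expect_equal(n_sel[1], 0)  # alpha -> 0 admits nothing
})

test_that("mahalanobis distances behave at centroids and under identity cov", {
  s <- cbind(PC1 = c(0, 0, 4, 4, 0, 8), PC2 = c(0, 2, 1, 3, 1, 2))
  labels <- c("control", "control", "case", "case", "control", "case")
  tbl <- mahalanobis_report(s, labels)
  expect_true(all(tbl$d2_own >= 0))

  # sample exactly at its class centroid -> d2_own = 0
  s2 <- rbind(s, c(4, 2))  # case centroid of first four rows? compute below
  cent_case <- colMeans(s[labels == "case", ])
  s3 <- rbind(s, cent_case)
  tbl3 <- mahalanobis_report(s3, c(labels, "case"))
  expect_equal(tbl3$d2_own[7], 0, tolerance = 1e-10)

  # identity pooled covariance -> squared Euclidean distance
  fit <- list(centroids = rbind(control = c(0, 0), case = c(3, 4)),
              pooled_cov = diag(2))
  tbl_id <- mahalanobis_report(matrix(c(0, 0), 1, 2,
                                      dimnames = list("s1", c("PC1", "PC2"))),
                               "control", model = fit)
  expect_equal(tbl_id$d2_own, 0)
  expect_equal(tbl_id$d2_other, 25)  # 3^2 + 4^2

  # constructed midpoint sample is flagged ambiguous
  mid <- matrix((fit$centroids[1, ] + fit$centroids[2, ]) / 2, 1, 2,
                dimnames = list("mid", c("PC1", "PC2")))
  tbl_mid <- mahalanobis_report(mid, "case", model = fit, margin = 0.5)
  expect_true(tbl_mid$ambiguous)
})
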