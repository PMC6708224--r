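# Standardization, outlier policy, KMO, PCA/oblimin, key-measure selection.

test_that("z-scoring centers, scales and round-trips", {
  df <- data.frame(participant_id = c("a", "b", "c"),
                   pct_sb = c(1, 2, 3), tt_mvpa = c(10, 30, 20))
  zs <- zscore_measures(df)
  expect_equal(unname(zs$z[, "pct_sb"]), c(-1, 0, 1))
  back <- sweep(sweep(zs$z, 2, zs$scale, "*"), 2, zs$center, "+")
  expect_equal(unname(back[, "tt_mvpa"]), df$tt_mvpa, tolerance = 1e-12)
  df$pct_sb <- 5
  expect_error(zscore_measures(df), "zero-variance")
})

test_that("outlier flagging masks exactly the extreme entries, idempotently", {
  set.seed(1)
  z <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("P%02d", 1:50), letters[1:4]))
  z[z > 3] <- 0
  z[7, 2] <- 5.2
  z[13, 4] <- -4.0  # boundary: inclusive
  fl <- flag_outliers(z)
  expect_equal(fl$report$participant_id, c("P07", "P13"))
  expect_true(is.na(fl$z[7, 2]) && is.na(fl$z[13, 4]))
  expect_equal(sum(is.na(fl$z)), 2)
  again <- flag_outliers(fl$z)
  expect_equal(nrow(again$report), 0)
  clean <- flag_outliers(z * 0.5)
  expect_equal(nrow(clean$report), 0)
})

test_that("KMO is exactly 0.5 for two correlated variables", {
  set.seed(2)
  x <- matrix(rnorm(200), 100, 2)
  x[, 2] <- x[, 1] * 0.6 + x[, 2]
  expect_equal(kmo(x)$kmo, 0.5, tolerance = 1e-12)
})

test_that("KMO matches the regression-residual oracle", {
  set.seed(3)
  for (rep in 1:100) {
    p <- sample(3:6, 1)
    n <- sample((p + 5):40, 1)
    x <- matrix(rnorm(n * p), n, p)
    if (rep %% 3 == 0) x[, 1] <- x[, 1] + x[, p] # induce structure sometimes
    expect_equal(kmo(x)$kmo, kmo_oracle(x), tolerance = 1e-8)
  }
})

test_that("strong one-factor data yields high KMO", {
  set.seed(4)
  f <- rnorm(800)
  x <- sapply(1:8, function(i) 0.95 * f + 0.3 * rnorm(800))
  expect_gt(kmo(x)$kmo, 0.9)
  expect_true(kmo(x)$suitable)
})

test_that("eigenvalue bookkeeping and communalities survive rotation", {
  set.seed(5)
  coh <- simulate_cohort(cohort_config(n_participants = 80, seed = 5),
                         mode = "measures")
  z <- zscore_measures(coh$measures)$z
  p <- suppressWarnings(pca_oblimin(z))
  expect_equal(sum(p$eigenvalues), ncol(z), tolerance = 1e-6)
  expect_true(all(p$eigenvalues >= 0))
  expect_equal(p$pct_variance, 100 * p$eigenvalues / ncol(z))
  # oblique rotation preserves the reproduced common variance
  rec_rot <- p$pattern %*% p$phi %*% t(p$pattern)
  rec_unrot <- p$unrotated %*% t(p$unrotated)
  expect_equal(rec_rot, rec_unrot, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(p$total_explained_variance,
               sum(p$pct_variance[seq_len(p$n_retained)]))
})

test_that("oblimin recovers a planted 5-factor structure", {
  set.seed(6)
  p <- 15; m <- 5; n <- 500
  Ltrue <- matrix(0, p, m)
  for (j in 1:m) Ltrue[((j - 1) * 3 + 1):(j * 3), j] <- 0.8
  f <- matrix(rnorm(n * m), n, m)
  x <- f %*% t(Ltrue) + 0.2 * matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("v%02d", 1:p)
  fit <- pca_oblimin(scale(x))
  expect_equal(fit$n_retained, 5)
  # factor congruence against the generating loadings, best column match
  congr <- abs(crossprod(Ltrue / sqrt(colSums(Ltrue^2)),
                         apply(fit$pattern, 2,
                               function(v) v / sqrt(sum(v^2)))))
  expect_true(all(apply(congr, 1, max) >= 0.95))
})

test_that("the reference loading matrix selects the published key measures", {
  sel <- select_key_measures(pb_reference_loadings())
  expect_equal(sel$measure,
               c("pct_sb", "d_sb1", "sb_nob", "tt_mvpa", "d_sb2"))
  expect_equal(sel$loading, c(0.92, 0.91, 0.94, 0.67, -0.93))
})

test_that("selection is pure argmax when no sedentary measure competes", {
  L <- matrix(0, 4, 2,
              dimnames = list(c("pct_mvpa", "cpd", "cpm", "mvpa_bl"), NULL))
  L[1, 1] <- 0.9; L[2, 1] <- 0.2
  L[3, 2] <- -0.8; L[4, 2] <- 0.3
  sel <- select_key_measures(L)
  expect_equal(sel$measure, c("pct_mvpa", "cpm"))
})

test_that("selection agrees with the rule oracle on random loading matrices", {
  info <- pb_measure_info()
  domain <- setNames(info$domain, info$measure)
  set.seed(7)
  for (rep in 1:100) {
    m <- sample(2:5, 1)
    L <- matrix(runif(15 * m, -1, 1), 15, m,
                dimnames = list(info$measure, NULL))
    margin <- runif(1, 0, 0.2)
    got <- suppressWarnings(select_key_measures(L, margin))$measure
    expect_equal(got, selection_oracle(L, margin, domain))
  }
})

test_that("near-singular measure sets are handled via the pseudoinverse", {
  set.seed(8)
  x <- matrix(rnorm(300), 100, 3)
  x <- cbind(x, 100 - x[, 1])  # exact collinearity, like %Active = 100 - %SB
  expect_warning(k <- kmo(x), "singular")
  expect_true(k$kmo >= 0 && k$kmo <= 1)
})
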