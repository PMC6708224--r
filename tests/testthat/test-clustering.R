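# Two-step clustering, k selection, k-means refinement, Cramer's V,
# split-half validation.

sep_clusters <- function(n_per = 5, d = 20, p = 2, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(d, 0), c(0, d))[, seq_len(p), drop = FALSE]
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(n_per * p, sd = 0.5), n_per, p), 2,
          centers[i, ], "+")))
  rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
  list(x = x, truth = rep(1:3, each = n_per))
}

test_that("well-separated triplets dominate the last merges", {
  sc <- sep_clusters()
  hc <- hierarchical_cluster(sc$x)
  co <- hc$schedule$coefficient
  n <- length(co)
  expect_gt(min(co[(n - 1):n]), 10 * max(co[1:(n - 2)]))
  expect_equal(nrow(hierarchical_cluster(matrix(c(0, 1, 5), 3))$schedule), 2)
  expect_error(hierarchical_cluster(cbind(c(1, NA, 2))), "missing")
})

test_that("Ward agglomeration matches the greedy minimum-SS oracle", {
  set.seed(9)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    hc <- hierarchical_cluster(x)
    oracle <- ward_oracle(x)
    expect_equal(hc$schedule$coefficient, oracle$coefficients,
                 tolerance = 1e-8)
    for (k in seq_len(n - 1)) {
      got <- cutree(hc$hclust, k = k)
      want <- oracle$partitions[[n - k]]
      expect_equal(ari_of(got, want), 1)
    }
  }
})

test_that("k selection finds a constructed elbow and rejects degeneracy", {
  sch <- data.frame(step = 1:9, n_clusters = 9:1,
                    coefficient = c(1, 1.2, 1.5, 1.7, 2.0, 2.2, 2.5,
                                    40, 55))
  expect_equal(choose_k(sch)$k, 3)
  flat <- data.frame(step = 1:5, n_clusters = 5:1, coefficient = rep(2, 5))
  expect_error(choose_k(flat), "degenerate")
})

test_that("k-means refinement descends and respects fixed points", {
  sc <- sep_clusters(n_per = 10)
  ctr <- rowsum(sc$x, sc$truth) / 10
  km <- kmeans_refine(sc$x, ctr)
  expect_equal(unname(km$cluster), sc$truth)  # already a fixed point
  expect_equal(km$centers, unname(ctr), tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(10)
  for (rep in 1:20) {
    x <- matrix(rnorm(40), 20, 2)
    init_lab <- sample(1:3, 20, replace = TRUE)
    init <- rowsum(x, init_lab) / as.vector(table(init_lab))
    km <- kmeans_refine(x, init)
    expect_lte(km$tot_withinss,
               sum(vapply(split(seq_len(20), init_lab), function(ix)
                 sum(sweep(x[ix, , drop = FALSE], 2,
                           colMeans(x[ix, , drop = FALSE]))^2), numeric(1))) +
                 1e-8)
    # agreement with stats::kmeans run from the same centers
    km2 <- suppressWarnings(stats::kmeans(x, centers = km$centers,
                                          algorithm = "Lloyd",
                                          iter.max = 300))
    expect_equal(km$tot_withinss, km2$tot.withinss, tolerance = 1e-6)
  }
  expect_error(kmeans_refine(matrix(0, 2, 2), matrix(0, 3, 2)), "more centers")
})

test_that("tiny-instance refinement reaches the exhaustive optimum", {
  set.seed(11)
  for (rep in 1:20) {
    # two latent groups: Lloyd from the Ward seed must find the global
    # optimum that exhaustive partition enumeration identifies
    x <- matrix(rnorm(12, sd = 0.7), 6, 2) +
      cbind(rep(c(0, 3), each = 3), 0)
    hc <- hierarchical_cluster(x)
    seed_lab <- cutree(hc$hclust, k = 2)
    ctr <- rowsum(x, seed_lab) / as.vector(table(seed_lab))
    km <- kmeans_refine(x, ctr)
    best <- Inf
    for (mask in 1:(2^5)) {  # all 2-part partitions up to symmetry
      lab <- c(1, as.integer(intToBits(mask))[1:5] + 1)
      if (length(unique(lab)) < 2) next
      best <- min(best, total_withinss_oracle(x, lab))
    }
    expect_equal(km$tot_withinss, best, tolerance = 1e-8)
  }
})

test_that("Cramer's V matches hand computation and is relabel-invariant", {
  a <- rep(1:3, each = 10)
  expect_equal(cramers_v(a, a), 1)
  expect_equal(cramers_v(rep(1:2, each = 10), rep(c("x", "y"), each = 10)), 1)

  # fixed 2x2 table [[20,5],[5,20]]: all expected counts 12.5,
  # chi2 = 4 * 7.5^2 / 12.5 = 18, V = sqrt(18 / 50)
  a <- rep(1:2, c(25, 25))
  b <- c(rep(1, 20), rep(2, 5), rep(1, 5), rep(2, 20))
  expect_equal(cramers_v(a, b), sqrt(18 / 50))

  set.seed(12)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    u <- sample(1:3, n, replace = TRUE)
    v <- ifelse(runif(n) < 0.6, u, sample(1:3, n, replace = TRUE))
    expect_equal(cramers_v(u, v), cramers_oracle(u, v), tolerance = 1e-10)
    expect_equal(cramers_v(u, v), cramers_v(v, u))
    perm <- sample(1:3)
    expect_equal(cramers_v(perm[u], v), cramers_v(u, v))
  }
  expect_error(cramers_v(1:3, 1:2), "equal length")
  expect_error(cramers_v(rep(1, 5), rep(1, 5)), "2 categories")
})

test_that("split-half validation is perfect on separated data, ~0 on noise", {
  sc <- sep_clusters(n_per = 20, seed = 13)
  cv <- cross_validate(sc$x, k = 3, seed = 1)
  expect_equal(cv$v_a, 1)
  expect_equal(cv$v_b, 1)
  expect_equal(cv$n_a + cv$n_b, nrow(sc$x))

  set.seed(14)
  own <- rep(1:3, each = 30)
  expect_lt(cramers_v(own, sample(own)), 0.25)
})

test_that("the two-step run is deterministic and labels its profile", {
  sc <- sep_clusters(n_per = 15, seed = 15)
  r1 <- run_two_step(sc$x, seed = 5)
  r2 <- run_two_step(sc$x, seed = 5)
  expect_identical(r1$solution$cluster, r2$solution$cluster)
  expect_identical(r1$validation$v, r2$validation$v)
  expect_equal(r1$k, 3)
  expect_equal(dim(r1$profile), c(3, ncol(sc$x)))
  expect_equal(ari_of(r1$solution$cluster, sc$truth), 1)
})

test_that("recovered subtype profiles carry the published sign structure", {
  coh <- simulate_cohort(cohort_config(n_participants = 208, seed = 31),
                         specs = default_subtype_specs(sd_scale = 0.5),
                         mode = "measures")
  fit <- suppressWarnings(pb_subtype(coh$measures, k = 3, seed = 31))
  prof <- coef(fit, "z")
  raw <- coef(fit, "raw")
  sed <- which.max(prof[, "pct_sb"])     # most-sedentary subtype
  act <- which.max(prof[, "tt_mvpa"])    # most-active subtype
  aft <- setdiff(1:3, c(sed, act))       # afternoon-active subtype
  expect_true(length(aft) == 1)
  expect_lt(prof[aft, "d_sb1"], 0)
  expect_equal(unname(which.max(prof[, "d_sb2"])), aft)
  expect_gt(raw[act, "tt_mvpa"], raw[sed, "tt_mvpa"])
})

test_that("adjusted Rand agrees with the independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(16)
  for (rep in 1:50) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(1:10, 1:10), 1)
})

test_that("the dendrogram export is a valid nested Newick string", {
  sc <- sep_clusters(n_per = 3, seed = 17)
  nwk <- dendrogram_newick(hierarchical_cluster(sc$x))
  expect_match(nwk, "^\\(.*;$")
  expect_equal(lengths(regmatches(nwk, gregexpr("\\(", nwk))),
               lengths(regmatches(nwk, gregexpr("\\)", nwk))))
  expect_true(all(vapply(rownames(sc$x), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})
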