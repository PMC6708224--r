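# Two-step cluster analysis: Ward hierarchical agglomeration on squared
# Euclidean distances for k selection, k-means (Lloyd) refinement seeded
# with the hierarchical centroids, and double split-half cross-validation
# scored with Cramer's V.

#' Agglomerative hierarchical clustering with an agglomeration schedule
#'
#' Ward linkage over squared Euclidean distances (the classical companion
#' of the squared-Euclidean criterion); single, complete and average
#' linkage are provided as options (these operate on unsquared distances).
#' The agglomeration coefficient reported for each step is the merge
#' criterion value of that step (for Ward, the squared-Euclidean-scale
#' merge height, i.e. twice the within-cluster sum-of-squares increase);
#' its relative jumps drive k selection. For Ward the cumulative
#' within-cluster SS is reported alongside as `cum_withinss`.
#'
#' @param x numeric matrix (participants x key measures), no missing values.
#' @param linkage `"ward"`, `"single"`, `"complete"` or `"average"`.
#' @return list of class `pb_hclust`: `hclust` (the stats::hclust tree) and
#'   `schedule` (data.frame `step`, `n_clusters`, `coefficient`).
#' @export
hierarchical_cluster <- function(x, linkage = "ward") {
  x <- as.matrix(x)
  if (anyNA(x))
    stop("missing values present; remove flagged participants first")
  if (nrow(x) < 3) stop("need at least 3 participants")
  d <- dist(x)
  hc <- switch(linkage,
    ward = hclust(d^2, method = "ward.D"),
    single = hclust(d, method = "single"),
    complete = hclust(d, method = "complete"),
    average = hclust(d, method = "average"),
    stop("unknown linkage: ", linkage))
  schedule <- data.frame(step = seq_along(hc$height),
                         n_clusters = nrow(x) - seq_along(hc$height),
                         coefficient = hc$height)
  if (linkage == "ward") schedule$cum_withinss <- cumsum(hc$height) / 2
  structure(list(hclust = hc, schedule = schedule, linkage = linkage),
            class = "pb_hclust")
}

#' Choose the number of clusters from the agglomeration schedule
#'
#' k* maximizes the relative agglomeration-coefficient change
#' (c(k-1) - c(k)) / c(k) over k in 2..k_max, where c(k) is the coefficient
#' of the merge producing k clusters — the automated analogue of reading
#' the dendrogram's rescaled distances together with the percentage change
#' in agglomeration coefficients.
#'
#' @param schedule a `pb_hclust` object or its `schedule` data.frame.
#' @param k_max largest k considered.
#' @return list of class `pb_elbow`: `k`, `elbow` (data.frame `k`,
#'   `coefficient`, `pct_change`).
#' @export
choose_k <- function(schedule, k_max = 10) {
  sch <- if (inherits(schedule, "pb_hclust")) schedule$schedule else schedule
  co <- function(k) sch$coefficient[sch$n_clusters == k]
  if (max(sch$coefficient) - min(sch$coefficient) < 1e-12)
    stop("degenerate agglomeration schedule: all coefficients equal, ",
         "cluster count undetermined")
  ks <- 2:min(k_max, max(sch$n_clusters))
  ratio <- vapply(ks, function(k) {
    ck <- co(k); ck1 <- co(k - 1)
    if (ck == 0) {
      if (ck1 == 0) NA_real_ else Inf
    } else (ck1 - ck) / ck
  }, numeric(1))
  if (all(is.na(ratio))) stop("degenerate agglomeration schedule")
  elbow <- data.frame(k = ks,
                      coefficient = vapply(ks, co, numeric(1)),
                      pct_change = 100 * ratio)
  k <- ks[which.max(ratio)]
  structure(list(k = k, elbow = elbow), class = "pb_elbow")
}

cluster_centroids <- function(x, labels) {
  x <- as.matrix(x)
  ctr <- rowsum(x, labels) / as.vector(table(labels))
  ctr[order(as.numeric(rownames(ctr))), , drop = FALSE]
}

#' Deterministic k-means (Lloyd) refinement from given centroids
#'
#' Lloyd iterations from the supplied initial centroids until the maximal
#' centroid shift falls below `tol` or `max_iter` is reached. Ties in
#' assignment go to the lowest cluster index; an emptied cluster is
#' reseeded with the point farthest from its assigned centroid.
#'
#' @param x numeric matrix (n x p).
#' @param centers initial centroid matrix (k x p).
#' @param tol convergence tolerance on centroid movement.
#' @param max_iter iteration cap.
#' @return list of class `pb_kmeans`: `cluster` (labels 1..k), `centers`,
#'   `withinss`, `tot_withinss`, `iterations`, `converged`.
#' @export
kmeans_refine <- function(x, centers, tol = 1e-6, max_iter = 300L) {
  x <- as.matrix(x)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k > nrow(x)) stop("more centers than points")
  if (ncol(centers) != ncol(x)) stop("centroid dimension mismatch")
  assign_nearest <- function(ctr) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(ctr) +
      outer(rep(1, nrow(x)), rowSums(ctr^2))
    max.col(-d2, ties.method = "first")
  }
  lab <- assign_nearest(centers)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # empty-cluster repair: reseed with the farthest point
    for (j in seq_len(k)) {
      if (!any(lab == j)) {
        dists <- rowSums((x - centers[lab, , drop = FALSE])^2)
        far <- which.max(dists)
        centers[j, ] <- x[far, ]
        lab[far] <- j
      }
    }
    new_centers <- rowsum(x, lab) / as.vector(table(lab))
    new_centers <- new_centers[order(as.numeric(rownames(new_centers))), ,
                               drop = FALSE]
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    lab <- assign_nearest(centers)
    if (shift < tol) { converged <- TRUE; break }
  }
  rownames(centers) <- NULL
  wss <- vapply(seq_len(k), function(j) {
    pts <- x[lab == j, , drop = FALSE]
    if (!nrow(pts)) 0 else sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1))
  structure(list(cluster = setNames(lab, rownames(x)), centers = centers,
                 withinss = wss, tot_withinss = sum(wss),
                 iterations = iter, converged = converged),
            class = "pb_kmeans")
}

total_withinss <- function(x, labels) {
  x <- as.matrix(x)
  sum(vapply(unique(labels), function(j) {
    pts <- x[labels == j, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
}

#' Cramer's V between two labelings
#'
#' V = sqrt(chi^2 / (n (min(r, c) - 1))) from the r x c cross-tabulation,
#' without continuity correction. 1 indicates perfect agreement up to
#' relabeling; 0 independence.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return numeric in \[0, 1\].
#' @export
cramers_v <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0) stop("empty labelings")
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2 && ncol(tab) < 2)
    stop("need at least 2 categories in total")
  if (min(nrow(tab), ncol(tab)) < 2) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  v2 <- chi2 / (n * (min(dim(tab)) - 1))
  sqrt(max(0, min(1, v2)))
}

two_step_core <- function(x, k, linkage = "ward") {
  hc <- hierarchical_cluster(x, linkage)
  seed_labels <- cutree(hc$hclust, k = k)
  if (length(unique(seed_labels)) < k)
    stop("hierarchical seeding yielded fewer than ", k,
         " non-empty clusters")
  centers <- cluster_centroids(x, seed_labels)
  km <- kmeans_refine(x, centers)
  list(hclust = hc, seed_labels = seed_labels, km = km)
}

#' Double split-half cross-validation of a cluster solution
#'
#' The sample is split randomly into halves; each half gets its own
#' two-step solution; k-means is then re-run on each half seeded with the
#' other half's cluster centers, and agreement between a half's own and
#' cross-seeded labels is scored with Cramer's V. The summary V is the mean
#' of the two per-half values.
#'
#' @param x numeric matrix (participants x key measures).
#' @param k number of clusters.
#' @param seed RNG seed for the split.
#' @param linkage linkage for the per-half hierarchical step.
#' @return list of class `pb_splitval`: `v_a`, `v_b`, `v`, `n_a`, `n_b`,
#'   `seed`.
#' @export
cross_validate <- function(x, k, seed = 1L, linkage = "ward") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4 * k)
    warning("fewer than 2k participants per half; validation unstable")
  with_seed(seed, {
    idx <- sample.int(n)
    a <- sort(idx[seq_len(floor(n / 2))])
    b <- sort(idx[(floor(n / 2) + 1):n])
    fit_a <- two_step_core(x[a, , drop = FALSE], k, linkage)
    fit_b <- two_step_core(x[b, , drop = FALSE], k, linkage)
    cross_a <- kmeans_refine(x[a, , drop = FALSE], fit_b$km$centers)
    cross_b <- kmeans_refine(x[b, , drop = FALSE], fit_a$km$centers)
    structure(list(
      v_a = cramers_v(fit_a$km$cluster, cross_a$cluster),
      v_b = cramers_v(fit_b$km$cluster, cross_b$cluster),
      v = mean(c(cramers_v(fit_a$km$cluster, cross_a$cluster),
                 cramers_v(fit_b$km$cluster, cross_b$cluster))),
      n_a = length(a), n_b = length(b), seed = seed),
      class = "pb_splitval")
  })
}

#' Run the full two-step clustering with validation
#'
#' Hierarchical agglomeration, agglomeration-coefficient k selection
#' (unless `k` is given), k-means refinement from the hierarchical
#' centroids, and double split-half cross-validation.
#'
#' @param x numeric matrix of key-measure z-scores, no missing values.
#' @param seed RNG seed (used for the validation split).
#' @param k fixed cluster count; `NULL` selects k from the schedule.
#' @param k_max largest k considered during selection.
#' @param linkage hierarchical linkage.
#' @return list of class `pb_twostep`: `k`, `solution` (`pb_kmeans`),
#'   `hierarchical` (`pb_hclust`), `elbow`, `validation`, `profile`
#'   (per-cluster mean z-scores).
#' @export
run_two_step <- function(x, seed = 1L, k = NULL, k_max = 10,
                         linkage = "ward") {
  x <- as.matrix(x)
  hc <- hierarchical_cluster(x, linkage)
  elbow <- choose_k(hc, k_max = k_max)
  if (is.null(k)) k <- elbow$k
  seed_labels <- cutree(hc$hclust, k = k)
  centers <- cluster_centroids(x, seed_labels)
  km <- kmeans_refine(x, centers)
  validation <- cross_validate(x, k, seed = seed, linkage = linkage)
  profile <- cluster_centroids(x, km$cluster)
  rownames(profile) <- paste0("cluster", seq_len(nrow(profile)))
  structure(list(k = k, solution = km, hierarchical = hc, elbow = elbow,
                 validation = validation, profile = profile, seed = seed),
            class = "pb_twostep")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement in \[-1, 1\]; 1 means identical partitions up
#' to relabeling. Used to score recovery of generated subtypes.
#'
#' @param a,b equal-length label vectors.
#' @return numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Newick-like text export of a hierarchical tree
#'
#' @param hc an `hclust` or `pb_hclust` object.
#' @return a single Newick string with merge heights as branch annotations.
#' @export
dendrogram_newick <- function(hc) {
  if (inherits(hc, "pb_hclust")) hc <- hc$hclust
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  node <- function(i) {
    if (i < 0) return(lab[-i])
    sprintf("(%s,%s):%g", node(hc$merge[i, 1]), node(hc$merge[i, 2]),
            hc$height[i])
  }
  paste0(node(nrow(hc$merge)), ";")
}
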