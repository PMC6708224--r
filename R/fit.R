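# pb_subtype(): the central model-fitting interface. Takes a per-participant
# measure table and carries out the full subtyping analysis: z-scoring,
# outlier masking, KMO screening, PCA with oblimin rotation, key-measure
# selection, two-step clustering and split-half validation.

#' Fit physical-behavior subtypes to a measure table
#'
#' Runs the complete subtyping analysis on a per-participant
#' physical-behavior measure table. The 15 measures are z-standardized;
#' measurements at or beyond `outlier_threshold` SD are set missing and
#' participants carrying any flagged key measure are removed before
#' clustering; sampling adequacy is screened with KMO; PCA with direct
#' oblimin rotation retains components with eigenvalue >= 1 and one key
#' measure is selected per component (sedentary-domain preference within
#' `sb_preference_margin`); subtypes come from Ward-then-k-means two-step
#' clustering on the key-measure z-scores, validated by double split-half
#' cross-validation (Cramer's V).
#'
#' When the table carries only the five canonical key measures (e.g. the
#' generator's measure-level fast mode), the PCA stage is skipped and those
#' measures are used directly.
#'
#' @param measures data.frame with `participant_id` and measure columns
#'   (see [measures_table()]), or a numeric matrix.
#' @param keys `"auto"` (select via PCA) or a character vector of measure
#'   names.
#' @param outlier_threshold |z| threshold for the outlier-to-missing policy.
#' @param sb_preference_margin see [select_key_measures()].
#' @param k fixed number of subtypes, or `NULL` to select via the
#'   agglomeration schedule.
#' @param k_max largest k considered.
#' @param linkage hierarchical linkage.
#' @param rotation `"oblimin"`, `"varimax"` or `"none"`.
#' @param seed RNG seed (validation split).
#' @return an object of class `pb_subtype`; see [print.pb_subtype()],
#'   [summary.pb_subtype()], [coef.pb_subtype()], [predict.pb_subtype()],
#'   [plot.pb_subtype()].
#' @export
pb_subtype <- function(measures, keys = "auto", outlier_threshold = 4.0,
                       sb_preference_margin = 0.05, k = NULL, k_max = 10,
                       linkage = "ward", rotation = "oblimin", seed = 1L) {
  cl <- match.call()
  zs <- zscore_measures(measures)
  fl <- flag_outliers(zs, threshold = outlier_threshold)

  have <- colnames(zs$z)
  pca <- NULL
  selection <- NULL
  if (identical(keys, "auto")) {
    if (all(pb_measure_info()$measure %in% have)) {
      pca <- pca_oblimin(fl$z, rotation = rotation)
      selection <- select_key_measures(
        pca, sb_preference_margin = sb_preference_margin)
      keys <- selection$measure
    } else if (all(pb_key_measures() %in% have)) {
      keys <- pb_key_measures()
    } else {
      stop("measure table has neither all 15 measures nor the 5 key ",
           "measures; pass `keys` explicitly")
    }
  }
  missing_keys <- setdiff(keys, have)
  if (length(missing_keys))
    stop("key measures absent from table: ",
         paste(missing_keys, collapse = ", "))

  zkey <- fl$z[, keys, drop = FALSE]
  removed <- rownames(zkey)[!complete.cases(zkey)]
  kept <- setdiff(rownames(zkey), removed)
  fit <- run_two_step(zkey[kept, , drop = FALSE], seed = seed, k = k,
                      k_max = k_max, linkage = linkage)

  centers_raw <- sweep(sweep(fit$solution$centers, 2, zs$scale[keys], "*"),
                       2, zs$center[keys], "+")
  colnames(centers_raw) <- keys
  structure(list(
    call = cl, measures = measures,
    center = zs$center, scale = zs$scale,
    outliers = fl$report, removed = removed,
    kmo = if (!is.null(pca)) pca$kmo else NULL,
    pca = pca, selection = selection, keys = keys,
    k = fit$k, solution = fit$solution, hierarchical = fit$hierarchical,
    elbow = fit$elbow, validation = fit$validation,
    profile = fit$profile, centers_raw = centers_raw,
    seed = seed),
    class = "pb_subtype")
}

#' Cluster labels of a fitted subtype model
#'
#' @param object a `pb_subtype` fit.
#' @return named integer vector of cluster labels (participants removed as
#'   outliers are absent).
#' @export
cluster_labels <- function(object) {
  stopifnot(inherits(object, "pb_subtype"))
  object$solution$cluster
}

#' @rdname pb_subtype
#' @param x a `pb_subtype` object.
#' @param ... unused.
#' @export
print.pb_subtype <- function(x, ...) {
  cat("Physical-behavior subtype model\n")
  cat(sprintf("  participants clustered: %d (removed as outliers: %d)\n",
              length(x$solution$cluster), length(x$removed)))
  if (!is.null(x$kmo))
    cat(sprintf("  KMO = %.3f; PCA retained %d components (%.1f%% variance)\n",
                x$kmo$kmo, x$pca$n_retained, x$pca$total_explained_variance))
  cat(sprintf("  key measures: %s\n", paste(x$keys, collapse = ", ")))
  sizes <- table(x$solution$cluster)
  cat(sprintf("  k = %d subtypes (sizes %s); split-half Cramer's V = %.2f\n",
              x$k, paste(sizes, collapse = "/"), x$validation$v))
  invisible(x)
}

#' @rdname pb_subtype
#' @param object a `pb_subtype` object.
#' @export
summary.pb_subtype <- function(object, ...) {
  out <- list(
    n = length(object$solution$cluster),
    n_removed = length(object$removed),
    keys = object$keys, k = object$k,
    sizes = as.vector(table(object$solution$cluster)),
    kmo = if (!is.null(object$kmo)) object$kmo$kmo else NA_real_,
    explained_variance = if (!is.null(object$pca))
      object$pca$total_explained_variance else NA_real_,
    cramers_v = object$validation$v,
    profile_z = object$profile,
    profile_raw = object$centers_raw,
    elbow = object$elbow$elbow)
  class(out) <- "summary.pb_subtype"
  out
}

#' @export
print.summary.pb_subtype <- function(x, ...) {
  cat(sprintf("Subtypes: k = %d; sizes %s; n = %d (+%d removed)\n",
              x$k, paste(x$sizes, collapse = "/"), x$n, x$n_removed))
  if (!is.na(x$kmo))
    cat(sprintf("KMO = %.3f; explained variance %.1f%%\n",
                x$kmo, x$explained_variance))
  cat(sprintf("Split-half Cramer's V = %.2f\n", x$cramers_v))
  cat("\nPer-subtype mean z-scores:\n")
  print(round(x$profile_z, 2))
  cat("\nPer-subtype means (original units):\n")
  print(round(x$profile_raw, 1))
  invisible(x)
}

#' @rdname pb_subtype
#' @param scale `"z"` for centroids in z-space, `"raw"` for original units.
#' @export
coef.pb_subtype <- function(object, scale = c("z", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "z") object$profile else object$centers_raw
}

#' Assign new participants to fitted subtypes
#'
#' New measure rows are standardized with the training means/SDs of the key
#' measures and assigned to the nearest fitted centroid in z-space.
#'
#' @param object a `pb_subtype` fit.
#' @param newdata data.frame or matrix carrying the key-measure columns.
#' @param ... unused.
#' @return integer vector of subtype assignments.
#' @export
predict.pb_subtype <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[object$keys])
  z <- sweep(sweep(x, 2, object$center[object$keys]), 2,
             object$scale[object$keys], "/")
  ctr <- object$solution$centers
  d2 <- outer(rowSums(z^2), rep(1, nrow(ctr))) - 2 * z %*% t(ctr) +
    outer(rep(1, nrow(z)), rowSums(ctr^2))
  max.col(-d2, ties.method = "first")
}

#' Plot a fitted subtype model
#'
#' `type = "profile"` draws per-subtype mean z-scores of the key measures
#' (the subtype signature plot); `"dayparts"` the per-subtype day-part
#' sedentary percentages (requires the auxiliary `sb_*` columns in the
#' fitted measure table); `"elbow"` the agglomeration-coefficient changes;
#' `"dendrogram"` the hierarchical tree.
#'
#' @param x a `pb_subtype` fit.
#' @param type plot type.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.pb_subtype <- function(x, type = c("profile", "dayparts", "elbow",
                                        "dendrogram"), ...) {
  type <- match.arg(type)
  if (type == "profile") {
    matplot(t(x$profile), type = "b", pch = 19, lty = 1,
            xaxt = "n", xlab = "", ylab = "mean z-score",
            main = "Subtype profiles (key measures)", ...)
    axis(1, at = seq_along(x$keys), labels = x$keys, las = 2, cex.axis = 0.8)
    abline(h = 0, lty = 3)
    legend("topright", legend = rownames(x$profile), col = seq_len(x$k),
           pch = 19, bty = "n")
  } else if (type == "dayparts") {
    md <- as.data.frame(x$measures)
    need <- c("sb_morning", "sb_afternoon", "sb_evening")
    if (!all(need %in% names(md)))
      stop("measure table lacks day-part columns ",
           paste(need, collapse = ", "))
    rownames(md) <- md$participant_id
    md <- md[names(x$solution$cluster), need]
    prof <- rowsum(as.matrix(md), x$solution$cluster) /
      as.vector(table(x$solution$cluster))
    matplot(t(prof), type = "b", pch = 19, lty = 1, xaxt = "n",
            xlab = "day part", ylab = "% sedentary of wear time",
            main = "Day-part sedentary behavior per subtype", ...)
    axis(1, at = 1:3, labels = c("morning", "afternoon", "evening"))
    legend("topright", legend = paste0("cluster", seq_len(nrow(prof))),
           col = seq_len(nrow(prof)), pch = 19, bty = "n")
  } else if (type == "elbow") {
    el <- x$elbow$elbow
    plot(el$k, el$pct_change, type = "b", pch = 19,
         xlab = "number of clusters k",
         ylab = "% change in agglomeration coefficient",
         main = "Agglomeration-coefficient elbow", ...)
    abline(v = x$k, lty = 2)
  } else {
    plot(x$hierarchical$hclust, labels = FALSE,
         main = "Ward agglomeration (squared Euclidean)",
         xlab = "", sub = "", ...)
  }
  invisible(x)
}
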