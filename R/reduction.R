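# Dimension reduction: z-standardization, the outlier-to-missing policy,
# Kaiser-Meyer-Olkin sampling adequacy, correlation-matrix PCA with direct
# oblimin (quartimin) rotation, and the key-measure selection rule.

#' Standardize measure columns to z-scores
#'
#' @param measures measure data.frame (with `participant_id`) or numeric
#'   matrix.
#' @param columns measure columns to standardize; defaults to whichever of
#'   the 15 canonical measures are present.
#' @return list of class `pb_zscore`: `z` (matrix, participants x measures,
#'   rownames = participant ids), `center`, `scale`.
#' @export
zscore_measures <- function(measures, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(pb_measure_info()$measure, colnames(measures))
  if (!length(columns)) stop("no measure columns found")
  x <- as.matrix(as.data.frame(measures)[columns])
  if (nrow(x) < 2) stop("need at least 2 participants to standardize")
  if (!is.null(measures$participant_id))
    rownames(x) <- measures$participant_id
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, sd, na.rm = TRUE)
  zero <- which(!is.finite(scl) | scl == 0)
  if (length(zero))
    stop("zero-variance column(s): ", paste(columns[zero], collapse = ", "))
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(z = z, center = ctr, scale = scl), class = "pb_zscore")
}

#' Flag outlier measurements and set them missing
#'
#' Entries at or beyond `threshold` standard deviations are set to `NA`
#' (single measurements become missing values; participants carrying one or
#' more flagged measurements are removed before clustering by the caller).
#'
#' @param zs a `pb_zscore` object or a z-score matrix.
#' @param threshold |z| flagging threshold (inclusive).
#' @return list: `z` (masked matrix), `report` (data.frame `participant_id`,
#'   `measure`, `z`), `flagged_participants`.
#' @export
flag_outliers <- function(zs, threshold = 4.0) {
  z <- if (inherits(zs, "pb_zscore")) zs$z else as.matrix(zs)
  hits <- which(abs(z) >= threshold, arr.ind = TRUE)
  report <- data.frame(
    participant_id = rownames(z)[hits[, 1]] %||% as.character(hits[, 1]),
    measure = colnames(z)[hits[, 2]],
    z = z[hits],
    stringsAsFactors = FALSE)
  report <- report[order(report$participant_id, report$measure), ,
                   drop = FALSE]
  rownames(report) <- NULL
  z[hits] <- NA
  list(z = z, report = report,
       flagged_participants = unique(report$participant_id))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO = sum of squared off-diagonal correlations divided by that sum plus
#' the sum of squared off-diagonal anti-image partial correlations. Partial
#' correlations come from the inverse correlation matrix; for a
#' rank-deficient correlation matrix (e.g. exactly collinear measures such
#' as %Active = 100 - %SB) the Moore-Penrose pseudoinverse is used with a
#' warning.
#'
#' @param x data matrix (rows = participants) or correlation matrix.
#' @param is_cor set TRUE when `x` is already a correlation matrix.
#' @return list of class `pb_kmo`: `kmo`, `suitable` (kmo > 0.5),
#'   `n_complete`.
#' @export
kmo <- function(x, is_cor = FALSE) {
  if (is_cor) {
    R <- as.matrix(x)
    n_complete <- NA_integer_
  } else {
    x <- as.matrix(x)
    cc <- complete.cases(x)
    n_complete <- sum(cc)
    if (n_complete < ncol(x) + 1)
      warning("fewer complete cases than variables; KMO may be unstable")
    R <- cor(x[cc, , drop = FALSE])
  }
  rc <- rcond(R)
  if (rc < 1e-10) {
    warning("correlation matrix is (near-)singular; ",
            "using Moore-Penrose pseudoinverse for anti-image correlations")
    S <- MASS::ginv(R)
  } else {
    S <- solve(R)
  }
  d <- sqrt(abs(diag(S)))
  P <- -S / tcrossprod(d)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  p2 <- sum(P[off]^2)
  k <- r2 / (r2 + p2)
  structure(list(kmo = k, suitable = k > 0.5, n_complete = n_complete),
            class = "pb_kmo")
}

# Quartimin criterion and gradient for a pattern matrix L.
vgq_quartimin <- function(L) {
  L2 <- L^2
  X <- L2 %*% (matrix(1, ncol(L), ncol(L)) - diag(ncol(L)))
  list(f = sum(L2 * X) / 4, G = L * X)
}

#' Direct oblimin (quartimin) rotation by gradient projection
#'
#' Oblique rotation of an unrotated loading matrix minimizing the quartimin
#' criterion (direct oblimin with delta = 0), via the gradient-projection
#' algorithm, with optional Kaiser row normalization.
#'
#' @param A unrotated loading matrix (variables x components).
#' @param normalize apply Kaiser normalization (rows scaled to unit
#'   communality during rotation).
#' @param eps convergence tolerance on the projected gradient norm.
#' @param max_iter iteration cap.
#' @return list: `pattern`, `structure`, `phi` (component correlations),
#'   `converged`, `iterations`.
#' @export
oblimin_rotate <- function(A, normalize = TRUE, eps = 1e-6,
                           max_iter = 1000L) {
  A <- as.matrix(A)
  m <- ncol(A)
  if (m == 1) {
    return(list(pattern = A, structure = A, phi = matrix(1, 1, 1),
                converged = TRUE, iterations = 0L))
  }
  h <- if (normalize) sqrt(rowSums(A^2)) else rep(1, nrow(A))
  h[h == 0] <- 1
  Aw <- A / h

  Tmat <- diag(m)
  al <- 1
  L <- Aw %*% t(solve(Tmat))
  vg <- vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% solve(Tmat))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)))
      L <- Aw %*% t(solve(Tt))
      vgt <- vgq_quartimin(L)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$G %*% solve(Tmat))
  }
  if (!converged)
    warning("oblimin rotation did not converge in ", max_iter, " iterations")
  pattern <- (Aw %*% t(solve(Tmat))) * h
  phi <- crossprod(Tmat)
  # sign convention: dominant loading positive per component
  flip <- apply(pattern, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pattern <- sweep(pattern, 2, flip, "*")
  phi <- diag(flip) %*% phi %*% diag(flip)
  dimnames(phi) <- list(colnames(A), colnames(A))
  structure_m <- pattern %*% phi
  dimnames(pattern) <- dimnames(structure_m) <- dimnames(A)
  list(pattern = pattern, structure = structure_m, phi = phi,
       converged = converged, iterations = iter)
}

#' Correlation-matrix PCA with eigenvalue-one retention and rotation
#'
#' Eigendecomposition of the complete-case correlation matrix of the
#' (z-scored) measures; components with eigenvalue >= 1 are retained and
#' rotated (direct oblimin by default, varimax optionally). Sampling
#' adequacy (KMO) is checked first and a warning is raised when KMO <= 0.5.
#'
#' @param z z-score matrix (participants x measures), possibly with `NA`s.
#' @param rotation `"oblimin"`, `"varimax"` or `"none"`.
#' @param kaiser_normalize Kaiser row normalization during rotation.
#' @return object of class `pb_pca`: `eigenvalues`, `pct_variance`,
#'   `n_retained`, `pattern`, `structure`, `phi`, `communalities`, `kmo`,
#'   `total_explained_variance`, `n_complete`, `rotation`.
#' @export
pca_oblimin <- function(z, rotation = c("oblimin", "varimax", "none"),
                        kaiser_normalize = TRUE) {
  rotation <- match.arg(rotation)
  z <- as.matrix(z)
  cc <- complete.cases(z)
  zc <- z[cc, , drop = FALSE]
  if (nrow(zc) <= ncol(zc))
    stop("need more complete cases than measures for PCA")
  R <- cor(zc)
  km <- kmo(zc)
  if (!km$suitable)
    warning(sprintf("KMO = %.3f <= 0.5: sampling adequacy not met", km$kmo))
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  pct <- 100 * ev / ncol(z)
  m <- sum(ev >= 1)
  if (m == 0) stop("no component with eigenvalue >= 1")
  A <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(m)]), m)
  dimnames(A) <- list(colnames(z), paste0("PC", seq_len(m)))
  rot <- switch(rotation,
    none = list(pattern = A, structure = A, phi = diag(m),
                converged = TRUE, iterations = 0L),
    varimax = {
      v <- stats::varimax(A, normalize = kaiser_normalize)
      L <- A %*% v$rotmat
      dimnames(L) <- dimnames(A)
      list(pattern = L, structure = L, phi = diag(m),
           converged = TRUE, iterations = NA_integer_)
    },
    oblimin = oblimin_rotate(A, normalize = kaiser_normalize))
  structure(list(
    eigenvalues = ev, pct_variance = pct, n_retained = m,
    pattern = rot$pattern, structure = rot$structure, phi = rot$phi,
    communalities = rowSums(A^2), unrotated = A,
    kmo = km, total_explained_variance = sum(pct[seq_len(m)]),
    n_complete = nrow(zc), rotation = rotation,
    rotation_converged = rot$converged),
    class = "pb_pca")
}

#' @export
print.pb_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d measures, %d complete cases\n",
              length(x$eigenvalues), x$n_complete))
  cat(sprintf("KMO = %.3f (%s)\n", x$kmo$kmo,
              if (x$kmo$suitable) "adequate" else "inadequate"))
  cat(sprintf("Retained %d components (eigenvalue >= 1), %s rotation\n",
              x$n_retained, x$rotation))
  cat(sprintf("Total explained variance: %.1f%%\n",
              x$total_explained_variance))
  ev <- rbind(eigenvalue = x$eigenvalues[seq_len(x$n_retained)],
              pct_variance = x$pct_variance[seq_len(x$n_retained)])
  colnames(ev) <- colnames(x$pattern)
  print(round(ev, 2))
  invisible(x)
}

#' Select one key measure per retained component
#'
#' Per component (in descending component-variance order) the candidate is
#' the measure with the largest absolute pattern loading among measures not
#' yet taken; when a sedentary-domain measure loads within
#' `sb_preference_margin` of that maximum, the sedentary measure is
#' preferred (domain consistency and interpretability). Each measure is
#' assigned to at most one component.
#'
#' @param pca a `pb_pca` object or a pattern-loading matrix with measure
#'   rownames.
#' @param sb_preference_margin absolute-loading margin within which a
#'   sedentary-domain measure wins (inclusive).
#' @param info measure metadata, see [pb_measure_info()].
#' @return data.frame of class `pb_keyselection`: `component`, `measure`,
#'   `loading`, `competitors`.
#' @export
select_key_measures <- function(pca, sb_preference_margin = 0.05,
                                info = pb_measure_info()) {
  L <- if (inherits(pca, "pb_pca")) pca$pattern else as.matrix(pca)
  if (is.null(rownames(L))) stop("pattern matrix needs measure rownames")
  domain <- setNames(info$domain, info$measure)
  taken <- character(0)
  out <- list()
  for (j in seq_len(ncol(L))) {
    avail <- setdiff(rownames(L), taken)
    al <- abs(L[avail, j])
    top <- max(al)
    if (top < 0.4)
      warning("component ", j, ": max |loading| = ", round(top, 2),
              " < 0.4 (weakly interpretable)")
    within <- avail[al >= top - sb_preference_margin]
    sb_within <- within[domain[within] == "SB"]
    chosen <- if (length(sb_within)) {
      sb_within[which.max(al[sb_within])]
    } else {
      avail[which.max(al)]
    }
    competitors <- setdiff(within, chosen)
    out[[j]] <- data.frame(
      component = colnames(L)[j] %||% paste0("PC", j),
      measure = chosen, loading = L[chosen, j],
      competitors = paste(competitors, collapse = ";"),
      stringsAsFactors = FALSE)
    taken <- c(taken, chosen)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pb_keyselection", "data.frame")
  res
}
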