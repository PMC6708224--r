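# Independent brute-force oracles used by the equivalence tests. These are
# deliberately naive re-derivations from first principles, kept separate
# from the package's implementations.

# Bout detection by explicit scan over epochs.
bout_oracle <- function(labels, state, min_duration_min,
                        interruption_allowance_min = 0) {
  labels <- as.character(labels)
  n <- length(labels)
  bouts <- list()
  i <- 1
  while (i <= n) {
    if (labels[i] != state) { i <- i + 1; next }
    start <- i
    in_state <- 0
    last_state_idx <- i
    j <- i
    gap <- 0
    while (j <= n) {
      if (labels[j] == state) {
        in_state <- in_state + 1
        last_state_idx <- j
        gap <- 0
      } else if (labels[j] == "nonwear") {
        break
      } else {
        gap <- gap + 1
        if (gap > interruption_allowance_min) break
      }
      j <- j + 1
    }
    if (in_state >= min_duration_min)
      bouts[[length(bouts) + 1]] <- data.frame(start = start,
                                               end = last_state_idx,
                                               duration = in_state)
    i <- last_state_idx + 1
    while (i <= n && labels[i] == state) i <- i + 1  # safety (unreachable)
  }
  if (!length(bouts))
    return(data.frame(start = integer(0), end = integer(0),
                      duration = numeric(0)))
  do.call(rbind, bouts)
}

# Greedy Ward agglomeration by direct minimum-SS-increase search.
# Coefficients on the same scale as hclust ward.D heights over squared
# Euclidean distances (= 2 x the within-SS increase of the merge).
ward_oracle <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  coefficients <- numeric(0)
  partitions <- list()
  ss <- function(idx) {
    pts <- x[idx, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      delta <- ss(c(clusters[[i]], clusters[[j]])) -
        ss(clusters[[i]]) - ss(clusters[[j]])
      if (delta < best[1]) best <- c(delta, j, i)
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
    coefficients <- c(coefficients, 2 * best[1])
    lab <- integer(nrow(x))
    for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
    partitions[[length(partitions) + 1]] <- lab
  }
  list(coefficients = coefficients, partitions = partitions)
}

# KMO by regression-residual partial correlations (no matrix inversion).
kmo_oracle <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  R <- cor(x)
  P <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    others <- setdiff(seq_len(p), c(i, j))
    ri <- residuals(lm(x[, i] ~ x[, others, drop = FALSE]))
    rj <- residuals(lm(x[, j] ~ x[, others, drop = FALSE]))
    P[i, j] <- P[j, i] <- cor(ri, rj)
  }
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
}

# Cramer's V via stats::chisq.test.
cramers_oracle <- function(a, b) {
  tab <- table(a, b)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi2) / (length(a) * (min(dim(tab)) - 1)))
}

# Key-measure selection by straightforward rule re-statement.
selection_oracle <- function(L, margin, domain) {
  taken <- character(0)
  chosen <- character(ncol(L))
  for (j in seq_len(ncol(L))) {
    avail <- setdiff(rownames(L), taken)
    al <- abs(L[avail, j])
    best <- max(al)
    cands <- avail[al >= best - margin]
    sb <- cands[domain[cands] == "SB"]
    pick <- if (length(sb)) sb[which.max(abs(L[sb, j]))] else
      avail[which.max(al)]
    chosen[j] <- pick
    taken <- c(taken, pick)
  }
  chosen
}

total_withinss_oracle <- function(x, lab) {
  sum(vapply(unique(lab), function(g) {
    pts <- x[lab == g, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
}

ari_of <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else adjusted_rand(a, b)
}

# Small labeled-epoch builder: one participant, states given per minute.
build_epochs <- function(states, start = "2023-05-01 08:00:00",
                         pid = "P001") {
  counts <- c(SB = 50L, light = 500L, MVPA = 2500L, nonwear = 0L)[states]
  data.frame(participant_id = pid,
             timestamp = as.POSIXct(start, tz = "UTC") +
               60 * (seq_along(states) - 1),
             counts = unname(counts),
             worn = states != "nonwear",
             stringsAsFactors = FALSE)
}

random_label_seq <- function(n, p_nonwear = 0.05) {
  sample(c("SB", "light", "MVPA", "nonwear"), n, replace = TRUE,
         prob = c(0.45, 0.3, 0.2, p_nonwear))
}
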