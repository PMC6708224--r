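# Between-subtype comparison battery: one-way ANOVA with Bonferroni
# post-hoc for normal continuous variables, Kruskal-Wallis with pairwise
# Mann-Whitney post-hoc for skewed ones, chi-square for categorical ones.

default_variable_kinds <- function(vars) {
  kinds <- c(age = "continuous-normal", bmi = "continuous-normal",
             cis20r = "continuous-normal",
             edss = "continuous-skewed",
             duration_ms_years = "continuous-skewed",
             sex = "categorical", ms_type = "categorical")
  keym <- setNames(rep("continuous-normal", 5), pb_key_measures())
  kinds <- c(kinds, keym)
  out <- kinds[vars]
  names(out) <- vars
  out
}

summarise_cell <- function(x, kind) {
  if (kind == "continuous-normal") {
    sprintf("%.1f ± %.1f (%.1f - %.1f)", mean(x), sd(x),
            min(x), max(x))
  } else if (kind == "continuous-skewed") {
    sprintf("%.1f (%.1f)", median(x), stats::IQR(x))
  } else {
    tab <- table(x)
    paste(sprintf("%s: %.1f%%", names(tab), 100 * tab / length(x)),
          collapse = ", ")
  }
}

#' Compare subtypes on covariates and measures
#'
#' For every variable: per-cluster summary, an omnibus test chosen by the
#' variable kind (ANOVA / Kruskal-Wallis / chi-square), and — when the
#' omnibus p is below `alpha` — pairwise post-hoc p-values
#' (Bonferroni-adjusted pooled-SD t tests after ANOVA; Mann-Whitney U,
#' unadjusted by default, after Kruskal-Wallis).
#'
#' @param data data.frame with one row per participant (covariates and/or
#'   measures) and a `participant_id` column.
#' @param cluster named vector of cluster labels (names = participant ids),
#'   e.g. [cluster_labels()].
#' @param variables variables to compare; defaults to the intersection of
#'   the standard covariates and key measures with `names(data)`.
#' @param kinds named character vector over `variables` with values
#'   `continuous-normal`, `continuous-skewed`, `categorical`; defaults per
#'   variable as in the reference analysis.
#' @param alpha significance level gating post-hoc tests.
#' @param posthoc_adjust p-adjustment for the Mann-Whitney post-hoc grid
#'   (`"none"` default, `"bonferroni"` optional).
#' @return object of class `pb_comparison`: a list of rows, each with
#'   `variable`, `kind`, `summaries`, `statistic`, `p`, `posthoc`,
#'   `warning`.
#' @export
compare_groups <- function(data, cluster, variables = NULL, kinds = NULL,
                           alpha = 0.05, posthoc_adjust = "none") {
  data <- as.data.frame(data)
  if (is.null(names(cluster)))
    stop("cluster must be a named vector (participant ids)")
  if (!"participant_id" %in% names(data))
    stop("data needs a participant_id column")
  data <- data[match(names(cluster), data$participant_id), , drop = FALSE]
  if (anyNA(data$participant_id))
    stop("cluster labels refer to participants missing from data")
  g <- factor(cluster)
  if (nlevels(g) < 2) stop("need at least 2 clusters")
  if (is.null(variables))
    variables <- intersect(c("sex", "ms_type", "age", "bmi", "edss",
                             "cis20r", "duration_ms_years",
                             pb_key_measures()), names(data))
  if (is.null(kinds)) kinds <- default_variable_kinds(variables)
  if (anyNA(kinds)) stop("no kind assigned for: ",
                         paste(variables[is.na(kinds)], collapse = ", "))

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    kind <- kinds[[v]]
    warn <- NULL
    summaries <- vapply(split(x, g), summarise_cell, character(1),
                        kind = kind)
    posthoc <- NULL
    if (kind == "continuous-normal") {
      if (any(table(g) < 2)) warn <- "cluster with < 2 members"
      fit <- aov(x ~ g)
      an <- summary(fit)[[1]]
      stat <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      if (!is.na(p) && p < alpha) {
        pt <- pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                              pool.sd = TRUE)
        posthoc <- pairwise_grid(pt$p.value, pairs)
      }
    } else if (kind == "continuous-skewed") {
      kw <- suppressWarnings(kruskal.test(x, g))
      stat <- unname(kw$statistic)
      p <- kw$p.value
      if (is.na(p)) { p <- 1; warn <- "all values tied; p set to 1" }
      if (p < alpha) {
        posthoc <- setNames(vapply(pairs, function(pr) {
          suppressWarnings(wilcox.test(x[g == pr[1]],
                                       x[g == pr[2]])$p.value)
        }, numeric(1)), vapply(pairs, paste, character(1), collapse = " vs "))
        posthoc <- p.adjust(posthoc, method = posthoc_adjust)
      }
    } else {
      tab <- table(g, x)
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      if (any(ct$expected < 1))
        warn <- "expected cell count < 1; chi-square approximation doubtful"
      stat <- unname(ct$statistic)
      p <- ct$p.value
      if (is.na(stat)) { stat <- 0; p <- 1 }
    }
    list(variable = v, kind = kind, summaries = summaries,
         statistic = stat, p = p, posthoc = posthoc, warning = warn)
  })
  structure(list(rows = rows, alpha = alpha,
                 clusters = levels(g), n = as.vector(table(g))),
            class = "pb_comparison")
}

pairwise_grid <- function(pmat, pairs) {
  out <- setNames(numeric(length(pairs)),
                  vapply(pairs, paste, character(1), collapse = " vs "))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    val <- if (b %in% rownames(pmat) && a %in% colnames(pmat))
      pmat[b, a] else pmat[a, b]
    out[i] <- val
  }
  out
}

#' @export
print.pb_comparison <- function(x, ...) {
  cat(sprintf("Between-subtype comparisons (%d clusters, n = %s; alpha = %g)\n\n",
              length(x$clusters), paste(x$n, collapse = "/"), x$alpha))
  for (r in x$rows) {
    star <- if (!is.na(r$p) && r$p < x$alpha) " *" else ""
    cat(sprintf("%s [%s]  p = %s%s\n", r$variable, r$kind,
                format.pval(r$p, digits = 3), star))
    for (i in seq_along(r$summaries))
      cat(sprintf("    %s: %s\n", names(r$summaries)[i], r$summaries[i]))
    if (!is.null(r$posthoc)) {
      ph <- paste(sprintf("%s: %s", names(r$posthoc),
                          format.pval(r$posthoc, digits = 2)),
                  collapse = "; ")
      cat("    post-hoc: ", ph, "\n", sep = "")
    }
    if (!is.null(r$warning)) cat("    note: ", r$warning, "\n", sep = "")
  }
  invisible(x)
}

#' Flatten a comparison to a data.frame (one row per variable)
#'
#' @param x a `pb_comparison`.
#' @param ... unused.
#' @return data.frame with per-cluster summary columns, the omnibus
#'   statistic and p-value, significance marker and post-hoc p-values.
#' @export
as.data.frame.pb_comparison <- function(x, ...) {
  rows <- lapply(x$rows, function(r) {
    s <- as.list(r$summaries)
    names(s) <- paste0("cluster_", names(r$summaries))
    ph <- r$posthoc
    php <- if (is.null(ph)) "" else
      paste(sprintf("%s=%.4g", names(ph), ph), collapse = "; ")
    data.frame(variable = r$variable, kind = r$kind, s,
               statistic = r$statistic, p = r$p,
               significant = !is.na(r$p) && r$p < x$alpha,
               posthoc = php,
               note = r$warning %||% "",
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
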