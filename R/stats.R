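#' Coerce paired condition data to a subjects x conditions matrix
#'
#' @param x a numeric matrix (rows = subjects, columns = conditions) or a
#'   long data.frame with columns `subject`, `condition`, `value`.
#' @return numeric matrix with condition column names.
#' @export
as_condition_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x),
            all(c("subject", "condition", "value") %in% names(x)))
  wide <- stats::xtabs(value ~ subject + condition, data = x)
  counts <- stats::xtabs(~ subject + condition, data = x)
  if (any(counts != 1L))
    stop("design is not complete paired: each subject needs exactly one ",
         "value per condition")
  m <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
              dimnames = dimnames(wide))
  m
}

#' Normality gate for the paired comparison cascade
#'
#' Runs the Shapiro-Wilk test on each condition's raw values. The cascade
#' branch is `"parametric"` only if every condition's p-value is at or above
#' `alpha`; otherwise `"nonparametric"`. A condition with (near-)constant
#' values, for which Shapiro-Wilk is undefined, forces the nonparametric
#' branch.
#'
#' @param x condition data (see [as_condition_matrix()]); >= 3 complete
#'   subjects required.
#' @param alpha significance level of the gate.
#' @return `"parametric"` or `"nonparametric"`, with attribute
#'   `"shapiro"` holding the per-condition p-values.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  m <- as_condition_matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 subjects per condition")
  if (anyNA(m)) stop("incomplete pairing: NA values present")
  p <- apply(m, 2L, function(v) {
    if (stats::sd(v) < .Machine$double.eps^0.5) return(NA_real_)
    stats::shapiro.test(v)$p.value
  })
  branch <- if (all(!is.na(p)) && all(p >= alpha)) "parametric"
            else "nonparametric"
  attr(branch, "shapiro") <- p
  branch
}

# Tie-corrected Friedman chi-square from a subjects x conditions matrix
# (same statistic as stats::friedman.test).
.friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  ties <- sum(apply(r, 1L, function(u) {
    tab <- table(u); sum(tab^3 - tab)
  }))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 0) return(0)  # every subject fully tied: no evidence, statistic 0
  num / den
}

#' Overall repeated-measures test across conditions
#'
#' Parametric branch: one-way repeated-measures ANOVA
#' (`aov(value ~ condition + Error(subject))`). Nonparametric branch:
#' Friedman test; for small designs (at most `exact_limit` equally likely
#' within-subject orderings) the p-value is computed from the exact
#' permutation null of the tie-corrected Friedman statistic, otherwise from
#' the usual chi-square asymptote.
#'
#' @param x condition data (see [as_condition_matrix()]).
#' @param branch `"parametric"`, `"nonparametric"`, or `"auto"` to apply
#'   [normality_gate()].
#' @param alpha gate level when `branch = "auto"`.
#' @param exact_limit maximum number of permutations for the exact Friedman
#'   null.
#' @return list with `test` ("RM-ANOVA" or "Friedman"), `statistic`, `p`,
#'   `branch`, and `exact` (logical, Friedman only).
#' @export
overall_test <- function(x, branch = c("auto", "parametric", "nonparametric"),
                         alpha = 0.05, exact_limit = 2e5) {
  branch <- match.arg(branch)
  m <- as_condition_matrix(x)
  if (anyNA(m)) stop("incomplete pairing: NA values present")
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("need at least 2 conditions")
  if (branch == "auto") branch <- as.character(normality_gate(m, alpha))
  if (branch == "parametric") {
    df <- data.frame(
      value = as.vector(m),
      condition = factor(rep(colnames(m) %||% seq_len(k), each = n)),
      subject = factor(rep(rownames(m) %||% seq_len(n), times = k))
    )
    fit <- stats::aov(value ~ condition + Error(subject), data = df)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    list(test = "RM-ANOVA", statistic = tab["condition", "F value"],
         p = tab["condition", "Pr(>F)"], branch = "parametric")
  } else {
    stat <- .friedman_stat(m)
    n_perm <- factorial(k)^n
    if (n_perm <= exact_limit) {
      perms <- .permutations(k)
      grid <- rep(1L, n)
      total <- 0L; ge <- 0L
      repeat {
        mp <- m
        for (i in seq_len(n)) mp[i, ] <- m[i, perms[[grid[i]]]]
        total <- total + 1L
        if (.friedman_stat(mp) >= stat - 1e-12) ge <- ge + 1L
        j <- 1L
        while (j <= n && grid[j] == length(perms)) {
          grid[j] <- 1L; j <- j + 1L
        }
        if (j > n) break
        grid[j] <- grid[j] + 1L
      }
      list(test = "Friedman", statistic = stat, p = ge / total,
           branch = "nonparametric", exact = TRUE)
    } else {
      list(test = "Friedman", statistic = stat,
           p = stats::pchisq(stat, k - 1, lower.tail = FALSE),
           branch = "nonparametric", exact = FALSE)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..k, built by inserting k into each position of the
# permutations of 1..k-1.
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) for (pos in 0:(k - 1L)) {
    out[[idx]] <- append(p, k, after = pos)
    idx <- idx + 1L
  }
  out
}

#' All pairwise paired comparisons
#'
#' Two-sided paired t-tests (parametric branch) or Wilcoxon signed-rank
#' tests (nonparametric branch) for each of the `k(k-1)/2` condition pairs.
#' A pair whose within-subject differences are all zero has an undefined
#' signed-rank statistic and is reported with `p = 1` and
#' `degenerate = TRUE`.
#'
#' @inheritParams overall_test
#' @return data.frame with one row per pair: `cond_a`, `cond_b`, `test`,
#'   `statistic`, `p`, `degenerate`.
#' @export
pairwise_tests <- function(x, branch = c("auto", "parametric",
                                         "nonparametric"),
                           alpha = 0.05) {
  branch <- match.arg(branch)
  m <- as_condition_matrix(x)
  if (anyNA(m)) stop("incomplete pairing: NA values present")
  k <- ncol(m)
  if (branch == "auto") branch <- as.character(normality_gate(m, alpha))
  conds <- colnames(m) %||% as.character(seq_len(k))
  rows <- list()
  for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k)) {
    diffs <- m[, b] - m[, a]
    if (all(abs(diffs) < .Machine$double.eps^0.5)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cond_a = conds[a], cond_b = conds[b],
        test = if (branch == "parametric") "paired-t" else "wilcoxon",
        statistic = NA_real_, p = 1, degenerate = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    if (branch == "parametric") {
      tt <- stats::t.test(m[, a], m[, b], paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        cond_a = conds[a], cond_b = conds[b], test = "paired-t",
        statistic = unname(tt$statistic), p = tt$p.value, degenerate = FALSE,
        stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(m[, a], m[, b],
                                                paired = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        cond_a = conds[a], cond_b = conds[b], test = "wilcoxon",
        statistic = unname(wt$statistic), p = wt$p.value, degenerate = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_comparisons`, with a display value rounded down to three
#' decimals as conventionally printed (0.05 over 15 comparisons is
#' 0.00333..., displayed as 0.003).
#'
#' @param alpha base significance level.
#' @param n_comparisons number of pairwise comparisons (>= 1).
#' @return list with `corrected` (exact) and `display` (floored to 3
#'   decimals).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  stopifnot(n_comparisons >= 1, alpha > 0, alpha < 1)
  corrected <- alpha / n_comparisons
  list(corrected = corrected, display = floor(corrected * 1000) / 1000)
}

#' Full comparison cascade for one sharpness metric
#'
#' Reproduces the intraindividual comparison workflow on a measurement
#' table: per-condition Shapiro-Wilk normality gate, overall test
#' (repeated-measures ANOVA or Friedman), all pairwise single comparisons
#' (paired t or Wilcoxon signed-rank), and the Bonferroni-corrected
#' threshold. The `"pooled"` edge uses each subject's mean across the four
#' edges (per-subject pooling before cohort averaging, matching the
#' intraindividual design).
#'
#' @param table a `measurement_table` from [measure_cohort()].
#' @param metric `"d"` or `"m"`.
#' @param factor `"averaging_level"` or `"recon_variant"`; the conditions
#'   compared. With only two conditions the overall test is skipped (not
#'   needed for a two-level factor) and the pair is tested directly.
#' @param edge an edge label (1-4) or `"pooled"`.
#' @param alpha base significance level.
#' @return an object of class `stats_report`: list with `metric`, `edge`,
#'   `factor`, `conditions`, `n_subjects`, `normality` (per-condition p),
#'   `branch`, `overall`, `pairwise`, `n_comparisons`, `corrected_alpha`,
#'   `summary` (mean, sd per condition).
#' @export
sharpness_stats <- function(table, metric = c("d", "m"),
                            factor = c("averaging_level", "recon_variant"),
                            edge = "pooled", alpha = 0.05) {
  metric <- match.arg(metric)
  factor <- match.arg(factor)
  col <- if (metric == "d") "d_mm" else "m_hu_per_mm"
  df <- as.data.frame(table)
  if (!identical(edge, "pooled")) df <- df[df$edge_label == edge, ]
  if (nrow(df) == 0L) stop("no rows for edge ", edge)
  agg <- stats::aggregate(df[[col]],
                          by = list(subject = df$subject_id,
                                    condition = df[[factor]]),
                          FUN = mean)
  names(agg)[3L] <- "value"
  m <- as_condition_matrix(agg)
  ord <- order(suppressWarnings(as.numeric(colnames(m))))
  if (!anyNA(suppressWarnings(as.numeric(colnames(m))))) m <- m[, ord, drop = FALSE]
  k <- ncol(m)
  if (k < 2L || nrow(m) < 3L) {
    # too small a design to test: summary only, with a notice
    return(structure(
      list(metric = metric, edge = edge, factor = factor,
           conditions = colnames(m), n_subjects = nrow(m),
           normality = NULL, branch = "none", overall = NULL,
           pairwise = NULL, n_comparisons = 0L, alpha = alpha,
           corrected_alpha = NA_real_, corrected_alpha_display = NA_real_,
           note = sprintf(paste0("tests skipped: %d condition(s), %d ",
                                 "subject(s); need >= 2 and >= 3"),
                          k, nrow(m)),
           summary = data.frame(condition = colnames(m),
                                mean = colMeans(m),
                                sd = apply(m, 2L, stats::sd),
                                row.names = NULL)),
      class = "stats_report"))
  }
  branch <- normality_gate(m, alpha)
  overall <- if (k > 2L) overall_test(m, as.character(branch)) else NULL
  pw <- pairwise_tests(m, as.character(branch))
  nc <- nrow(pw)
  thr <- bonferroni_threshold(alpha, nc)
  pw$significant <- pw$p < thr$corrected
  structure(
    list(metric = metric, edge = edge, factor = factor,
         conditions = colnames(m), n_subjects = nrow(m),
         normality = attr(branch, "shapiro"), branch = as.character(branch),
         overall = overall, pairwise = pw, n_comparisons = nc,
         alpha = alpha, corrected_alpha = thr$corrected,
         corrected_alpha_display = thr$display,
         summary = data.frame(condition = colnames(m),
                              mean = colMeans(m),
                              sd = apply(m, 2L, stats::sd),
                              row.names = NULL)),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("Contour sharpness %s, edge %s, by %s (%d subjects, %s branch)\n",
              x$metric, format(x$edge), x$factor, x$n_subjects, x$branch))
  if (!is.null(x$overall))
    cat(sprintf("  overall %s: statistic %.3f, p = %.4g\n",
                x$overall$test, x$overall$statistic, x$overall$p))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  if (x$n_comparisons > 0L)
    cat(sprintf("  %d pairwise comparisons, Bonferroni alpha %.4g (<%.3f)\n",
                x$n_comparisons, x$corrected_alpha, x$corrected_alpha_display))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Condition-by-edge summary table of a measurement table
#'
#' Mean (SD) of the chosen metric for every condition at each edge plus the
#' pooled per-subject mean across edges, in the layout of a comparison
#' table: rows = conditions, columns = edges 1-4 and "mean".
#'
#' @param table a `measurement_table`.
#' @param metric `"d"` or `"m"`.
#' @param factor condition column, as in [sharpness_stats()].
#' @param digits digits for the formatted cells.
#' @return list with `formatted` (character data.frame of "mean (SD)"
#'   cells) and `numeric` (long data.frame of means and SDs).
#' @export
sharpness_summary <- function(table, metric = c("d", "m"),
                              factor = "averaging_level", digits = 2) {
  metric <- match.arg(metric)
  col <- if (metric == "d") "d_mm" else "m_hu_per_mm"
  df <- as.data.frame(table)
  edges <- sort(unique(df$edge_label))
  conds <- sort(unique(df[[factor]]))
  num <- list()
  cells <- matrix("", length(conds), length(edges) + 1L,
                  dimnames = list(as.character(conds),
                                  c(paste0("edge", edges), "mean")))
  for (ci in seq_along(conds)) {
    sub <- df[df[[factor]] == conds[ci], ]
    for (ei in seq_along(edges)) {
      v <- sub[[col]][sub$edge_label == edges[ei]]
      cells[ci, ei] <- sprintf("%.*f (%.*f)", digits, mean(v), digits,
                               stats::sd(v))
      num[[length(num) + 1L]] <- data.frame(
        condition = conds[ci], edge = as.character(edges[ei]),
        mean = mean(v), sd = stats::sd(v))
    }
    pooled <- stats::aggregate(sub[[col]], by = list(sub$subject_id), mean)$x
    cells[ci, length(edges) + 1L] <-
      sprintf("%.*f (%.*f)", digits, mean(pooled), digits, stats::sd(pooled))
    num[[length(num) + 1L]] <- data.frame(
      condition = conds[ci], edge = "mean", mean = mean(pooled),
      sd = stats::sd(pooled))
  }
  list(formatted = as.data.frame(cells, stringsAsFactors = FALSE),
       numeric = do.call(rbind, num))
}
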