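test_that("normality gate has the expected operating characteristics", {
  set.seed(41)
  hits <- replicate(100, {
    m <- matrix(rnorm(29 * 3), 29, 3)
    as.character(normality_gate(m)) == "parametric"
  })
  expect_gte(mean(hits), 0.80)  # ~ (1 - alpha)^3 = 0.857 nominal

  heavy <- replicate(100, {
    m <- cbind(matrix(rnorm(29 * 2), 29, 2), rcauchy(29))
    as.character(normality_gate(m)) == "nonparametric"
  })
  expect_gte(mean(heavy), 0.9)

  expect_error(normality_gate(matrix(rnorm(4), 2, 2)), "3 subjects")
  # constant condition: Shapiro-Wilk undefined -> nonparametric branch
  g <- normality_gate(cbind(rnorm(10), rep(1, 10)))
  expect_equal(as.character(g), "nonparametric")
})

test_that("Friedman branch matches the exhaustive permutation oracle", {
  set.seed(52)
  for (rep in 1:4) {
    m <- matrix(rnorm(4 * 3, sd = 2) + rep(c(0, 0.5, 1), each = 4), 4, 3)
    ours <- overall_test(m, branch = "nonparametric")
    expect_true(ours$exact)
    expect_equal(ours$p, friedman_perm_oracle(m), tolerance = 0.01)
  }
  m5 <- matrix(rnorm(5 * 3), 5, 3)
  ours5 <- overall_test(m5, branch = "nonparametric")
  expect_equal(ours5$p, friedman_perm_oracle(m5), tolerance = 0.01)
})

test_that("Friedman statistic and asymptotic p agree with stats::friedman.test", {
  set.seed(53)
  m <- matrix(rnorm(29 * 6), 29, 6)
  ours <- overall_test(m, branch = "nonparametric", exact_limit = 0)
  ref <- stats::friedman.test(m)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("identical conditions give a null overall test", {
  m <- matrix(rep(rnorm(5), 3), 5, 3)
  res <- overall_test(m, branch = "nonparametric")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("a large shift is detected below the corrected threshold", {
  set.seed(54)
  m <- matrix(rnorm(29 * 3), 29, 3)
  m[, 3] <- m[, 3] + 10  # 10 SD shift
  thr <- bonferroni_threshold(0.05, 3)$corrected
  res <- overall_test(m, branch = "nonparametric")
  expect_lt(res$p, thr)
  pw <- pairwise_tests(m, branch = "nonparametric")
  expect_lt(min(pw$p[pw$cond_b == "3" | pw$cond_a == "3"]), thr)
})

test_that("pairwise tests: count, degenerate pairs, closed forms, oracle", {
  set.seed(55)
  m6 <- matrix(rnorm(8 * 6), 8, 6)
  expect_equal(nrow(pairwise_tests(m6, branch = "nonparametric")), 15L)

  dup <- cbind(a = rnorm(6), b = 0)
  dup[, 2] <- dup[, 1]
  pw <- pairwise_tests(dup, branch = "nonparametric")
  expect_equal(pw$p, 1)
  expect_true(pw$degenerate)

  # paired t equals the textbook formula on a 5-subject toy table
  x <- c(10.2, 11.5, 9.8, 12.1, 10.9)
  y <- c(11.0, 12.2, 10.1, 13.0, 11.1)
  pwt <- pairwise_tests(cbind(A = x, B = y), branch = "parametric")
  dif <- y - x
  t_hand <- mean(dif) / (sd(dif) / sqrt(5))
  expect_equal(abs(pwt$statistic), abs(t_hand), tolerance = 1e-12)
  expect_equal(pwt$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)

  # Wilcoxon signed-rank agrees with exhaustive sign-flip enumeration
  set.seed(56)
  for (rep in 1:3) {
    a <- rnorm(6); b <- a + rnorm(6, 0.5)
    pww <- pairwise_tests(cbind(a = a, b = b), branch = "nonparametric")
    expect_equal(pww$p, wilcoxon_flip_oracle(b, a), tolerance = 0.01)
  }
})

test_that("Bonferroni threshold and its printed form", {
  th <- bonferroni_threshold(0.05, 15)
  expect_equal(th$corrected, 0.05 / 15)
  expect_equal(th$display, 0.003)
  expect_equal(bonferroni_threshold(0.05, 1)$corrected, 0.05)
  expect_equal(bonferroni_threshold(0.05, 2)$corrected, 0.025)
})

test_that("family-wise error stays controlled on null cohorts", {
  set.seed(57)
  k <- 6
  thr <- bonferroni_threshold(0.05, k * (k - 1) / 2)$corrected
  fw <- replicate(300, {
    m <- matrix(rnorm(29 * k), 29, k)
    pw <- pairwise_tests(m, branch = "nonparametric")
    any(pw$p < thr)
  })
  se <- sqrt(0.05 * 0.95 / length(fw))
  expect_lte(mean(fw), 0.05 + 2 * se)
})

test_that("sharpness_stats recovers generative means and full cascade", {
  set.seed(58)
  n <- 25
  levels <- c(1, 2, 4)
  true_d <- c(1.5, 1.7, 1.9)
  rows <- list()
  for (si in seq_len(n)) for (li in seq_along(levels)) for (e in 1:4) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("S%02d", si), recon_variant = "fbp_like",
      averaging_level = levels[li], edge_label = e,
      d_mm = rnorm(1, true_d[li], 0.2),
      m_hu_per_mm = rnorm(1, 200 / true_d[li], 15))
  }
  tab <- do.call(rbind, rows)
  rep_d <- sharpness_stats(tab, "d", "averaging_level", edge = "pooled")
  expect_equal(rep_d$n_comparisons, 3L)
  expect_equal(rep_d$corrected_alpha, 0.05 / 3)
  for (li in seq_along(levels)) {
    sem <- 0.2 / sqrt(n * 4)
    expect_lt(abs(rep_d$summary$mean[li] - true_d[li]), 2 * sem * 2)
  }
  expect_true(rep_d$branch %in% c("parametric", "nonparametric"))
  expect_false(is.null(rep_d$overall))
  # the strong simulated trend is detected
  expect_lt(rep_d$overall$p, 0.05 / 3)

  # two conditions: overall test skipped, single pair reported
  two <- tab[tab$averaging_level %in% c(1, 2), ]
  rep2 <- sharpness_stats(two, "d", "averaging_level")
  expect_null(rep2$overall)
  expect_equal(nrow(rep2$pairwise), 1L)

  # summary table layout: conditions x edges 1-4 + pooled mean
  sm <- sharpness_summary(tab, "d")
  expect_equal(dim(sm$formatted), c(3L, 5L))
  expect_true(all(grepl("^[0-9.]+ \\([0-9.]+\\)$",
                        unlist(sm$formatted))))
  # permuting subject labels within conditions leaves summary means intact
  perm <- tab
  for (li in levels) {
    idx <- perm$averaging_level == li
    relab <- perm[idx, ]
    new_ids <- sample(unique(relab$subject_id))
    names(new_ids) <- unique(relab$subject_id)
    perm$subject_id[idx] <- new_ids[relab$subject_id]
  }
  sm_perm <- sharpness_summary(perm, "d")
  expect_equal(sm_perm$numeric$mean, sm$numeric$mean, tolerance = 1e-12)
})
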