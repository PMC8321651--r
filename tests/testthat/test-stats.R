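test_that("Mann-Whitney on fully separated tiny groups is exact", {
  res <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                       method = "mann_whitney")
  expect_equal(res$statistic, 0)              # U = 0: complete separation
  expect_equal(res$p_raw, 2 / 20)             # 2 of the 20 rank arrangements
  # invariant under monotone transforms
  res2 <- compareGroups(exp(c(1, 2, 3, 4, 5, 6)),
                        rep(c("a", "b"), each = 3), method = "mann_whitney")
  expect_equal(res2$p_raw, res$p_raw)
})

test_that("identical groups give maximal p-values", {
  suppressWarnings(
    res <- compareGroups(rep(1, 9), rep(c("a", "b", "c"), each = 3),
                         method = "mann_whitney"))
  expect_true(all(res$p_adjusted == 1))
})

test_that("kruskal_bh reports an omnibus row and BH-adjusted pairs", {
  set.seed(2)
  vals <- c(rnorm(8), rnorm(8, 2), rnorm(8, 4))
  grp <- rep(c("a", "b", "c"), each = 8)
  res <- compareGroups(vals, grp, method = "kruskal_bh")
  expect_equal(res$comparison[1], "omnibus")
  pairs <- res[-1, ]
  expect_equal(nrow(pairs), 3L)
  expect_true(all(pairs$p_adjusted >= pairs$p_raw - 1e-12))
  expect_equal(pairs$p_adjusted, p.adjust(pairs$p_raw, "BH"))
  # adjusted p monotone in raw p within the family
  o <- order(pairs$p_raw)
  expect_true(all(diff(pairs$p_adjusted[o]) >= -1e-12))
})

test_that("Holm-adjusted t tests and control-only comparisons work", {
  set.seed(3)
  vals <- c(rnorm(6), rnorm(6, 1), rnorm(6, 3))
  grp <- rep(c("ctl", "uva", "uvb"), each = 6)
  res <- compareGroups(vals, grp, method = "t_holm", control = "ctl")
  expect_equal(nrow(res), 2L)
  expect_true(all(grepl("^ctl vs ", res$comparison)))
  expect_equal(res$p_adjusted, p.adjust(res$p_raw, "holm"))
})

test_that("ANOVA post hocs: Tukey adjusts, LSD is gated on the omnibus F", {
  set.seed(4)
  vals <- c(rnorm(10), rnorm(10, 0.2), rnorm(10, 3))
  grp <- rep(c("a", "b", "c"), each = 10)
  tk <- compareGroups(vals, grp, method = "anova_tukey")
  expect_equal(tk$comparison[1], "omnibus")
  expect_equal(nrow(tk), 4L)
  lsd <- compareGroups(vals, grp, method = "anova_lsd")
  # pooled-variance pairwise t by hand for one pair
  mse <- summary(aov(vals ~ factor(grp)))[[1]]$`Mean Sq`[2]
  tval <- (mean(vals[grp == "a"]) - mean(vals[grp == "b"])) /
    sqrt(mse * (1 / 10 + 1 / 10))
  expect_equal(lsd$statistic[lsd$comparison == "a vs b"], tval)
  expect_error(compareGroups(c(1, 2), c("a", "b"), method = "anova_tukey"),
               ">= 2 observations")
})

test_that("Kaplan-Meier matches the hand-computed product-limit table", {
  rec <- data.frame(time = c(2, 3, 5, 7, 8),
                    event = c(TRUE, FALSE, TRUE, TRUE, FALSE), group = "g")
  km <- kmEstimate(rec)
  drops <- km[km$n_event > 0, ]
  # S(2) = 4/5; S(5) = 4/5 * 2/3; S(7) = 4/5 * 2/3 * 1/2
  expect_equal(drops$survival, c(4 / 5, 4 / 5 * 2 / 3, 4 / 15 ))
  # no censoring: survival drops 1/n per distinct event time
  rec2 <- data.frame(time = 1:5, event = TRUE, group = "g")
  km2 <- kmEstimate(rec2)
  expect_equal(km2$survival, seq(0.8, 0, by = -0.2))
  # all censored: flat at 1
  rec3 <- data.frame(time = 1:4, event = FALSE, group = "g")
  expect_true(all(kmEstimate(rec3)$survival == 1))
  expect_error(kmEstimate(data.frame(time = c(1, -2), event = TRUE,
                                     group = "g")), "positive")
})

test_that("identical survival experience gives a null Gehan statistic", {
  rec <- data.frame(time = rep(c(1, 3, 5, 9), 2),
                    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                    group = rep(c("a", "b"), each = 4))
  g <- gehanBreslowWilcoxon(rec)
  expect_lt(g$chi_square, 1e-10)
  expect_gt(g$p, 0.999)
})

test_that("Gehan p agrees with a label-permutation null", {
  set.seed(6)
  n <- 30
  rec <- data.frame(time = c(rexp(n, 1 / 10), rexp(n, 1 / 16)),
                    event = TRUE, group = rep(c("a", "b"), each = n))
  rec$event <- rec$time < 25
  rec$time <- pmin(rec$time, 25)
  g <- gehanBreslowWilcoxon(rec)
  n_perm <- 3000
  stats <- replicate(n_perm, {
    r <- rec; r$group <- sample(r$group)
    gehanBreslowWilcoxon(r)$chi_square
  })
  p_perm <- mean(stats >= g$chi_square - 1e-12)
  se <- sqrt(max(p_perm * (1 - p_perm), 1e-4) / n_perm)
  expect_lt(abs(g$p - p_perm), 3 * se + 0.01)
})

test_that("the Gehan weights emphasize early separation relative to log-rank", {
  # conflicting evidence: group a dies early (full risk sets), group b
  # dies late after interim censoring has shrunk the risk sets, so the
  # number-at-risk weights side with the early difference
  cens <- c(4, 4.5, 5, 5.5, 12, 12, 12)
  mk <- function(a_ev, b_ev)
    data.frame(time = c(a_ev, cens, b_ev, cens),
               event = c(rep(TRUE, length(a_ev)), rep(FALSE, 7),
                         rep(TRUE, length(b_ev)), rep(FALSE, 7)),
               group = c(rep("a", length(a_ev) + 7),
                         rep("b", length(b_ev) + 7)))
  early_heavy <- mk(c(1, 1.5, 2), 9)
  late_heavy <- mk(1, c(8, 9, 10))
  expect_gt(gehanBreslowWilcoxon(early_heavy)$chi_square,
            logRankTest(early_heavy)$chi_square)
  expect_lt(gehanBreslowWilcoxon(late_heavy)$chi_square,
            logRankTest(late_heavy)$chi_square)
})
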