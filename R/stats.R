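## Group-comparison and survival statistics: pairwise nonparametric and
## parametric tests with their stated multiple-testing families,
## Kaplan-Meier estimation and the Gehan-Breslow-Wilcoxon weighted
## log-rank test.

groupPairs <- function(levels, control = NULL) {
  if (!is.null(control)) {
    if (!control %in% levels) stop("control group not present: ", control)
    others <- setdiff(levels, control)
    cbind(rep(control, length(others)), others)
  } else t(combn(levels, 2L))
}

exactOrApprox <- function(x, y) {
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  w <- suppressWarnings(wilcox.test(x, y, exact = (n <= 20L && !ties),
                                    correct = TRUE))
  # fully tied data: no evidence against the null, not NaN
  if (is.nan(w$p.value)) w$p.value <- 1
  w
}

#' Group comparisons with the matching multiple-testing family
#'
#' Applies the study's group-comparison recipes to a numeric response:
#' \describe{
#'   \item{mann_whitney}{pairwise Mann-Whitney U tests; exact p for
#'     combined n <= 20 without ties, normal approximation with tie
#'     correction otherwise; no adjustment.}
#'   \item{kruskal_bh}{"nonparametric ANOVA": Kruskal-Wallis omnibus
#'     followed by pairwise Mann-Whitney with Benjamini-Hochberg FDR
#'     adjustment.}
#'   \item{t_holm}{pairwise Welch t-tests with Holm adjustment.}
#'   \item{anova_tukey}{one-way ANOVA with Tukey HSD post hoc
#'     (studentized-range adjusted p).}
#'   \item{anova_lsd}{one-way ANOVA with Fisher's least-significant-
#'     difference posttest: unadjusted pairwise t on the pooled residual
#'     variance, protected by the omnibus F.}
#' }
#'
#' @param values numeric response per subject.
#' @param groups group label per subject.
#' @param method one of the five recipes above.
#' @param alpha significance level used to gate the LSD posttest.
#' @param control optional control-group label: only comparisons against
#'   it are formed (all pairs otherwise).
#' @return data.frame with columns comparison, method, statistic, p_raw,
#'   p_adjusted (omnibus rows carry the omnibus statistic and NA
#'   adjustment).
#' @export
compareGroups <- function(values, groups,
                          method = c("mann_whitney", "kruskal_bh", "t_holm",
                                     "anova_tukey", "anova_lsd"),
                          alpha = 0.05, control = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("at least two groups required")
  sizes <- table(groups)
  if (method %in% c("t_holm", "anova_tukey", "anova_lsd") && any(sizes < 2L))
    stop("variance-based methods need >= 2 observations per group")
  pairs <- groupPairs(lev, control)
  lab <- paste(pairs[, 1L], pairs[, 2L], sep = " vs ")
  row <- function(comparison, statistic, p_raw, p_adjusted)
    data.frame(comparison = comparison, method = method,
               statistic = statistic, p_raw = p_raw,
               p_adjusted = p_adjusted, stringsAsFactors = FALSE)
  pick <- function(g) values[groups == g]

  if (method == "mann_whitney") {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      w <- exactOrApprox(pick(pairs[i, 1L]), pick(pairs[i, 2L]))
      row(lab[i], unname(w$statistic), w$p.value, w$p.value)
    })
    return(do.call(rbind, res))
  }
  if (method == "kruskal_bh") {
    kw <- kruskal.test(values, factor(groups))
    praw <- vapply(seq_len(nrow(pairs)), function(i)
      exactOrApprox(pick(pairs[i, 1L]), pick(pairs[i, 2L]))$p.value,
      numeric(1))
    stat <- vapply(seq_len(nrow(pairs)), function(i)
      unname(exactOrApprox(pick(pairs[i, 1L]), pick(pairs[i, 2L]))$statistic),
      numeric(1))
    return(rbind(
      row("omnibus", unname(kw$statistic), kw$p.value, NA_real_),
      row(lab, stat, praw, p.adjust(praw, "BH"))))
  }
  if (method == "t_holm") {
    tt <- lapply(seq_len(nrow(pairs)), function(i)
      t.test(pick(pairs[i, 1L]), pick(pairs[i, 2L])))
    praw <- vapply(tt, function(x) x$p.value, numeric(1))
    stat <- vapply(tt, function(x) unname(x$statistic), numeric(1))
    return(row(lab, stat, praw, p.adjust(praw, "holm")))
  }
  fit <- aov(values ~ factor(groups))
  ftab <- summary(fit)[[1]]
  fstat <- ftab$`F value`[1L]
  fp <- ftab$`Pr(>F)`[1L]
  omnibus <- row("omnibus", fstat, fp, NA_real_)
  if (method == "anova_tukey") {
    tk <- TukeyHSD(fit)[[1]]
    cmp <- sub("-", " vs ", rownames(tk), fixed = TRUE)
    keep <- if (is.null(control)) seq_len(nrow(tk))
      else grep(paste0("(^|\\s)", control, "($|\\s)"), cmp)
    return(rbind(omnibus, row(cmp[keep], tk[keep, "diff"],
                              tk[keep, "p adj"], tk[keep, "p adj"])))
  }
  # anova_lsd: pooled-variance pairwise t, unadjusted, gated on omnibus F
  mse <- ftab$`Mean Sq`[2L]
  dfres <- ftab$Df[2L]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- pick(pairs[i, 1L]); y <- pick(pairs[i, 2L])
    se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
    tval <- (mean(x) - mean(y)) / se
    p <- 2 * pt(-abs(tval), dfres)
    row(lab[i], tval, p, if (fp < alpha) p else NA_real_)
  })
  rbind(omnibus, do.call(rbind, res))
}

checkSurvival <- function(records) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(records)))
    stop("survival records need columns time, event, group")
  if (any(records$time <= 0)) stop("survival times must be positive")
  records$event <- as.logical(records$event)
  if (anyNA(records$event)) stop("event must be logical or 0/1")
  records
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator honoring right-censoring; each curve starts at
#' probability 1 at time 0.
#'
#' @param records data.frame with columns time (> 0), event (TRUE =
#'   observed, FALSE = censored) and group.
#' @return data.frame with columns group, time, n_risk, n_event,
#'   survival.
#' @export
kmEstimate <- function(records) {
  records <- checkSurvival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                              unique(records$group))
    else fit$strata
  grp <- rep(sub("^group=", "", names(strata)), strata)
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Gehan-Breslow-Wilcoxon two-sample test
#'
#' Weighted log-rank test with weight equal to the total number at risk
#' at each event time, so early differences between the survival curves
#' weigh more than late ones (the generalized Wilcoxon of Gehan and
#' Breslow).  Returns the 1-d.f. chi-square statistic and p-value.
#'
#' @param records data.frame (time, event, group) with exactly two
#'   groups, both non-empty.
#' @return list with chi_square, p, observed_minus_expected, variance.
#' @export
gehanBreslowWilcoxon <- function(records) {
  records <- checkSurvival(records)
  lev <- sort(unique(records$group))
  if (length(lev) != 2L) stop("exactly two groups required")
  if (!any(records$event)) stop("no events observed")
  times <- sort(unique(records$time[records$event]))
  U <- 0; V <- 0
  for (t in times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & records$group == lev[1L])
    d <- sum(records$time == t & records$event)
    d1 <- sum(records$time == t & records$event & records$group == lev[1L])
    w <- n
    U <- U + w * (d1 - d * n1 / n)
    if (n > 1L)
      V <- V + w^2 * d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chi_square = 0, p = 1,
                          observed_minus_expected = U, variance = 0))
  chi <- U^2 / V
  list(chi_square = chi, p = pchisq(chi, df = 1L, lower.tail = FALSE),
       observed_minus_expected = U, variance = V)
}

#' Unweighted log-rank statistic (for comparison with the Gehan weights)
#'
#' @param records two-group survival records.
#' @return list with chi_square and p.
#' @export
logRankTest <- function(records) {
  records <- checkSurvival(records)
  lev <- sort(unique(records$group))
  if (length(lev) != 2L) stop("exactly two groups required")
  times <- sort(unique(records$time[records$event]))
  U <- 0; V <- 0
  for (t in times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & records$group == lev[1L])
    d <- sum(records$time == t & records$event)
    d1 <- sum(records$time == t & records$event & records$group == lev[1L])
    U <- U + (d1 - d * n1 / n)
    if (n > 1L)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) U^2 / V else 0
  list(chi_square = chi, p = pchisq(chi, df = 1L, lower.tail = FALSE))
}
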