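#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS test against a normal distribution with mean and SD estimated from the
#' sample, using the Lilliefors correction for the estimated parameters.
#'
#' @param x Numeric vector, n >= 4, non-constant.
#' @return A `stat_result` list: `method`, `statistic` (D), `p`, `n`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector", call. = FALSE)
  res <- nortest::lillie.test(x)
  stat_result("ks_lilliefors", statistic = unname(res$statistic),
              p = res$p.value, n = length(x))
}

stat_result <- function(method, ...) {
  structure(c(list(method = method), list(...)), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("[%s]", x$method))
  for (nm in setdiff(names(x), "method")) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1)
      cat(sprintf(" %s=%.4g", nm, v))
  }
  cat("\n")
  invisible(x)
}

check_complete_design <- function(table, within, between = NULL) {
  facs <- c("subject", within, between)
  missing_cols <- setdiff(c(facs, "value"), names(table))
  if (length(missing_cols))
    stop("long table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cells <- table(table$subject, interaction(table[within], drop = FALSE))
  if (any(cells != 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)
    lab <- apply(utils::head(bad, 5), 1, function(ij)
      paste0(rownames(cells)[ij[1]], " x ", colnames(cells)[ij[2]]))
    stop("incomplete/unbalanced design at subject x cell: ",
         paste(lab, collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Repeated-measures analysis of variance
#'
#' Univariate RM-ANOVA on a complete balanced long table with one or two
#' within-subject factors and an optional between-subjects factor (used for
#' the condition-order covariate), built on error strata
#' `Error(subject / (within factors))`. Returns one row per effect.
#'
#' @param table Long data.frame with columns `subject`, the factors, and
#'   `value` (one row per subject x within-cell).
#' @param within Character vector of within-subject factor column names.
#' @param between Optional single between-subjects factor column name.
#' @return Data.frame with columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(table, within, between = NULL) {
  check_complete_design(table, within, between)
  df <- table
  df$subject <- factor(df$subject)
  for (f in c(within, between)) df[[f]] <- factor(df[[f]])
  within_term <- paste(within, collapse = " * ")
  rhs <- if (is.null(between)) within_term
         else paste0(within_term, " * ", between)
  fml <- stats::as.formula(sprintf(
    "value ~ %s + Error(subject/(%s))", rhs, within_term))
  fit <- stats::aov(fml, data = df)
  tidy_aov_error(fit)
}

# flatten a multi-stratum aov summary into effect rows
tidy_aov_error <- function(fit) {
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    rn <- trimws(rownames(tab))
    resid_row <- which(rn == "Residuals")
    if (!length(resid_row)) next
    df2 <- tab$Df[resid_row]
    for (i in setdiff(seq_len(nrow(tab)), resid_row)) {
      if (is.na(tab$`F value`[i])) next
      out[[length(out) + 1L]] <- data.frame(
        effect = rn[i], df1 = tab$Df[i], df2 = df2,
        F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired contrast with dual effect-size conventions
#'
#' Two-tailed paired t-test with df = n - 1. Two effect-size conventions are
#' both reported, because the literature uses either without always saying
#' which: `r_t = sqrt(t^2 / (t^2 + df))` from the t statistic, and
#' `r_z = |Z| / sqrt(2 n)` where Z is the normal-approximation statistic of
#' the matching Wilcoxon signed-rank test on the same pairs. Cohen's dz is
#' included as well.
#'
#' @param x,y Paired numeric vectors of equal length, n >= 2.
#' @return A `stat_result`: `statistic` (t), `df`, `p`, `mean_diff`,
#'   `dz`, `r_t`, `r_z`, `n`.
#' @export
paired_contrast <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of paired differences", call. = FALSE)
  tval <- mean(d) / (sdd / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(tval), df)
  wz <- tryCatch(wilcoxon_signed_rank(x, y, exact_max_n = 0L)$z,
                 error = function(e) NA_real_)
  stat_result("paired_t", statistic = tval, df = df, p = p,
              mean_diff = mean(d), dz = mean(d) / sdd,
              r_t = sqrt(tval^2 / (tval^2 + df)),
              r_z = if (is.na(wz)) NA_real_ else abs(wz) / sqrt(2 * n),
              n = n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped and tied absolute differences receive
#' mid-ranks. For `n` nonzero differences at most `exact_max_n`, the
#' two-tailed p-value is computed by full enumeration of all `2^n` sign
#' assignments (via a dynamic-programming convolution over the doubled
#' mid-ranks, so ties are handled exactly); otherwise a normal approximation
#' with continuity correction and a tie-corrected variance is used. The
#' approximate Z is always reported (it feeds the `r_z` effect size).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max_n Largest n for which the exact enumeration is used.
#' @return A `stat_result`: `statistic` (W, sum of positive-signed ranks),
#'   `p`, `z`, `n` (nonzero differences), `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max_n = 20L) {
  stopifnot(length(x) == length(y))
  d <- (x - y)[is.finite(x - y)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))                       # mid-ranks for ties
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
       else 0
  if (n <= exact_max_n) {
    p <- wilcoxon_exact_p(r, W)
    return(stat_result("wilcoxon_signed_rank", statistic = W, p = p,
                       z = z, n = n, exact = TRUE))
  }
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  stat_result("wilcoxon_signed_rank", statistic = W, p = p, z = z, n = n,
              exact = FALSE)
}

# exact two-tailed p by enumerating all 2^n sign assignments of the ranks:
# dynamic programming over doubled ranks (mid-ranks are multiples of 1/2)
wilcoxon_exact_p <- function(r, W) {
  d2 <- as.integer(round(2 * r))
  total <- sum(d2)
  counts <- numeric(total + 1L)          # counts[s + 1] = #subsets with sum s
  counts[1L] <- 1
  for (k in d2) {
    shifted <- c(numeric(k), counts[seq_len(total + 1L - k)])
    counts <- counts + shifted
  }
  mu2 <- total / 2
  obs_dev <- abs(2 * W - mu2)
  s <- 0:total
  p <- sum(counts[abs(s - mu2) >= obs_dev - 1e-9]) / 2^length(r)
  min(1, p)
}

#' Rank-transform analysis of covariance
#'
#' Nonparametric fallback for the condition effect when the outcome is
#' non-normal: the outcome is rank-transformed across *all* observations
#' (subjects and conditions pooled), then the same covariate-adjusted
#' repeated-measures model used for the raw outcome is applied to the
#' ranks, and the condition effect is tested by its within-subject F.
#' Invariant to any monotone transform of the outcome. The df follow the
#' within-subject error stratum of the rank model.
#'
#' @param table Long data.frame with `subject`, `condition`, the covariate
#'   column, and `value`.
#' @param covariate Between-subjects covariate column name (the day the
#'   subject received control stimulation), treated as a factor.
#' @return A `stat_result`: `statistic` (condition F), `df1`, `df2`, `p`.
#' @export
rank_ancova <- function(table, covariate = "order") {
  check_complete_design(table, "condition")
  if (!covariate %in% names(table))
    stop("covariate column not found: ", covariate, call. = FALSE)
  df <- table
  df$value <- rank(df$value)
  res <- rm_anova(df, within = "condition", between = covariate)
  i <- which(res$effect == "condition")
  stat_result("rank_ancova", statistic = res$F[i],
              df1 = res$df1[i], df2 = res$df2[i], p = res$p[i])
}

#' Intraclass correlation, two-way mixed, consistency, average measures
#'
#' ICC(3,k): from the two-way (subjects x sessions) ANOVA decomposition,
#' `ICC = (MS_subjects - MS_error) / MS_subjects`, where MS_error is the
#' residual after removing subject and session effects. Measures whether
#' subjects keep their relative standing across sessions (additive session
#' shifts do not reduce it). The F test is `MS_subjects / MS_error` with
#' df `(n - 1, (n - 1)(k - 1))`.
#'
#' @param mat Numeric matrix, subjects x sessions, no missing cells,
#'   at least 2 rows and 2 columns.
#' @return A `stat_result`: `icc`, `statistic` (F), `df1`, `df2`, `p`.
#' @export
icc_consistency_average <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("missing cells in ICC matrix", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  grand <- mean(mat)
  ssr <- k * sum((rowMeans(mat) - grand)^2)
  ssc <- n * sum((colMeans(mat) - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (msr > 0) (msr - mse) / msr else NA_real_
  f <- msr / mse
  stat_result("icc_3k_consistency_average", icc = icc, statistic = f,
              df1 = n - 1, df2 = (n - 1) * (k - 1),
              p = stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

#' Bayes factor for a Pearson correlation (log BF10)
#'
#' Default Bayesian correlation test: the stretched-beta prior of width 1 on
#' the population correlation (i.e. uniform on (-1, 1)) combined with
#' Jeffreys' approximate sampling density of the observed correlation r,
#' `f(r | rho) %prop% (1 - rho^2)^((n-1)/2) / (1 - rho r)^(n - 3/2)`,
#' marginalized by numerical integration. `log BF10 < 0` favours the null.
#'
#' @param x,y Numeric vectors, n >= 4, non-constant.
#' @return A `stat_result`: `log_bf10`, `r`, `n`.
#' @export
bayes_cor_logbf <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  r <- stats::cor(x, y)
  # likelihood ratio f(r | rho) / f(r | 0); the rho-free factors cancel
  lik_ratio <- function(rho)
    exp(((n - 1) / 2) * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r))
  bf10 <- stats::integrate(function(rho) 0.5 * lik_ratio(rho), -1, 1,
                           rel.tol = 1e-10)$value
  stat_result("bayes_pearson_cor", log_bf10 = log(bf10), r = r, n = n)
}

#' Power of a two-tailed paired t-test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and df `n - 1`.
#'
#' @param dz Standardized paired effect size (mean difference / SD of
#'   differences).
#' @param n Sample size (pairs), >= 2.
#' @param alpha Two-tailed significance level.
#' @return Power in (0, 1).
#' @export
paired_ttest_power <- function(dz, n, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, all(n >= 2))
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- dz * sqrt(n)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Smallest sample size reaching a target power
#'
#' @param dz Standardized paired effect size (nonzero).
#' @param power Target power in (0, 1).
#' @param alpha Two-tailed significance level.
#' @param n_max Search ceiling.
#' @return Smallest integer n with paired-t power >= `power`.
#' @export
solve_n <- function(dz, power = 0.95, alpha = 0.05, n_max = 1e6) {
  stopifnot(power > 0, power < 1)
  if (dz == 0 && power > alpha)
    stop("no finite n reaches the target power at dz = 0", call. = FALSE)
  n <- 2
  while (n <= n_max) {
    if (paired_ttest_power(dz, n, alpha) >= power) return(as.integer(n))
    n <- n + 1
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}

#' Stay probabilities by previous reward and transition type
#'
#' The behavioural signature of the two learning systems: for each pair of
#' consecutive valid trials, "stay" means repeating the previous stage-1
#' choice. Model-free control predicts a main effect of previous reward on
#' staying; model-based control predicts a reward x transition interaction
#' (rewarded-common and unrewarded-rare promote staying). Cell probabilities
#' and a logistic regression of stay on effect-coded previous reward
#' (+1 rewarded / -1 not) and transition (+1 common / -1 rare) are returned.
#'
#' @param trials Data.frame of one session's trials ordered by `trial`, with
#'   `choice1`, `reward`, `transition`, `valid` (and `trial` indices).
#' @return A `stay_prob_table` list: `table` (2x2 stay probabilities, rows
#'   previous reward 0/1, columns previous transition common/rare),
#'   `n_pairs`, `coefficients` (intercept, reward, transition, interaction;
#'   `NA` with `separation = TRUE` if the logistic fit separated),
#'   `empty_cells`.
#' @export
stay_probability_table <- function(trials) {
  tr <- trials[order(trials$trial), ]
  idx <- which(tr$valid[-1] & tr$valid[-nrow(tr)] &
               diff(tr$trial) == 1) + 1L
  if (length(idx) < 2L)
    stop("need at least 2 consecutive valid trial pairs", call. = FALSE)
  stay <- as.integer(tr$choice1[idx] == tr$choice1[idx - 1L])
  prev_rew <- tr$reward[idx - 1L]
  prev_trans <- tr$transition[idx - 1L]
  tab <- matrix(NA_real_, 2, 2,
                dimnames = list(reward = c("0", "1"),
                                transition = c("common", "rare")))
  for (rw in 0:1) for (tt in c("common", "rare")) {
    sel <- prev_rew == rw & prev_trans == tt
    if (any(sel)) tab[as.character(rw), tt] <- mean(stay[sel])
  }
  empty <- sum(is.na(tab))
  re <- 2 * prev_rew - 1
  te <- ifelse(prev_trans == "common", 1, -1)
  co <- rep(NA_real_, 4)
  names(co) <- c("intercept", "reward", "transition", "interaction")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stay ~ re * te, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!separation && all(is.finite(stats::coef(fit))) &&
      all(abs(stats::coef(fit)) < 15)) {
    co[] <- stats::coef(fit)
  } else {
    separation <- TRUE
  }
  structure(list(table = tab, n_pairs = length(stay), coefficients = co,
                 empty_cells = empty, separation = separation),
            class = "stay_prob_table")
}

#' @export
print.stay_prob_table <- function(x, ...) {
  cat(sprintf("stay probabilities over %d pairs:\n", x$n_pairs))
  print(round(x$table, 3))
  cat("logistic coefficients:\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Second-stage response-time slowing after rare transitions
#'
#' Computes each subject's mean valid stage-2 RT separately for common and
#' rare transitions, then tests the rare - common slowing across subjects
#' with a paired t-test. More goal-directed subjects slow more after rare
#' transitions. Subjects lacking valid trials of either type are excluded
#' with a warning.
#'
#' @param trials Data.frame with `subject`, `transition`, `rt2_ms`, `valid`.
#' @return List with `per_subject` (subject, mean common/rare RT, slowing)
#'   and `test` (a [paired_contrast()] `stat_result`, or `NULL` if fewer
#'   than 2 usable subjects).
#' @export
rt_by_transition <- function(trials) {
  ok <- trials$valid & is.finite(trials$rt2_ms)
  tr <- trials[ok, ]
  subjects <- unique(tr$subject)
  rows <- lapply(subjects, function(s) {
    g <- tr[tr$subject == s, ]
    mc <- mean(g$rt2_ms[g$transition == "common"])
    mr <- mean(g$rt2_ms[g$transition == "rare"])
    data.frame(subject = s, rt_common_ms = mc, rt_rare_ms = mr,
               slowing_ms = mr - mc)
  })
  per <- do.call(rbind, rows)
  usable <- is.finite(per$slowing_ms)
  if (any(!usable))
    warning("excluding subject(s) without both transition types: ",
            paste(per$subject[!usable], collapse = ", "), call. = FALSE)
  per <- per[usable, ]
  test <- if (nrow(per) >= 2L && stats::sd(per$slowing_ms) > 0)
    paired_contrast(per$rt_rare_ms, per$rt_common_ms) else NULL
  list(per_subject = per, test = test)
}

#' Per-subject condition ratios of w and precision
#'
#' Relates the goal-directedness shift to the working-memory shift:
#' `delta_w = w_control / w_IPS->LPFC` and
#' `delta_p = p_IPS->LPFC / p_control`, per subject. Non-positive
#' denominators give missing values with a flag.
#'
#' @param w_ctrl,w_ips_lpfc Per-subject fitted w in the control and
#'   IPS->LPFC conditions.
#' @param p_ctrl,p_ips_lpfc Per-subject WM precision in the two conditions.
#' @return Data.frame with `delta_w`, `delta_p`, `delta_w_flagged`,
#'   `delta_p_flagged`.
#' @export
delta_ratios <- function(w_ctrl, w_ips_lpfc, p_ctrl, p_ips_lpfc) {
  stopifnot(length(w_ctrl) == length(w_ips_lpfc),
            length(p_ctrl) == length(p_ips_lpfc),
            length(w_ctrl) == length(p_ctrl))
  dw_bad <- !is.finite(w_ips_lpfc) | w_ips_lpfc <= 0
  dp_bad <- !is.finite(p_ctrl) | p_ctrl <= 0
  data.frame(
    delta_w = ifelse(dw_bad, NA_real_, w_ctrl / w_ips_lpfc),
    delta_p = ifelse(dp_bad, NA_real_, p_ips_lpfc / p_ctrl),
    delta_w_flagged = dw_bad,
    delta_p_flagged = dp_bad)
}
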