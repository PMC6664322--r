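test_that("normality screening separates normal from skewed samples", {
  withr::with_seed(1, x <- rnorm(500))
  expect_gt(ks_normality(x)$p, 0.05)

  withr::with_seed(2, {
    rejected <- mean(replicate(40, ks_normality(exp(rnorm(29)))$p < 0.05))
  })
  expect_gt(rejected, 0.5)

  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("repeated-measures ANOVA produces textbook df and null F", {
  tab <- null_w_table(29)
  res <- rm_anova(tab, within = "condition")
  cond <- res[res$effect == "condition", ]
  expect_equal(c(cond$df1, cond$df2), c(2, 56))

  # remove the condition means exactly: condition SS is 0 up to rounding
  # while genuine within-subject residual variance remains
  centred <- tab
  centred$value <- centred$value - ave(centred$value, centred$condition)
  res0 <- rm_anova(centred, within = "condition")
  expect_lt(res0[res0$effect == "condition", "F"], 1e-10)
})

test_that("condition F grows with an injected shift", {
  withr::with_seed(3, {
    f_at <- vapply(c(0, 0.1, 0.3), function(shift) {
      tab <- null_w_table(29)
      tab$value[tab$condition == "IPS_to_LPFC"] <-
        tab$value[tab$condition == "IPS_to_LPFC"] + shift
      res <- rm_anova(tab, within = "condition")
      res[res$effect == "condition", "F"]
    }, numeric(1))
  })
  expect_true(all(diff(f_at) > 0))
})

test_that("incomplete designs are rejected with the offending cells", {
  tab <- null_w_table(8)
  tab <- tab[-1, ]
  expect_error(rm_anova(tab, within = "condition"), "incomplete|unbalanced")
})

test_that("paired contrast matches the closed-form t and its effect sizes", {
  expect_error(paired_contrast(1:5, 1:5), "zero variance")

  withr::with_seed(4, {
    x <- rnorm(29); y <- x - 0.4 + rnorm(29, 0, 0.5)
  })
  res <- paired_contrast(x, y)
  d <- x - y
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(29)), tolerance = 1e-12)
  expect_equal(res$df, 28)
  expect_equal(res$p, 2 * pt(-abs(res$statistic), 28), tolerance = 1e-12)
  expect_equal(res$r_t, sqrt(res$statistic^2 / (res$statistic^2 + 28)),
               tolerance = 1e-12)
  expect_true(res$r_z > 0 && res$r_z < 1)

  # two-condition RM-ANOVA F equals the squared paired t
  tab <- data.frame(subject = rep(1:29, 2),
                    condition = rep(c("a", "b"), each = 29),
                    value = c(x, y))
  f <- rm_anova(tab, within = "condition")
  expect_equal(f[f$effect == "condition", "F"], res$statistic^2,
               tolerance = 1e-9)
})

test_that("exact Wilcoxon enumeration matches brute force and wilcox.test", {
  # all-positive differences: p = 2/2^5
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_true(res$exact)
  expect_equal(res$p, 0.0625)

  # antisymmetric differences sit at the null mean
  res2 <- wilcoxon_signed_rank(c(4, 3, 2, -2, -3, -4), rep(0, 6))
  expect_equal(res2$p, 1)

  withr::with_seed(5, {
    for (rep in 1:5) {
      x <- rnorm(10); y <- rnorm(10)
      ours <- wilcoxon_signed_rank(x, y)
      expect_equal(ours$p, wilcoxon_bruteforce_p(x - y), tolerance = 1e-12)
    }
    # tie-free case agrees with the base-R exact test (independent oracle)
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(wilcoxon_signed_rank(x, y)$p,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    # mid-ranked ties still match brute force
    x <- c(3, 3, 5, 1, 1, 9, 2); y <- c(1, 1, 2, 3, 3, 2, 1)
    expect_equal(wilcoxon_signed_rank(x, y)$p,
                 wilcoxon_bruteforce_p(x - y), tolerance = 1e-12)
  })

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "all paired differences")
})

test_that("exact and approximate Wilcoxon p-values agree at moderate n", {
  withr::with_seed(6, {
    diffs <- vapply(1:10, function(i) {
      x <- rnorm(15); y <- rnorm(15)
      pe <- wilcoxon_signed_rank(x, y, exact_max_n = 20)$p
      pa <- wilcoxon_signed_rank(x, y, exact_max_n = 0)$p
      abs(pe - pa)
    }, numeric(1))
  })
  expect_lt(max(diffs), 0.02)
})

test_that("rank ANCOVA is invariant to monotone outcome transforms", {
  withr::with_seed(7, tab <- null_w_table(18))
  f1 <- rank_ancova(tab)$statistic
  tab2 <- tab
  tab2$value <- exp(5 * tab2$value)
  expect_equal(rank_ancova(tab2)$statistic, f1, tolerance = 1e-12)

  # power grows with an injected shift
  withr::with_seed(8, {
    f_shift <- vapply(c(0, 0.3), function(s) {
      t2 <- null_w_table(29)
      t2$value[t2$condition == "IPS_to_LPFC"] <-
        t2$value[t2$condition == "IPS_to_LPFC"] + s
      rank_ancova(t2)$statistic
    }, numeric(1))
  })
  expect_gt(f_shift[2], f_shift[1])
})

test_that("ICC(3,k) matches an independent ANOVA decomposition", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8), 4, 3)
  fit <- stats::aov(value ~ subject + session, data = data.frame(
    value = as.vector(m),
    subject = factor(rep(1:4, 3)),
    session = factor(rep(1:3, each = 4))))
  ms <- summary(fit)[[1]]$`Mean Sq`
  expected <- (ms[1] - ms[3]) / ms[1]
  res <- icc_consistency_average(m)
  expect_equal(res$icc, expected, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(3, 6))

  # additive per-session shifts leave consistency at 1
  base <- matrix(rnorm(12), 4, 3)
  shifted <- sweep(matrix(base[, 1], 4, 3), 2, c(0, 5, -2), "+")
  expect_equal(icc_consistency_average(shifted)$icc, 1, tolerance = 1e-9)

  # pure noise has no subject effect: ICC scatters around zero (the
  # estimator is slightly negatively biased under the null, shrinking with
  # the number of subjects)
  withr::with_seed(9, {
    iccs <- replicate(200, icc_consistency_average(matrix(rnorm(90), 30))$icc)
  })
  expect_lt(abs(mean(iccs)), 0.15)
  expect_lt(abs(median(iccs)), 0.15)
})

test_that("correlation Bayes factor favours the truth at n = 30", {
  withr::with_seed(10, {
    x <- rnorm(30)
    y0 <- rnorm(30)
    y0 <- residuals(lm(y0 ~ x))          # exactly zero sample correlation
    expect_lt(bayes_cor_logbf(x, y0)$log_bf10, 0)
    y1 <- x + rnorm(30, 0, 0.45)         # strong correlation (~0.9)
    expect_gt(bayes_cor_logbf(x, y1)$log_bf10, 1)
  })
  expect_error(bayes_cor_logbf(1:3, 2:4), "at least 4")
  expect_error(bayes_cor_logbf(rep(1, 10), rnorm(10)), "constant")
})

test_that("paired-t power analysis reproduces the design calculation", {
  expect_equal(solve_n(0.7, power = 0.95, alpha = 0.05), 29L)
  expect_equal(paired_ttest_power(0, 50), 0.05, tolerance = 1e-9)
  expect_error(solve_n(0, power = 0.95), "no finite n")
  pw <- paired_ttest_power(0.5, c(5, 10, 20, 40, 80))
  expect_true(all(diff(pw) > 0))
})

test_that("stay probabilities and their logistic signature are computed", {
  # an agent that always repeats: every cell at 1, logistic fit separates
  tr <- make_trials(choice1 = rep(0L, 30),
                    state2 = rep(c("B", "C"), 15),
                    choice2 = rep(0L, 30),
                    reward = rep(c(1L, 0L), each = 15),
                    transition = rep(c("common", "rare"), 15))
  res <- stay_probability_table(tr)
  expect_true(all(res$table == 1, na.rm = TRUE))
  expect_true(res$separation)

  # constructed reward-driven stay behaviour gives a positive reward coef
  withr::with_seed(11, {
    n <- 400
    prev_rew <- rep(0:1, each = n / 2)
    prev_trans <- rep(c("common", "rare"), n / 2)
    stay <- rbinom(n, 1, ifelse(prev_rew == 1, 0.8, 0.3))
    c1 <- integer(n + 1)
    c1[1] <- 0L
    for (i in seq_len(n)) c1[i + 1] <- if (stay[i]) c1[i] else 1L - c1[i]
    tr2 <- make_trials(choice1 = c1,
                       state2 = "B", choice2 = 0L,
                       reward = c(prev_rew, 0L),
                       transition = c(prev_trans, "common"))
  })
  res2 <- stay_probability_table(tr2)
  expect_false(res2$separation)
  expect_gt(res2$coefficients[["reward"]], 0.5)
  expect_lt(abs(res2$coefficients[["interaction"]]),
            res2$coefficients[["reward"]])
})

test_that("RT slowing after rare transitions is recovered as constructed", {
  withr::with_seed(12, {
    rows <- lapply(1:12, function(s) {
      trans <- rep(c("common", "rare"), each = 30)
      rt <- 700 + (trans == "rare") * 100 + rnorm(60, 0, 30)
      data.frame(subject = s, transition = trans, rt2_ms = rt, valid = TRUE)
    })
    tr <- do.call(rbind, rows)
  })
  res <- rt_by_transition(tr)
  expect_equal(mean(res$per_subject$slowing_ms), 100, tolerance = 10)
  expect_lt(res$test$p, 0.001)

  # identical distributions give a near-zero difference
  withr::with_seed(13, {
    tr0 <- tr
    tr0$rt2_ms <- 700 + rnorm(nrow(tr0), 0, 30)
  })
  expect_lt(abs(mean(rt_by_transition(tr0)$per_subject$slowing_ms)), 15)

  # a subject with no rare trials is excluded with a warning
  lop <- rbind(tr, data.frame(subject = 99, transition = "common",
                              rt2_ms = 700, valid = TRUE))
  expect_warning(res2 <- rt_by_transition(lop), "99")
  expect_false(99 %in% res2$per_subject$subject)
})

test_that("condition ratios follow their definitions and flag zeros", {
  r <- delta_ratios(0.3, 0.6, 2, 4)
  expect_equal(r$delta_w, 0.5)
  expect_equal(r$delta_p, 2)

  eq <- delta_ratios(0.4, 0.4, 3, 3)
  expect_equal(eq$delta_w, 1)
  expect_equal(eq$delta_p, 1)

  z <- delta_ratios(c(0.3, 0.2), c(0.6, 0), c(0, 2), c(1, 3))
  expect_true(is.na(z$delta_p[1]) && z$delta_p_flagged[1])
  expect_true(is.na(z$delta_w[2]) && z$delta_w_flagged[2])
})
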