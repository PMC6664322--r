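struct <- transition_structure(0.7)

test_that("unconstrained transform is a numerical inverse pair", {
  p <- model_params(1, 1, 0.5, 0.5, 0.5, 0, 0.5)
  round_trip <- from_unconstrained(to_unconstrained(p))
  expect_equal(unlist(round_trip), unlist(p), tolerance = 1e-9)

  expect_equal(unname(to_unconstrained(p)["w"]), 0)
  pe <- model_params(exp(1), 1, 0.5, 0.5, 0.5, 0, 0.5)
  expect_equal(unname(to_unconstrained(pe)["beta1"]), 1, tolerance = 1e-12)

  # boundary values are clipped, not mapped to infinities
  pb <- model_params(0, 5, 0, 1, 1, 0, 1)
  th <- to_unconstrained(pb)
  expect_true(all(is.finite(th)))
  back <- unlist(from_unconstrained(th))
  expect_equal(back[["alpha1"]], 0, tolerance = 1e-5)
  expect_equal(back[["w"]], 1, tolerance = 1e-5)
})

test_that("fitting recovers a strongly model-based generator", {
  gen <- model_params(5, 5, 0.7, 0.7, 0.6, 0.1, 0.95)
  env <- build_session(task_config(n_trials = 1000), 0, 21)
  tr <- simulate_agent(gen, env, seed = 22)
  fit <- fit_subject(tr, struct, fit_settings(n_restarts = 6), seed = 23)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$w - 0.95), 0.15)
  # maximization contract: at least as good as the generating parameters
  expect_gte(fit$loglik, session_loglik(gen, tr, struct) - 1e-6)
})

test_that("a coin-flip responder is fitted as effectively value-blind", {
  # with choices independent of values the stage-1 likelihood is flat along
  # (beta1, alpha1, w) trade-offs, so beta1 alone can drift; the robust
  # statement of "near-zero reliability" is that the fitted model predicts
  # no better than coin flipping and assigns ~0.5 to every stage-1 choice
  rand <- model_params(0, 0, 0.5, 0.5, 0.5, 0, 0.5)
  env <- build_session(task_config(n_trials = 1000), 0, 31)
  tr <- simulate_agent(rand, env, seed = 32)
  fit <- fit_subject(tr, struct, fit_settings(n_restarts = 6), seed = 33)
  ll_uniform <- 2 * nrow(tr) * log(0.5)
  expect_lt(fit$loglik - ll_uniform, 10)     # no real structure found
  p <- fit$estimates
  qs <- q_state(); prev <- NULL; dev <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    tri <- tr[i, ]
    pr <- stage1_probs(p, qs$q_mf, mb_stage1_values(qs$q2, struct), prev)
    dev[i] <- abs(pr[tri$choice1 + 1] - 0.5)
    qs <- apply_updates(p, qs, tri)$qstate
    prev <- tri$choice1
  }
  expect_lt(mean(dev), 0.05)
})

test_that("zero valid trials is a data error", {
  tr <- make_trials(valid = FALSE)
  expect_error(fit_subject(tr, struct), "zero valid trials")
})

test_that("more restarts never worsen the returned likelihood", {
  gen <- default_params()
  env <- build_session(task_config(), 0, 41)
  tr <- simulate_agent(gen, env, seed = 42)
  ll <- vapply(c(1, 3, 6), function(k)
    fit_subject(tr, struct, fit_settings(n_restarts = k), seed = 7)$loglik,
    numeric(1))
  expect_true(all(diff(ll) >= -1e-9))
})

test_that("profile MLE of w matches a dense grid search", {
  gen <- model_params(4, 4, 0.6, 0.6, 0.5, 0, 0.9)
  env <- build_session(task_config(n_trials = 300), 0, 51)
  tr <- simulate_agent(gen, env, seed = 52)
  prof <- function(w) session_loglik(
    model_params(4, 4, 0.6, 0.6, 0.5, 0, w), tr, struct)
  grid <- seq(0, 1, by = 0.002)
  w_grid <- grid[which.max(vapply(grid, prof, numeric(1)))]
  w_opt <- stats::optimize(prof, c(0, 1), maximum = TRUE)$maximum
  expect_lt(abs(w_opt - w_grid), 0.002)
})

test_that("recovery study tabulates and flags degenerate samplers", {
  sampler <- function(n) data.frame(
    beta1 = 5, beta2 = 5, alpha1 = runif(n, 0.3, 0.9),
    alpha2 = runif(n, 0.3, 0.9), lam = runif(n), persev = 0,
    w = runif(n))
  rep <- recovery_study(sampler, n_agents = 6, n_trials = 300, seed = 61,
                        settings = fit_settings(n_restarts = 4))
  expect_equal(nrow(rep$agents), 6)
  expect_true(all(abs(stats::na.omit(rep$summary$correlation)) <= 1))
  expect_true(rep$summary$degenerate[rep$summary$parameter == "beta1"])
  expect_false(rep$summary$degenerate[rep$summary$parameter == "w"])

  degen <- function(n) data.frame(beta1 = rep(5, n), beta2 = 5,
                                  alpha1 = 0.5, alpha2 = 0.5, lam = 0.5,
                                  persev = 0, w = 0.5)
  rep2 <- recovery_study(degen, n_agents = 2, n_trials = 50, seed = 62,
                         settings = fit_settings(n_restarts = 2))
  expect_true(all(rep2$summary$degenerate))
  expect_true(all(is.na(rep2$summary$correlation)))
})

test_that("estimates always respect the parameter limits", {
  env <- build_session(task_config(), 0, 71)
  withr::with_seed(72, {
    for (rep in 1:3) {
      gen <- model_params(runif(1, 0, 8), runif(1, 0, 8), runif(1),
                          runif(1), runif(1), rnorm(1), runif(1))
      tr <- simulate_agent(gen, env, seed = rep)
      fit <- fit_subject(tr, struct, fit_settings(n_restarts = 3),
                         seed = rep)
      e <- fit$estimates
      expect_true(e$beta1 >= 0 && e$beta2 >= 0)
      expect_true(all(unlist(e[c("alpha1", "alpha2", "lam", "w")]) >= 0))
      expect_true(all(unlist(e[c("alpha1", "alpha2", "lam", "w")]) <= 1))
    }
  })
})
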