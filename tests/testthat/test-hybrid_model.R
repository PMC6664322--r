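struct <- transition_structure(0.7)

test_that("model-based values apply the transition-weighted max", {
  q2 <- matrix(0, 2, 2, dimnames = list(c("B", "C"), NULL))
  expect_equal(mb_stage1_values(q2, struct), c(0, 0))

  q2["B", ] <- c(1, 0)
  expect_equal(mb_stage1_values(q2, struct), c(0.7, 0.3))

  s_half <- transition_structure(0.5 + 1e-12)
  q2r <- matrix(runif(4), 2, 2, dimnames = list(c("B", "C"), NULL))
  v <- mb_stage1_values(q2r, s_half)
  expect_equal(v[1], v[2], tolerance = 1e-9)
})

test_that("stage-1 softmax mixes values and perseveration correctly", {
  p0 <- default_params(persev = 0)
  expect_equal(stage1_probs(p0, c(0, 0), c(0, 0)), c(0.5, 0.5))

  pz <- default_params(beta1 = 0, persev = 0)
  expect_equal(stage1_probs(pz, c(3, -1), c(2, 5)), c(0.5, 0.5))

  p1 <- default_params(beta1 = 1, persev = 0, w = 0)
  pr <- stage1_probs(p1, c(1, 0), c(0, 0))
  expect_equal(pr[1], 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(sum(pr), 1)
})

test_that("stage-2 softmax follows beta2 and the q gap", {
  p <- default_params()
  q2 <- matrix(c(0.4, 0.1, 0.4, 0.9), 2, 2,
               dimnames = list(c("B", "C"), NULL))
  expect_equal(stage2_probs(p, matrix(0.4, 2, 2,
                                      dimnames = list(c("B", "C"), NULL)),
                            "B"),
               c(0.5, 0.5))

  pg <- default_params(beta2 = 2)
  q2g <- matrix(c(0.5, 0, 0, 0), 2, 2, dimnames = list(c("B", "C"), NULL))
  expect_equal(stage2_probs(pg, q2g, "B")[1], 1 / (1 + exp(-1)),
               tolerance = 1e-9)

  ph <- default_params(beta2 = 200)
  expect_gt(stage2_probs(ph, q2g, "B")[1], 0.999)

  expect_error(stage2_probs(p, q2, "D"), "state2")
})

test_that("value updates match the hand-traced SARSA(lambda) recursion", {
  frozen <- default_params(alpha1 = 0, alpha2 = 0)
  st <- q_state()
  out <- apply_updates(frozen, st, make_trials())
  expect_equal(out$qstate$q_mf, st$q_mf)
  expect_equal(out$qstate$q2, st$q2)

  full <- default_params(alpha1 = 1, alpha2 = 1, lam = 1)
  out2 <- apply_updates(full, q_state(), make_trials(reward = 1L))
  expect_equal(out2$trace$delta1, 0)
  expect_equal(out2$trace$delta2, 1)
  expect_equal(out2$qstate$q2["B", 1], 1)
  expect_equal(out2$qstate$q_mf[1], 1)

  inv <- make_trials(valid = FALSE)
  out3 <- apply_updates(full, q_state(0.5), inv)
  expect_equal(out3$qstate, q_state(0.5))
  expect_true(is.na(out3$trace$delta1))
})

test_that("session log-likelihood handles uniform, empty and invalid cases", {
  unif <- default_params(beta1 = 0, beta2 = 0, persev = 0)
  expect_equal(session_loglik(unif, make_trials(), struct), 2 * log(0.5),
               tolerance = 1e-9)

  none <- make_trials()[0, ]
  expect_equal(session_loglik(default_params(), none, struct), 0)

  skipped <- make_trials(choice1 = c(0L, 1L), state2 = c("B", "C"),
                         choice2 = c(0L, 1L), reward = c(1L, 0L),
                         valid = c(FALSE, FALSE))
  expect_equal(session_loglik(default_params(), skipped, struct), 0)

  expect_error(session_loglik(c(NA, 1, 1, 1, 1, 0, 1),
                              make_trials(), struct), "non-finite")
})

test_that("exp(loglik) sums to one over all choice sequences", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      params <- model_params(runif(1, 0, 8), runif(1, 0, 8), runif(1),
                             runif(1), runif(1), rnorm(1), runif(1))
      expect_equal(enumerate_loglik_mass(params, "B", 1L, struct), 1,
                   tolerance = 1e-12)
      states <- sample(c("B", "C"), 2, replace = TRUE)
      rewards <- sample(0:1, 2, replace = TRUE)
      expect_equal(enumerate_loglik_mass(params, states, rewards, struct),
                   1, tolerance = 1e-12)
    }
  })
})

test_that("compiled and R likelihoods agree on random sessions", {
  withr::with_seed(7, {
    env <- build_session(task_config(), 0, 11)
    for (rep in 1:5) {
      params <- model_params(runif(1, 0, 6), runif(1, 0, 6), runif(1),
                             runif(1), runif(1), rnorm(1), runif(1))
      tr <- simulate_agent(params, env, seed = rep, miss_rate = 0.05)
      expect_equal(session_loglik(params, tr, struct, use_cpp = TRUE),
                   session_loglik(params, tr, struct, use_cpp = FALSE),
                   tolerance = 1e-12)
    }
  })
})

test_that("strong perseveration repeats the last valid choice", {
  sticky <- default_params(beta1 = 0, beta2 = 0, persev = 50)
  pr <- stage1_probs(sticky, c(0, 0), c(0, 0), prev_choice1 = 1)
  expect_gt(pr[2], 0.999999)
})

test_that("simulated sessions are reproducible and schema-complete", {
  env <- build_session(task_config(), 0, 3)
  p <- default_params()
  a <- simulate_agent(p, env, seed = 5)
  b <- simulate_agent(p, env, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 67)
  expect_true(all(a$choice1 %in% 0:1))
  expect_true(all(a$state2 %in% c("B", "C")))
  expect_true(all(a$transition %in% c("common", "rare")))
  # transition label consistent with (choice1, state2) under the structure
  cs <- attr(env$structure, "common_state")
  expect_equal(a$transition == "common",
               cs[paste0("a", a$choice1)] == a$state2,
               ignore_attr = TRUE)
})
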