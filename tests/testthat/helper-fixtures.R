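# shared fixtures and independent oracles, built in code at test time

default_params <- function(...) {
  args <- utils::modifyList(
    list(beta1 = 5, beta2 = 5, alpha1 = 0.6, alpha2 = 0.6, lam = 0.6,
         persev = 0.2, w = 0.8),
    list(...))
  do.call(model_params, args)
}

# a trial table with explicit fields (defaults give one valid trial)
make_trials <- function(choice1 = 0L, state2 = "B", choice2 = 0L,
                        reward = 1L, transition = "common",
                        rt2_ms = NA_real_, valid = TRUE) {
  data.frame(trial = seq_along(choice1), choice1 = choice1,
             state2 = state2, choice2 = choice2, reward = reward,
             transition = transition, rt2_ms = rt2_ms, valid = valid)
}

# enumeration oracle: sum of exp(session log-likelihood) over every choice
# sequence for a fixed state/reward sequence must equal 1
enumerate_loglik_mass <- function(params, states, rewards, structure) {
  n <- length(states)
  grid <- expand.grid(rep(list(0:1), 2 * n))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    ch <- as.integer(grid[i, ])
    tr <- make_trials(choice1 = ch[seq_len(n)], state2 = states,
                      choice2 = ch[n + seq_len(n)], reward = rewards)
    total <- total + exp(session_loglik(params, tr, structure))
  }
  total
}

# brute-force exact Wilcoxon two-tailed p by explicit 2^n sign enumeration
# (independent of the package's dynamic-programming implementation)
wilcoxon_bruteforce_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# small cohort configuration used by pipeline-level tests
small_cohort_config <- function(...) {
  cohort_config(n_subjects = 8L, wm_n_trials = 30L,
                task = task_config(n_trials = 40L), ...)
}

# long table with exchangeable conditions: subject effect plus noise on the
# unit interval, counterbalanced order factor (null calibration model)
null_w_table <- function(n_subjects = 29, noise_sd = 0.15) {
  b <- rbeta(n_subjects, 1.3, 2.5)
  orders <- twostepfit:::perm3()[(seq_len(n_subjects) - 1L) %% 6L + 1L, ]
  conds <- c("control", "LPFC_to_IPS", "IPS_to_LPFC")
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    pos <- match(1:3, orders[i, ])   # serial position of each condition
    data.frame(subject = i, condition = conds,
               session_order = pos,
               order = pos[1],       # day of control stimulation
               value = pmin(pmax(b[i] + rnorm(3, 0, noise_sd), 0), 1))
  }))
}
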