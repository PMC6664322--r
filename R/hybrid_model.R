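#' Hybrid model parameters
#'
#' The seven parameters of the hybrid model-free/model-based learner:
#' stage-wise softmax choice reliabilities (inverse temperatures) `beta1`,
#' `beta2` in \[0, Inf); stage-wise learning rates `alpha1`, `alpha2` in
#' \[0, 1\]; the reinforcement eligibility `lam` in \[0, 1\] (how much of the
#' stage-2 reward prediction error propagates to the stage-1 model-free
#' value); an unbounded stage-1 perseveration rate `persev`; and the
#' model-based weighting `w` in \[0, 1\] (0 = purely habitual/model-free,
#' 1 = purely goal-directed/model-based).
#'
#' @param beta1,beta2 Choice reliability (inverse temperature), >= 0.
#' @param alpha1,alpha2 Learning rates in \[0, 1\].
#' @param lam Eligibility in \[0, 1\].
#' @param persev Perseveration rate, any finite real.
#' @param w Model-based weighting in \[0, 1\].
#' @return An object of class `model_params` (named numeric list).
#' @export
model_params <- function(beta1, beta2, alpha1, alpha2, lam, persev, w) {
  p <- list(beta1 = beta1, beta2 = beta2, alpha1 = alpha1, alpha2 = alpha2,
            lam = lam, persev = persev, w = w)
  vals <- unlist(p)
  if (any(!is.finite(vals)))
    stop("all model parameters must be finite", call. = FALSE)
  if (beta1 < 0 || beta2 < 0)
    stop("beta1 and beta2 must be >= 0", call. = FALSE)
  for (nm in c("alpha1", "alpha2", "lam", "w"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("%s must lie in [0, 1]", nm), call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("hybrid model parameters:\n")
  print(round(unlist(x), 4))
  invisible(x)
}

# canonical parameter order used throughout the package
PARAM_NAMES <- c("beta1", "beta2", "alpha1", "alpha2", "lam", "persev", "w")

# floor applied to choice probabilities before taking logs, keeping the
# optimizer objective finite at extreme parameter values
PROB_FLOOR <- 1e-12

#' Initial Q-value state
#'
#' @param q_init Initialization constant for all action values (default 0).
#' @return A `q_state` list with `q_mf` (2 stage-1 model-free values) and
#'   `q2` (2x2 stage-2 values, rows states B/C, columns actions 0/1).
#' @export
q_state <- function(q_init = 0) {
  structure(list(
    q_mf = rep(q_init, 2),
    q2 = matrix(q_init, 2, 2, dimnames = list(c("B", "C"), c("a0", "a1")))),
    class = "q_state")
}

#' Model-based stage-1 action values
#'
#' Bellman evaluation of the stage-1 actions under the (true, fixed)
#' transition structure: `Q_MB(a) = sum_s P(s | a) * max_a' q2(s, a')`.
#'
#' @param q2 2x2 matrix of stage-2 values (rows states B/C, cols actions).
#' @param structure A [transition_structure()].
#' @return Numeric vector of 2 model-based values.
#' @export
mb_stage1_values <- function(q2, structure) {
  stopifnot(all(is.finite(q2)))
  best <- apply(q2, 1, max)   # max over actions within each state
  as.numeric(structure %*% best)
}

#' Stage-1 choice probabilities
#'
#' Softmax over `beta1 * (w * q_mb + (1 - w) * q_mf) + persev * rep(a)`,
#' where `rep(a)` indicates that `a` repeats the previous valid stage-1
#' choice (0 for both actions on the first trial).
#'
#' @param params A [model_params()].
#' @param q_mf,q_mb Length-2 stage-1 value vectors.
#' @param prev_choice1 Previous valid stage-1 choice (0/1) or `NULL`/`NA`.
#' @return Probability pair summing to 1.
#' @export
stage1_probs <- function(params, q_mf, q_mb, prev_choice1 = NULL) {
  net <- params$beta1 * (params$w * q_mb + (1 - params$w) * q_mf)
  if (!is.null(prev_choice1) && !is.na(prev_choice1))
    net[prev_choice1 + 1L] <- net[prev_choice1 + 1L] + params$persev
  softmax2(net)
}

#' Stage-2 choice probabilities
#'
#' Softmax over `beta2 * q2(state2, .)`.
#'
#' @param params A [model_params()].
#' @param q2 2x2 stage-2 value matrix.
#' @param state2 `"B"` or `"C"`.
#' @return Probability pair summing to 1.
#' @export
stage2_probs <- function(params, q2, state2) {
  if (!(length(state2) == 1L && state2 %in% c("B", "C")))
    stop("`state2` must be \"B\" or \"C\"", call. = FALSE)
  softmax2(params$beta2 * q2[state2, ])
}

softmax2 <- function(v) {
  v <- v - max(v)           # guard against overflow
  e <- exp(v)
  p <- e / sum(e)
  unname(p)
}

#' Apply the hybrid model's value updates for one trial
#'
#' SARSA(lambda)-style updates. With stage-1 choice `a1`, stage-2 state `s`,
#' stage-2 choice `a2` and reward `r`:
#' `delta1 = q2(s, a2) - q_mf(a1)`; `q_mf(a1) += alpha1 * delta1`;
#' `delta2 = r - q2(s, a2)`; `q2(s, a2) += alpha2 * delta2`;
#' `q_mf(a1) += alpha1 * lam * delta2`. Invalid (missed) trials leave the
#' state untouched and return an empty trace.
#'
#' @param params A [model_params()].
#' @param qstate A [q_state()].
#' @param trial One-row data.frame (or list) with `choice1`, `state2`,
#'   `choice2`, `reward`, `valid`.
#' @return List with the updated `qstate` and a `trace` (prediction errors
#'   `delta1`, `delta2`; both `NA` for invalid trials).
#' @export
apply_updates <- function(params, qstate, trial) {
  if (!isTRUE(as.logical(trial$valid)))
    return(list(qstate = qstate,
                trace = list(delta1 = NA_real_, delta2 = NA_real_)))
  a1 <- trial$choice1 + 1L
  s  <- as.character(trial$state2)
  a2 <- trial$choice2 + 1L
  r  <- as.numeric(trial$reward)
  q2sa <- qstate$q2[s, a2]
  delta1 <- q2sa - qstate$q_mf[a1]
  qstate$q_mf[a1] <- qstate$q_mf[a1] + params$alpha1 * delta1
  delta2 <- r - q2sa
  qstate$q2[s, a2] <- q2sa + params$alpha2 * delta2
  qstate$q_mf[a1] <- qstate$q_mf[a1] + params$alpha1 * params$lam * delta2
  list(qstate = qstate, trace = list(delta1 = delta1, delta2 = delta2))
}

#' Session log-likelihood of the hybrid model
#'
#' Sums, over valid trials, the log probability of the observed stage-1 and
#' stage-2 choices under the hybrid model, applying the value updates after
#' each valid trial. Invalid trials contribute nothing and trigger no
#' update; perseveration is keyed to the last *valid* stage-1 choice.
#' Choice probabilities are floored at `1e-12` before the log.
#'
#' The default path runs a compiled C++ kernel; `use_cpp = FALSE` runs an
#' equivalent pure-R reference implementation (used for cross-checking).
#'
#' @param params A [model_params()] (or named numeric vector in canonical
#'   order beta1, beta2, alpha1, alpha2, lam, persev, w).
#' @param trials Data.frame of trials with columns `choice1`, `state2`,
#'   `choice2`, `reward`, `valid`.
#' @param structure A [transition_structure()].
#' @param q_init Q-value initialization constant.
#' @param use_cpp Use the compiled kernel (default) or the R reference.
#' @return Log-likelihood (0 for a session with no valid trials).
#' @export
session_loglik <- function(params, trials, structure, q_init = 0,
                           use_cpp = TRUE) {
  p <- as_param_vector(params)
  if (any(!is.finite(p))) stop("non-finite parameter", call. = FALSE)
  if (nrow(trials) == 0L) return(0)
  if (use_cpp) {
    return(cpp_session_loglik(
      p,
      as.integer(trials$choice1),
      as.integer(trials$state2 == "C"),
      as.integer(trials$choice2),
      as.numeric(trials$reward),
      as.logical(trials$valid),
      attr(structure, "common_prob"),
      q_init, PROB_FLOOR))
  }
  session_loglik_r(p, trials, structure, q_init)
}

# pure-R reference implementation of the likelihood recursion
session_loglik_r <- function(p, trials, structure, q_init = 0) {
  params <- do.call(model_params, as.list(p))
  qs <- q_state(q_init)
  prev <- NULL
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (!isTRUE(as.logical(tr$valid))) next
    qmb <- mb_stage1_values(qs$q2, structure)
    p1 <- stage1_probs(params, qs$q_mf, qmb, prev)
    p2 <- stage2_probs(params, qs$q2, as.character(tr$state2))
    ll <- ll + log(max(p1[tr$choice1 + 1L], PROB_FLOOR)) +
               log(max(p2[tr$choice2 + 1L], PROB_FLOOR))
    qs <- apply_updates(params, qs, tr)$qstate
    prev <- tr$choice1
  }
  ll
}

as_param_vector <- function(params) {
  if (inherits(params, "model_params")) return(unlist(params)[PARAM_NAMES])
  v <- unlist(params)
  if (!is.null(names(v)) && all(PARAM_NAMES %in% names(v)))
    return(v[PARAM_NAMES])
  if (length(v) != 7L)
    stop("parameters must be a model_params or a length-7 vector",
         call. = FALSE)
  stats::setNames(as.numeric(v), PARAM_NAMES)
}

#' Simulate an agent playing a two-step session
#'
#' Generates trials by sampling stage-1 and stage-2 choices from the hybrid
#' model, the transition from the session's transition structure, and reward
#' as Bernoulli with the walk probability of the visited option at that
#' trial. Optionally marks a fraction of trials invalid (missed deadline)
#' and attaches stage-2 response times with rare-transition slowing scaled
#' by the agent's goal-directedness `w`.
#'
#' @param params A [model_params()].
#' @param env A `session_env` from [build_session()].
#' @param seed Integer seed (full trial sequence reproducible).
#' @param q_init Q-value initialization constant.
#' @param miss_rate Probability a trial is invalid (no update, no choices
#'   recorded as usable); fields of invalid trials are still filled so the
#'   schema stays rectangular.
#' @param rt_model `NULL` for `NA` response times, or a list with
#'   `base_ms`, `rare_slowing_ms`, `w_gain`, `noise_sd_ms`: then
#'   `rt2 = base + rare_slowing * (1 + w_gain * w) * is_rare + noise`,
#'   truncated below at 150 ms.
#' @return Data.frame of trials: `trial`, `choice1`, `state2`, `choice2`,
#'   `reward`, `transition` ("common"/"rare"), `rt2_ms`, `valid`.
#' @export
simulate_agent <- function(params, env, seed, q_init = 0, miss_rate = 0,
                           rt_model = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(env, "session_env"))
  n <- env$config$n_trials
  withr::with_seed(as.integer(seed), {
    # scalar state kept in plain vectors/matrices for speed; the update
    # arithmetic mirrors apply_updates()
    q_mf <- rep(q_init, 2)
    q2 <- matrix(q_init, 2, 2, dimnames = list(c("B", "C"), c("a0", "a1")))
    cp <- attr(env$structure, "common_prob")
    prev <- NA_integer_
    choice1 <- integer(n); choice2 <- integer(n); reward <- integer(n)
    state2 <- character(n); transition <- character(n)
    rt2_ms <- rep(NA_real_, n); valid <- logical(n)
    beta1 <- params$beta1; beta2 <- params$beta2
    for (t in seq_len(n)) {
      best <- c(max(q2[1, ]), max(q2[2, ]))
      qmb <- c(cp * best[1] + (1 - cp) * best[2],
               (1 - cp) * best[1] + cp * best[2])
      net <- beta1 * (params$w * qmb + (1 - params$w) * q_mf)
      if (!is.na(prev)) net[prev + 1L] <- net[prev + 1L] + params$persev
      p1 <- 1 / (1 + exp(net[1] - net[2]))          # P(choice1 = 1)
      c1 <- as.integer(stats::runif(1) < p1)
      sB <- stats::runif(1) < (if (c1 == 0L) cp else 1 - cp)
      s <- if (sB) 1L else 2L
      common <- (c1 == 0L) == sB
      p2 <- 1 / (1 + exp(beta2 * (q2[s, 1] - q2[s, 2])))
      c2 <- as.integer(stats::runif(1) < p2)
      r <- as.integer(stats::runif(1) < env$walks[t, (s - 1L) * 2L + c2 + 1L])
      ok <- stats::runif(1) >= miss_rate
      if (!is.null(rt_model)) {
        rt <- rt_model$base_ms +
          (!common) * rt_model$rare_slowing_ms *
            (1 + rt_model$w_gain * params$w) +
          stats::rnorm(1, 0, rt_model$noise_sd_ms)
        rt2_ms[t] <- max(rt, 150)
      }
      choice1[t] <- c1; choice2[t] <- c2; reward[t] <- r
      state2[t] <- c("B", "C")[s]
      transition[t] <- if (common) "common" else "rare"
      valid[t] <- ok
      if (ok) {
        q2sa <- q2[s, c2 + 1L]
        delta1 <- q2sa - q_mf[c1 + 1L]
        q_mf[c1 + 1L] <- q_mf[c1 + 1L] + params$alpha1 * delta1
        delta2 <- r - q2sa
        q2[s, c2 + 1L] <- q2sa + params$alpha2 * delta2
        q_mf[c1 + 1L] <- q_mf[c1 + 1L] + params$alpha1 * params$lam * delta2
        prev <- c1
      }
    }
    data.frame(trial = seq_len(n), choice1 = choice1, state2 = state2,
               choice2 = choice2, reward = reward, transition = transition,
               rt2_ms = rt2_ms, valid = valid)
  })
}

# retained reference implementation of the generative loop, written directly
# on the module operations; simulate_agent must match it draw-for-draw
simulate_agent_reference <- function(params, env, seed, q_init = 0,
                                     miss_rate = 0, rt_model = NULL) {
  n <- env$config$n_trials
  withr::with_seed(as.integer(seed), {
    qs <- q_state(q_init)
    prev <- NULL
    out <- data.frame(trial = seq_len(n), choice1 = NA_integer_,
                      state2 = NA_character_, choice2 = NA_integer_,
                      reward = NA_integer_, transition = NA_character_,
                      rt2_ms = NA_real_, valid = TRUE)
    for (t in seq_len(n)) {
      qmb <- mb_stage1_values(qs$q2, env$structure)
      p1 <- stage1_probs(params, qs$q_mf, qmb, prev)
      c1 <- as.integer(stats::runif(1) < p1[2])
      tr2 <- sample_transition(c1, env$structure)
      p2 <- stage2_probs(params, qs$q2, tr2$state2)
      c2 <- as.integer(stats::runif(1) < p2[2])
      pcol <- paste0("p", tr2$state2, c2)
      r <- as.integer(stats::runif(1) < env$walks[t, pcol])
      valid <- stats::runif(1) >= miss_rate
      rt <- NA_real_
      if (!is.null(rt_model)) {
        rt <- rt_model$base_ms +
          (!tr2$is_common) * rt_model$rare_slowing_ms *
            (1 + rt_model$w_gain * params$w) +
          stats::rnorm(1, 0, rt_model$noise_sd_ms)
        rt <- max(rt, 150)
      }
      out[t, c("choice1", "choice2", "reward")] <- list(c1, c2, r)
      out$state2[t] <- tr2$state2
      out$transition[t] <- if (tr2$is_common) "common" else "rare"
      out$rt2_ms[t] <- rt
      out$valid[t] <- valid
      if (valid) {
        qs <- apply_updates(params, qs, out[t, ])$qstate
        prev <- c1
      }
    }
    out
  })
}
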