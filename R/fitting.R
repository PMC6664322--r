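#' Transform parameters to and from unconstrained space
#'
#' Maximum-likelihood search runs on an unconstrained reparameterization:
#' log for the nonnegative choice reliabilities `beta1`, `beta2`; logit for
#' the unit-interval parameters `alpha1`, `alpha2`, `lam`, `w`; identity for
#' `persev`. Values exactly at a bound are clipped inward by `eps` before
#' transforming so the map stays finite; `from_unconstrained()` inverts the
#' map, so the round trip is the identity up to that clip.
#'
#' @param params A [model_params()].
#' @param theta Numeric vector of 7 unconstrained reals in canonical order.
#' @param eps Boundary clip applied before the transform.
#' @return `to_unconstrained()`: named numeric vector of 7 reals;
#'   `from_unconstrained()`: a [model_params()].
#' @export
to_unconstrained <- function(params, eps = 1e-6) {
  p <- as_param_vector(params)
  clip01 <- function(x) pmin(pmax(x, eps), 1 - eps)
  c(beta1 = log(max(p[["beta1"]], eps)),
    beta2 = log(max(p[["beta2"]], eps)),
    alpha1 = stats::qlogis(clip01(p[["alpha1"]])),
    alpha2 = stats::qlogis(clip01(p[["alpha2"]])),
    lam = stats::qlogis(clip01(p[["lam"]])),
    persev = p[["persev"]],
    w = stats::qlogis(clip01(p[["w"]])))
}

#' @rdname to_unconstrained
#' @export
from_unconstrained <- function(theta) {
  stopifnot(length(theta) == 7L, all(is.finite(theta)))
  theta <- unname(theta)
  model_params(beta1 = exp(theta[1]), beta2 = exp(theta[2]),
               alpha1 = stats::plogis(theta[3]),
               alpha2 = stats::plogis(theta[4]),
               lam = stats::plogis(theta[5]),
               persev = theta[6],
               w = stats::plogis(theta[7]))
}

#' Fit settings for per-subject maximum likelihood
#'
#' @param n_restarts Number of random optimizer starts.
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum BFGS iterations per restart.
#' @param start_box Half-width of the uniform box (centred at 0) in
#'   unconstrained space from which starts are drawn.
#' @param q_init Q-value initialization used by the likelihood.
#' @param prior_sd `NULL` for plain maximum likelihood (the default), or a
#'   positive number enabling a ridge-like MAP penalty: an independent
#'   N(0, `prior_sd`^2) prior on every unconstrained parameter (logit for
#'   the unit-interval parameters, log for the betas, identity for the
#'   perseveration rate). A weak prior (e.g. 2) stabilizes estimates on
#'   short sessions where the likelihood is nearly flat in some directions.
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(n_restarts = 10L, reltol = 1e-6, maxit = 500L,
                         start_box = 2.5, q_init = 0, prior_sd = NULL) {
  stopifnot(n_restarts >= 1L, reltol > 0, maxit >= 1L, start_box > 0)
  if (!is.null(prior_sd)) stopifnot(length(prior_sd) == 1L, prior_sd > 0)
  structure(list(n_restarts = as.integer(n_restarts), reltol = reltol,
                 maxit = as.integer(maxit), start_box = start_box,
                 q_init = q_init, prior_sd = prior_sd),
            class = "fit_settings")
}

#' Per-subject maximum-likelihood fit of the hybrid model
#'
#' Maximizes the session log-likelihood by quasi-Newton (BFGS) search in
#' unconstrained parameter space from `n_restarts` random starts, returning
#' the best restart. Deterministic given `seed`.
#'
#' @param trials Data.frame of trials (see [session_loglik()]); must contain
#'   at least one valid trial.
#' @param structure A [transition_structure()].
#' @param settings A [fit_settings()].
#' @param seed Integer seed controlling the restart draws.
#' @return A `fit_result` list: `estimates` ([model_params()]), `loglik`,
#'   `n_restarts`, `best_restart`, `converged`, `n_valid_trials`.
#' @export
fit_subject <- function(trials, structure, settings = fit_settings(),
                        seed = 1L) {
  n_valid <- sum(as.logical(trials$valid))
  if (n_valid < 1L)
    stop("cannot fit a session with zero valid trials", call. = FALSE)
  penalty <- if (is.null(settings$prior_sd)) function(theta) 0
             else function(theta) sum(theta^2) / (2 * settings$prior_sd^2)
  dat_negll <- function(theta) {
    p <- c(exp(theta[1]), exp(theta[2]), stats::plogis(theta[3]),
           stats::plogis(theta[4]), stats::plogis(theta[5]), theta[6],
           stats::plogis(theta[7]))
    -cpp_session_loglik(p,
                        as.integer(trials$choice1),
                        as.integer(trials$state2 == "C"),
                        as.integer(trials$choice2),
                        as.numeric(trials$reward),
                        as.logical(trials$valid),
                        attr(structure, "common_prob"),
                        settings$q_init, PROB_FLOOR)
  }
  negll <- function(theta) dat_negll(theta) + penalty(theta)
  withr::with_seed(as.integer(seed), {
    best <- NULL
    best_val <- Inf
    best_idx <- NA_integer_
    any_conv <- FALSE
    for (k in seq_len(settings$n_restarts)) {
      start <- stats::runif(7, -settings$start_box, settings$start_box)
      fit <- tryCatch(
        stats::optim(start, negll, method = "BFGS",
                     control = list(reltol = settings$reltol,
                                    maxit = settings$maxit)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      if (fit$convergence == 0) any_conv <- TRUE
      if (fit$value < best_val) {
        best_val <- fit$value
        best <- fit
        best_idx <- k
      }
    }
    if (is.null(best))
      return(structure(list(estimates = NULL, loglik = NA_real_,
                            n_restarts = settings$n_restarts,
                            best_restart = NA_integer_, converged = FALSE,
                            n_valid_trials = n_valid),
                       class = "fit_result"))
    structure(list(estimates = from_unconstrained(best$par),
                   # data log-likelihood at the optimum (penalty excluded)
                   loglik = -dat_negll(best$par),
                   n_restarts = settings$n_restarts,
                   best_restart = best_idx,
                   converged = any_conv,
                   n_valid_trials = n_valid),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("hybrid model fit: loglik %.3f over %d valid trials (%s)\n",
              x$loglik, x$n_valid_trials,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Parameter-recovery study
#'
#' Simulates `n_agents` agents with parameters drawn from `param_sampler`,
#' fits each with [fit_subject()], and tabulates true against estimated
#' parameters, with per-parameter Pearson correlation and mean bias
#' (emphasis on the model-based weighting `w`).
#'
#' @param param_sampler Function of one argument `n` returning a data.frame
#'   with the 7 parameter columns in canonical order.
#' @param n_agents Number of simulated agents (>= 2).
#' @param n_trials Session length per agent.
#' @param seed Master integer seed.
#' @param config A [task_config()] template; `n_trials` overrides its count.
#' @param settings A [fit_settings()].
#' @return A `recovery_report` list: `agents` (data.frame of true and
#'   estimated parameters plus fit diagnostics) and `summary` (data.frame of
#'   per-parameter correlation and bias; correlation is `NA` with
#'   `degenerate = TRUE` when a true parameter has zero variance).
#' @export
recovery_study <- function(param_sampler, n_agents, n_trials = 500L,
                           seed = 1L, config = task_config(),
                           settings = fit_settings()) {
  stopifnot(n_agents >= 2L)
  config$n_trials <- as.integer(n_trials)
  seed <- as.integer(seed)
  true <- withr::with_seed(seed, param_sampler(n_agents))
  true <- as.data.frame(true)
  if (nrow(true) == 1L)
    true <- true[rep(1L, n_agents), , drop = FALSE]  # constant samplers
  if (nrow(true) != n_agents)
    stop("param_sampler must return one row per agent", call. = FALSE)
  true <- true[, PARAM_NAMES]
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    sub_seed <- (seed * 613L + i) %% 2147483629L
    env <- build_session(config, walk_id = (i - 1L) %% config$n_walk_sets,
                         seed = sub_seed)
    pars <- do.call(model_params, as.list(true[i, ]))
    trials <- simulate_agent(pars, env, seed = sub_seed + 1L,
                             q_init = settings$q_init)
    fit <- fit_subject(trials, env$structure, settings,
                       seed = sub_seed + 2L)
    est <- if (is.null(fit$estimates)) rep(NA_real_, 7)
           else unlist(fit$estimates)
    rows[[i]] <- c(agent = i, stats::setNames(unlist(true[i, ]),
                                              paste0("true_", PARAM_NAMES)),
                   stats::setNames(est, paste0("est_", PARAM_NAMES)),
                   loglik = fit$loglik, converged = as.numeric(fit$converged))
  }
  agents <- as.data.frame(do.call(rbind, rows))
  summ <- do.call(rbind, lapply(PARAM_NAMES, function(nm) {
    tv <- agents[[paste0("true_", nm)]]
    ev <- agents[[paste0("est_", nm)]]
    ok <- is.finite(tv) & is.finite(ev)
    degen <- sum(ok) < 3L || stats::sd(tv[ok]) == 0 || stats::sd(ev[ok]) == 0
    data.frame(parameter = nm,
               correlation = if (degen) NA_real_
                             else stats::cor(tv[ok], ev[ok]),
               bias = mean(ev[ok] - tv[ok]),
               degenerate = degen)
  }))
  structure(list(agents = agents, summary = summ,
                 n_trials = as.integer(n_trials)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery: %d agents x %d trials\n",
              nrow(x$agents), x$n_trials))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export fit results for a cohort as a CSV table
#'
#' @param fits Data.frame with columns `subject`, `condition`,
#'   `session_order`, the seven parameters, `loglik`, `converged` (as
#'   produced by the pipeline's fit stage).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_fits <- function(fits, path) {
  need <- c("subject", "condition", "session_order", PARAM_NAMES,
            "loglik", "converged")
  missing <- setdiff(need, names(fits))
  if (length(missing))
    stop("fit table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(fits[, need], path, row.names = FALSE)
  invisible(path)
}
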