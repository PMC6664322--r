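# fixed stimulation-condition label set used across all tables
COND_LABELS <- c("control", "LPFC_to_IPS", "IPS_to_LPFC")

#' Synthetic-cohort configuration
#'
#' Defines the generative study conditions for a full synthetic cohort:
#' subjects with per-subject hybrid-model parameters, three
#' counterbalanced stimulation conditions, two-step sessions played by the
#' subject's own parameters, orientation working-memory sessions with
#' load-dependent noise, rare-transition RT slowing scaled by
#' goal-directedness, and opaque questionnaire totals.
#'
#' Defaults emulate the study design the package targets: 29 analysable
#' subjects, three conditions with order counterbalanced over all six
#' permutations, 67 two-step trials and 150 working-memory trials (75 per
#' load) per session, a positively skewed control-condition distribution of
#' the model-based weighting (Beta(1.3, 2.5)), and an additive shift of the
#' true w of +0.15 in the IPS->LPFC condition.
#'
#' @param n_subjects Number of subjects (>= 2; >= 6 for full
#'   counterbalancing).
#' @param conditions The three condition labels (fixed set).
#' @param order_scheme `"all_permutations"` (cycle the 6 condition orders
#'   across subjects) or `"random"`.
#' @param control_w_dist Function of `n` drawing control-condition true w.
#' @param w_shift_ips_lpfc,w_shift_lpfc_ips Additive shifts applied to the
#'   true w in the active conditions (result clipped to \[0, 1\]).
#' @param beta_dist,alpha_dist,lam_dist,persev_dist Functions of `n` drawing
#'   the remaining baseline parameters (betas shared sampler for stages 1
#'   and 2; alphas likewise).
#' @param wm_kappa_by_load Named numeric: von Mises concentration of the
#'   doubled-angle report noise per set size.
#' @param wm_subject_kappa_sd SD of the subject-level log-normal factor
#'   multiplying kappa (stable across conditions; gives realistic
#'   between-subject reliability).
#' @param wm_precision_shift Named per-condition multiplier applied to
#'   kappa (1 = no stimulation effect on working memory).
#' @param rt_base_ms,rt_rare_slowing_ms,rt_slowing_w_gain,rt_noise_sd_ms
#'   Stage-2 RT model: `base + rare_slowing * (1 + gain * w)` on rare
#'   transitions, plus Gaussian noise.
#' @param miss_rate Probability a two-step trial is invalid (missed), in
#'   \[0, 0.2\].
#' @param questionnaire_dists Named list of functions of `n` drawing opaque
#'   questionnaire totals.
#' @param task A [task_config()] for the two-step sessions.
#' @param wm_n_trials,wm_loads Working-memory trial count and the two set
#'   sizes (split equally).
#' @param drop_one_subject Emulate the loss of one subject by dropping a
#'   random one after generation.
#' @param master_seed Integer master seed; the whole cohort is a pure
#'   function of the configuration including this seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 29L,
                          conditions = COND_LABELS,
                          order_scheme = c("all_permutations", "random"),
                          control_w_dist = function(n) stats::rbeta(n, 1.3, 2.5),
                          w_shift_ips_lpfc = 0.15,
                          w_shift_lpfc_ips = 0,
                          beta_dist = function(n) stats::rgamma(n, 6, rate = 1.5),
                          alpha_dist = function(n) stats::rbeta(n, 3, 3),
                          lam_dist = function(n) stats::rbeta(n, 3, 2),
                          persev_dist = function(n) stats::rnorm(n, 0.1, 0.3),
                          wm_kappa_by_load = c("3" = 8, "6" = 2),
                          wm_subject_kappa_sd = 0.3,
                          wm_precision_shift = c(control = 1,
                                                 LPFC_to_IPS = 1,
                                                 IPS_to_LPFC = 1),
                          rt_base_ms = 700,
                          rt_rare_slowing_ms = 50,
                          rt_slowing_w_gain = 1,
                          rt_noise_sd_ms = 150,
                          miss_rate = 0.02,
                          questionnaire_dists = list(
                            oci_r = function(n) pmax(0, round(stats::rnorm(n, 11, 7))),
                            bdi = function(n) pmax(0, round(stats::rnorm(n, 5, 4))),
                            stai_trait = function(n) pmax(20, round(stats::rnorm(n, 36, 8)))),
                          task = task_config(),
                          wm_n_trials = 150L,
                          wm_loads = c(3L, 6L),
                          drop_one_subject = FALSE,
                          master_seed = 1L) {
  order_scheme <- match.arg(order_scheme)
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 2L)
  if (!identical(sort(conditions), sort(COND_LABELS)))
    stop("conditions must be exactly: ",
         paste(COND_LABELS, collapse = ", "), call. = FALSE)
  if (miss_rate < 0 || miss_rate > 0.2)
    stop("`miss_rate` must lie in [0, 0.2]", call. = FALSE)
  if (order_scheme == "all_permutations" && n_subjects < 6L)
    stop("full counterbalancing needs at least 6 subjects (6 condition ",
         "orders); use order_scheme = \"random\"", call. = FALSE)
  stopifnot(wm_n_trials %% length(wm_loads) == 0L)
  structure(as.list(environment()), class = "cohort_config")
}

perm3 <- function() {
  m <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  m
}

#' Generate a full synthetic cohort with sealed ground truth
#'
#' Draws per-subject baseline hybrid-model parameters, applies the
#' configured condition shifts to the true w, simulates every subject x
#' condition two-step session (with RTs and missed trials) and
#' working-memory session, and records the ground truth separately from the
#' "observed" tables. Fully reproducible from the configuration's
#' `master_seed`.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_dataset` list: `twostep`, `wm`, `questionnaires`,
#'   `ground_truth` data.frames plus the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  withr::with_seed(as.integer(config$master_seed), {
    orders <- switch(config$order_scheme,
      all_permutations = perm3()[(seq_len(n) - 1L) %% 6L + 1L, , drop = FALSE],
      random = t(vapply(seq_len(n), function(i) sample(3L), integer(3))))
    walk_ids <- sample(0:(config$task$n_walk_sets - 1L), n, replace = TRUE)
    base <- data.frame(
      subject = seq_len(n),
      beta1 = config$beta_dist(n), beta2 = config$beta_dist(n),
      alpha1 = config$alpha_dist(n), alpha2 = config$alpha_dist(n),
      lam = config$lam_dist(n), persev = config$persev_dist(n),
      w_control = config$control_w_dist(n),
      wm_kappa_factor = exp(stats::rnorm(n, 0, config$wm_subject_kappa_sd)))
    quests <- data.frame(subject = seq_len(n))
    for (nm in names(config$questionnaire_dists))
      quests[[nm]] <- config$questionnaire_dists[[nm]](n)

    shift_for <- c(control = 0,
                   LPFC_to_IPS = config$w_shift_lpfc_ips,
                   IPS_to_LPFC = config$w_shift_ips_lpfc)

    ts_rows <- list(); wm_rows <- list(); gt_rows <- list()
    per_load <- config$wm_n_trials / length(config$wm_loads)
    for (i in seq_len(n)) {
      env <- build_session(config$task, walk_id = walk_ids[i],
                           seed = as.integer(config$master_seed))
      for (ci in seq_along(COND_LABELS)) {
        cond <- COND_LABELS[ci]
        pos <- which(orders[i, ] == ci)   # serial position of this condition
        w_true <- min(1, max(0, base$w_control[i] + shift_for[[cond]]))
        pars <- model_params(base$beta1[i], base$beta2[i], base$alpha1[i],
                             base$alpha2[i], base$lam[i], base$persev[i],
                             w_true)
        sub_seed <- (as.integer(config$master_seed) * 7919L +
                       i * 31L + ci) %% 2147483629L
        rt_model <- list(base_ms = config$rt_base_ms,
                         rare_slowing_ms = config$rt_rare_slowing_ms,
                         w_gain = config$rt_slowing_w_gain,
                         noise_sd_ms = config$rt_noise_sd_ms)
        tr <- simulate_agent(pars, env, seed = sub_seed,
                             miss_rate = config$miss_rate,
                             rt_model = rt_model)
        tr <- cbind(subject = i, condition = cond, session_order = pos, tr)
        ts_rows[[length(ts_rows) + 1L]] <- tr

        loads <- sample(rep(config$wm_loads, each = per_load))
        target <- stats::runif(config$wm_n_trials, 0, pi)
        err <- numeric(config$wm_n_trials)
        for (ld in config$wm_loads) {
          sel <- loads == ld
          k <- config$wm_kappa_by_load[[as.character(ld)]] *
            base$wm_kappa_factor[i] * config$wm_precision_shift[[cond]]
          err[sel] <- rvonmises(sum(sel), 0, k) / 2
        }
        wm_rows[[length(wm_rows) + 1L]] <- data.frame(
          subject = i, condition = cond, session_order = pos,
          trial = seq_len(config$wm_n_trials), load = loads,
          target_theta = target,
          response_theta = (target + err) %% pi)

        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          subject = i, condition = cond, session_order = pos,
          beta1 = base$beta1[i], beta2 = base$beta2[i],
          alpha1 = base$alpha1[i], alpha2 = base$alpha2[i],
          lam = base$lam[i], persev = base$persev[i], w = w_true,
          wm_kappa_load3 = config$wm_kappa_by_load[["3"]] *
            base$wm_kappa_factor[i] * config$wm_precision_shift[[cond]],
          wm_kappa_load6 = config$wm_kappa_by_load[["6"]] *
            base$wm_kappa_factor[i] * config$wm_precision_shift[[cond]],
          walk_id = walk_ids[i])
      }
    }
    ds <- list(twostep = do.call(rbind, ts_rows),
               wm = do.call(rbind, wm_rows),
               questionnaires = quests,
               ground_truth = do.call(rbind, gt_rows),
               config = config)
    if (config$drop_one_subject) {
      drop <- sample(n, 1)
      for (nm in c("twostep", "wm", "questionnaires", "ground_truth"))
        ds[[nm]] <- ds[[nm]][ds[[nm]]$subject != drop, ]
    }
    structure(ds, class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d subjects x %d conditions; %d two-step and %d WM trials\n",
    length(unique(x$twostep$subject)), length(unique(x$twostep$condition)),
    nrow(x$twostep), nrow(x$wm)))
  invisible(x)
}

#' Export / load a cohort as a directory of delimited text files
#'
#' `export_cohort()` writes `twostep.csv`, `wm.csv`, `questionnaires.csv`,
#' `ground_truth.csv`, a `config.yaml` snapshot of the scalar configuration
#' fields, and a `README.md` documenting the schemas. `load_cohort()` reads
#' and validates them back; the round trip reproduces all tables.
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Target/source directory.
#' @return `export_cohort()` returns `dir` invisibly; `load_cohort()` a
#'   `cohort_dataset` (with `config = NULL`: the YAML snapshot documents the
#'   generation settings but function-valued fields are not round-tripped).
#' @export
export_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ts <- dataset$twostep
  ts$valid <- as.integer(ts$valid)
  ts$rt2_ms <- round(ts$rt2_ms, 1)
  utils::write.csv(ts, file.path(dir, "twostep.csv"), row.names = FALSE)
  write_wm_csv(dataset$wm, file.path(dir, "wm.csv"))
  utils::write.csv(dataset$questionnaires,
                   file.path(dir, "questionnaires.csv"), row.names = FALSE)
  gt <- dataset$ground_truth
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  if (!is.null(dataset$config)) {
    cfg <- dataset$config
    scalars <- Filter(function(v) is.numeric(v) || is.character(v) ||
                        is.logical(v), unclass(cfg))
    scalars$task <- Filter(is.numeric, unclass(cfg$task))
    yaml::write_yaml(scalars, file.path(dir, "config.yaml"))
  }
  writeLines(c(
    "# Synthetic cohort files",
    "",
    "- `twostep.csv`: subject, condition, session_order, trial, choice1 (0/1),",
    "  state2 (B/C), choice2 (0/1), reward (0/1), transition (common/rare),",
    "  rt2_ms, valid (0/1).",
    "- `wm.csv`: subject, condition, session_order, trial, load (3/6),",
    "  target_deg, response_deg (orientations in [0, 180) degrees).",
    "- `questionnaires.csv`: subject plus opaque questionnaire totals.",
    "- `ground_truth.csv`: sealed generative parameters per subject x",
    "  condition (hybrid-model parameters incl. true w, WM noise kappas,",
    "  assigned reward walk).",
    "- `config.yaml`: scalar snapshot of the generating configuration.",
    "",
    sprintf("Condition labels: %s.", paste(COND_LABELS, collapse = ", "))),
    file.path(dir, "README.md"))
  invisible(dir)
}

#' @rdname export_cohort
#' @export
load_cohort <- function(dir) {
  req <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file: ", p, call. = FALSE)
    p
  }
  ts <- utils::read.csv(req("twostep.csv"))
  need <- c("subject", "condition", "session_order", "trial", "choice1",
            "state2", "choice2", "reward", "transition", "rt2_ms", "valid")
  missing <- setdiff(need, names(ts))
  if (length(missing))
    stop("twostep.csv missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  badc <- which(!ts$condition %in% COND_LABELS)
  if (length(badc))
    stop("twostep.csv condition label outside the fixed set at row(s): ",
         paste(utils::head(badc, 5), collapse = ", "), call. = FALSE)
  ts$valid <- as.logical(ts$valid)
  wm <- read_wm_csv(req("wm.csv"))
  badc <- which(!wm$condition %in% COND_LABELS)
  if (length(badc))
    stop("wm.csv condition label outside the fixed set at row(s): ",
         paste(utils::head(badc, 5), collapse = ", "), call. = FALSE)
  quests <- utils::read.csv(req("questionnaires.csv"))
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) utils::read.csv(gt_path) else NULL
  structure(list(twostep = ts, wm = wm, questionnaires = quests,
                 ground_truth = gt, config = NULL),
            class = "cohort_dataset")
}

# sample skewness (g1, the moment estimator)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
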