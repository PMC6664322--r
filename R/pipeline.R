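#' Pipeline run configuration
#'
#' @param mode One of `"simulate"`, `"fit"`, `"analyze"`, `"full"`.
#' @param input_dir Directory holding cohort CSVs (for `fit`/`analyze`).
#' @param output_dir Directory for all outputs (created if absent).
#' @param cohort A [cohort_config()] (used by `simulate`/`full`; its
#'   `master_seed` is overridden by `seed`).
#' @param fit A [fit_settings()].
#' @param exact_wilcoxon_max_n Exact-enumeration threshold for the Wilcoxon
#'   test.
#' @param effect_size Which effect-size convention to flag as primary in the
#'   report (`"t_based"` or `"z_based"`); both are always computed.
#' @param chance_correct_precision Chance-correct WM precision.
#' @param seed Master integer seed for the whole run.
#' @param verbose Print stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("full", "simulate", "fit", "analyze"),
                       input_dir = NULL, output_dir = tempfile("twostepfit_"),
                       cohort = cohort_config(), fit = fit_settings(),
                       exact_wilcoxon_max_n = 20L,
                       effect_size = c("t_based", "z_based"),
                       chance_correct_precision = FALSE,
                       seed = 1L, verbose = TRUE) {
  structure(list(mode = match.arg(mode), input_dir = input_dir,
                 output_dir = output_dir, cohort = cohort, fit = fit,
                 exact_wilcoxon_max_n = as.integer(exact_wilcoxon_max_n),
                 effect_size = match.arg(effect_size),
                 chance_correct_precision = chance_correct_precision,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

stage_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[twostepfit] %s", sprintf(fmt, ...)))
}

#' Run the simulate / fit / analyse pipeline
#'
#' Executes the requested stages in order, writing every intermediate CSV
#' and the final JSON report into `output_dir`. The full pipeline is a pure
#' function of (inputs, configuration, seed).
#'
#' @param config A [run_config()].
#' @return A `study_report` list (also written to
#'   `file.path(output_dir, "report.json")` when the analyze stage runs).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- config$input_dir
  dataset <- NULL

  if (config$mode %in% c("simulate", "full")) {
    stage_msg(config, "simulate: generating cohort (seed %d)", config$seed)
    cc <- config$cohort
    cc$master_seed <- config$seed
    dataset <- generate_cohort(cc)
    data_dir <- file.path(config$output_dir, "cohort")
    export_cohort(dataset, data_dir)
    stage_msg(config, "simulate: wrote %s", data_dir)
    if (config$mode == "simulate") return(invisible(dataset))
  }

  if (is.null(data_dir))
    stop("`input_dir` is required for mode ", config$mode, call. = FALSE)
  if (is.null(dataset)) {
    val <- validate_inputs(data_dir)
    if (length(val$errors))
      stop("input validation failed: ", paste(val$errors, collapse = "; "),
           call. = FALSE)
    dataset <- load_cohort(data_dir)
  }

  fits_path <- file.path(config$output_dir, "fits.csv")
  if (config$mode %in% c("fit", "full")) {
    stage_msg(config, "fit: per subject x condition maximum likelihood")
    fits <- fit_cohort(dataset$twostep, settings = config$fit,
                       seed = config$seed)
    export_fits(fits, fits_path)
    stage_msg(config, "fit: wrote %s", fits_path)
    if (config$mode == "fit") return(invisible(fits))
  } else {
    fits_path <- file.path(data_dir, "fits.csv")
    if (!file.exists(fits_path))
      stop("fits table not found: ", fits_path, call. = FALSE)
    fits <- utils::read.csv(fits_path)
  }

  stage_msg(config, "analyze: statistical battery")
  report <- analyze_study(fits, dataset, config)
  report_path <- file.path(config$output_dir, "report.json")
  jsonlite::write_json(report_to_json(report), report_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report_tables(report, file.path(config$output_dir, "report.txt"))
  stage_msg(config, "analyze: wrote %s", report_path)
  invisible(report)
}

#' Fit every subject x condition session of a trial table
#'
#' @param twostep Trial table in the two-step CSV schema.
#' @param settings A [fit_settings()].
#' @param seed Master seed; per-session sub-seeds are derived from it.
#' @return Data.frame: subject, condition, session_order, the seven
#'   parameter estimates, loglik, converged, n_valid_trials.
#' @export
fit_cohort <- function(twostep, settings = fit_settings(), seed = 1L) {
  struct <- transition_structure(infer_common_prob(twostep))
  keys <- unique(twostep[, c("subject", "condition", "session_order")])
  keys <- keys[order(keys$subject, keys$condition), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    tr <- twostep[twostep$subject == k$subject &
                    twostep$condition == k$condition, ]
    sub_seed <- (as.integer(seed) * 2711L + i) %% 2147483629L
    fit <- fit_subject(tr, struct, settings, seed = sub_seed)
    est <- if (is.null(fit$estimates))
      stats::setNames(rep(NA_real_, 7), PARAM_NAMES) else unlist(fit$estimates)
    cbind(k, as.data.frame(as.list(est)),
          loglik = fit$loglik, converged = fit$converged,
          n_valid_trials = fit$n_valid_trials)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the empirical common-transition frequency identifies the design constant;
# round to the nearest .05 grid to undo sampling noise
infer_common_prob <- function(twostep) {
  ok <- twostep$valid & !is.na(twostep$transition)
  p <- mean(twostep$transition[ok] == "common")
  min(max(round(p / 0.05) * 0.05, 0.55), 1)
}

#' Validate a cohort directory
#'
#' Schema, label-set, range, and balance checks over the cohort CSVs.
#' Balance problems (a subject missing a condition) are warnings here but
#' abort the analyze stage, which needs a complete design.
#'
#' @param dir Cohort directory.
#' @return List with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(dir) {
  errors <- character(); warnings <- character()
  ds <- tryCatch(load_cohort(dir), error = function(e) {
    errors <<- c(errors, conditionMessage(e)); NULL
  })
  if (is.null(ds)) return(list(errors = errors, warnings = warnings))
  ts <- ds$twostep
  bad <- which(!(ts$choice1 %in% c(0, 1) | !ts$valid) |
                 !(ts$state2 %in% c("B", "C") | !ts$valid))
  if (length(bad))
    errors <- c(errors, paste0("twostep.csv invalid choice/state at row(s): ",
                               paste(utils::head(bad, 5), collapse = ", ")))
  cells <- table(ts$subject, ts$condition)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    warnings <- c(warnings, apply(miss, 1, function(ij)
      sprintf("subject %s lacks condition %s", rownames(cells)[ij[1]],
              colnames(cells)[ij[2]])))
  }
  wcells <- table(ds$wm$subject, ds$wm$condition)
  if (any(wcells == 0))
    warnings <- c(warnings, "wm.csv has subject x condition gaps")
  list(errors = errors, warnings = warnings)
}

#' Statistical analysis of a fitted cohort
#'
#' Runs the full statistical battery over the fitted w table, the
#' working-memory precision summaries, and the RT data: per-condition
#' descriptives and normality checks, RM-ANOVA with the order covariate,
#' planned contrasts (with a Bonferroni-corrected alpha of .025 for the two
#' active-vs-control comparisons), the exact/approximate Wilcoxon fallback,
#' rank ANCOVA, ICC reliability, the load x condition ANOVA on
#' log-precision, rare-transition RT slowing, the delta-ratio correlation
#' with its Bayes factor, questionnaire correlations, and recovery
#' diagnostics whenever sealed ground truth is available.
#'
#' @param fits Fit table from [fit_cohort()].
#' @param dataset A `cohort_dataset`.
#' @param config A [run_config()].
#' @return A `study_report` list.
#' @export
analyze_study <- function(fits, dataset, config = run_config()) {
  wtab <- fits[, c("subject", "condition", "session_order")]
  wtab$value <- fits$w
  wtab$order <- order_covariate(fits)

  wide_w <- stats::reshape(wtab[, c("subject", "condition", "value")],
                           direction = "wide", idvar = "subject",
                           timevar = "condition")
  names(wide_w) <- sub("^value\\.", "", names(wide_w))
  wide_w <- wide_w[order(wide_w$subject), ]

  descr <- do.call(rbind, lapply(COND_LABELS, function(cc) {
    v <- wtab$value[wtab$condition == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v),
               skew = sample_skewness(v))
  }))

  normality <- lapply(stats::setNames(COND_LABELS, COND_LABELS), function(cc)
    ks_normality(wtab$value[wtab$condition == cc]))

  anova_w <- rm_anova(wtab, within = "condition", between = "order")
  contrast_ips <- paired_contrast(wide_w$IPS_to_LPFC, wide_w$control)
  contrast_lpfc <- paired_contrast(wide_w$LPFC_to_IPS, wide_w$control)
  wilcox_ips <- wilcoxon_signed_rank(wide_w$IPS_to_LPFC, wide_w$control,
                                     exact_max_n = config$exact_wilcoxon_max_n)
  ranked <- rank_ancova(wtab, covariate = "order")
  icc_w <- icc_consistency_average(as.matrix(wide_w[, COND_LABELS]))

  # working-memory precision per subject x condition x load
  wm <- dataset$wm
  prec_rows <- list()
  for (s in unique(wm$subject)) for (cc in COND_LABELS) {
    g <- wm[wm$subject == s & wm$condition == cc, ]
    if (!nrow(g)) next
    pr <- precision_by_load(g, chance_correct = config$chance_correct_precision)
    pr$subject <- s; pr$condition <- cc
    pr$session_order <- g$session_order[1]
    prec_rows[[length(prec_rows) + 1L]] <- pr
  }
  prec <- do.call(rbind, prec_rows)
  ptab <- data.frame(subject = prec$subject, condition = prec$condition,
                     session_order = prec$session_order, load = prec$load,
                     value = log_transform_precision(prec$precision))
  ptab$order <- order_covariate(ptab)
  anova_wm <- rm_anova(ptab, within = c("load", "condition"),
                       between = "order")

  # per subject x condition precision pooled over loads (for ratios / ICC)
  pool_rows <- list()
  for (s in unique(wm$subject)) for (cc in COND_LABELS) {
    g <- wm[wm$subject == s & wm$condition == cc, ]
    if (!nrow(g)) next
    err <- angular_error(g$target_theta, g$response_theta)
    pool_rows[[length(pool_rows) + 1L]] <- data.frame(
      subject = s, condition = cc,
      precision = 1 / circular_sd(err)$sd_rad)
  }
  pool <- do.call(rbind, pool_rows)
  wide_p <- stats::reshape(pool, direction = "wide", idvar = "subject",
                           timevar = "condition")
  names(wide_p) <- sub("^precision\\.", "", names(wide_p))
  wide_p <- wide_p[order(wide_p$subject), ]
  icc_p <- icc_consistency_average(as.matrix(wide_p[, COND_LABELS]))

  rt <- rt_by_transition(dataset$twostep)

  ratios <- delta_ratios(wide_w$control, wide_w$IPS_to_LPFC,
                         wide_p$control, wide_p$IPS_to_LPFC)
  ok <- is.finite(ratios$delta_w) & is.finite(ratios$delta_p)
  ratio_cor <- if (sum(ok) >= 4)
    list(pearson_r = stats::cor(ratios$delta_w[ok], ratios$delta_p[ok]),
         bayes = bayes_cor_logbf(ratios$delta_w[ok], ratios$delta_p[ok]))
  else list(pearson_r = NA_real_, bayes = NULL)

  quest_cor <- NULL
  qdf <- dataset$questionnaires
  if (!is.null(qdf) && nrow(qdf)) {
    qdf <- qdf[order(qdf$subject), ]
    qnames <- setdiff(names(qdf), "subject")
    quest_cor <- do.call(rbind, lapply(qnames, function(qn) {
      ct <- stats::cor.test(qdf[[qn]], wide_w$control)
      data.frame(questionnaire = qn, outcome = "w_control",
                 r = unname(ct$estimate), p = ct$p.value)
    }))
  }

  recovery <- NULL
  if (!is.null(dataset$ground_truth)) {
    gt <- dataset$ground_truth
    m <- merge(fits, gt, by = c("subject", "condition"),
               suffixes = c("_est", "_true"))
    recovery <- data.frame(
      parameter = PARAM_NAMES,
      correlation = vapply(PARAM_NAMES, function(nm) {
        tv <- m[[paste0(nm, "_true")]]; ev <- m[[paste0(nm, "_est")]]
        ok <- is.finite(tv) & is.finite(ev)
        if (sum(ok) < 3 || stats::sd(tv[ok]) == 0 || stats::sd(ev[ok]) == 0)
          NA_real_ else stats::cor(tv[ok], ev[ok])
      }, numeric(1)))
  }

  structure(list(
    descriptives_w = descr, normality_w = normality, anova_w = anova_w,
    contrast_ips_vs_control = contrast_ips,
    contrast_lpfc_vs_control = contrast_lpfc,
    corrected_alpha = 0.025,
    wilcoxon_ips_vs_control = wilcox_ips,
    rank_ancova_w = ranked, icc_w = icc_w,
    anova_wm = anova_wm, icc_precision = icc_p,
    rt_by_transition = rt$test, rt_per_subject = rt$per_subject,
    delta_ratios = ratios, ratio_correlation = ratio_cor,
    questionnaire_correlations = quest_cor,
    recovery = recovery,
    provenance = list(seed = config$seed, effect_size = config$effect_size,
                      chance_correct_precision = config$chance_correct_precision,
                      package_version = as.character(utils::packageVersion("twostepfit")))),
    class = "study_report")
}

# condition order covariate: the session_order at which the subject received
# control stimulation (3-level between-subjects factor)
order_covariate <- function(df) {
  ctrl <- df[df$condition == "control", c("subject", "session_order")]
  ctrl <- unique(ctrl)
  m <- stats::setNames(ctrl$session_order, ctrl$subject)
  as.integer(m[as.character(df$subject)])
}

report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "stat_result")) return(unclass(x))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  lapply(unclass(report)[setdiff(names(report), "rt_per_subject")], strip)
}

write_report_tables <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("== Fitted model-based weighting (w) by condition ==")
  utils::capture.output(print(report$descriptives_w, row.names = FALSE),
                        file = con)
  w("\n== Condition RM-ANOVA on w (order covariate) ==")
  utils::capture.output(print(report$anova_w, row.names = FALSE), file = con)
  w("\n== Planned contrasts (corrected alpha = %.3f) ==",
    report$corrected_alpha)
  utils::capture.output(print(report$contrast_ips_vs_control), file = con)
  utils::capture.output(print(report$contrast_lpfc_vs_control), file = con)
  w("\n== Nonparametric fallbacks ==")
  utils::capture.output(print(report$wilcoxon_ips_vs_control), file = con)
  utils::capture.output(print(report$rank_ancova_w), file = con)
  w("\n== Reliability ==")
  utils::capture.output(print(report$icc_w), file = con)
  utils::capture.output(print(report$icc_precision), file = con)
  w("\n== Working memory: load x condition ANOVA on log precision ==")
  utils::capture.output(print(report$anova_wm, row.names = FALSE), file = con)
  if (!is.null(report$rt_by_transition)) {
    w("\n== Stage-2 RT slowing after rare transitions ==")
    utils::capture.output(print(report$rt_by_transition), file = con)
  }
  if (!is.null(report$ratio_correlation$bayes)) {
    w("\n== Delta-w vs Delta-p association ==")
    utils::capture.output(print(report$ratio_correlation$bayes), file = con)
  }
  invisible(path)
}
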