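#' Two-step task configuration
#'
#' Bundles the parameters of the two-step task environment: the number of
#' trials, the common-transition probability, the Gaussian-random-walk
#' dynamics of the four stage-2 reward probabilities, and the trial timing.
#'
#' Defaults follow the standard two-step design: 67 trials per session,
#' a 0.7/0.3 transition structure, and reward probabilities drifting with
#' per-trial Gaussian steps of SD 0.025, reflected into \[0.25, 0.75\].
#'
#' @param n_trials Number of trials per session.
#' @param common_prob Probability that a stage-1 action leads to its
#'   "common" stage-2 state. Must be in (0.5, 1].
#' @param walk_sd Per-trial SD of the Gaussian increments of the reward
#'   probabilities.
#' @param walk_bounds Length-2 numeric, reflecting bounds `c(lo, hi)` for the
#'   reward probabilities, with `0 <= lo < hi <= 1`.
#' @param walk_init Either `"random"` (initial probabilities drawn uniformly
#'   within `walk_bounds`) or a numeric vector of 4 initial probabilities in
#'   the order pB0, pB1, pC0, pC1.
#' @param n_walk_sets Number of pre-generated reward-walk sets a study uses;
#'   each subject is assigned one of them.
#' @param stage_duration_s,outcome_duration_s,isi_s Stimulus timing, seconds.
#' @param iti_range_s Closed range for the uniformly jittered inter-trial
#'   interval, seconds.
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
#' @export
task_config <- function(n_trials = 67L,
                        common_prob = 0.7,
                        walk_sd = 0.025,
                        walk_bounds = c(0.25, 0.75),
                        walk_init = "random",
                        n_walk_sets = 3L,
                        stage_duration_s = 2.22,
                        outcome_duration_s = 1.11,
                        isi_s = 0.8,
                        iti_range_s = c(0, 3.6)) {
  n_trials <- as.integer(n_trials)
  stopifnot(length(n_trials) == 1L, n_trials >= 1L)
  if (!(length(common_prob) == 1L && common_prob > 0.5 && common_prob <= 1))
    stop("`common_prob` must lie in (0.5, 1]", call. = FALSE)
  if (length(walk_bounds) != 2L || walk_bounds[1] >= walk_bounds[2] ||
      walk_bounds[1] < 0 || walk_bounds[2] > 1)
    stop("`walk_bounds` must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  stopifnot(walk_sd >= 0)
  if (is.numeric(walk_init)) {
    if (length(walk_init) != 4L)
      stop("numeric `walk_init` must have 4 values (pB0, pB1, pC0, pC1)",
           call. = FALSE)
    if (any(walk_init < walk_bounds[1]) || any(walk_init > walk_bounds[2]))
      stop("`walk_init` values must lie within `walk_bounds`", call. = FALSE)
  } else if (!identical(walk_init, "random")) {
    stop("`walk_init` must be \"random\" or a numeric vector of 4 values",
         call. = FALSE)
  }
  stopifnot(stage_duration_s >= 0, outcome_duration_s >= 0, isi_s >= 0,
            length(iti_range_s) == 2L, iti_range_s[1] >= 0,
            iti_range_s[2] >= iti_range_s[1])
  structure(
    list(n_trials = n_trials, common_prob = common_prob, walk_sd = walk_sd,
         walk_bounds = as.numeric(walk_bounds), walk_init = walk_init,
         n_walk_sets = as.integer(n_walk_sets),
         stage_duration_s = stage_duration_s,
         outcome_duration_s = outcome_duration_s, isi_s = isi_s,
         iti_range_s = as.numeric(iti_range_s)),
    class = "task_config")
}

#' Fixed stage-1 to stage-2 transition structure
#'
#' Each stage-1 action (0 or 1) leads to one of two stage-2 states ("B", "C").
#' Action 0's common (modal) state is B, action 1's is C; the common state is
#' reached with probability `common_prob`, the other with its complement.
#'
#' @param common_prob Common-transition probability, in (0.5, 1].
#' @return A 2x2 matrix of transition probabilities with rows `a0`, `a1` and
#'   columns `B`, `C`, class `transition_structure` with attribute
#'   `common_state` (the modal state per action).
#' @export
transition_structure <- function(common_prob = 0.7) {
  if (!(length(common_prob) == 1L && common_prob > 0.5 && common_prob <= 1))
    stop("`common_prob` must lie in (0.5, 1]", call. = FALSE)
  m <- matrix(c(common_prob, 1 - common_prob,
                1 - common_prob, common_prob),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("a0", "a1"), c("B", "C")))
  structure(m, class = c("transition_structure", "matrix", "array"),
            common_state = c(a0 = "B", a1 = "C"),
            common_prob = common_prob)
}

# Reflect values into [lo, hi]; repeated folding handles overshoot > range.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Generate Gaussian-random-walk reward probabilities
#'
#' Produces the per-trial reward probabilities of the four stage-2 options
#' (state B/C x action 0/1). Each option's probability evolves independently:
#' the next value is the current value plus a N(0, `walk_sd`) step, reflected
#' at `walk_bounds` so that the walk stays strictly inside the bounds without
#' piling up on them.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; identical `(config, seed)` gives identical walks.
#' @param walk_id Optional identifier stored on the result (which of the
#'   study's pre-generated walk sets this is).
#' @return A `reward_walk_set`: numeric matrix `n_trials x 4` with columns
#'   `pB0`, `pB1`, `pC0`, `pC1` and attribute `walk_id`.
#' @export
generate_reward_walks <- function(config, seed, walk_id = 0L) {
  stopifnot(inherits(config, "task_config"))
  lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
  if (lo >= hi) stop("degenerate walk bounds: lo >= hi", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    init <- if (is.numeric(config$walk_init)) config$walk_init
            else stats::runif(4, lo, hi)
    n <- config$n_trials
    walks <- matrix(NA_real_, n, 4,
                    dimnames = list(NULL, c("pB0", "pB1", "pC0", "pC1")))
    walks[1, ] <- init
    if (n > 1) {
      for (t in 2:n) {
        step <- stats::rnorm(4, 0, config$walk_sd)
        walks[t, ] <- reflect_into(walks[t - 1, ] + step, lo, hi)
      }
    }
    structure(walks, class = c("reward_walk_set", "matrix", "array"),
              walk_id = as.integer(walk_id))
  })
}

#' Sample a stage-2 state from the transition structure
#'
#' @param action Stage-1 action, 0 or 1.
#' @param structure A [transition_structure()].
#' @return List with `state2` ("B" or "C") and `is_common` (TRUE iff the
#'   modal state of `action` was reached). Uses the current RNG stream.
#' @export
sample_transition <- function(action, structure) {
  if (!(length(action) == 1L && action %in% c(0, 1)))
    stop("`action` must be 0 or 1", call. = FALSE)
  p <- structure[action + 1L, ]
  state2 <- if (stats::runif(1) < p["B"]) "B" else "C"
  common <- attr(structure, "common_state")[[action + 1L]]
  list(state2 = state2, is_common = identical(state2, common))
}

#' Sample an inter-trial interval
#'
#' Uniform draw on the closed jitter range of the task configuration
#' (default \[0, 3.6\] s, mean 1.8 s). Uses the current RNG stream.
#'
#' @param config A [task_config()].
#' @param n Number of draws.
#' @return Numeric vector of ITIs in seconds.
#' @export
sample_iti <- function(config, n = 1L) {
  stopifnot(inherits(config, "task_config"))
  stats::runif(n, config$iti_range_s[1], config$iti_range_s[2])
}

#' Build a playable two-step session environment
#'
#' Assembles the fixed transition structure, one of the study's pre-generated
#' reward-walk sets, and a per-trial ITI schedule. The walk set is derived
#' deterministically from the master seed and `walk_id`, so two sessions with
#' the same seed but different `walk_id` share a transition structure but
#' differ in reward dynamics.
#'
#' @param config A [task_config()].
#' @param walk_id Which pre-generated walk set to use, `0 .. n_walk_sets - 1`.
#' @param seed Master integer seed.
#' @return A `session_env` list: `config`, `structure`, `walks`, `iti_s`
#'   (length `n_trials`).
#' @export
build_session <- function(config, walk_id = 0L, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  walk_id <- as.integer(walk_id)
  if (walk_id < 0L || walk_id >= config$n_walk_sets)
    stop("`walk_id` must be in 0 .. n_walk_sets - 1", call. = FALSE)
  seed <- as.integer(seed)
  # sub-seed derivation keeps the three walk sets fixed functions of the
  # master seed while staying inside 32-bit integer range
  walk_seed <- (abs(seed) * 101L + walk_id) %% 2147483629L
  walks <- generate_reward_walks(config, seed = walk_seed, walk_id = walk_id)
  iti <- withr::with_seed((abs(seed) * 101L + 97L) %% 2147483629L,
                          sample_iti(config, config$n_trials))
  structure(
    list(config = config,
         structure = transition_structure(config$common_prob),
         walks = walks, iti_s = iti),
    class = "session_env")
}

#' Export / import a session environment as delimited text
#'
#' `export_session_env()` writes the per-trial reward probabilities and ITIs
#' as a header CSV (columns `trial`, `pB0`, `pB1`, `pC0`, `pC1`, `iti_s`;
#' trials numbered from 1) plus the configuration as a YAML key-value file.
#' `import_session_env()` reads them back.
#'
#' @param env A `session_env` from [build_session()].
#' @param csv_path,config_path Output/input file paths.
#' @return `export_session_env()` returns `csv_path` invisibly;
#'   `import_session_env()` returns a `session_env`.
#' @export
export_session_env <- function(env, csv_path, config_path = NULL) {
  stopifnot(inherits(env, "session_env"))
  df <- data.frame(trial = seq_len(nrow(env$walks)), env$walks,
                   iti_s = env$iti_s)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(config_path)) {
    cfg <- env$config
    cfg$walk_init <- if (is.numeric(cfg$walk_init)) cfg$walk_init else "random"
    yaml::write_yaml(unclass(cfg), config_path)
  }
  invisible(csv_path)
}

#' @rdname export_session_env
#' @export
import_session_env <- function(csv_path, config_path) {
  cfg_raw <- yaml::read_yaml(config_path)
  config <- do.call(task_config, cfg_raw)
  df <- utils::read.csv(csv_path)
  need <- c("trial", "pB0", "pB1", "pC0", "pC1", "iti_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("session CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  walks <- as.matrix(df[, c("pB0", "pB1", "pC0", "pC1")])
  structure(
    list(config = config,
         structure = transition_structure(config$common_prob),
         walks = structure(walks,
                           class = c("reward_walk_set", "matrix", "array"),
                           walk_id = NA_integer_),
         iti_s = df$iti_s),
    class = "session_env")
}
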