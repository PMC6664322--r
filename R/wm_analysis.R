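#' Signed angular error between two line orientations
#'
#' Line orientations live on a period-pi circle (a line rotated by pi is the
#' same line). The error is `response - target` wrapped the short way around
#' that circle, mapped into `(-pi/2, pi/2]` (the boundary case of exactly
#' half a period maps to `+pi/2` by convention).
#'
#' @param target_theta,response_theta Orientations in radians, in `[0, pi)`.
#'   Vectorized.
#' @return Signed errors in radians, in `(-pi/2, pi/2]`.
#' @export
angular_error <- function(target_theta, response_theta) {
  if (any(target_theta < 0 | target_theta >= pi) ||
      any(response_theta < 0 | response_theta >= pi))
    stop("orientations must lie in [0, pi); pre-normalize inputs",
         call. = FALSE)
  d <- (response_theta - target_theta) %% pi   # into [0, pi)
  ifelse(d > pi / 2, d - pi, d)
}

# documented maximum reported when the resultant length underflows to zero
# (errors uniform on the orientation circle carry no directional information)
CIRC_SD_MAX <- sqrt(-2 * log(1e-12)) / 2

#' Circular standard deviation of orientation errors
#'
#' Errors on the period-pi orientation circle are doubled onto the full
#' circle, where the resultant length `R = |mean(exp(2i * err))|` is
#' computed; the circular SD is `sqrt(-2 log R) / 2` (the halving undoes the
#' doubling). When `R` underflows to zero (uniform errors) the SD is
#' reported as the documented maximum with `resultant_zero = TRUE`.
#'
#' @param errors Signed errors in radians (any values; treated mod pi).
#' @return List with `sd_rad`, `n`, `resultant_length`, `resultant_zero`.
#' @export
circular_sd <- function(errors) {
  errors <- errors[is.finite(errors)]
  n <- length(errors)
  if (n < 2L) stop("need at least 2 error values", call. = FALSE)
  z <- exp(2i * errors)
  R <- Mod(mean(z))
  if (R < 1e-12)
    return(list(sd_rad = CIRC_SD_MAX, n = n, resultant_length = R,
                resultant_zero = TRUE))
  list(sd_rad = sqrt(-2 * log(min(R, 1))) / 2, n = n,
       resultant_length = R, resultant_zero = FALSE)
}

#' Recall precision per memory load
#'
#' Groups working-memory trials by set size, computes the circular SD of the
#' orientation report errors in each group, and returns recall precision as
#' the reciprocal of that SD (rad^-1), with its natural log for downstream
#' parametric analysis. Optionally subtracts the precision expected from
#' uniform random responding, estimated by permuting the responses across
#' trials within the group (`n_perm` shuffles of the target-response
#' pairing) — off by default.
#'
#' A degenerate SD of exactly 0 (all errors identical) yields a missing
#' precision with `degenerate = TRUE`, never an infinity.
#'
#' @param trials Data.frame with columns `target_theta`, `response_theta`
#'   (radians in `[0, pi)`) and `load`; at least 2 trials per load.
#' @param chance_correct Subtract the permutation-estimated chance precision.
#' @param n_perm Number of permutations for the chance estimate.
#' @return Data.frame, one row per load: `load`, `n_trials`,
#'   `circular_sd_rad`, `precision`, `log_precision`, `chance_corrected`,
#'   `degenerate`.
#' @export
precision_by_load <- function(trials, chance_correct = FALSE,
                              n_perm = 100L) {
  stopifnot(all(c("target_theta", "response_theta", "load") %in%
                names(trials)))
  loads <- sort(unique(trials$load))
  out <- lapply(loads, function(ld) {
    g <- trials[trials$load == ld, ]
    if (nrow(g) < 2L)
      stop(sprintf("load %s has fewer than 2 trials", ld), call. = FALSE)
    err <- angular_error(g$target_theta, g$response_theta)
    cs <- circular_sd(err)
    degenerate <- cs$sd_rad == 0
    prec <- if (degenerate) NA_real_ else 1 / cs$sd_rad
    if (chance_correct && !degenerate) {
      chance <- vapply(seq_len(n_perm), function(k) {
        perm_err <- angular_error(g$target_theta,
                                  sample(g$response_theta))
        1 / circular_sd(perm_err)$sd_rad
      }, numeric(1))
      prec <- prec - mean(chance)
    }
    data.frame(load = ld, n_trials = nrow(g),
               circular_sd_rad = cs$sd_rad,
               precision = prec,
               log_precision = if (is.na(prec) || prec <= 0) NA_real_
                               else log(prec),
               chance_corrected = chance_correct,
               degenerate = degenerate)
  })
  do.call(rbind, out)
}

#' Natural-log transform of precision values
#'
#' Applied before parametric analysis (the raw precision distribution is
#' right-skewed; it is approximately normal on the log scale). Missing and
#' non-positive values propagate as missing.
#'
#' @param precision Numeric vector of precisions (rad^-1).
#' @return Numeric vector of the same length.
#' @export
log_transform_precision <- function(precision) {
  out <- rep(NA_real_, length(precision))
  ok <- is.finite(precision) & precision > 0
  out[ok] <- log(precision[ok])
  out
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler on the full circle. Used to
#' generate orientation report noise on the doubled-angle circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, >= 0 (0 gives the uniform distribution).
#' @return Angles in `(-pi, pi]`. Uses the current RNG stream.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa < 1e-6) {
    # wrapped-normal limit avoids pathological rejection constants
    return(((stats::rnorm(n, mu, 1 / sqrt(kappa)) + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- ((theta + pi) %% (2 * pi)) - pi
      i <- i + 1L
    }
  }
  out
}

#' Theoretical circular SD of von Mises orientation noise
#'
#' For report errors whose doubled angles are von Mises with concentration
#' `kappa`, the population resultant length is the Bessel ratio
#' `I1(kappa) / I0(kappa)` and the orientation-scale circular SD is
#' `sqrt(-2 log(I1/I0)) / 2`. Used as a closed-form oracle for the
#' Monte-Carlo estimator.
#'
#' @param kappa Concentration on the doubled circle.
#' @return SD in radians on the orientation (period-pi) scale.
#' @export
vm_orientation_sd <- function(kappa) {
  R <- besselI(kappa, 1) / besselI(kappa, 0)
  sqrt(-2 * log(R)) / 2
}

#' Read / write working-memory trial tables
#'
#' Files store orientations in degrees (`target_deg`, `response_deg`,
#' 0-180); internally the package works in radians in `[0, pi)`.
#'
#' @param trials Data.frame with `subject`, `condition`, `session_order`,
#'   `trial`, `load`, `target_theta`, `response_theta` (radians).
#' @param path CSV path.
#' @return `write_wm_csv()` returns `path` invisibly; `read_wm_csv()` the
#'   trials data.frame with radian columns added.
#' @export
write_wm_csv <- function(trials, path) {
  df <- trials
  df$target_deg <- round(df$target_theta * 180 / pi, 4)
  df$response_deg <- round(df$response_theta * 180 / pi, 4)
  cols <- c("subject", "condition", "session_order", "trial", "load",
            "target_deg", "response_deg")
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wm_csv
#' @export
read_wm_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "condition", "session_order", "trial", "load",
            "target_deg", "response_deg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("WM CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(df$target_deg < 0 | df$target_deg >= 180 |
               df$response_deg < 0 | df$response_deg >= 180)
  if (length(bad))
    stop("WM CSV orientation outside [0, 180) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  df$target_theta <- df$target_deg * pi / 180
  df$response_theta <- df$response_deg * pi / 180
  df
}
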