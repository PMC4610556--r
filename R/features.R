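#' Feature-extraction configuration
#'
#' Thresholds for the windowed drowsiness features.
#'
#' @param t_m Mouth-opening ratio (height / width) at or above which a frame
#'   counts as yawning.
#' @param nonsteer_band Steering angular-velocity band (degrees/second)
#'   within which a sample counts as non-steering.
#' @param ecd_min_closure Minimum continuous eye-closure duration (seconds)
#'   for a run to count toward the eye-closed-duration feature.
#' @param lambda_l,lambda_r Left / right lane-deviation thresholds on the
#'   slope-angle ratio \eqn{\xi}.
#' @param lane_rule `"symmetric"` flags a frame when \eqn{\xi > \lambda_L}
#'   (drifting left) or \eqn{\xi < 1/\lambda_R} (drifting right);
#'   `"literal"` applies the one-sided disjunction
#'   \eqn{\xi > \lambda_L \lor \xi > \lambda_R} as sometimes printed, which
#'   is degenerate whenever the thresholds differ.
#' @export
feature_config <- function(t_m = 0.5, nonsteer_band = 0.1,
                           ecd_min_closure = 2, lambda_l = 1.2,
                           lambda_r = 1.2,
                           lane_rule = c("symmetric", "literal")) {
  stopifnot(t_m >= 0, nonsteer_band > 0, ecd_min_closure > 0,
            lambda_l > 0, lambda_r > 0)
  structure(list(t_m = t_m, nonsteer_band = nonsteer_band,
                 ecd_min_closure = ecd_min_closure,
                 lambda_l = lambda_l, lambda_r = lambda_r,
                 lane_rule = match.arg(lane_rule)), class = "feature_config")
}

.check_window <- function(df, what = "window") {
  if (is.null(df) || nrow(df) == 0) {
    rlang::abort(paste("empty", what), class = "drowsefuse_invalid_window")
  }
}

.frame_rate <- function(t) {
  if (length(t) < 2) {
    rlang::abort("cannot infer a frame rate from fewer than two frames",
                 class = "drowsefuse_invalid_window")
  }
  1 / stats::median(diff(t))
}

#' Blink frequency
#'
#' Fraction of frames in the window whose eyes are identified as closed,
#' \eqn{f_b = n_b / N_b}.
#'
#' @param frames Data frame of the facial stream for one window, with at
#'   least an `eye_closed` logical column (and `t` for duration-based
#'   features).
#' @return Fraction in \[0, 1\].
#' @export
blink_frequency <- function(frames) {
  .check_window(frames)
  mean(as.logical(frames$eye_closed))
}

#' Eye-closed duration
#'
#' Fraction of frames belonging to maximal closed-eye runs lasting at least
#' `ecd_min_closure` seconds (default 2 s), \eqn{f_c = n_c / N_c}.  A
#' PERCLOS-like measure of sustained closure; always bounded above by
#' [blink_frequency()] since only a subset of closed frames qualifies.
#'
#' @inheritParams blink_frequency
#' @param config A [feature_config()].
#' @param frame_rate Frames per second; inferred from the median timestamp
#'   spacing when omitted.
#' @export
eye_closed_duration <- function(frames, config = feature_config(),
                                frame_rate = NULL) {
  .check_window(frames)
  closed <- as.logical(frames$eye_closed)
  if (!any(closed)) return(0)
  if (is.null(frame_rate)) frame_rate <- .frame_rate(frames$t)
  runs <- rle(closed)
  qualifying <- runs$values & (runs$lengths / frame_rate >= config$ecd_min_closure)
  sum(runs$lengths[qualifying]) / length(closed)
}

#' Mean eye-opened level
#'
#' Arithmetic mean of the eyelid-separation height (pixels) over the window,
#' \eqn{f_o = \sum_i h_{o,i} / N_o}.
#'
#' @param frames Data frame with an `eyelid_h` column.
#' @export
mean_eye_opened_level <- function(frames) {
  .check_window(frames)
  mean(frames$eyelid_h)
}

#' Yawning frequency
#'
#' Per frame the mouth-opening level \eqn{r_m = h_m / w_m} is compared with
#' the threshold `t_m`; the feature is the fraction of frames flagged as
#' yawning, \eqn{f_m = n_m / N_m}.  Frames with zero mouth width are
#' geometrically degenerate: they are excluded from the ratio and reported
#' through a warning.
#'
#' @param frames Data frame with `mouth_h` and `mouth_w` columns.
#' @inheritParams eye_closed_duration
#' @export
yawning_frequency <- function(frames, config = feature_config()) {
  .check_window(frames)
  ok <- frames$mouth_w > 0
  if (!all(ok)) {
    rlang::warn(sprintf("%d frame(s) with zero mouth width excluded", sum(!ok)),
                class = "drowsefuse_degenerate_geometry")
  }
  if (!any(ok)) return(0)
  mean(frames$mouth_h[ok] / frames$mouth_w[ok] >= config$t_m)
}

.steer_rate <- function(vehicle) {
  if ("steer_rate" %in% names(vehicle)) return(vehicle[["steer_rate"]])
  # estimator when only angles are recorded: first difference over the
  # sampling interval, first sample carried forward
  dt <- diff(vehicle$t)
  rate <- diff(vehicle$steer_angle) / dt
  c(rate[1], rate)
}

#' Percentage of non-steering
#'
#' Fraction of samples whose steering angular velocity lies within
#' `nonsteer_band` (default 0.1 degree/s) of zero, \eqn{p_a = n_a / N_a}.
#' Uses a `steer_rate` column if present, otherwise differentiates
#' `steer_angle`.
#'
#' @param vehicle Data frame of the vehicle stream for one window.
#' @inheritParams eye_closed_duration
#' @export
percent_non_steering <- function(vehicle, config = feature_config()) {
  .check_window(vehicle)
  mean(abs(.steer_rate(vehicle)) <= config$nonsteer_band)
}

#' Steering-angle standard deviation
#'
#' Population standard deviation (1/N inside the root) of the steering-wheel
#' angle over the window, in degrees.
#'
#' @inheritParams percent_non_steering
#' @export
steering_angle_sd <- function(vehicle) {
  .check_window(vehicle)
  x <- vehicle$steer_angle
  sqrt(mean((x - mean(x))^2))
}

#' Abnormal lane-deviation frequency
#'
#' From the left/right lane-line slope angles each frame yields the ratio
#' \eqn{\xi(k) = (\pi/2 - \theta_L(k)) / (\theta_R(k) - \pi/2)}, equal to 1
#' for symmetric lane geometry.  A frame counts as deviating according to
#' the configured `lane_rule`; the feature is the deviating fraction
#' \eqn{f_l = n_l / N_l}.  Frames with \eqn{\theta_R = \pi/2} are
#' indeterminate and excluded with a warning.
#'
#' @param vehicle Data frame with `theta_l` and `theta_r` columns (radians).
#' @inheritParams eye_closed_duration
#' @export
lane_deviation_frequency <- function(vehicle, config = feature_config()) {
  .check_window(vehicle)
  denom <- vehicle$theta_r - pi / 2
  ok <- abs(denom) > 1e-12
  if (!all(ok)) {
    rlang::warn(sprintf("%d frame(s) with vertical right lane line excluded",
                        sum(!ok)),
                class = "drowsefuse_indeterminate_lane")
  }
  if (!any(ok)) return(0)
  xi <- (pi / 2 - vehicle$theta_l[ok]) / denom[ok]
  dev <- if (config$lane_rule == "symmetric") {
    xi > config$lambda_l | xi < 1 / config$lambda_r
  } else {
    xi > config$lambda_l | xi > config$lambda_r
  }
  mean(dev)
}

#' Vehicle-speed standard deviation
#'
#' Population standard deviation of GPS speed (km/h) over the window.
#'
#' @param vehicle Data frame with a `speed` column.
#' @export
speed_sd <- function(vehicle) {
  .check_window(vehicle)
  x <- vehicle$speed
  sqrt(mean((x - mean(x))^2))
}

#' Extract windowed fatigue features from raw streams
#'
#' Aligns the facial and vehicle streams on their overlapping time span and
#' cuts it into contiguous, non-overlapping 60 s recognition windows
#' (incomplete trailing windows are dropped).  Facial features (bf, ecd,
#' meol, yf) and the lane feature (fald) are computed over the full minute;
#' steering and speed features (pns, sdsa, sdvs) over the final 10 s
#' sub-window of that minute, matching their shorter natural time scale.
#'
#' @param facial Data frame with columns `t`, `eye_closed`, `eyelid_h`,
#'   `mouth_h`, `mouth_w` (per video frame).
#' @param vehicle Data frame with columns `t`, `steer_angle` (and/or
#'   `steer_rate`), `theta_l`, `theta_r`, `speed` (per sample).
#' @param config A [feature_config()].
#' @param window_len,sub_len Recognition-window and vehicle-sub-window
#'   lengths in seconds.
#' @return Tibble with one row per window: `window_start` plus the eight
#'   features `bf`, `ecd`, `meol`, `yf`, `pns`, `sdsa`, `fald`, `sdvs`.
#' @export
extract_features <- function(facial, vehicle, config = feature_config(),
                             window_len = 60, sub_len = 10) {
  .check_window(facial, "facial stream")
  .check_window(vehicle, "vehicle stream")
  t0 <- max(min(facial$t), min(vehicle$t))
  t1 <- min(max(facial$t), max(vehicle$t))
  if (t1 <= t0) {
    rlang::abort("facial and vehicle streams do not overlap in time",
                 class = "drowsefuse_invalid_input")
  }
  fps <- .frame_rate(facial$t)
  # a window is complete when sampling covers it up to one sample interval
  n_win <- floor((t1 - t0 + 1 / fps) / window_len + 1e-9)
  purrr::map_dfr(seq_len(n_win), function(w) {
    ws <- t0 + (w - 1) * window_len
    fr <- facial[facial$t >= ws & facial$t < ws + window_len, , drop = FALSE]
    vh <- vehicle[vehicle$t >= ws & vehicle$t < ws + window_len, , drop = FALSE]
    sub <- vh[vh$t >= ws + window_len - sub_len, , drop = FALSE]
    tibble::tibble(
      window_start = ws,
      bf = blink_frequency(fr),
      ecd = eye_closed_duration(fr, config, frame_rate = fps),
      meol = mean_eye_opened_level(fr),
      yf = yawning_frequency(fr, config),
      pns = percent_non_steering(sub, config),
      sdsa = steering_angle_sd(sub),
      fald = lane_deviation_frequency(vh, config),
      sdvs = speed_sd(sub))
  })
}
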