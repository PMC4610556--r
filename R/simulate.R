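#' Simulation configuration
#'
#' Study conditions for the synthetic-session generator: a Markov chain over
#' the three fatigue states and state-conditional Gaussian distributions for
#' the eight windowed features.  The default per-state means are monotone
#' increasing in fatigue for bf, ecd, yf, pns, fald and sdvs and decreasing
#' for meol and sdsa (matching the correlation signs the screening module
#' expects), with adjacent states separated by at least 1.5 within-state
#' standard deviations so that state recovery is well posed.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including the seed.
#' @param transition 3x3 row-stochastic matrix over (NF, MF, SF).
#' @param state_means,state_sds 3x8 matrices (rows = NF/MF/SF, columns =
#'   bf, ecd, meol, yf, pns, sdsa, fald, sdvs).
#' @param n_windows Session length in 60 s recognition windows.
#' @param start_state Initial Markov state.
#' @param frame_rate Facial/vehicle stream sampling rate (Hz) for raw-stream
#'   synthesis.
#' @export
sim_config <- function(seed = 1L,
                       transition = matrix(c(0.90, 0.08, 0.02,
                                             0.05, 0.90, 0.05,
                                             0.02, 0.08, 0.90),
                                           3, 3, byrow = TRUE),
                       state_means = NULL, state_sds = NULL,
                       n_windows = 50L, start_state = "NF",
                       frame_rate = 10) {
  feats <- c("bf", "ecd", "meol", "yf", "pns", "sdsa", "fald", "sdvs")
  if (is.null(state_means)) {
    state_means <- rbind(
      NF = c(bf = 0.08, ecd = 0.02, meol = 12.0, yf = 0.05, pns = 0.25,
             sdsa = 16.0, fald = 0.05, sdvs = 3.0),
      MF = c(bf = 0.14, ecd = 0.08, meol = 10.0, yf = 0.13, pns = 0.35,
             sdsa = 12.5, fald = 0.15, sdvs = 5.0),
      SF = c(bf = 0.22, ecd = 0.18, meol = 8.0, yf = 0.24, pns = 0.47,
             sdsa = 9.0, fald = 0.28, sdvs = 7.5))
  }
  if (is.null(state_sds)) {
    state_sds <- matrix(rep(c(bf = 0.02, ecd = 0.025, meol = 1.2,
                              yf = 0.035, pns = 0.05, sdsa = 1.8,
                              fald = 0.05, sdvs = 1.0), each = 3),
                        3, 8, dimnames = list(fatigue_states(), feats))
  }
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-9), all(transition >= 0),
            all(state_sds > 0), n_windows >= 1,
            identical(colnames(state_means), feats))
  structure(list(seed = as.integer(seed), transition = transition,
                 state_means = state_means, state_sds = state_sds,
                 n_windows = as.integer(n_windows),
                 start_state = .as_state(start_state),
                 frame_rate = frame_rate), class = "sim_config")
}

# Draw one feature vector for a state, respecting natural ranges.
.draw_features <- function(state, config) {
  i <- match(state, fatigue_states())
  x <- stats::rnorm(8, config$state_means[i, ], config$state_sds[i, ])
  names(x) <- colnames(config$state_means)
  frac <- c("bf", "ecd", "yf", "pns", "fald")
  x[frac] <- pmin(pmax(x[frac], 0), 1)
  x[c("meol", "sdsa", "sdvs")] <- pmax(x[c("meol", "sdsa", "sdvs")], 0)
  x["ecd"] <- min(x["ecd"], x["bf"])   # sustained closures are closed frames
  x
}

#' Generate a labelled training table
#'
#' Draws `n_per_state` feature vectors from each state's Gaussian
#' distribution and encodes the targets as 0.8 for the true state's output
#' and 0.1 for each of the other two, the soft coding used to train the
#' membership networks.
#'
#' @param n_per_state Samples per fatigue state.
#' @param config A [sim_config()].
#' @return Tibble with `state`, the eight features, and targets `y_nf`,
#'   `y_mf`, `y_sf` (each row's targets sum to 1).
#' @examples
#' generate_training_table(5, sim_config(seed = 7))
#' @export
generate_training_table <- function(n_per_state, config = sim_config()) {
  stopifnot(n_per_state >= 1)
  set.seed(config$seed)
  purrr::map_dfr(fatigue_states(), function(s) {
    feats <- t(vapply(seq_len(n_per_state), function(k) .draw_features(s, config),
                      numeric(8)))
    targ <- matrix(0.1, n_per_state, 3,
                   dimnames = list(NULL, c("y_nf", "y_mf", "y_sf")))
    targ[, match(s, fatigue_states())] <- 0.8
    dplyr::bind_cols(tibble::tibble(state = s),
                     tibble::as_tibble(feats), tibble::as_tibble(targ))
  })
}

# Logical frame vector with the given closed-run lengths placed disjointly,
# separated by at least one open frame, in random positions and order.
.place_runs <- function(n_frames, run_lengths) {
  out <- logical(n_frames)
  run_lengths <- run_lengths[run_lengths > 0]
  R <- length(run_lengths)
  if (R == 0) return(out)
  run_lengths <- run_lengths[sample.int(length(run_lengths))]
  spare <- n_frames - sum(run_lengths) - (R - 1)
  if (spare < 0) {
    rlang::abort("closed runs do not fit in the window",
                 class = "drowsefuse_invalid_input")
  }
  # distribute the spare open frames over the R + 1 gaps
  cuts <- sort(sample.int(spare + R, R)) - seq_len(R)
  gaps <- diff(c(0, cuts, spare))
  pos <- 1
  for (r in seq_len(R)) {
    pos <- pos + gaps[r] + (r > 1)
    out[pos:(pos + run_lengths[r] - 1)] <- TRUE
    pos <- pos + run_lengths[r]
  }
  out
}

# Closed-run lengths realizing n_long frames of sustained (>= min_len)
# closure; small remainders are realized probabilistically so the expected
# frame count stays unbiased.
.long_runs <- function(n_long, min_len, typical_len) {
  if (n_long <= 0) return(integer(0))
  if (n_long < min_len) {
    return(if (stats::runif(1) < n_long / min_len) min_len else integer(0))
  }
  k <- max(1L, n_long %/% typical_len)
  base <- n_long %/% k
  lens <- rep(base, k)
  lens[1] <- lens[1] + n_long - base * k
  lens
}

.synth_window_streams <- function(target, t0, config,
                                  fcfg = feature_config()) {
  fps <- config$frame_rate
  nfr <- round(60 * fps)
  t <- t0 + (seq_len(nfr) - 1) / fps
  min_closure <- ceiling(fcfg$ecd_min_closure * fps)
  # eye closure: long runs realize ecd, short blinks the rest of bf
  n_total <- round(target[["bf"]] * nfr)
  n_long <- min(round(target[["ecd"]] * nfr), n_total)
  long <- .long_runs(n_long, min_closure, round(1.5 * min_closure))
  n_short <- max(n_total - sum(long), 0)
  short_len <- max(1L, min_closure %/% 4)  # well under the sustained cutoff
  short <- c(rep(short_len, n_short %/% short_len),
             if (n_short %% short_len > 0) n_short %% short_len)
  closed <- .place_runs(nfr, c(long, short))
  # yawns: 4 s mouth-open episodes realizing yf
  n_yawn <- round(target[["yf"]] * nfr)
  yl <- round(4 * fps)
  yawns <- c(rep(yl, n_yawn %/% yl), if (n_yawn %% yl > 0) n_yawn %% yl)
  yawning <- .place_runs(nfr, yawns)
  facial <- tibble::tibble(
    t = t, eye_closed = closed,
    eyelid_h = pmax(stats::rnorm(nfr, target[["meol"]], 0.3), 0),
    mouth_h = ifelse(yawning, 0.8, 0.2) * 50, mouth_w = 50)
  # lane geometry: deviating frames get xi above the left threshold
  n_dev <- round(target[["fald"]] * nfr)
  deviating <- .place_runs(nfr, .long_runs(n_dev, round(2 * fps),
                                           round(3 * fps)))
  xi <- ifelse(deviating, stats::runif(nfr, 1.35, 1.8),
               stats::runif(nfr, 0.92, 1.08))
  # vehicle features are measured on the final 10 s sub-window
  sub <- t >= t0 + 50
  nsub <- sum(sub)
  n_ns <- round(target[["pns"]] * nsub)
  in_band <- sample(c(rep(TRUE, n_ns), rep(FALSE, nsub - n_ns)))
  rate_sub <- ifelse(in_band, stats::runif(nsub, -0.05, 0.05),
                     sample(c(-1, 1), nsub, TRUE) * stats::runif(nsub, 0.2, 5))
  scale_to_sd <- function(n, s) {
    z <- cumsum(stats::rnorm(n))
    z <- z - mean(z)
    r <- sqrt(mean(z^2))
    if (r == 0 || s == 0) rep(0, n) else z * s / r
  }
  angle <- stats::rnorm(nfr, 0, 2)
  angle[sub] <- scale_to_sd(nsub, target[["sdsa"]])
  speed <- stats::rnorm(nfr, 100, 1)
  speed[sub] <- 100 + scale_to_sd(nsub, target[["sdvs"]])
  rate <- stats::rnorm(nfr, 0, 2)
  rate[sub] <- rate_sub
  vehicle <- tibble::tibble(
    t = t, steer_angle = angle, steer_rate = rate,
    theta_l = pi / 2 - 0.2 * xi, theta_r = pi / 2 + 0.2, speed = speed)
  list(facial = facial, vehicle = vehicle)
}

#' Generate a labelled synthetic driving session
#'
#' Samples a fatigue-state path from the configured Markov chain and, per
#' 60 s window, draws target feature values from the state's Gaussian
#' distribution.  With `raw_streams = TRUE` the generator additionally
#' synthesizes per-frame facial and per-sample vehicle streams constructed
#' to realize those targets (Poisson-like placement of sustained closures,
#' short blinks and yawn episodes; lane-angle, steering and speed series
#' scaled to the target dispersions), and the returned features are
#' re-extracted from the streams by [extract_features()].
#'
#' @param config A [sim_config()].
#' @param raw_streams Also synthesize and re-extract raw streams.
#' @return A list of class `"labeled_session"`: `features` (tibble with
#'   `window_start` and the eight features), `states` (true per-window
#'   states), `targets` (the drawn per-window feature targets), and
#'   `streams` (`NULL`, or list of `facial`/`vehicle` tibbles).
#' @examples
#' s <- generate_session(sim_config(seed = 3, n_windows = 5))
#' s$states
#' @export
generate_session <- function(config = sim_config(), raw_streams = FALSE) {
  set.seed(config$seed)
  states <- character(config$n_windows)
  cur <- match(config$start_state, fatigue_states())
  for (w in seq_len(config$n_windows)) {
    states[w] <- fatigue_states()[cur]
    cur <- sample.int(3, 1, prob = config$transition[cur, ])
  }
  targets <- t(vapply(states, function(s) .draw_features(s, config),
                      numeric(8)))
  rownames(targets) <- NULL
  target_tab <- dplyr::bind_cols(
    tibble::tibble(window_start = (seq_len(config$n_windows) - 1) * 60),
    tibble::as_tibble(targets))
  streams <- NULL
  features <- target_tab
  if (raw_streams) {
    per_win <- purrr::map(seq_len(config$n_windows), function(w)
      .synth_window_streams(targets[w, ], (w - 1) * 60, config))
    streams <- list(
      facial = dplyr::bind_rows(purrr::map(per_win, "facial")),
      vehicle = dplyr::bind_rows(purrr::map(per_win, "vehicle")))
    features <- extract_features(streams$facial, streams$vehicle)
  }
  structure(list(features = features, states = states,
                 targets = target_tab, streams = streams,
                 config = config), class = "labeled_session")
}

#' @export
print.labeled_session <- function(x, ...) {
  cat(sprintf("<labeled_session> %d windows (%s)\n", length(x$states),
              paste(table(factor(x$states, fatigue_states())), collapse = "/")))
  invisible(x)
}
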