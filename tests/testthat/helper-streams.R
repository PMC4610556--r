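# Builders for small raw-stream fixtures used across the feature tests.

make_facial <- function(n, fps = 10, t0 = 0, eye_closed = FALSE,
                        eyelid_h = 10, mouth_h = 10, mouth_w = 50) {
  tibble::tibble(
    t = t0 + (seq_len(n) - 1) / fps,
    eye_closed = rep_len(eye_closed, n),
    eyelid_h = rep_len(eyelid_h, n),
    mouth_h = rep_len(mouth_h, n),
    mouth_w = rep_len(mouth_w, n))
}

make_vehicle <- function(n, fps = 10, t0 = 0, steer_angle = 0,
                         steer_rate = NULL, theta_l = pi / 3,
                         theta_r = 2 * pi / 3, speed = 100) {
  v <- tibble::tibble(
    t = t0 + (seq_len(n) - 1) / fps,
    steer_angle = rep_len(steer_angle, n),
    theta_l = rep_len(theta_l, n),
    theta_r = rep_len(theta_r, n),
    speed = rep_len(speed, n))
  if (!is.null(steer_rate)) v$steer_rate <- rep_len(steer_rate, n)
  v
}

random_mass <- function(with_theta = TRUE) {
  x <- stats::runif(if (with_theta) 4 else 3)
  if (!with_theta) x <- c(x, 0)
  mass(x / sum(x))
}

# Brute-force Dempster oracle: enumerate all 4 x 4 focal-set intersections
# on the frame {NF, MF, SF} with Theta as the fourth focal set.
dempster_oracle <- function(m1, m2) {
  m1 <- unclass(m1); m2 <- unclass(m2)
  acc <- c(0, 0, 0, 0)  # nf, mf, sf, theta
  K <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      p <- m1[i] * m2[j]
      target <- if (i == 4) j else if (j == 4) i else if (i == j) i else 0
      if (target == 0) K <- K + p else acc[target] <- acc[target] + p
    }
  }
  list(K = unname(K), mass = unname(acc / sum(acc)))
}

# constant-output network: one rule, outputs equal to the weight column
constant_tsfnn <- function(outputs, inputs) {
  structure(list(
    structure = list(n = length(inputs), m = 1L, r = length(outputs)),
    inputs = inputs, targets = c("y_nf", "y_mf", "y_sf"),
    scaling = list(min = stats::setNames(rep(0, length(inputs)), inputs),
                   range = stats::setNames(rep(1, length(inputs)), inputs)),
    params = list(centers = matrix(0.5, length(inputs), 1),
                  widths = matrix(1, length(inputs), 1),
                  weights = matrix(outputs, ncol = 1)),
    trace = numeric(0),
    meta = list(seed = 0L, iterations = 0L, final_fitness = NA_real_,
                converged = FALSE)), class = "tsfnn")
}

constant_recognizer <- function(facial_out, vehicle_out,
                                fusion = fusion_config()) {
  structure(list(
    facial = constant_tsfnn(facial_out, c("bf", "ecd", "yf")),
    vehicle = constant_tsfnn(vehicle_out, c("pns", "sdsa", "fald", "sdvs")),
    fusion = fusion), class = "fatigue_recognizer")
}

feature_row <- function() {
  tibble::tibble(bf = 0.1, ecd = 0.05, yf = 0.1, pns = 0.3, sdsa = 12,
                 fald = 0.1, sdvs = 4)
}
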