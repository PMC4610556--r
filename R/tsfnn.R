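#' Takagi-Sugeno fuzzy neural network
#'
#' A five-layer zero-order Takagi-Sugeno fuzzy neural network (T-SFNN):
#' inputs are fuzzified by Gaussian membership functions
#' \eqn{\mu_{ij} = \exp(-(x_i - c_{ij})^2 / \sigma_{ij}^2)}, each rule fires
#' with strength \eqn{\alpha_j = \prod_i \mu_{ij}}, strengths are normalized
#' to \eqn{\bar\alpha_j = \alpha_j / \sum_j \alpha_j}, and each output is the
#' strength-weighted sum \eqn{y_k = \sum_j w_{kj} \bar\alpha_j}.  The number
#' of rules (= linguistic values per input) comes from subtractive
#' clustering of the training data rather than a full rule grid, which
#' collapses the parameter count from \eqn{2nL + rL^n} to \eqn{2nm + rm}.
#'
#' @name tsfnn
NULL

#' Trainable-parameter and rule counts of a T-SFNN
#'
#' With clustering-derived structure a network with `n` inputs, `m` rules and
#' `r` outputs has one Gaussian center and one width per input-rule pair plus
#' one weight per output-rule pair: \eqn{2nm + rm} parameters and `m` rules.
#' Without clustering, `m` is read as the number of linguistic values per
#' input, the rule base is the full grid of \eqn{m^n} combinations, and the
#' count is \eqn{2nm + r m^n}.
#'
#' @param n Number of inputs.
#' @param m Number of rules (with clustering) or linguistic values per input
#'   (grid structure).
#' @param r Number of outputs.
#' @param with_sca Structure from subtractive clustering (`TRUE`) or the full
#'   rule grid (`FALSE`).
#' @return Integer parameter (or rule) count.
#' @examples
#' count_parameters(3, 3, 3)                    # 27
#' count_parameters(4, 3, 3, with_sca = FALSE)  # 267
#' @export
count_parameters <- function(n, m, r, with_sca = TRUE) {
  stopifnot(n >= 1, m >= 1, r >= 1)
  if (with_sca) as.integer(2 * n * m + r * m)
  else as.integer(2 * n * m + r * m^n)
}

#' @rdname count_parameters
#' @export
count_rules <- function(n, m, with_sca = TRUE) {
  stopifnot(n >= 1, m >= 1)
  if (with_sca) as.integer(m) else as.integer(m^n)
}

#' Subtractive-clustering configuration
#'
#' Chiu-style density-potential clustering constants.  Radii are on the
#' min-max-scaled \[0, 1\] feature space.
#'
#' @param r_a Accept radius defining the potential neighbourhood.
#' @param r_b Squash radius used when revising potentials (default
#'   `1.5 * r_a`).
#' @param accept_ratio,reject_ratio Fractions of the first center's
#'   potential above which a candidate is accepted outright and below which
#'   selection stops.
#' @export
sca_config <- function(r_a = 0.5, r_b = 1.5 * r_a,
                       accept_ratio = 0.5, reject_ratio = 0.15) {
  stopifnot(r_a > 0, r_b >= r_a,
            reject_ratio > 0, reject_ratio < accept_ratio, accept_ratio <= 1)
  structure(list(r_a = r_a, r_b = r_b, accept_ratio = accept_ratio,
                 reject_ratio = reject_ratio), class = "sca_config")
}

#' Subtractive clustering of data points
#'
#' Selects cluster centers among the data points by density-potential
#' maximization: each point's potential is the sum of Gaussian kernels to all
#' points at radius `r_a`; the highest-potential point becomes a center and
#' nearby potentials are squashed at radius `r_b`; selection continues with
#' accept/reject thresholds relative to the first center's potential.
#'
#' @param x Numeric matrix (rows = observations) or data frame of features,
#'   pre-scaled to comparable ranges.
#' @param config An [sca_config()].
#' @return Matrix of cluster centers (rows = centers), at least one.
#' @export
subtractive_clustering <- function(x, config = sca_config()) {
  x <- as.matrix(x)
  n_obs <- nrow(x)
  if (n_obs < 1) {
    rlang::abort("subtractive clustering needs at least one data point",
                 class = "drowsefuse_invalid_input")
  }
  if (n_obs == 1) return(x)
  alpha <- 4 / config$r_a^2
  beta <- 4 / config$r_b^2
  d2 <- as.matrix(stats::dist(x))^2
  pot <- rowSums(exp(-alpha * d2))
  centers <- integer(0)
  p_first <- NULL
  repeat {
    k <- which.max(pot)
    p_k <- pot[[k]]
    if (is.null(p_first)) {
      p_first <- p_k
      accept <- TRUE
    } else if (p_k > config$accept_ratio * p_first) {
      accept <- TRUE
    } else if (p_k < config$reject_ratio * p_first) {
      break
    } else {
      # gray zone: trade off distance to existing centers against potential
      d_min <- sqrt(min(d2[k, centers]))
      if (d_min / config$r_a + p_k / p_first >= 1) {
        accept <- TRUE
      } else {
        pot[k] <- 0
        if (all(pot <= 0)) break
        next
      }
    }
    if (accept) {
      centers <- c(centers, k)
      pot <- pot - p_k * exp(-beta * d2[, k])
      pot[pot < 0] <- 0
      if (length(centers) >= n_obs || all(pot <= 0)) break
    }
  }
  x[centers, , drop = FALSE]
}

#' Initial Gaussian parameters from cluster centers
#'
#' The j-th rule's membership centers are the coordinates of the j-th
#' cluster center.  All initial widths are set, coordinate-wise, to half the
#' absolute difference between the first center and its Euclidean-nearest
#' neighbour center; zero differences (and the single-center case, where no
#' neighbour exists) fall back to `sigma_floor`.
#'
#' @param centers Matrix of cluster centers (rows = centers).
#' @param sigma_floor Lower bound for initial widths.
#' @return List with `centers` and `widths`, both n-inputs x m-rules
#'   matrices.
#' @export
init_from_clusters <- function(centers, sigma_floor = 0.05) {
  centers <- as.matrix(centers)
  m <- nrow(centers)
  n <- ncol(centers)
  stopifnot(m >= 1, sigma_floor > 0)
  c_mat <- t(centers)                      # n x m
  if (m == 1) {
    sig <- rep(sigma_floor, n)
  } else {
    d <- sqrt(colSums((t(centers[-1, , drop = FALSE]) - centers[1, ])^2))
    nearest <- which.min(d) + 1
    sig <- abs(centers[1, ] - centers[nearest, ]) / 2
    sig[sig < sigma_floor] <- sigma_floor
  }
  list(centers = c_mat, widths = matrix(sig, n, m))
}

# Row-wise stable forward pass.  X: N x n (already scaled), returns list with
# log-firing (N x m), normalized strengths (N x m), outputs (N x r).
.tsfnn_eval <- function(centers, widths, weights, X) {
  m <- ncol(centers)
  N <- nrow(X)
  loga <- matrix(0, N, m)
  for (j in seq_len(m)) {
    dev <- sweep(X, 2, centers[, j], "-")
    loga[, j] <- -rowSums(sweep(dev^2, 2, widths[, j]^2, "/"))
  }
  shift <- loga - apply(loga, 1, max)      # log-space guard against underflow
  a <- exp(shift)
  abar <- a / rowSums(a)
  list(loga = loga, abar = abar, outputs = abar %*% t(weights))
}

#' Forward pass of a T-SFNN
#'
#' Evaluates the five network layers at a single input point and returns the
#' full trace.  Firing strengths are computed in log space and shifted by
#' their maximum before exponentiation, so normalized strengths stay finite
#' even when the point is far from every rule center.
#'
#' @param object A fitted [fit_tsfnn()] model, or a bare list with `centers`,
#'   `widths` (n x m matrices) and `weights` (r x m).
#' @param x Numeric input vector of length n, on the model's input scale
#'   (already scaled if the parameter list came from a scaled fit).
#' @return List with `memberships` (n x m), `firing` (m), `normalized` (m,
#'   summing to 1) and `outputs` (r).
#' @export
tsfnn_forward <- function(object, x) {
  p <- if (inherits(object, "tsfnn")) object$params else object
  stopifnot(is.numeric(x), length(x) == nrow(p$centers), all(is.finite(x)))
  ev <- .tsfnn_eval(p$centers, p$widths, p$weights, matrix(x, nrow = 1))
  memberships <- exp(-(x - p$centers)^2 / p$widths^2)
  list(memberships = memberships,
       firing = exp(ev$loga[1, ]),
       normalized = ev$abar[1, ],
       outputs = drop(ev$outputs))
}

#' Mean squared multi-output training error
#'
#' \eqn{f = \frac{1}{N}\sum_k \sum_j (y_{kj} - \hat y_{kj})^2}: the fitness
#' minimized by the particle swarm.
#'
#' @param params Parameter list with `centers`, `widths`, `weights`.
#' @param X Scaled input matrix (N x n).
#' @param Y Target matrix (N x r).
#' @export
tsfnn_fitness <- function(params, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(X) != nrow(Y) || ncol(Y) != nrow(params$weights)) {
    rlang::abort("fitness needs a nonempty dataset with matching shapes",
                 class = "drowsefuse_invalid_input")
  }
  pred <- .tsfnn_eval(params$centers, params$widths, params$weights, X)$outputs
  mean(rowSums((Y - pred)^2))
}

#' Particle-swarm training configuration
#'
#' Standard global-best PSO controls: swarm of particles moved by inertia
#' plus cognitive/social attraction toward personal and global bests, with
#' velocities clamped to a fraction of each parameter's search range and the
#' inertia weight decayed linearly across iterations.
#'
#' @param swarm_size Number of particles.
#' @param max_iters Iteration budget.
#' @param inertia Length-2 numeric `(start, end)` of the linear inertia
#'   schedule.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param velocity_clamp Velocity bound as a fraction of each search range.
#' @param target_fitness Early-stopping fitness.
#' @param sigma_floor Positivity floor for Gaussian widths.
#' @param restart_after Stagnation guard: when the global best has not
#'   improved for this many iterations, the worse half of the swarm is
#'   re-drawn uniformly in the search bounds with zeroed velocities (the
#'   personal and global bests are kept).  `Inf` disables it.
#' @param seed Integer seed; training is bit-reproducible for a fixed seed.
#' @export
pso_config <- function(swarm_size = 30, max_iters = 2000,
                       inertia = c(0.9, 0.4), c1 = 2, c2 = 2,
                       velocity_clamp = 0.2, target_fitness = 1e-4,
                       sigma_floor = 1e-3, restart_after = 50, seed = 1L) {
  stopifnot(swarm_size >= 2, max_iters >= 0, length(inertia) == 2,
            velocity_clamp > 0, target_fitness > 0, sigma_floor > 0,
            restart_after > 0)
  structure(list(swarm_size = swarm_size, max_iters = max_iters,
                 inertia = inertia, c1 = c1, c2 = c2,
                 velocity_clamp = velocity_clamp,
                 target_fitness = target_fitness,
                 sigma_floor = sigma_floor, restart_after = restart_after,
                 seed = as.integer(seed)),
            class = "pso_config")
}

# Search bounds per flattened parameter: centers within data range +/- 1 sd,
# widths in [floor, per-dimension range], weights in [-2, 2].
.pso_bounds <- function(X, n, m, r, sigma_floor) {
  sd_i <- apply(X, 2, stats::sd)
  sd_i[!is.finite(sd_i) | sd_i == 0] <- 1e-6
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng <= 0] <- 1
  # width lower bound at 2 % of the per-dimension range: a narrower Gaussian
  # is effectively a delta, which silences the rule and strands the swarm
  # with a smaller rule base
  lb <- c(rep(apply(X, 2, min) - sd_i, m), rep(pmax(0.02 * rng, sigma_floor), m),
          rep(-2, r * m))
  ub <- c(rep(apply(X, 2, max) + sd_i, m), rep(rng, m), rep(2, r * m))
  list(lb = lb, ub = ub)
}

.pso_decode <- function(theta, n, m, r, sigma_floor) {
  list(centers = matrix(theta[seq_len(n * m)], n, m),
       widths = pmax(matrix(theta[n * m + seq_len(n * m)], n, m), sigma_floor),
       weights = matrix(theta[2 * n * m + seq_len(r * m)], r, m))
}

#' Train a T-SFNN by global-best particle swarm optimization
#'
#' Minimizes [tsfnn_fitness()] over the flattened (centers, widths, weights)
#' vector.  The first particle starts at `init`; the rest are drawn uniformly
#' inside the search bounds.  Widths are clamped to a positivity floor
#' throughout.  The returned best-fitness trace is monotone non-increasing.
#'
#' @param X,Y Scaled inputs (N x n) and targets (N x r).
#' @param init Initial parameter list (e.g. from [init_from_clusters()] plus
#'   random weights).
#' @param config A [pso_config()].
#' @return List with `params` (best parameters), `trace` (best fitness per
#'   iteration), `final_fitness`, `iterations`, `converged`.
#' @export
pso_train <- function(X, Y, init, config = pso_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0) {
    rlang::abort("cannot train on an empty dataset",
                 class = "drowsefuse_invalid_input")
  }
  n <- nrow(init$centers); m <- ncol(init$centers); r <- nrow(init$weights)
  theta0 <- c(init$centers, init$widths, init$weights)
  f0 <- tsfnn_fitness(init, X, Y)
  if (config$max_iters == 0) {
    return(list(params = init, trace = numeric(0), final_fitness = f0,
                iterations = 0L, converged = f0 <= config$target_fitness))
  }
  set.seed(config$seed)
  b <- .pso_bounds(X, n, m, r, config$sigma_floor)
  dim_n <- length(theta0)
  S <- config$swarm_size
  pos <- matrix(stats::runif(S * dim_n, b$lb, b$ub), nrow = S, byrow = TRUE)
  pos[1, ] <- pmin(pmax(theta0, b$lb), b$ub)
  vel <- matrix(0, S, dim_n)
  vmax <- config$velocity_clamp * (b$ub - b$lb)
  eval_theta <- function(th)
    tsfnn_fitness(.pso_decode(th, n, m, r, config$sigma_floor), X, Y)
  fit <- apply(pos, 1, eval_theta)
  pbest <- pos; pbest_fit <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]; gbest_fit <- fit[[g]]
  trace <- numeric(config$max_iters)
  iters <- 0L
  stall <- 0L
  for (t in seq_len(config$max_iters)) {
    w <- config$inertia[1] -
      (config$inertia[1] - config$inertia[2]) * (t - 1) / max(config$max_iters - 1, 1)
    r1 <- matrix(stats::runif(S * dim_n), S, dim_n)
    r2 <- matrix(stats::runif(S * dim_n), S, dim_n)
    vel <- w * vel + config$c1 * r1 * (pbest - pos) +
      config$c2 * r2 * sweep(-pos, 2, gbest, "+")
    vel <- pmin(pmax(vel, matrix(-vmax, S, dim_n, byrow = TRUE)),
                matrix(vmax, S, dim_n, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(b$lb, S, dim_n, byrow = TRUE)),
                matrix(b$ub, S, dim_n, byrow = TRUE))
    fit <- apply(pos, 1, eval_theta)
    improved <- fit < pbest_fit
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    g <- which.min(pbest_fit)
    if (pbest_fit[[g]] < gbest_fit) {
      # stagnation counts only meaningful drops, not numerical creep
      if (pbest_fit[[g]] < gbest_fit * (1 - 1e-3)) stall <- -1L
      gbest_fit <- pbest_fit[[g]]
      gbest <- pbest[g, ]
    }
    stall <- stall + 1L
    iters <- t
    trace[t] <- gbest_fit
    if (gbest_fit <= config$target_fitness) break
    if (stall >= config$restart_after) {
      worst <- order(pbest_fit, decreasing = TRUE)[seq_len(S %/% 2)]
      pos[worst, ] <- matrix(stats::runif(length(worst) * dim_n, b$lb, b$ub),
                             nrow = length(worst), byrow = TRUE)
      vel[worst, ] <- 0
      pbest[worst, ] <- pos[worst, , drop = FALSE]
      pbest_fit[worst] <- apply(pos[worst, , drop = FALSE], 1, eval_theta)
      stall <- 0L
    }
  }
  list(params = .pso_decode(gbest, n, m, r, config$sigma_floor),
       trace = trace[seq_len(iters)], final_fitness = gbest_fit,
       iterations = iters, converged = gbest_fit <= config$target_fitness)
}

#' Fit a Takagi-Sugeno fuzzy neural network
#'
#' End-to-end model fit: inputs are min-max scaled to \[0, 1\] (scaling
#' stored with the model), the rule base is derived by
#' [subtractive_clustering()], Gaussian parameters are initialized from the
#' cluster geometry with output weights drawn uniformly in \[0, 1\], and all
#' parameters are refined by [pso_train()].
#'
#' @param data Data frame holding input and target columns.
#' @param inputs,targets Character vectors of column names.
#' @param sca An [sca_config()].
#' @param pso A [pso_config()]; its `seed` controls weight initialization and
#'   swarm randomness.
#' @param n_starts Independent swarm runs (weight initialization and swarm
#'   seed varied deterministically from `pso$seed`); the best final fitness
#'   wins.  Guards against the occasional swarm that commits early to a poor
#'   basin of the permutation-multimodal fitness surface.
#' @return An object of class `"tsfnn"` with elements `structure`, `inputs`,
#'   `targets`, `scaling`, `params`, `trace` and `meta`.  Supports
#'   [predict()][predict.tsfnn], [generics::tidy()] and [generics::glance()].
#' @examples
#' \donttest{
#' tab <- generate_training_table(40, sim_config(seed = 1))
#' fit <- fit_tsfnn(tab, c("bf", "ecd", "yf"), c("y_nf", "y_mf", "y_sf"),
#'                  pso = pso_config(max_iters = 50, seed = 1))
#' glance(fit)
#' }
#' @export
fit_tsfnn <- function(data, inputs, targets,
                      sca = sca_config(), pso = pso_config(), n_starts = 3) {
  data <- as.data.frame(data)
  stopifnot(all(inputs %in% names(data)), all(targets %in% names(data)),
            n_starts >= 1)
  X <- as.matrix(data[inputs])
  Y <- as.matrix(data[targets])
  mins <- apply(X, 2, min)
  ranges <- apply(X, 2, function(v) diff(range(v)))
  ranges[ranges <= 0] <- 1
  Xs <- sweep(sweep(X, 2, mins, "-"), 2, ranges, "/")
  centers <- subtractive_clustering(Xs, sca)
  init <- init_from_clusters(centers, sigma_floor = max(pso$sigma_floor, 0.05))
  fitres <- NULL
  for (s in seq_len(n_starts)) {
    pso_s <- pso
    pso_s$seed <- pso$seed + (s - 1L) * 7919L
    set.seed(pso_s$seed)
    init$weights <- matrix(stats::runif(length(targets) * ncol(init$centers)),
                           length(targets), ncol(init$centers))
    run <- pso_train(Xs, Y, init, pso_s)
    if (is.null(fitres) || run$final_fitness < fitres$final_fitness) fitres <- run
    if (fitres$converged) break
  }
  structure(list(
    structure = list(n = length(inputs), m = ncol(init$centers),
                     r = length(targets)),
    inputs = inputs, targets = targets,
    scaling = list(min = mins, range = ranges),
    params = fitres$params, trace = fitres$trace,
    meta = list(seed = pso$seed, iterations = fitres$iterations,
                final_fitness = fitres$final_fitness,
                converged = fitres$converged)), class = "tsfnn")
}

.tsfnn_scale <- function(object, X) {
  sweep(sweep(X, 2, object$scaling$min, "-"), 2, object$scaling$range, "/")
}

#' Predict from a fitted T-SFNN
#'
#' @param object A `"tsfnn"` model.
#' @param newdata Data frame containing the model's input columns.
#' @param ... Unused.
#' @return Tibble of network outputs, one column per target.
#' @export
predict.tsfnn <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[object$inputs])
  out <- .tsfnn_eval(object$params$centers, object$params$widths,
                     object$params$weights, .tsfnn_scale(object, X))$outputs
  colnames(out) <- object$targets
  tibble::as_tibble(out)
}

#' @export
print.tsfnn <- function(x, ...) {
  s <- x$structure
  cat(sprintf("<tsfnn> %d inputs, %d rules, %d outputs (%d parameters)\n",
              s$n, s$m, s$r, count_parameters(s$n, s$m, s$r)))
  cat(sprintf("  trained %d iterations, fitness %.3g%s\n", x$meta$iterations,
              x$meta$final_fitness,
              if (isTRUE(x$meta$converged)) " (converged)" else ""))
  invisible(x)
}

#' Tidy a fitted T-SFNN into one row per parameter
#'
#' @param x A `"tsfnn"` model.
#' @param ... Unused.
#' @return Tibble with columns `term` (center/width/weight), `input`,
#'   `output`, `rule`, `estimate`.
#' @method tidy tsfnn
#' @export
tidy.tsfnn <- function(x, ...) {
  p <- x$params
  s <- x$structure
  dplyr::bind_rows(
    tidyr::expand_grid(input = x$inputs, rule = seq_len(s$m)) |>
      dplyr::mutate(term = "center", output = NA_character_,
                    estimate = as.vector(t(p$centers))),
    tidyr::expand_grid(input = x$inputs, rule = seq_len(s$m)) |>
      dplyr::mutate(term = "width", output = NA_character_,
                    estimate = as.vector(t(p$widths))),
    tidyr::expand_grid(output = x$targets, rule = seq_len(s$m)) |>
      dplyr::mutate(term = "weight", input = NA_character_,
                    estimate = as.vector(t(p$weights)))
  ) |>
    dplyr::select("term", "input", "output", "rule", "estimate")
}

#' One-row summary of a fitted T-SFNN
#'
#' @inheritParams tidy.tsfnn
#' @method glance tsfnn
#' @export
glance.tsfnn <- function(x, ...) {
  s <- x$structure
  tibble::tibble(n_inputs = s$n, n_rules = s$m, n_outputs = s$r,
                 n_parameters = count_parameters(s$n, s$m, s$r),
                 iterations = x$meta$iterations,
                 final_fitness = x$meta$final_fitness,
                 converged = isTRUE(x$meta$converged))
}

#' Serialize / restore a fitted T-SFNN as JSON
#'
#' @param object A `"tsfnn"` model.
#' @param path File path.
#' @export
write_tsfnn <- function(object, path) {
  stopifnot(inherits(object, "tsfnn"))
  obj <- object
  obj$params <- lapply(obj$params, function(m) list(dim = dim(m), data = as.vector(m)))
  obj$scaling <- lapply(obj$scaling, as.numeric)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tsfnn
#' @export
read_tsfnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- lapply(obj$params, function(m) {
    matrix(as.numeric(m$data), m$dim[[1]], m$dim[[2]])
  })
  obj$scaling <- list(min = stats::setNames(as.numeric(obj$scaling$min), obj$inputs),
                      range = stats::setNames(as.numeric(obj$scaling$range), obj$inputs))
  obj$trace <- as.numeric(obj$trace)
  structure(obj, class = "tsfnn")
}
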