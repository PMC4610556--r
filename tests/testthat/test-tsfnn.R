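random_params <- function(n, m, r) {
  list(centers = matrix(stats::runif(n * m), n, m),
       widths = matrix(stats::runif(n * m, 0.1, 0.5), n, m),
       weights = matrix(stats::rnorm(r * m), r, m))
}

# plain-arithmetic re-evaluation of the five layers, no log-space tricks
forward_oracle <- function(p, x) {
  mu <- exp(-(x - p$centers)^2 / p$widths^2)
  a <- apply(mu, 2, prod)
  abar <- a / sum(a)
  drop(p$weights %*% abar)
}

test_that("parameter and rule counts cover clustered and grid structures", {
  expect_equal(count_parameters(1, 1, 1), 3L)
  expect_equal(count_parameters(3, 3, 3, with_sca = FALSE), 99L)
  expect_equal(count_rules(4, 3, with_sca = FALSE), 81L)
})

test_that("forward pass matches the layer formulas", {
  set.seed(5)
  # single rule: normalized strength is 1 and outputs equal the weight column
  p1 <- random_params(3, 1, 2)
  tr <- tsfnn_forward(p1, stats::runif(3))
  expect_equal(tr$normalized, 1)
  expect_equal(tr$outputs, drop(p1$weights))
  # input at a center with all other rules far away: that rule dominates
  p2 <- list(centers = cbind(c(0, 0), c(10, 10)),
             widths = matrix(0.5, 2, 2),
             weights = cbind(c(1, 2), c(3, 4)))
  tr2 <- tsfnn_forward(p2, c(0, 0))
  expect_gte(tr2$normalized[1], 1 - 1e-4)
  expect_equal(tr2$outputs, c(1, 2), tolerance = 1e-4)
  # random instances against the straight re-evaluation oracle
  for (i in 1:20) {
    p <- random_params(3, 3, 3)
    x <- stats::runif(3)
    expect_equal(tsfnn_forward(p, x)$outputs, forward_oracle(p, x),
                 tolerance = 1e-12)
  }
})

test_that("normalized firing strengths sum to one and survive underflow", {
  set.seed(6)
  for (i in 1:50) {
    p <- random_params(2, 4, 2)
    x <- stats::runif(2, -5, 5)
    expect_equal(sum(tsfnn_forward(p, x)$normalized), 1, tolerance = 1e-12)
  }
  # all firing strengths underflow in linear space; log-space stays finite
  p <- list(centers = matrix(c(0, 100), 1, 2),
            widths = matrix(0.01, 1, 2), weights = matrix(c(1, 2), 1, 2))
  tr <- tsfnn_forward(p, 50)
  expect_true(all(is.finite(tr$normalized)))
  expect_equal(sum(tr$normalized), 1)
})

test_that("forward pass is invariant under joint rule permutation", {
  set.seed(7)
  p <- random_params(3, 4, 2)
  perm <- sample(4)
  q <- list(centers = p$centers[, perm], widths = p$widths[, perm],
            weights = p$weights[, perm])
  x <- stats::runif(3)
  expect_equal(tsfnn_forward(p, x)$outputs, tsfnn_forward(q, x)$outputs,
               tolerance = 1e-12)
})

test_that("subtractive clustering finds the density modes", {
  expect_equal(subtractive_clustering(matrix(c(0.3, 0.7), 1, 2)),
               matrix(c(0.3, 0.7), 1, 2))
  # all points identical: a single center
  same <- matrix(0.5, 25, 2)
  expect_equal(nrow(subtractive_clustering(same)), 1)
  # two tight, well-separated blobs: exactly two centers near the centroids
  set.seed(8)
  blob1 <- matrix(stats::rnorm(40, 0, 0.01), 20, 2)
  blob2 <- matrix(stats::rnorm(40, 5, 0.01), 20, 2)
  x <- rbind(blob1, blob2)
  cen <- subtractive_clustering(x, sca_config(r_a = 0.5))
  expect_equal(nrow(cen), 2)
  d1 <- min(sqrt(rowSums((cen - matrix(colMeans(blob1), 2, 2, TRUE))^2)))
  d2 <- min(sqrt(rowSums((cen - matrix(colMeans(blob2), 2, 2, TRUE))^2)))
  expect_lt(d1, 0.03)
  expect_lt(d2, 0.03)
  # exhaustive potential oracle: the first center maximizes the potential
  d2mat <- as.matrix(stats::dist(x))^2
  pot <- rowSums(exp(-(4 / 0.5^2) * d2mat))
  expect_equal(unname(cen[1, ]), unname(x[which.max(pot), ]))
  expect_error(subtractive_clustering(matrix(numeric(0), 0, 2)),
               class = "drowsefuse_invalid_input")
})

test_that("cluster-derived initial widths follow the nearest-center rule", {
  init <- init_from_clusters(rbind(c(0, 0), c(4, 2)))
  expect_equal(init$widths, matrix(c(2, 1), 2, 2))
  expect_equal(init$centers, cbind(c(0, 0), c(4, 2)))
  # single cluster: floor fallback
  one <- init_from_clusters(matrix(c(1, 2), 1, 2), sigma_floor = 0.07)
  expect_equal(one$widths, matrix(0.07, 2, 1))
  # collinear centers: nearest to the first decides
  col3 <- init_from_clusters(matrix(c(0, 1, 10), 3, 1))
  expect_equal(col3$widths, matrix(0.5, 1, 3))
})

test_that("fitness is the per-sample multi-output squared error", {
  p <- list(centers = matrix(0, 1, 1), widths = matrix(1, 1, 1),
            weights = matrix(c(0.5, 0.2, 0.1), 3, 1))
  X <- matrix(0, 1, 1)
  expect_equal(tsfnn_fitness(p, X, matrix(c(0.5, 0.2, 0.1), 1, 3)), 0)
  expect_equal(tsfnn_fitness(p, X, matrix(c(0.6, 0.2, 0.1), 1, 3)), 0.01)
  p2 <- list(centers = matrix(0, 1, 1), widths = matrix(1, 1, 1),
             weights = matrix(1, 1, 1))
  expect_equal(tsfnn_fitness(p2, matrix(0, 2, 1), matrix(c(1.3, 0.6), 2, 1)),
               (0.09 + 0.16) / 2)
  expect_error(tsfnn_fitness(p2, matrix(0, 0, 1), matrix(0, 0, 1)),
               class = "drowsefuse_invalid_input")
})

test_that("swarm training is reproducible with a monotone best-fitness trace", {
  set.seed(9)
  p <- random_params(2, 2, 2)
  X <- matrix(stats::runif(60), 30, 2)
  Y <- predictions <- t(apply(X, 1, function(x) forward_oracle(p, x)))
  init <- random_params(2, 2, 2)
  cfg <- pso_config(max_iters = 40, seed = 123)
  r1 <- pso_train(X, Y, init, cfg)
  r2 <- pso_train(X, Y, init, cfg)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 0))
  expect_lte(r1$final_fitness, tsfnn_fitness(init, X, Y))
  # zero-iteration budget returns the initial parameters and their fitness
  r0 <- pso_train(X, Y, init, pso_config(max_iters = 0, seed = 1))
  expect_identical(r0$params, init)
  expect_equal(r0$final_fitness, tsfnn_fitness(init, X, Y))
  expect_length(r0$trace, 0)
  expect_error(pso_train(matrix(0, 0, 2), matrix(0, 0, 2), init, cfg),
               class = "drowsefuse_invalid_input")
})

test_that("model fitting, prediction, tidiers and serialization round-trip", {
  tab <- generate_training_table(30, sim_config(seed = 17))
  fit <- fit_tsfnn(tab, c("bf", "ecd", "yf"), c("y_nf", "y_mf", "y_sf"),
                   pso = pso_config(max_iters = 30, seed = 2), n_starts = 1)
  expect_s3_class(fit, "tsfnn")
  pred <- predict(fit, tab[1:5, ])
  expect_named(pred, c("y_nf", "y_mf", "y_sf"))
  expect_equal(nrow(pred), 5)
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("center", "width", "weight"))
  s <- fit$structure
  expect_equal(nrow(td), count_parameters(s$n, s$m, s$r))
  g <- glance(fit)
  expect_equal(g$n_inputs, 3)
  expect_equal(g$n_parameters, count_parameters(s$n, s$m, s$r))
  path <- withr::local_tempfile(fileext = ".json")
  write_tsfnn(fit, path)
  fit2 <- read_tsfnn(path)
  expect_equal(predict(fit2, tab[1:5, ]), pred, tolerance = 1e-12)
})
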