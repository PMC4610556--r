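test_that("mass constructor validates and normalizes", {
  m <- mass(0.7, 0.2, 0.1)
  expect_s3_class(m, "mass")
  expect_equal(sum(m), 1)
  expect_equal(unname(vacuous_mass()[["theta"]]), 1)
  expect_error(mass(0.5, 0.5, 0.5), class = "drowsefuse_invalid_mass")
  expect_equal(sum(mass(c(0.5, 0.5, 0.5), normalize = TRUE)), 1)
  expect_error(mass(-0.2, 0.6, 0.6), class = "drowsefuse_invalid_mass")
})

test_that("dynamic BPA normalizes network outputs and clamps negatives", {
  m <- bpa_from_outputs(c(0.203, 0.763, 0.052))
  expect_equal(round(unname(m[1:3]), 3), c(0.199, 0.750, 0.051))
  expect_equal(unname(bpa_from_outputs(c(1, 1, 1))[1:3]), rep(1 / 3, 3))
  expect_equal(unname(bpa_from_outputs(c(0, 0, 5))[1:3]), c(0, 0, 1))
  expect_equal(unname(bpa_from_outputs(c(-1, 0, 2))[1:3]), c(0, 0, 1))
  expect_error(bpa_from_outputs(c(-1, -2, 0)),
               class = "drowsefuse_uninformative")
})

test_that("conflict degree matches hand-derived and worked-example values", {
  p1 <- mass(1, 0, 0)
  p2 <- mass(0, 1, 0)
  expect_equal(conflict_degree(p1, p1), 0)
  expect_equal(conflict_degree(p1, p2), 1)
  # worked example: first-fusion sample 3
  K <- conflict_degree(mass(c(0.228, 0.601, 0.171)),
                       mass(c(0.359, 0.516, 0.125)))
  expect_equal(K, 0.587, tolerance = 0.003 / 0.587)
  # identity: K(m, m) = (sum m_i)^2 - sum m_i^2 <= 1 - sum m_i^2
  set.seed(11)
  for (i in 1:50) {
    m <- random_mass(with_theta = i %% 2 == 0)
    bound <- 1 - sum(m[1:3]^2)
    expect_lte(conflict_degree(m, m), bound + 1e-12)
    if (m[["theta"]] == 0) {
      expect_equal(conflict_degree(m, m), bound)
    }
  }
})

test_that("Dempster combination has the vacuous neutral element and known sums", {
  m <- mass(c(0.3, 0.5, 0.2))
  expect_equal(unclass(dempster_combine(vacuous_mass(), m)), unclass(m))
  # two-focal-set hand enumeration: {A1 .4, Th .6} x {A1 .5, Th .5}
  f <- dempster_combine(mass(0.4, 0, 0, theta = 0.6),
                        mass(0.5, 0, 0, theta = 0.5))
  expect_equal(unname(f[["nf"]]), 0.7)
  expect_equal(unname(f[["theta"]]), 0.3)
  # worked example sample 3: fused moderate-fatigue mass
  f3 <- dempster_combine(mass(c(0.228, 0.601, 0.171)),
                         mass(c(0.359, 0.516, 0.125)))
  expect_equal(unname(f3[["mf"]]), 0.751, tolerance = 0.003 / 0.751)
  expect_error(dempster_combine(mass(1, 0, 0), mass(0, 1, 0)),
               class = "drowsefuse_total_conflict")
})

test_that("Dempster combination agrees with the focal-set enumeration oracle", {
  set.seed(21)
  for (i in 1:200) {
    m1 <- random_mass(with_theta = i %% 3 != 0)
    m2 <- random_mass(with_theta = i %% 2 == 0)
    oracle <- dempster_oracle(m1, m2)
    expect_equal(conflict_degree(m1, m2), oracle$K, tolerance = 1e-12)
    expect_equal(unname(unclass(dempster_combine(m1, m2))), oracle$mass,
                 tolerance = 1e-12)
  }
})

test_that("combination is commutative and associative and conserves mass", {
  set.seed(31)
  for (i in 1:100) {
    m1 <- random_mass(); m2 <- random_mass(); m3 <- random_mass()
    ab <- dempster_combine(m1, m2)
    expect_equal(unclass(ab), unclass(dempster_combine(m2, m1)),
                 tolerance = 1e-12)
    lhs <- dempster_combine(ab, m3)
    rhs <- dempster_combine(m1, dempster_combine(m2, m3))
    expect_equal(unclass(lhs), unclass(rhs), tolerance = 1e-9)
    expect_equal(sum(lhs), 1, tolerance = 1e-9)
  }
})

test_that("evidence distance is a normalized Euclidean form", {
  m <- mass(c(0.5, 0.5, 0))
  expect_equal(evidence_distance(m, m), 0)
  expect_equal(evidence_distance(mass(1, 0, 0), mass(0, 1, 0)), 1)
})

test_that("belief factors discount conflicting sources, eta decreasing in c", {
  m <- mass(c(0.5, 0.3, 0.2))
  rep0 <- belief_factors(list(m, m))
  expect_equal(rep0$c_i, c(0, 0))
  expect_equal(rep0$eta, c(1, 1))
  eta <- function(c) (1 - c) * exp(c)
  expect_equal(eta(0), 1)
  expect_equal(eta(1), 0)
  expect_true(eta(0.2) > eta(0.5) && eta(0.5) > eta(0.9))
  # strict decrease across [0, 1]
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(eta(grid)) < 0))
  # averaging convention: self-inclusive halves c_i for two sources
  p1 <- mass(0.9, 0.05, 0.05)
  p2 <- mass(0.1, 0.8, 0.1)
  expect_equal(belief_factors(list(p1, p2), include_self = TRUE)$c_i,
               belief_factors(list(p1, p2))$c_i / 2)
  expect_error(belief_factors(list(m)), class = "drowsefuse_invalid_input")
})

test_that("BPA discounting transfers released mass to the frame", {
  m <- mass(c(0.5, 0.3, 0.2))
  expect_equal(unclass(discount_bpa(m, 1)), unclass(m))
  expect_equal(unname(discount_bpa(m, 0)[["theta"]]), 1)
  d <- discount_bpa(m, 0.8)
  expect_equal(unname(unclass(d)), c(0.4, 0.24, 0.16, 0.2))
  expect_error(discount_bpa(m, 1.2), class = "drowsefuse_invalid_input")
})

test_that("conflict-gated combination corrects only above the threshold", {
  p <- mass(1, 0, 0)
  r0 <- combine_with_correction(p, p)
  expect_false(r0$corrected)
  expect_equal(r0$K, 0)
  # worked example sample 5: K = 0.835 stays on the plain path at k_T = 0.9
  r5 <- combine_with_correction(mass(c(0.126, 0.072, 0.802)),
                                mass(c(0.402, 0.501, 0.097)))
  expect_false(r5$corrected)
  expect_equal(unname(r5$mass[["sf"]]), 0.471, tolerance = 0.003 / 0.471)
  # total conflict is finite on the corrected path
  rc <- combine_with_correction(mass(1, 0, 0), mass(0, 1, 0),
                                fusion_config(k_t = 0.5))
  expect_true(rc$corrected)
  expect_gt(unname(rc$mass[["theta"]]), 0)
  expect_equal(sum(rc$mass), 1, tolerance = 1e-9)
})

test_that("every fusion operation conserves unit mass", {
  set.seed(41)
  cfg <- fusion_config(k_t = 0.3)
  for (i in 1:100) {
    m1 <- random_mass(); m2 <- random_mass()
    expect_equal(sum(dempster_combine(m1, m2)), 1, tolerance = 1e-9)
    expect_equal(sum(combine_with_correction(m1, m2, cfg)$mass), 1,
                 tolerance = 1e-9)
    expect_equal(sum(discount_bpa(m1, stats::runif(1))), 1, tolerance = 1e-9)
  }
})
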