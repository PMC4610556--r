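#' Mass functions over the fatigue frame of discernment
#'
#' The recognizer reasons over the frame \eqn{\Theta = \{NF, MF, SF\}}
#' (non-fatigue, moderate fatigue, severe fatigue).  A basic probability
#' assignment (BPA, or mass function) allocates nonnegative mass to the three
#' singleton hypotheses and, after discounting, possibly to the whole frame
#' \eqn{\Theta} itself; masses sum to one and the empty set carries none.
#' Two-element subsets never receive mass anywhere in the pipeline, so a mass
#' function is represented as a named numeric vector
#' `c(nf, mf, sf, theta)`.
#'
#' @param nf,mf,sf Nonnegative masses on the three singleton states.  `nf`
#'   may also be a numeric vector of length 3 or 4 giving all components at
#'   once.
#' @param theta Mass on the whole frame (total ignorance); defaults to 0.
#' @param normalize If `TRUE`, rescale the components to unit sum instead of
#'   requiring it.  Useful when replaying vectors printed to a few decimals.
#' @return A `"mass"` object: named numeric of length 4.
#' @examples
#' mass(0.7, 0.2, 0.1)
#' mass(c(0.228, 0.601, 0.171))
#' vacuous_mass()
#' @export
mass <- function(nf, mf = NULL, sf = NULL, theta = 0, normalize = FALSE) {
  if (is.null(mf) && length(nf) >= 3) {
    x <- as.numeric(nf)
    if (length(x) == 3) x <- c(x, theta)
  } else {
    x <- c(nf, mf, sf, theta)
  }
  if (length(x) != 4 || anyNA(x) || !is.numeric(x)) {
    rlang::abort("a mass function needs components (nf, mf, sf, theta)",
                 class = "drowsefuse_invalid_mass")
  }
  if (any(x < -1e-12)) {
    rlang::abort("mass components must be nonnegative",
                 class = "drowsefuse_invalid_mass")
  }
  x <- pmax(x, 0)
  s <- sum(x)
  if (normalize) {
    if (s <= 0) {
      rlang::abort("cannot normalize an all-zero mass vector",
                   class = "drowsefuse_invalid_mass")
    }
    x <- x / s
  } else if (abs(s - 1) > 1e-6) {
    rlang::abort(
      sprintf("mass components must sum to 1 (got %.8f); use normalize = TRUE for rounded inputs", s),
      class = "drowsefuse_invalid_mass")
  }
  structure(stats::setNames(x, c("nf", "mf", "sf", "theta")), class = "mass")
}

#' @rdname mass
#' @export
vacuous_mass <- function() mass(0, 0, 0, theta = 1)

#' @export
print.mass <- function(x, ...) {
  cat(sprintf("<mass> nf=%.4f mf=%.4f sf=%.4f theta=%.4f\n",
              x[[1]], x[[2]], x[[3]], x[[4]]))
  invisible(x)
}

as_mass <- function(x, normalize = FALSE) {
  if (inherits(x, "mass")) return(x)
  mass(as.numeric(x), normalize = normalize)
}

#' Dynamic basic probability assignment from network outputs
#'
#' Converts the raw output vector of a fuzzy neural network into a mass
#' function over the singleton fatigue states: negative components are
#' clamped to zero and the remainder is normalized to unit sum,
#' \eqn{m(A_i) = y_i / \sum_i y_i}.  Because the outputs move with every new
#' feature window, the resulting BPA is dynamic rather than fixed by expert
#' judgement.
#'
#' @param y Numeric vector of length 3: network outputs for (NF, MF, SF).
#' @return A [mass()] object with zero mass on \eqn{\Theta}.
#' @examples
#' bpa_from_outputs(c(0.203, 0.763, 0.052))
#' @export
bpa_from_outputs <- function(y) {
  stopifnot(is.numeric(y), length(y) == 3)
  y <- pmax(y, 0)
  if (sum(y) <= 0) {
    rlang::abort("all network outputs are nonpositive; evidence is uninformative",
                 class = "drowsefuse_uninformative")
  }
  mass(y / sum(y))
}

# Pairwise singleton agreement sum_i m1_i * m2_i; theta intersects everything
# so it never contributes to conflict.
.agreement <- function(m1, m2) sum(m1[1:3] * m2[1:3])

#' Conflict degree between two mass functions
#'
#' The Dempster conflict degree \eqn{K} is the total product mass falling on
#' empty intersections of focal sets.  On this frame only singleton-singleton
#' pairs with different states conflict; mass on \eqn{\Theta} intersects
#' everything.  \eqn{K = 1} means total conflict and invalidates the plain
#' combination rule.
#'
#' @param m1,m2 [mass()] objects (plain numeric vectors are coerced).
#' @return `K` in \[0, 1\].
#' @examples
#' conflict_degree(mass(c(0.228, 0.601, 0.171)), mass(c(0.359, 0.516, 0.125)))
#' @export
conflict_degree <- function(m1, m2) {
  m1 <- as_mass(m1); m2 <- as_mass(m2)
  s1 <- sum(m1[1:3]); s2 <- sum(m2[1:3])
  K <- s1 * s2 - .agreement(m1, m2)
  min(max(K, 0), 1)
}

#' Dempster's rule of combination
#'
#' Combines two mass functions by the orthogonal sum: products of masses on
#' intersecting focal sets are accumulated on the intersection and
#' renormalized by \eqn{1 - K}.  The vacuous mass (all on \eqn{\Theta}) is
#' the neutral element.
#'
#' @inheritParams conflict_degree
#' @return The fused [mass()].
#' @examples
#' m1 <- mass(c(0.228, 0.601, 0.171))
#' m2 <- mass(c(0.359, 0.516, 0.125))
#' dempster_combine(m1, m2)
#' @export
dempster_combine <- function(m1, m2) {
  m1 <- as_mass(m1); m2 <- as_mass(m2)
  K <- conflict_degree(m1, m2)
  if (K >= 1 - 1e-12) {
    rlang::abort("total conflict (K = 1): Dempster combination undefined",
                 class = "drowsefuse_total_conflict")
  }
  t1 <- m1[["theta"]]; t2 <- m2[["theta"]]
  singles <- m1[1:3] * m2[1:3] + m1[1:3] * t2 + t1 * m2[1:3]
  v <- c(singles, t1 * t2)
  # dividing by the retained product mass (= 1 - K) keeps the result exactly
  # normalized even when K is within rounding of 1
  mass(v / sum(v))
}

#' Euclidean distance between two mass functions
#'
#' \eqn{d = \sqrt{(\lVert m_1\rVert^2 + \lVert m_2\rVert^2 - 2\langle m_1, m_2\rangle)/2}}
#' over the four focal coordinates (three singletons and \eqn{\Theta}).
#' Ranges from 0 (identical) to 1 (disjoint point masses).
#'
#' @inheritParams conflict_degree
#' @export
evidence_distance <- function(m1, m2) {
  m1 <- as_mass(m1); m2 <- as_mass(m2)
  v <- unclass(m1) - unclass(m2)
  sqrt(max(sum(v^2), 0) / 2)
}

#' Belief factors for a set of conflicting evidence
#'
#' For every ordered pair of evidence sources computes the conflict degree
#' \eqn{K_{ij}}, the Euclidean evidence distance \eqn{d_{ij}}, and the
#' confidence level \eqn{c_{ij} = K_{ij} d_{ij}}.  Each source's average
#' confidence \eqn{c_i} is turned into a belief factor
#' \eqn{\eta_i = (1 - c_i) e^{c_i}}, a discount in \[0, 1\] that shrinks a
#' source the more it disagrees with the others.
#'
#' @param evidence A list of [mass()] objects, length at least 2.
#' @param include_self If `TRUE`, average \eqn{c_{ij}} over all j including
#'   the zero self-term (divide by n); the default averages over the other
#'   sources only (divide by n - 1), which does not dilute the conflict
#'   signal.
#' @return A list of class `"conflict_report"` with matrices `K`, `d`, `c`
#'   and vectors `c_i`, `eta`.
#' @export
belief_factors <- function(evidence, include_self = FALSE) {
  if (!is.list(evidence) || length(evidence) < 2) {
    rlang::abort("belief factors need at least two pieces of evidence",
                 class = "drowsefuse_invalid_input")
  }
  evidence <- lapply(evidence, as_mass)
  n <- length(evidence)
  K <- d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      K[i, j] <- conflict_degree(evidence[[i]], evidence[[j]])
      d[i, j] <- evidence_distance(evidence[[i]], evidence[[j]])
    }
  }
  cm <- K * d
  denom <- if (include_self) n else n - 1
  c_i <- rowSums(cm) / denom
  eta <- pmin(pmax((1 - c_i) * exp(c_i), 0), 1)
  structure(list(K = K, d = d, c = cm, c_i = c_i, eta = eta),
            class = "conflict_report")
}

#' Discount a mass function by a belief factor
#'
#' Scales the singleton masses by \eqn{\eta} and transfers the released mass
#' to the whole frame: \eqn{m'(A_j) = \eta\, m(A_j)},
#' \eqn{m'(\Theta) = 1 - \eta \sum_j m(A_j)}.  With \eqn{\eta = 0} the result
#' is vacuous; with \eqn{\eta = 1} a theta-free mass is unchanged.
#'
#' @param m A [mass()].
#' @param eta Discount in \[0, 1\].
#' @export
discount_bpa <- function(m, eta) {
  m <- as_mass(m)
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta < 0 || eta > 1) {
    rlang::abort("belief factor eta must lie in [0, 1]",
                 class = "drowsefuse_invalid_input")
  }
  singles <- m[1:3] * eta
  mass(c(singles, 1 - sum(singles)))
}

#' Fusion thresholds
#'
#' @param k_t Conflict threshold in (0, 1\]: below it the plain Dempster rule
#'   is trusted; at or above it both sources are discounted by their belief
#'   factors first.  The default 0.9 keeps worked examples with conflict up
#'   to 0.835 on the uncorrected path.
#' @param eps_t1 Minimum margin between the largest and second-largest
#'   singleton mass for a confident decision.
#' @param eps_t2 Minimum largest singleton mass for a confident decision.
#' @return A list of class `"fusion_config"`.
#' @export
fusion_config <- function(k_t = 0.9, eps_t1 = 0.2, eps_t2 = 0.5) {
  stopifnot(k_t > 0, k_t <= 1, eps_t1 > 0, eps_t1 < 1, eps_t2 > 0, eps_t2 < 1)
  structure(list(k_t = k_t, eps_t1 = eps_t1, eps_t2 = eps_t2),
            class = "fusion_config")
}

#' Conflict-aware Dempster combination
#'
#' Computes the conflict degree \eqn{K} between two mass functions.  If
#' \eqn{K < k_T} the original BPAs are combined directly; otherwise each is
#' discounted by its belief factor ([belief_factors()]) before combination,
#' which moves unreliable mass onto \eqn{\Theta} and keeps the orthogonal sum
#' well behaved under high conflict (even at \eqn{K = 1}, where the plain
#' rule is undefined).
#'
#' @inheritParams conflict_degree
#' @param config A [fusion_config()].
#' @return A list with elements `mass` (the fused [mass()]), `K` (conflict of
#'   the original pair), `corrected` (logical), and `report` (the
#'   `conflict_report`, `NULL` on the uncorrected path).
#' @examples
#' m1 <- mass(c(0.126, 0.072, 0.802))
#' m2 <- mass(c(0.402, 0.501, 0.097))
#' combine_with_correction(m1, m2)
#' @export
combine_with_correction <- function(m1, m2, config = fusion_config()) {
  m1 <- as_mass(m1); m2 <- as_mass(m2)
  K <- conflict_degree(m1, m2)
  if (K < config$k_t) {
    return(list(mass = dempster_combine(m1, m2), K = K,
                corrected = FALSE, report = NULL))
  }
  rep <- belief_factors(list(m1, m2))
  fused <- dempster_combine(discount_bpa(m1, rep$eta[[1]]),
                            discount_bpa(m2, rep$eta[[2]]))
  list(mass = fused, K = K, corrected = TRUE, report = rep)
}
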