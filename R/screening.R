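#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the data against a normal distribution with
#' the sample's own mean and standard deviation, passed when the statistic
#' falls below the asymptotic 5 % critical value \eqn{1.36/\sqrt{n}}.  The
#' estimated-parameter statistic is used with the uncorrected asymptotic
#' quantile by default; `lilliefors = TRUE` substitutes the
#' Lilliefors-corrected test (requires the nortest package) which properly
#' accounts for parameter estimation.
#'
#' @param x Numeric sample, `n >= 8`.
#' @param alpha Significance level (only 0.05 is supported for the
#'   asymptotic quantile; the Lilliefors branch honours any level).
#' @param lilliefors Use `nortest::lillie.test()` instead.
#' @return List with `statistic`, `quantile`, `pass`, `degenerate`.
#' @export
ks_normality <- function(x, alpha = 0.05, lilliefors = FALSE) {
  n <- length(x)
  stopifnot(n >= 8)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) {
    return(list(statistic = NA_real_, quantile = NA_real_,
                pass = FALSE, degenerate = TRUE))
  }
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      rlang::abort("the Lilliefors variant needs the nortest package")
    }
    lt <- nortest::lillie.test(x)
    return(list(statistic = unname(lt$statistic), quantile = NA_real_,
                pass = lt$p.value > alpha, degenerate = FALSE))
  }
  D <- unname(suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$statistic))
  crit <- 1.36 / sqrt(n)
  list(statistic = D, quantile = crit, pass = D < crit, degenerate = FALSE)
}

#' Logarithmic normalization
#'
#' Natural log transform applied before re-testing normality of a skewed
#' feature.  Non-positive values are first shifted by `1 - min(x)` so the
#' smallest value maps to `log(1) = 0`; the shift is flagged in the result.
#'
#' @param x Numeric sample.
#' @return List with `values` and `shifted`.
#' @export
log_normalize <- function(x) {
  shifted <- any(x <= 0)
  if (shifted) x <- x + (1 - min(x))
  list(values = log(x), shifted = shifted)
}

#' Pearson correlation screen against fatigue labels
#'
#' Sample Pearson correlation between a feature and the ordinal fatigue
#' coding (0 = NF, 1 = MF, 2 = SF), tested with the Student statistic
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} against the two-sided critical value at
#' `alpha` with `n - 2` degrees of freedom.  Screening is by magnitude:
#' negatively correlated features are retained just as readily.
#'
#' @param x Numeric feature sample.
#' @param y Numeric fatigue labels (0/1/2 coding), same length.
#' @param alpha Significance level.
#' @return List with `r`, `statistic`, `quantile`, `retained`, `degenerate`.
#' @export
pearson_screen <- function(x, y, alpha = 0.05) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, statistic = NA_real_,
                quantile = stats::qt(1 - alpha / 2, n - 2),
                retained = FALSE, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  crit <- stats::qt(1 - alpha / 2, n - 2)
  list(r = r, statistic = tstat, quantile = crit,
       retained = abs(tstat) > crit, degenerate = FALSE)
}

#' Screen fatigue features for relevance
#'
#' Two-stage screening of a windowed feature table: each feature is checked
#' for normality by [ks_normality()] (with a [log_normalize()] fallback for
#' features that fail), then its (possibly transformed) values are tested
#' for correlation with the fatigue labels by [pearson_screen()].  Features
#' whose correlation magnitude is not significant are dropped from the
#' candidate set.
#'
#' @param data Data frame of feature columns (any non-feature columns can be
#'   excluded via `features`).
#' @param labels Fatigue labels: `"NF"/"MF"/"SF"` strings or a 0/1/2 numeric
#'   coding, one per row of `data`.
#' @param features Character vector of feature columns to screen; defaults
#'   to the eight standard features present in `data`.
#' @param alpha Significance level for both tests.
#' @return Tibble of class `"feature_screening"`, one row per feature:
#'   `feature`, `ks_statistic`, `ks_quantile`, `normal`, `log_transformed`,
#'   `r`, `statistic`, `quantile`, `retained`, `degenerate`.
#' @examples
#' tab <- generate_training_table(40, sim_config(seed = 1))
#' select_features(tab, tab$state)
#' @export
select_features <- function(data, labels, features = NULL, alpha = 0.05) {
  data <- as.data.frame(data)
  if (is.null(features)) {
    features <- intersect(
      c("bf", "ecd", "meol", "yf", "pns", "sdsa", "fald", "sdvs"),
      names(data))
  }
  stopifnot(length(features) > 0, all(features %in% names(data)))
  y <- if (is.numeric(labels)) labels
       else match(.as_state(labels), fatigue_states()) - 1
  stopifnot(length(y) == nrow(data))
  res <- purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    ks <- ks_normality(x, alpha)
    transformed <- FALSE
    if (!ks$pass && !ks$degenerate) {
      lx <- log_normalize(x)
      ks2 <- ks_normality(lx$values, alpha)
      if (ks2$pass) {
        x <- lx$values
        ks <- ks2
        transformed <- TRUE
      }
    }
    ps <- pearson_screen(x, y, alpha)
    tibble::tibble(feature = f,
                   ks_statistic = ks$statistic, ks_quantile = ks$quantile,
                   normal = ks$pass, log_transformed = transformed,
                   r = ps$r, statistic = ps$statistic,
                   quantile = ps$quantile, retained = ps$retained,
                   degenerate = ks$degenerate || ps$degenerate)
  })
  class(res) <- c("feature_screening", class(res))
  res
}

#' Retained features from a screening result
#'
#' @param screening A [select_features()] result.
#' @export
retained_features <- function(screening) {
  screening$feature[screening$retained]
}
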