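#' Fatigue-state decision rule
#'
#' Let \eqn{m(A_F)} be the largest singleton mass and \eqn{m(A_S)} the
#' runner-up.  The state \eqn{A_F} is output only when both
#' \eqn{m(A_F) - m(A_S) > \varepsilon_{T1}} and
#' \eqn{m(A_F) > \varepsilon_{T2}}; otherwise the previously recognized
#' state is carried forward.  Only the singleton masses enter the rule; mass
#' on \eqn{\Theta} lowers them implicitly but is never compared directly.
#' Exact ties are resolved by the fixed state order NF < MF < SF, where the
#' zero margin necessarily fails the rule.
#'
#' @param m A [mass()] (or numeric vector whose first three components are
#'   the singleton masses).
#' @param config A [fusion_config()] supplying `eps_t1` and `eps_t2`.
#' @param prev The previously decided state, returned when the rule is not
#'   met.
#' @return `"NF"`, `"MF"` or `"SF"`.
#' @examples
#' decide(c(0.854, 0.145, 0.002), prev = "MF")  # confident "NF"
#' decide(c(0.40, 0.38, 0.22), prev = "MF")     # margin too small -> "MF"
#' @export
decide <- function(m, config = fusion_config(), prev = "NF") {
  singles <- as.numeric(m)[1:3]
  prev <- .as_state(prev)
  top <- which.max(singles)
  runner <- max(singles[-top])
  if (singles[top] - runner > config$eps_t1 && singles[top] > config$eps_t2) {
    fatigue_states()[top]
  } else {
    prev
  }
}

#' Recognizer temporal state
#'
#' Carries the previous decision-level fused mass and the previous decided
#' state between recognition steps.  At the start of a session the prior is
#' vacuous (total ignorance, neutral under Dempster combination) and the
#' state is `"NF"`.
#'
#' @param prev_mass Previous fused [mass()].
#' @param prev_state Previous decided state.
#' @param step_index Number of steps already taken.
#' @export
recognizer_state <- function(prev_mass = vacuous_mass(), prev_state = "NF",
                             step_index = 0L) {
  structure(list(prev_mass = as_mass(prev_mass),
                 prev_state = .as_state(prev_state),
                 step_index = as.integer(step_index)),
            class = "recognizer_state")
}

#' Train the two-network fatigue recognizer
#'
#' Fits the facial network (inputs bf, ecd, yf) and the vehicle-behavior
#' network (inputs pns, sdsa, fald, sdvs), each with three outputs encoding
#' the NF/MF/SF memberships, on a labelled training table such as
#' [generate_training_table()] produces.
#'
#' @param data Training table with the feature columns and targets `y_nf`,
#'   `y_mf`, `y_sf`.
#' @param facial_inputs,vehicle_inputs Feature columns routed to each
#'   network.
#' @param sca,pso Structure and training configuration shared by both fits
#'   (the vehicle network uses `pso$seed + 1`).
#' @param fusion A [fusion_config()].
#' @return A `"fatigue_recognizer"` bundle with elements `facial`,
#'   `vehicle` (both `"tsfnn"`) and `fusion`.
#' @export
train_recognizer <- function(data,
                             facial_inputs = c("bf", "ecd", "yf"),
                             vehicle_inputs = c("pns", "sdsa", "fald", "sdvs"),
                             sca = sca_config(), pso = pso_config(),
                             fusion = fusion_config()) {
  targets <- c("y_nf", "y_mf", "y_sf")
  pso2 <- pso
  pso2$seed <- pso$seed + 1L
  structure(list(
    facial = fit_tsfnn(data, facial_inputs, targets, sca, pso),
    vehicle = fit_tsfnn(data, vehicle_inputs, targets, sca, pso2),
    fusion = fusion), class = "fatigue_recognizer")
}

#' @export
print.fatigue_recognizer <- function(x, ...) {
  cat("<fatigue_recognizer>\n  facial:  ")
  print(x$facial)
  cat("  vehicle: ")
  print(x$vehicle)
  invisible(x)
}

.safe_bpa <- function(y) {
  tryCatch(list(mass = bpa_from_outputs(y), informative = TRUE),
           drowsefuse_uninformative = function(e)
             list(mass = vacuous_mass(), informative = FALSE))
}

.safe_combine <- function(m1, m2, config) {
  tryCatch(combine_with_correction(m1, m2, config),
           drowsefuse_total_conflict = function(e) NULL)
}

#' One recognition step
#'
#' Runs the full per-window pipeline: both networks are evaluated on the
#' window's features, their outputs become dynamic BPAs, the two BPAs are
#' fused ([combine_with_correction()]), the normalized intermediate result
#' is fused with the previous step's decision-level mass, and [decide()]
#' produces the state.  A source whose outputs are all nonpositive
#' contributes vacuous evidence; if both are vacuous, or combination hits
#' total conflict, the step falls back to the previous state and mass.
#'
#' @param features One feature window: a one-row data frame or named list
#'   with the recognizer's input columns.
#' @param state A [recognizer_state()].
#' @param recognizer A [train_recognizer()] bundle.
#' @return List with `decision`, `mass`, `state` (advanced), and a one-row
#'   `diagnostics` tibble.
#' @export
step_recognizer <- function(features, state, recognizer) {
  row <- as.data.frame(features)[1, , drop = FALSE]
  y1 <- as.numeric(predict(recognizer$facial, row)[1, ])
  y2 <- as.numeric(predict(recognizer$vehicle, row)[1, ])
  e1 <- .safe_bpa(y1)
  e2 <- .safe_bpa(y2)
  cfg <- recognizer$fusion
  fallback <- function(reason) {
    list(decision = state$prev_state, mass = state$prev_mass,
         state = recognizer_state(state$prev_mass, state$prev_state,
                                  state$step_index + 1L),
         diagnostics = tibble::tibble(
           m_nf = state$prev_mass[[1]], m_mf = state$prev_mass[[2]],
           m_sf = state$prev_mass[[3]], theta = state$prev_mass[[4]],
           k_first = NA_real_, k_second = NA_real_,
           corrected = FALSE, fallback = reason,
           decision = state$prev_state))
  }
  if (!e1$informative && !e2$informative) {
    return(fallback("both sources uninformative"))
  }
  first <- .safe_combine(e1$mass, e2$mass, cfg)
  if (is.null(first)) return(fallback("total conflict in first fusion"))
  intermediate <- mass(unclass(first$mass), normalize = TRUE)
  second <- .safe_combine(intermediate, state$prev_mass, cfg)
  if (is.null(second)) return(fallback("total conflict in temporal fusion"))
  final <- second$mass
  decision <- decide(final, cfg, state$prev_state)
  list(decision = decision, mass = final,
       state = recognizer_state(final, decision, state$step_index + 1L),
       diagnostics = tibble::tibble(
         m_nf = final[[1]], m_mf = final[[2]], m_sf = final[[3]],
         theta = final[[4]],
         k_first = first$K, k_second = second$K,
         corrected = first$corrected || second$corrected,
         fallback = NA_character_, decision = decision))
}

#' Recognize fatigue states over a session of feature windows
#'
#' Applies [step_recognizer()] sequentially to each row of a feature table,
#' threading the temporal state.  Rows with missing or non-finite feature
#' values are skipped (with a warning) and do not advance the state.
#'
#' @param features Feature table: one row per window with the recognizer's
#'   input columns, optionally `window_start`.
#' @param recognizer A [train_recognizer()] bundle.
#' @param state Initial [recognizer_state()].
#' @return A tibble of class `"fatigue_session"`: `window_start`, the fused
#'   masses `m_nf`/`m_mf`/`m_sf`/`theta`, the conflict degrees `k_first` and
#'   `k_second`, `corrected`, `fallback` and `decision`.
#' @export
recognize_session <- function(features, recognizer,
                              state = recognizer_state()) {
  features <- as.data.frame(features)
  needed <- unique(c(recognizer$facial$inputs, recognizer$vehicle$inputs))
  stopifnot(all(needed %in% names(features)))
  ws <- if ("window_start" %in% names(features)) features$window_start
        else (seq_len(nrow(features)) - 1) * 60
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(features))) {
    vals <- as.numeric(features[i, needed])
    if (anyNA(vals) || !all(is.finite(vals))) {
      skipped <- skipped + 1L
      next
    }
    res <- step_recognizer(features[i, , drop = FALSE], state, recognizer)
    state <- res$state
    rows[[length(rows) + 1L]] <- dplyr::mutate(res$diagnostics,
                                               window_start = ws[[i]],
                                               .before = 1)
  }
  if (skipped > 0) {
    rlang::warn(sprintf("skipped %d malformed feature row(s)", skipped),
                class = "drowsefuse_skipped_rows")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(window_start = numeric(0), m_nf = numeric(0),
                          m_mf = numeric(0), m_sf = numeric(0),
                          theta = numeric(0), k_first = numeric(0),
                          k_second = numeric(0), corrected = logical(0),
                          fallback = character(0), decision = character(0))
  }
  class(out) <- c("fatigue_session", class(out))
  out
}

#' Serialize / restore a trained recognizer bundle as JSON
#'
#' @param recognizer A `"fatigue_recognizer"`.
#' @param path File path.
#' @export
write_recognizer <- function(recognizer, path) {
  stopifnot(inherits(recognizer, "fatigue_recognizer"))
  pack <- function(model) {
    model$params <- lapply(model$params,
                           function(m) list(dim = dim(m), data = as.vector(m)))
    model$scaling <- lapply(model$scaling, as.numeric)
    unclass(model)
  }
  jsonlite::write_json(list(facial = pack(recognizer$facial),
                            vehicle = pack(recognizer$vehicle),
                            fusion = unclass(recognizer$fusion)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recognizer
#' @export
read_recognizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(model) {
    model$params <- lapply(model$params, function(m)
      matrix(as.numeric(m$data), m$dim[[1]], m$dim[[2]]))
    model$scaling <- list(
      min = stats::setNames(as.numeric(model$scaling$min), model$inputs),
      range = stats::setNames(as.numeric(model$scaling$range), model$inputs))
    model$trace <- as.numeric(model$trace)
    structure(model, class = "tsfnn")
  }
  structure(list(facial = unpack(obj$facial), vehicle = unpack(obj$vehicle),
                 fusion = fusion_config(obj$fusion$k_t, obj$fusion$eps_t1,
                                        obj$fusion$eps_t2)),
            class = "fatigue_recognizer")
}
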