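#' @title Total fatigue index and fatigue-point detection
#' @name detect
#' @description
#' Per-pitch fatigue values A1..A3 are combined into the total fatigue
#' index `M_total = 100 * sum(A_m * W_m)` with simplex weights W. The x100
#' puts `M_total` on a percent scale in \[0, 100\], on which thresholds such
#' as `T = 50` (half-maximal fatigue) are meaningful; the raw \[0, 1\] scale
#' is available via `raw_scale`. The fatigue point R of a game is the first
#' pitch whose `M_total` reaches the threshold.
NULL

#' Scoring / detection parameters
#'
#' @param alpha fatigue interval index in (0, 1].
#' @param W weight triple (elbow, trunk, interval); non-negative, summing
#'   to 1 within 1e-9.
#' @param T_threshold fatigue threshold on the percent scale \[0, 100\]
#'   (or \[0, 1\] when `raw_scale`).
#' @param persistence number of consecutive pitches that must sit at or
#'   above the threshold before a crossing is declared (default 1, the
#'   plain first crossing; larger values add noise robustness).
#' @param search_window `"full"` (default): R is searched over the whole
#'   game; `"alpha"`: only over the first `floor(alpha * N)` pitches.
#' @param raw_scale report `M_total` on \[0, 1\] instead of percent.
#' @return An object of class `score_params`.
#' @export
score_params <- function(alpha = 0.7, W = c(0.7, 0.2, 0.1),
                         T_threshold = 50, persistence = 1L,
                         search_window = c("full", "alpha"),
                         raw_scale = FALSE) {
  search_window <- match.arg(search_window)
  pf_assert(is.numeric(alpha) && length(alpha) == 1L &&
              alpha > 0 && alpha <= 1,
            "parameter_error", "alpha must lie in (0, 1]")
  pf_assert(is.numeric(W) && length(W) == 3L && all(W >= 0),
            "parameter_error", "W must be 3 non-negative weights")
  pf_assert(abs(sum(W) - 1) <= 1e-9, "parameter_error",
            "weights must sum to 1 (got %.12f)", sum(W))
  top <- if (raw_scale) 1 else 100
  pf_assert(is.numeric(T_threshold) && length(T_threshold) == 1L &&
              T_threshold >= 0 && T_threshold <= top,
            "parameter_error", "T_threshold must lie in [0, %g]", top)
  pf_assert(persistence >= 1 && persistence == round(persistence),
            "parameter_error", "persistence must be a positive integer")
  structure(list(alpha = alpha, W = as.numeric(W),
                 T_threshold = T_threshold,
                 persistence = as.integer(persistence),
                 search_window = search_window, raw_scale = raw_scale),
            class = "score_params")
}

#' @export
print.score_params <- function(x, ...) {
  cat(sprintf(
    "<score_params> alpha = %g, W = (%g, %g, %g), T = %g%s, persistence = %d, window = %s\n",
    x$alpha, x$W[1], x$W[2], x$W[3], x$T_threshold,
    if (x$raw_scale) " (raw)" else "", x$persistence, x$search_window))
  invisible(x)
}

#' Total fatigue index of one pitch
#'
#' Weighted combination of the per-feature fatigue values. When a feature is
#' missing its weight is dropped and the remaining weights are renormalised
#' to the original total, keeping `M_total` on a stable scale:
#' `M_total = 100 * sum_present(A_m * W_m) / sum_present(W_m)`.
#'
#' @param A numeric triple of fatigue values (`NA` = missing).
#' @param params a [score_params].
#' @return `M_total` (percent, or \[0, 1\] under `raw_scale`); `NA` when all
#'   three features are missing.
#' @export
total_fatigue <- function(A, params) {
  pf_assert(length(A) == 3L, "parameter_error",
            "A must be the triple (A1, A2, A3)")
  present <- !is.na(A)
  if (!any(present)) return(NA_real_)
  scale <- if (params$raw_scale) 1 else 100
  scale * sum(A[present] * params$W[present]) / sum(params$W[present])
}

#' Detect the fatigue point of a game
#'
#' Scores every pitch, computes the `M_total` series and returns the first
#' pitch index R at which `M_total >= T` holds for `persistence` consecutive
#' pitches (pitches with undefined `M_total` never cross). With
#' `search_window = "alpha"` the search stops at `floor(alpha * N)`.
#'
#' @param session a [pitch_session].
#' @param bounds a `feature_bounds` object for this pitcher.
#' @param params a [score_params].
#' @inheritParams fatigue_value_elbow
#' @return An object of class `detection_result`: `game_id`, `R` (integer
#'   pitch index or `NA` if no crossing), `M_series`, and the per-pitch
#'   `scores` table with a `crossed` flag.
#' @export
detect_fatigue_point <- function(session, bounds, params = score_params(),
                                 degenerate = c("error", "step")) {
  degenerate <- match.arg(degenerate)
  scores <- score_session(session, bounds, degenerate)
  M <- vapply(seq_len(nrow(scores)), function(i)
    total_fatigue(c(scores$A1[i], scores$A2[i], scores$A3[i]), params),
    numeric(1))
  crossed <- !is.na(M) & M >= params$T_threshold
  limit <- if (params$search_window == "alpha")
    split_intervals(session$N, params$alpha)["n_nonfatigue"]
  else session$N
  R <- NA_integer_
  p <- params$persistence
  for (i in seq_len(max(0L, limit - p + 1L))) {
    if (all(crossed[i:(i + p - 1L)])) { R <- i; break }
  }
  scores$M_total <- M
  scores$crossed <- crossed
  structure(list(game_id = session$game_id, R = R, M_series = M,
                 scores = scores, params = params),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> game %s: %s (T = %g, %d pitches)\n",
              x$game_id,
              if (is.na(x$R)) "no crossing"
              else sprintf("fatigue point R = %d", x$R),
              x$params$T_threshold, length(x$M_series)))
  invisible(x)
}

#' Write a detection report
#'
#' Emits the per-pitch table as CSV
#' (`game_id, pitch_index, A1, A2, A3, M_total, crossed, R`) and a JSON
#' summary next to it.
#'
#' @param result a `detection_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_detection_report <- function(result, csv_path = NULL,
                                   json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- cbind(game_id = result$game_id, result$scores,
                R = ifelse(is.na(result$R), NA_integer_, result$R))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE,
                     na = "")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(game_id = result$game_id,
           R = if (is.na(result$R)) NULL else result$R,
           T_threshold = result$params$T_threshold,
           n_pitches = length(result$M_series),
           M_series = result$M_series),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(result)
}
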