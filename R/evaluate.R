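#' @title Leave-one-game-out evaluation and parameter search
#' @name evaluate
#' @description
#' Each of the n games serves once as the held-out validation game. Every
#' training game contributes its own fatigue point R_i, detected with that
#' game's own alpha-split bounds (the held-out game contributes only its
#' pitch count, so no held-out features leak into training). The training
#' fatigue points are pooled into the predicted fatigue point
#' `F_P = mean(R_i)` and scored against the held-out game's target pitch
#' `N * alpha`: `A_f = 1 - |F_P - N * alpha| / N`. The final accuracy is the
#' mean of the per-fold `A_f`.
NULL

#' Pool training-game fatigue points
#'
#' @param R_list detected fatigue points of the training games (`NA`s — no
#'   crossing — must be removed by the caller; see [cross_validate]).
#' @param mode `"absolute"` (default): `F_P = mean(R_i)`, the literal
#'   training-average; `"normalized"`: rescale by game length,
#'   `F_P = round(mean(R_i / N_i) * N_val)`.
#' @param N_list training-game pitch counts (normalized mode only).
#' @param N_val held-out game pitch count (normalized mode only).
#' @return The pooled fatigue point F_P (pitch index, possibly fractional
#'   in absolute mode).
#' @export
pooled_fatigue_point <- function(R_list, mode = c("absolute", "normalized"),
                                 N_list = NULL, N_val = NULL) {
  mode <- match.arg(mode)
  R_list <- as.numeric(R_list)
  if (length(R_list) == 0L || anyNA(R_list))
    pf_stop("no_detection",
            "R_list must be non-empty with all fatigue points present")
  if (mode == "absolute") return(mean(R_list))
  pf_assert(!is.null(N_list) && length(N_list) == length(R_list) &&
              !is.null(N_val), "parameter_error",
            "normalized pooling needs N_list and N_val")
  round(mean(R_list / N_list) * N_val)
}

#' Fold accuracy of a predicted fatigue point
#'
#' `A_f = 1 - |F_P - N * alpha| / N`: 1 when the prediction hits the target
#' pitch `N * alpha` exactly, decaying linearly with slope `1/N` in the
#' absolute error. The raw value may be negative when the prediction is off
#' by more than N pitches relative to the target; `clamp` floors it at 0
#' for reporting.
#'
#' @param F_P predicted fatigue point (pitch index).
#' @param N held-out game pitch count (>= 1).
#' @param alpha fatigue interval index.
#' @param clamp floor the accuracy at zero (default `FALSE`, raw value).
#' @return Accuracy in (-Inf, 1\] (or \[0, 1\] when clamped).
#' @export
fold_accuracy <- function(F_P, N, alpha, clamp = FALSE) {
  pf_assert(is.numeric(N) && all(N >= 1), "parameter_error", "N must be >= 1")
  a <- 1 - abs(F_P - N * alpha) / N
  if (clamp) a <- pmax(0, a)
  a
}

#' Leave-one-game-out cross-validation
#'
#' For each fold, every training game i gets bounds from its own alpha-split
#' ([interval_bounds]) and its own detected fatigue point R_i
#' ([detect_fatigue_point]); games with no crossing are excluded from the
#' pool (and counted). The pooled F_P is scored on the held-out game via
#' [fold_accuracy]. A fold is skipped (recorded with `NA` accuracy) only
#' when no training game yields a detection; if that happens in every fold
#' the whole run errors.
#'
#' @param sessions list of >= 2 [pitch_session] objects.
#' @param params a [score_params].
#' @param pooling F_P pooling mode, see [pooled_fatigue_point].
#' @param clamp floor per-fold accuracies at zero.
#' @param sd SD convention passed to [interval_bounds].
#' @inheritParams fatigue_value_elbow
#' @return An object of class `cv_report`: `n`, per-fold table `folds`
#'   (`held_out`, `N`, `F_P`, `A_f`, `n_detected`), the per-game detections
#'   `R_by_game`, and `mean_accuracy` over the valid folds.
#' @export
cross_validate <- function(sessions, params = score_params(),
                           pooling = c("absolute", "normalized"),
                           clamp = FALSE, sd = "sample",
                           degenerate = c("error", "step")) {
  pooling <- match.arg(pooling)
  degenerate <- match.arg(degenerate)
  n <- length(sessions)
  pf_assert(n >= 2L, "parameter_error",
            "cross-validation needs at least 2 games")
  ids <- vapply(sessions, function(s) s$game_id, character(1))
  Ns <- vapply(sessions, function(s) s$N, numeric(1))
  # A game's own-bounds detection does not depend on the fold: compute once.
  Rs <- vapply(sessions, function(s) {
    b <- interval_bounds(s, params$alpha, sd = sd)
    as.numeric(detect_fatigue_point(s, b, params, degenerate)$R)
  }, numeric(1))
  folds <- data.frame(held_out = ids, N = Ns, F_P = NA_real_,
                      A_f = NA_real_, n_detected = NA_integer_,
                      stringsAsFactors = FALSE)
  fold_R <- vector("list", n)
  for (j in seq_len(n)) {
    train_R <- Rs[-j]
    train_N <- Ns[-j]
    keep <- !is.na(train_R)
    folds$n_detected[j] <- sum(keep)
    fold_R[[j]] <- train_R
    if (!any(keep)) next  # skipped fold: no training detection
    folds$F_P[j] <- pooled_fatigue_point(train_R[keep], pooling,
                                         N_list = train_N[keep],
                                         N_val = Ns[j])
    folds$A_f[j] <- fold_accuracy(folds$F_P[j], Ns[j], params$alpha, clamp)
  }
  if (all(is.na(folds$A_f)))
    pf_stop("no_detection", "no training game yielded a detection in any fold")
  structure(list(n = n, folds = folds, R_by_game = stats::setNames(Rs, ids),
                 fold_R = fold_R,
                 mean_accuracy = mean(folds$A_f, na.rm = TRUE),
                 params = params, pooling = pooling, clamp = clamp),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold leave-one-game-out, mean accuracy %.4f\n",
              x$n, x$mean_accuracy))
  print(x$folds, row.names = FALSE)
  invisible(x)
}

#' Grid search over (alpha, W, T)
#'
#' Runs [cross_validate] for every parameter tuple and returns the tuple
#' with the highest mean accuracy. Ties are broken deterministically:
#' larger alpha, then lower threshold, then lexicographically larger weight
#' vector.
#'
#' @param sessions list of [pitch_session] objects.
#' @param alphas numeric vector of alpha values.
#' @param weights list of weight triples (each summing to 1).
#' @param thresholds numeric vector of T values (percent scale).
#' @param ... passed on to [cross_validate] (pooling, clamp, sd,
#'   degenerate).
#' @return An object of class `grid_result`: `results` (one row per tuple
#'   with its mean accuracy) and `best` (a [score_params]).
#' @export
grid_search <- function(sessions, alphas = c(0.7, 0.8),
                        weights = list(c(0.7, 0.2, 0.1), rep(1, 3) / 3),
                        thresholds = c(50, 60), ...) {
  pf_assert(length(alphas) > 0 && length(weights) > 0 &&
              length(thresholds) > 0, "parameter_error",
            "grid must be non-empty")
  grid <- expand.grid(ai = seq_along(alphas), wi = seq_along(weights),
                      ti = seq_along(thresholds))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    w <- weights[[grid$wi[g]]]
    p <- score_params(alpha = alphas[grid$ai[g]], W = w,
                      T_threshold = thresholds[grid$ti[g]])
    cv <- cross_validate(sessions, p, ...)
    data.frame(alpha = p$alpha, W1 = w[1], W2 = w[2], W3 = w[3],
               T_threshold = p$T_threshold,
               mean_accuracy = cv$mean_accuracy)
  })
  results <- do.call(rbind, rows)
  ord <- order(-results$mean_accuracy, -results$alpha,
               results$T_threshold, -results$W1, -results$W2)
  results <- results[ord, ]
  rownames(results) <- NULL
  best_row <- results[1, ]
  best <- score_params(alpha = best_row$alpha,
                       W = c(best_row$W1, best_row$W2, best_row$W3),
                       T_threshold = best_row$T_threshold)
  structure(list(results = results, best = best), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d tuples; best: alpha = %g, W = (%g, %g, %g), T = %g (mean accuracy %.4f)\n",
              nrow(x$results), x$best$alpha, x$best$W[1], x$best$W[2],
              x$best$W[3], x$best$T_threshold, x$results$mean_accuracy[1]))
  invisible(x)
}

#' The default eight-case parameter grid
#'
#' Two alpha values, two weight triples (feature-weighted and uniform) and
#' two thresholds: the standard 2 x 2 x 2 sweep used for parameter tuning.
#'
#' @return list with `alphas`, `weights`, `thresholds`.
#' @export
default_grid <- function() {
  list(alphas = c(0.7, 0.8),
       weights = list(c(0.7, 0.2, 0.1), rep(1, 3) / 3),
       thresholds = c(50, 60))
}
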