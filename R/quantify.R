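#' @title Fatigue quantification
#' @name quantify
#' @description
#' A game of N pitches is split by the fatigue interval index alpha into a
#' non-fatigue interval (the first `floor(alpha * N)` pitches) and a fatigue
#' interval (the rest). Per feature m (1 elbow angle, 2 trunk angle,
#' 3 interval), the bounds are
#' `x_m = mean + SD` over the non-fatigue interval and `y_m = mean + SD`
#' over the fatigue interval. Each pitch's features are then mapped to
#' fatigue values `A_m` in \[0, 1\] by piecewise-linear ramps between the
#' bounds: the elbow ramp rises with c (fatigue raises the arm), the trunk
#' ramp rises as k falls (fatigue keeps the trunk high), the interval ramp
#' rises with t (fatigued pitchers slow down).
NULL

#' Split a game into non-fatigue / fatigue intervals
#'
#' @param N total pitch count (>= 2).
#' @param alpha fatigue interval index in (0, 1]: the fraction of pitches
#'   labelled non-fatigue.
#' @return Named integer vector `c(n_nonfatigue, n_fatigue)`; pitches
#'   `1..n_nonfatigue` are non-fatigue, the rest fatigue.
#' @examples
#' split_intervals(100, 0.6)  # 60 non-fatigue, 40 fatigue
#' @export
split_intervals <- function(N, alpha) {
  pf_assert(is.numeric(N) && length(N) == 1L && N >= 2 && N == round(N),
            "parameter_error", "N must be an integer >= 2")
  pf_assert(is.numeric(alpha) && length(alpha) == 1L &&
              alpha > 0 && alpha <= 1,
            "parameter_error", "alpha must lie in (0, 1]")
  # tiny epsilon guards against products like 0.7 * 7 = 4.899999...
  n_nf <- as.integer(floor(alpha * N + 1e-9))
  c(n_nonfatigue = n_nf, n_fatigue = as.integer(N) - n_nf)
}

sd_fun <- function(type) {
  switch(type,
         sample = stats::sd,
         population = function(x) sqrt(mean((x - mean(x))^2)))
}

#' Per-feature interval bounds
#'
#' Computes the non-fatigue / fatigue mean and SD of each feature over the
#' alpha-split of a session and derives the ramp knots x (non-fatigue side)
#' and y (fatigue side). Orientation validity per feature: elbow needs
#' `y > x`, trunk needs `x > y`, interval needs `y > x`; the flags are
#' reported and enforced at scoring time.
#'
#' @param session a [pitch_session].
#' @param alpha fatigue interval index in (0, 1).
#' @param sd `"sample"` (n-1 denominator, default: per-interval counts are
#'   small) or `"population"` for sensitivity checks.
#' @param symmetric_bounds if `TRUE`, the down-shifting trunk feature uses
#'   mean - SD on both sides (the mirror-symmetric choice); default `FALSE`
#'   keeps the literal mean + SD on all features.
#' @return A `feature_bounds` object: per feature `nf_mean`, `nf_sd`,
#'   `f_mean`, `f_sd`, `x`, `y`, `valid`.
#' @export
interval_bounds <- function(session, alpha, sd = c("sample", "population"),
                            symmetric_bounds = FALSE) {
  sd <- match.arg(sd)
  pf_assert(inherits(session, "pitch_session"), "type_error",
            "session must be a pitch_session")
  split <- split_intervals(session$N, alpha)
  pf_assert(split["n_fatigue"] >= 2L, "insufficient_data",
            "fatigue interval has %d pitches; need >= 2", split["n_fatigue"])
  sdf <- sd_fun(sd)
  feats <- list(elbow = session$features$elbow_angle_deg,
                trunk = session$features$trunk_angle_deg,
                interval = session$features$interval_s)
  nf_idx <- seq_len(split["n_nonfatigue"])
  per_feature <- lapply(names(feats), function(nm) {
    v <- feats[[nm]]
    nf <- v[nf_idx][!is.na(v[nf_idx])]
    fa <- v[-nf_idx][!is.na(v[-nf_idx])]
    if (length(nf) < 2L || length(fa) < 2L)
      pf_stop("insufficient_data",
              "feature '%s' has fewer than 2 present values in an interval",
              nm)
    sign <- if (symmetric_bounds && nm == "trunk") -1 else 1
    x <- mean(nf) + sign * sdf(nf)
    y <- mean(fa) + sign * sdf(fa)
    valid <- switch(nm, elbow = y > x, trunk = x > y, interval = y > x)
    list(nf_mean = mean(nf), nf_sd = sdf(nf),
         f_mean = mean(fa), f_sd = sdf(fa),
         x = x, y = y, valid = valid)
  })
  names(per_feature) <- names(feats)
  structure(c(per_feature,
              list(alpha = alpha, sd = sd,
                   symmetric_bounds = symmetric_bounds,
                   game_id = session$game_id)),
            class = "feature_bounds")
}

#' @export
print.feature_bounds <- function(x, ...) {
  cat(sprintf("<feature_bounds> game %s, alpha = %g (%s SD)\n",
              x$game_id, x$alpha, x$sd))
  for (nm in c("elbow", "trunk", "interval")) {
    f <- x[[nm]]
    cat(sprintf("  %-8s x = %8.3f  y = %8.3f  (%s)\n", nm, f$x, f$y,
                if (f$valid) "valid" else "DEGENERATE"))
  }
  invisible(x)
}

# Shared ramp core. `rising` ramps from 0 at `lo` to 1 at `hi` (lo < hi);
# boundary values take the ramp (middle) branch, so the map is continuous.
ramp_up <- function(v, lo, hi) {
  a <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  a[ok & v < lo] <- 0
  a[ok & v > hi] <- 1
  mid <- ok & v >= lo & v <= hi
  a[mid] <- (v[mid] - lo) / (hi - lo)
  a
}

check_bounds_feature <- function(bounds, feature, degenerate) {
  f <- bounds[[feature]]
  if (!f$valid) {
    if (degenerate == "error")
      pf_stop("degenerate_bounds",
              "feature '%s' bounds have zero/negative ramp width (x = %g, y = %g)",
              feature, f$x, f$y)
    return(FALSE)  # step fallback
  }
  TRUE
}

#' Per-feature fatigue values
#'
#' Piecewise-linear membership maps from a raw feature to a fatigue value in
#' \[0, 1\]. `fatigue_value_elbow` is non-decreasing in c (0 below `x_1`,
#' ramp, 1 above `y_1`); `fatigue_value_trunk` is non-increasing in k
#' (0 above `x_2`, 1 below `y_2`); `fatigue_value_interval` is
#' non-decreasing in t. All are continuous at both knots and unit-free
#' (invariant under a common affine rescale of value and bounds).
#'
#' @param c,k,t feature values (vectorised); degrees, degrees, seconds.
#' @param bounds a `feature_bounds` object from [interval_bounds].
#' @param degenerate what to do when a ramp has zero or negative width:
#'   `"error"` (default, a hard error during training) or `"step"`
#'   (values past `x_m` toward fatigue score 1, others 0).
#' @return Fatigue values in \[0, 1\]; `NA` where the input is `NA`.
#' @export
fatigue_value_elbow <- function(c, bounds, degenerate = c("error", "step")) {
  degenerate <- match.arg(degenerate)
  f <- bounds$elbow
  if (!check_bounds_feature(bounds, "elbow", degenerate))
    return(ifelse(is.na(c), NA_real_, as.numeric(c > f$x)))
  ramp_up(c, f$x, f$y)
}

#' @rdname fatigue_value_elbow
#' @export
fatigue_value_trunk <- function(k, bounds, degenerate = c("error", "step")) {
  degenerate <- match.arg(degenerate)
  f <- bounds$trunk
  if (!check_bounds_feature(bounds, "trunk", degenerate))
    return(ifelse(is.na(k), NA_real_, as.numeric(k < f$x)))
  # falling ramp: 0 at x (high trunk angle, fresh), 1 at y (low, fatigued)
  ramp_up(-k, -f$x, -f$y)
}

#' @rdname fatigue_value_elbow
#' @export
fatigue_value_interval <- function(t, bounds,
                                   degenerate = c("error", "step")) {
  degenerate <- match.arg(degenerate)
  f <- bounds$interval
  if (!check_bounds_feature(bounds, "interval", degenerate))
    return(ifelse(is.na(t), NA_real_, as.numeric(t > f$x)))
  ramp_up(t, f$x, f$y)
}

#' Score every pitch of a session
#'
#' @param session a [pitch_session].
#' @param bounds a `feature_bounds` object.
#' @inheritParams fatigue_value_elbow
#' @return data.frame with `pitch_index`, `A1`, `A2`, `A3` (`NA` where the
#'   underlying feature is missing).
#' @export
score_session <- function(session, bounds, degenerate = c("error", "step")) {
  degenerate <- match.arg(degenerate)
  fx <- session$features
  data.frame(pitch_index = fx$pitch_index,
             A1 = fatigue_value_elbow(fx$elbow_angle_deg, bounds, degenerate),
             A2 = fatigue_value_trunk(fx$trunk_angle_deg, bounds, degenerate),
             A3 = fatigue_value_interval(fx$interval_s, bounds, degenerate))
}

#' Persist / load feature bounds as JSON
#'
#' The bounds file is the flat-file stand-in for a player information
#' database: one JSON object per feature with the interval statistics and
#' derived knots.
#'
#' @param bounds a `feature_bounds` object.
#' @param path JSON file path.
#' @export
write_bounds <- function(bounds, path) {
  payload <- list(game_id = bounds$game_id, alpha = bounds$alpha,
                  sd = bounds$sd,
                  symmetric_bounds = bounds$symmetric_bounds,
                  features = bounds[c("elbow", "trunk", "interval")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bounds
#' @return `read_bounds`: the restored `feature_bounds` object.
#' @export
read_bounds <- function(path) {
  pf_assert(file.exists(path), "schema_error", "no such file: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(p$features, as.list)
  structure(c(feats,
              list(alpha = p$alpha, sd = p$sd,
                   symmetric_bounds = isTRUE(p$symmetric_bounds),
                   game_id = p$game_id)),
            class = "feature_bounds")
}
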