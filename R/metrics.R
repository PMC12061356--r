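#' Distance from the screen midline
#'
#' Horizontal distance of a touch from the center of the 800-px-wide
#' screen, `|400 - x|`, in pixels. Only the x coordinate enters: the screen
#' midline is a vertical line, so vertical position does not change how far
#' a touch is from it.
#'
#' @param x Touch x coordinate(s) in pixels, `0 <= x < 800`.
#' @return Distance(s) in pixels, always nonnegative.
#' @examples
#' distance_from_center_px(34)  # 366
#' @export
distance_from_center_px <- function(x) {
  if (any(x < 0 | x >= .SCREEN_W)) {
    stop("x out of the [0, ", .SCREEN_W, ") screen range")
  }
  abs(.SCREEN_W / 2 - x)
}

#' Convert pixel distances to millimeters
#'
#' Applies the touchscreen calibration of 0.29 mm per pixel.
#'
#' @param d Distance(s) in pixels, nonnegative.
#' @return Distance(s) in millimeters.
#' @examples
#' px_to_mm(366)  # 106.14
#' @export
px_to_mm <- function(d) {
  if (any(d < 0)) stop("pixel distances must be nonnegative")
  d * .MM_PER_PX
}

#' @rdname distance_from_center_px
#' @return `center_distance_mm` returns the same distance converted to mm.
#' @export
center_distance_mm <- function(x) px_to_mm(distance_from_center_px(x))

require_columns <- function(df, cols, what = "trial table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

split_by_session <- function(trials) {
  if (all(c("mouse_id", "session") %in% names(trials))) {
    split(trials, list(trials$mouse_id, trials$session), drop = TRUE)
  } else {
    list(trials)
  }
}

#' Euclidean distances between successive touches
#'
#' For each pair of consecutive trials within a session, the straight-line
#' (hypotenuse) distance between the two touch coordinates, converted to
#' millimeters. A pair is only included when both trials come from the same
#' choice aperture and the same explore/exploit state; pairs spanning a side
#' change, a state change, or both are flagged excluded with the reason.
#' Pairs never span session boundaries.
#'
#' @param trials Trial table with columns `x`, `y`, `side`, `state` and
#'   (when multi-session) `mouse_id`, `session`, `trial`; rows ordered by
#'   trial within each session. A `reward` column, when present, is carried
#'   onto each pair as `prev_reward` (the outcome of the pair's first
#'   trial), supporting the prior-reward analysis.
#' @return A data frame with one row per consecutive pair: `trial_from`,
#'   `trial_to`, `side`, `state`, `dist_mm`, `included`,
#'   `exclusion_reason` (`"none"`, `"side_transition"`,
#'   `"state_transition"`, `"both"`), plus grouping columns and
#'   `prev_reward` when available. Summarise with [exclusion_summary()].
#' @examples
#' tr <- make_fixture("side_switch_6")
#' pairs <- successive_euclidean(tr)
#' table(pairs$exclusion_reason)
#' @export
successive_euclidean <- function(trials) {
  require_columns(trials, c("x", "y", "side", "state"))
  if (any(is.na(trials$state))) stop("state labels missing for some trials")
  out <- lapply(split_by_session(trials), function(g) {
    n <- nrow(g)
    if ("trial" %in% names(g)) g <- g[order(g$trial), , drop = FALSE]
    if (n < 2) return(NULL)
    i <- seq_len(n - 1)
    dpx <- sqrt(diff(g$x)^2 + diff(g$y)^2)
    side_tr <- g$side[i] != g$side[i + 1]
    state_tr <- g$state[i] != g$state[i + 1]
    reason <- ifelse(side_tr & state_tr, "both",
                     ifelse(side_tr, "side_transition",
                            ifelse(state_tr, "state_transition", "none")))
    res <- data.frame(
      trial_from = if ("trial" %in% names(g)) g$trial[i] else i,
      trial_to = if ("trial" %in% names(g)) g$trial[i + 1] else i + 1,
      side = g$side[i + 1], state = g$state[i + 1],
      dist_mm = px_to_mm(dpx),
      included = reason == "none", exclusion_reason = reason)
    for (col in c("mouse_id", "session", "sex")) {
      if (col %in% names(g)) res[[col]] <- g[[col]][i + 1]
    }
    if ("reward" %in% names(g)) res$prev_reward <- g$reward[i]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exclusion accounting for successive-distance pairs
#'
#' Tallies the pairs dropped by the same-side / same-state inclusion rule.
#' The identity `excluded = side_only + state_only + both` and
#' `included + excluded = n_pairs` always holds.
#'
#' @param pairs Output of [successive_euclidean()].
#' @return A list with counts (`n_pairs`, `n_included`, `n_excluded`,
#'   `n_side_only`, `n_state_only`, `n_both`) and percentages
#'   (`pct_excluded` of all pairs; `pct_side`, `pct_state`, `pct_both` of
#'   excluded pairs, where side/state percentages each include pairs with
#'   both transitions).
#' @export
exclusion_summary <- function(pairs) {
  n <- nrow(pairs)
  r <- pairs$exclusion_reason
  n_side <- sum(r == "side_transition")
  n_state <- sum(r == "state_transition")
  n_both <- sum(r == "both")
  n_exc <- n_side + n_state + n_both
  list(
    n_pairs = n, n_included = n - n_exc, n_excluded = n_exc,
    n_side_only = n_side, n_state_only = n_state, n_both = n_both,
    pct_excluded = 100 * n_exc / n,
    pct_side = if (n_exc > 0) 100 * (n_side + n_both) / n_exc else NA_real_,
    pct_state = if (n_exc > 0) 100 * (n_state + n_both) / n_exc else NA_real_,
    pct_both = if (n_exc > 0) 100 * n_both / n_exc else NA_real_)
}

#' Mahalanobis distances from a point cloud's centroid
#'
#' Distance of each 2D point from the componentwise mean of its group,
#' scaled by the group's sample covariance:
#' `sqrt( (p - centroid)' C^{-1} (p - centroid) )`. Unlike the successive
#' Euclidean analysis no points are excluded.
#'
#' @param points An n x 2 matrix or data frame of `(x, y)` coordinates.
#' @return Numeric vector of nonnegative distances, or `NULL` (with a
#'   `"degenerate"` attribute message) when the covariance is singular or
#'   fewer than 3 points are available.
#' @examples
#' pts <- cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 2))
#' mahalanobis_from_centroid(pts)
#' @export
mahalanobis_from_centroid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) return(NULL)
  C <- cov(points)
  if (!is.finite(determinant(C)$modulus) || abs(det(C)) < 1e-12) {
    return(NULL)
  }
  sqrt(mahalanobis(points, colMeans(points), C))
}

#' Add per-trial Mahalanobis distances to a trial table
#'
#' Builds one centroid per aperture side — separately for the explore and
#' exploit touch populations when `split = "state"` — within each animal
#' (pooling sessions), and scores every touch against its group's centroid
#' and covariance.
#'
#' @param trials Trial table with `x`, `y`, `side` and, for the state
#'   split, `state`; `mouse_id` when multiple animals are present.
#' @param split `"state"` (default) or `"all"` (side-only centroids).
#' @return `trials` with a `mahal` column (`NA` for members of degenerate
#'   groups); skipped groups are recorded in attribute `"skipped_groups"`.
#' @export
add_mahalanobis <- function(trials, split = c("state", "all")) {
  split <- match.arg(split)
  require_columns(trials, c("x", "y", "side"))
  keys <- list(side = trials$side)
  if (split == "state") {
    require_columns(trials, "state")
    keys$state <- trials$state
  }
  if ("mouse_id" %in% names(trials)) keys$mouse_id <- trials$mouse_id
  grp <- interaction(keys, drop = TRUE)
  trials$mahal <- NA_real_
  skipped <- character(0)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    d <- mahalanobis_from_centroid(cbind(trials$x[idx], trials$y[idx]))
    if (is.null(d)) {
      skipped <- c(skipped, g)
    } else {
      trials$mahal[idx] <- d
    }
  }
  attr(trials, "skipped_groups") <- skipped
  trials
}

#' Condition trials on the previous trial's outcome
#'
#' Attaches `prev_reward` (the reward on the immediately preceding trial of
#' the same session) and drops each session's first trial, for which no
#' previous outcome exists.
#'
#' @param trials Trial table with `reward` and, when multi-session,
#'   `mouse_id`/`session`/`trial`.
#' @return The conditioned table with `prev_reward` coded
#'   `"rewarded"`/`"nonrewarded"`. Attribute `"empty_groups"` names any
#'   outcome level absent from the data (e.g. an all-rewarded session).
#' @export
condition_on_prev_reward <- function(trials) {
  require_columns(trials, "reward")
  out <- lapply(split_by_session(trials), function(g) {
    if ("trial" %in% names(g)) g <- g[order(g$trial), , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    g$prev_reward <- c(NA_integer_, g$reward[-nrow(g)])
    g[-1, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$prev_reward <- factor(ifelse(out$prev_reward == 1, "rewarded",
                                   "nonrewarded"),
                            levels = c("nonrewarded", "rewarded"))
  missing_lv <- setdiff(levels(out$prev_reward),
                        unique(as.character(out$prev_reward)))
  attr(out, "empty_groups") <- missing_lv
  out
}

#' Response-latency summary by animal and state
#'
#' @param trials Trial table with `rt` (seconds), `state` and `mouse_id`.
#' @return A data frame with per mouse x state `mean_rt`, `median_rt`, `n`.
#' @export
latency_summary <- function(trials) {
  require_columns(trials, c("rt", "state", "mouse_id"))
  if (any(trials$rt < 0)) stop("negative response times")
  agg <- aggregate(rt ~ mouse_id + state, data = trials,
                   FUN = function(v) c(mean = mean(v), median = median(v),
                                       n = length(v)))
  out <- data.frame(mouse_id = agg$mouse_id, state = agg$state,
                    mean_rt = agg$rt[, "mean"],
                    median_rt = agg$rt[, "median"],
                    n = agg$rt[, "n"])
  out[order(out$mouse_id, out$state), ]
}

#' Per-session metric aggregates for mixed modelling
#'
#' Collapses trial- and pair-level precision metrics to one row per mouse,
#' session and state (optionally also split by the previous trial's
#' outcome): mean successive Euclidean distance (`dist_mm`), mean
#' Mahalanobis distance (`mahal`), mean distance from the screen midline
#' (`center_mm`) and mean response time (`rt`).
#'
#' @param trials Labeled trial table (`state` present).
#' @param by_reward Also split by `prev_reward` (default `FALSE`).
#' @return A tidy data frame keyed by `mouse_id`, `sex`, `session`, `state`
#'   (and `prev_reward` when requested).
#' @export
session_state_metrics <- function(trials, by_reward = FALSE) {
  require_columns(trials, c("mouse_id", "sex", "session", "trial", "x", "y",
                            "side", "state", "reward", "rt"))
  trials <- add_mahalanobis(trials)
  trials$center_mm <- center_distance_mm(trials$x)
  pairs <- successive_euclidean(trials)
  pairs <- pairs[pairs$included, , drop = FALSE]
  keys <- c("mouse_id", "sex", "session", "state")
  if (by_reward) {
    trials <- condition_on_prev_reward(trials)
    trials$prev_reward <- as.character(trials$prev_reward)
    pairs$prev_reward <- ifelse(pairs$prev_reward == 1, "rewarded",
                                "nonrewarded")
    keys <- c(keys, "prev_reward")
  }
  agg <- function(df, value) {
    df$.value <- df[[value]]
    f <- as.formula(paste(".value ~", paste(keys, collapse = " + ")))
    out <- aggregate(f, data = df, FUN = mean, na.rm = TRUE)
    names(out)[names(out) == ".value"] <- value
    out
  }
  out <- agg(pairs, "dist_mm")
  for (v in c("mahal", "center_mm", "rt")) {
    out <- merge(out, agg(trials, v), by = keys, all = TRUE)
  }
  out$state <- factor(out$state, levels = c("explore", "exploit"))
  out$sex <- factor(out$sex, levels = c("F", "M"))
  if (by_reward) {
    out$prev_reward <- factor(out$prev_reward,
                              levels = c("nonrewarded", "rewarded"))
  }
  out
}
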