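#' Restless bandit walk parameters
#'
#' Parameters of the drifting reward-probability walk that defines the
#' two-arm restless bandit task: on every trial each arm independently has a
#' `step_prob` chance of its reward probability moving up or down by
#' `step_size` (direction equiprobable), bounded to `[p_min, p_max]`.
#'
#' @param n_trials Number of trials in a session (default 300).
#' @param step_prob Per-trial, per-arm probability of a step (default 0.10).
#' @param step_size Size of a probability step (default 0.10).
#' @param p_min,p_max Bounds on the reward probability (defaults 0.20, 0.90).
#' @param p_init_left,p_init_right Initial probabilities. When `NULL` they
#'   are drawn uniformly from the grid `seq(p_min, p_max, by = step_size)`
#'   at simulation time.
#' @param boundary How a step that would cross a bound is handled:
#'   `"reflect"` (default) folds the overshoot back inside so every drawn
#'   step realises a change of exactly `step_size`, preserving the task's
#'   stated per-trial change rate; `"clamp"` pins the value at the bound,
#'   which silently absorbs boundary steps.
#' @return An object of class `walk_params`.
#' @examples
#' walk_params()
#' @export
walk_params <- function(n_trials = 300, step_prob = 0.1, step_size = 0.1,
                        p_min = 0.2, p_max = 0.9,
                        p_init_left = NULL, p_init_right = NULL,
                        boundary = c("reflect", "clamp")) {
  boundary <- match.arg(boundary)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (step_prob < 0 || step_prob > 1) stop("step_prob must be in [0, 1]")
  if (!(p_min > 0 && p_min < p_max && p_max < 1)) {
    stop("need 0 < p_min < p_max < 1")
  }
  if (step_size <= 0) stop("step_size must be > 0")
  if (step_size > p_max - p_min) stop("step_size exceeds the bound range")
  for (p in c(p_init_left, p_init_right)) {
    if (!is.null(p) && (p < p_min || p > p_max)) {
      stop("initial probabilities must lie within [p_min, p_max]")
    }
  }
  structure(
    list(n_trials = as.integer(n_trials), step_prob = step_prob,
         step_size = step_size, p_min = p_min, p_max = p_max,
         p_init_left = p_init_left, p_init_right = p_init_right,
         boundary = boundary),
    class = "walk_params"
  )
}

#' @export
print.walk_params <- function(x, ...) {
  cat("Restless bandit walk parameters\n")
  cat(sprintf("  trials: %d, step: %.2f with prob %.2f, bounds [%.2f, %.2f] (%s)\n",
              x$n_trials, x$step_size, x$step_prob, x$p_min, x$p_max,
              x$boundary))
  init <- c(x$p_init_left, x$p_init_right)
  if (length(init)) {
    cat("  initial p:", paste(sprintf("%.2f", init), collapse = ", "), "\n")
  } else {
    cat("  initial p: drawn uniformly from the step grid\n")
  }
  invisible(x)
}

step_walk_value <- function(p, dir, params) {
  p2 <- p + dir * params$step_size
  if (params$boundary == "reflect") {
    if (p2 < params$p_min) p2 <- 2 * params$p_min - p2
    if (p2 > params$p_max) p2 <- 2 * params$p_max - p2
  }
  min(max(p2, params$p_min), params$p_max)
}

#' Simulate a reward-probability walk
#'
#' Generates one session's pair of independently drifting reward
#' probabilities. Per trial and per arm (left drawn first, then right) a
#' uniform variate decides whether the arm steps; when it does, a second
#' variate picks the direction. Initial values, when unspecified, are drawn
#' uniformly from the grid `seq(p_min, p_max, by = step_size)` (left first).
#'
#' @param params A [walk_params()] object.
#' @param seed Optional integer seed (`set.seed()` is called when supplied),
#'   making the walk fully reproducible.
#' @return A data frame of class `probability_walk` with columns `trial`,
#'   `p_left`, `p_right`; the generating parameters are attached as
#'   attribute `"params"`.
#' @examples
#' w <- simulate_walk(walk_params(), seed = 1)
#' range(c(w$p_left, w$p_right))
#' @export
simulate_walk <- function(params = walk_params(), seed = NULL) {
  stopifnot(inherits(params, "walk_params"))
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(params$p_min, params$p_max, by = params$step_size)
  pl <- if (is.null(params$p_init_left)) sample(grid, 1) else params$p_init_left
  pr <- if (is.null(params$p_init_right)) sample(grid, 1) else params$p_init_right
  n <- params$n_trials
  p_left <- numeric(n)
  p_right <- numeric(n)
  p_left[1] <- pl
  p_right[1] <- pr
  if (n > 1) {
    for (t in 2:n) {
      for (arm in c("left", "right")) {
        p <- if (arm == "left") p_left[t - 1] else p_right[t - 1]
        if (runif(1) < params$step_prob) {
          dir <- if (runif(1) < 0.5) -1 else 1
          p <- step_walk_value(p, dir, params)
        }
        if (arm == "left") p_left[t] <- p else p_right[t] <- p
      }
    }
  }
  out <- data.frame(trial = seq_len(n), p_left = p_left, p_right = p_right)
  attr(out, "params") <- params
  class(out) <- c("probability_walk", "data.frame")
  out
}

#' @export
plot.probability_walk <- function(x, ...) {
  graphics::matplot(x$trial, cbind(x$p_left, x$p_right), type = "l",
                    lty = 1, xlab = "trial", ylab = "P(reward)",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = c("left", "right"), lty = 1,
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Draw a reward outcome from a walk
#'
#' Bernoulli reward draw at the chosen arm's probability on trial `t`.
#'
#' @param walk A `probability_walk` data frame.
#' @param t Trial index (1-based).
#' @param side `"left"` or `"right"`.
#' @return Logical: was the response rewarded.
#' @examples
#' w <- simulate_walk(walk_params(), seed = 1)
#' set.seed(2); draw_reward(w, 10, "left")
#' @export
draw_reward <- function(walk, t, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(t) != 1 || t < 1 || t > nrow(walk)) {
    stop("trial index out of range")
  }
  p <- if (side == "left") walk$p_left[t] else walk$p_right[t]
  runif(1) < p
}

#' Write / read a probability walk as CSV
#'
#' @param walk A `probability_walk` data frame.
#' @param path File path.
#' @return `write_walk` returns `path` invisibly; `read_walk` returns a
#'   `probability_walk` data frame.
#' @export
write_walk <- function(walk, path) {
  write.csv(as.data.frame(walk)[, c("trial", "p_left", "p_right")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_walk <- function(path) {
  out <- read.csv(path)
  stopifnot(all(c("trial", "p_left", "p_right") %in% names(out)))
  class(out) <- c("probability_walk", "data.frame")
  out
}
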