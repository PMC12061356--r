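#' RLCK agent parameters
#'
#' The four-parameter reinforcement-learning choice-kernel (RLCK) agent:
#' a delta-rule learner over the two arms' values plus a choice kernel that
#' captures value-independent choice repetition. The choice-kernel learning
#' rate is tied to `alpha`, keeping exactly four free parameters.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Decision noise (inverse temperature), `>= 0`.
#' @param bias Side bias on the logit scale; positive favours left.
#' @param kappa Choice-stickiness weight on the kernel difference.
#' @return An object of class `rlck_params`.
#' @examples
#' rlck_params(alpha = 0.4, beta = 3)
#' @export
rlck_params <- function(alpha, beta, bias = 0, kappa = 0) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, bias = bias, kappa = kappa),
            class = "rlck_params")
}

#' @export
print.rlck_params <- function(x, ...) {
  cat(sprintf(
    "RLCK parameters: alpha = %.3f, beta = %.3f, bias = %.3f, kappa = %.3f\n",
    x$alpha, x$beta, x$bias, x$kappa))
  invisible(x)
}

#' Fresh RLCK agent state
#'
#' Value estimates start at 0.5 (indifference between Bernoulli arms);
#' choice-kernel traces start at 0.
#'
#' @return A list with `q_left`, `q_right`, `ck_left`, `ck_right`.
#' @export
agent_state <- function() {
  list(q_left = 0.5, q_right = 0.5, ck_left = 0, ck_right = 0)
}

#' Probability of a left choice under the RLCK policy
#'
#' `plogis(beta * (q_left - q_right) + bias + kappa * (ck_left - ck_right))`.
#'
#' @param params An [rlck_params()] object.
#' @param state An agent state as returned by [agent_state()] /
#'   [update_agent()].
#' @return Probability in `(0, 1)`.
#' @examples
#' choice_prob_left(rlck_params(0.5, 2), list(q_left = 1, q_right = 0,
#'                                            ck_left = 0, ck_right = 0))
#' @export
choice_prob_left <- function(params, state) {
  plogis(params$beta * (state$q_left - state$q_right) + params$bias +
           params$kappa * (state$ck_left - state$ck_right))
}

#' Update the RLCK agent after one trial
#'
#' Delta-rule value update of the chosen arm,
#' `q <- q + alpha * (reward - q)`, plus a choice-kernel update in which the
#' chosen trace moves toward 1 and the unchosen toward 0 at the same rate.
#'
#' @inheritParams choice_prob_left
#' @param choice `"left"` or `"right"` (or 1/0).
#' @param reward 0 or 1.
#' @return The updated agent state.
#' @examples
#' s <- update_agent(rlck_params(0.5, 2), agent_state(), "left", 1)
#' s$q_left  # 0.75
#' @export
update_agent <- function(params, state, choice, reward) {
  ci <- as_choice_int(choice)
  if (!reward %in% c(0, 1)) stop("reward must be 0 or 1")
  a <- params$alpha
  if (ci == 1L) {
    state$q_left <- state$q_left + a * (reward - state$q_left)
    state$ck_left <- state$ck_left + a * (1 - state$ck_left)
    state$ck_right <- state$ck_right + a * (0 - state$ck_right)
  } else {
    state$q_right <- state$q_right + a * (reward - state$q_right)
    state$ck_right <- state$ck_right + a * (1 - state$ck_right)
    state$ck_left <- state$ck_left + a * (0 - state$ck_left)
  }
  state
}

#' RLCK negative log-likelihood of a choice sequence
#'
#' Sum over trials of `-log P(observed choice)` under the RLCK policy, with
#' the agent updated after each observed choice/reward pair. Sequences are
#' evaluated from a fresh agent state.
#'
#' @inheritParams choice_prob_left
#' @param choices Choice sequence (`"left"`/`"right"` or 1/0).
#' @param rewards 0/1 reward sequence of the same length.
#' @return Nonnegative scalar.
#' @examples
#' rlck_negloglik(rlck_params(0.5, 0), "left", 1)  # -log(0.5)
#' @export
rlck_negloglik <- function(params, choices, rewards) {
  ci <- as_choice_int(choices)
  if (length(ci) != length(rewards)) stop("choices/rewards length mismatch")
  if (length(ci) == 0) stop("empty sequence")
  if (any(!rewards %in% c(0, 1))) stop("rewards must be 0/1")
  rlck_nll_cpp(c(params$alpha, params$beta, params$bias, params$kappa),
               ci, as.integer(rewards))
}

#' Simulate choices from an RLCK agent on a probability walk
#'
#' Runs a pure RLCK agent (no latent explore/exploit structure) against a
#' restless walk; used mainly for parameter-recovery studies.
#'
#' @inheritParams choice_prob_left
#' @param walk_par A [walk_params()] object describing the session walks.
#' @param n_sessions Number of sessions to simulate.
#' @param seed Optional integer seed.
#' @return A list of per-session data frames with columns `trial`, `choice`,
#'   `reward`, `p_left`, `p_right`.
#' @export
simulate_rlck <- function(params, walk_par = walk_params(), n_sessions = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # an always-explore chain reduces the session simulator to the bare agent
  free <- matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  grid <- seq(walk_par$p_min, walk_par$p_max, by = walk_par$step_size)
  lapply(seq_len(n_sessions), function(s) {
    pl <- if (is.null(walk_par$p_init_left)) sample(grid, 1) else walk_par$p_init_left
    pr <- if (is.null(walk_par$p_init_right)) sample(grid, 1) else walk_par$p_init_right
    sim <- simulate_session_cpp(
      walk_par$n_trials, pl, pr, walk_par$step_prob, walk_par$step_size,
      walk_par$p_min, walk_par$p_max, walk_par$boundary == "reflect",
      free, c(1, 0, 0), 0.5,
      c(params$alpha, params$beta, params$bias, params$kappa), TRUE)
    data.frame(trial = seq_len(walk_par$n_trials),
               choice = choice_label(sim$choice), reward = sim$reward,
               p_left = sim$p_left, p_right = sim$p_right)
  })
}

#' Fit the RLCK model by maximum likelihood
#'
#' Bounded multi-restart L-BFGS-B minimisation of the summed negative
#' log-likelihood over one animal's sessions (the agent state resets at
#' each session boundary).
#'
#' @param sessions Either a list of data frames with columns `choice`
#'   (`side`) and `reward`, or a single such data frame, or a list of
#'   `list(choices=, rewards=)` pairs.
#' @param n_restarts Number of uniform-random restarts (default 20).
#' @param bounds Named list with `lower`/`upper` numeric vectors over
#'   `(alpha, beta, bias, kappa)`.
#' @param seed Optional integer seed for the restart draws.
#' @return An object of class `rlck_fit` with elements `par`
#'   (an [rlck_params()] object), `nll`, `converged`, `at_bound`,
#'   `n_trials`, `n_sessions`, and the per-restart table `restarts`.
#' @examples
#' \donttest{
#' sim <- simulate_rlck(rlck_params(0.4, 3), walk_params(n_trials = 200),
#'                      n_sessions = 2, seed = 1)
#' fit <- fit_rlck(sim, n_restarts = 5, seed = 1)
#' coef(fit)
#' }
#' @export
fit_rlck <- function(sessions, n_restarts = 20,
                     bounds = list(lower = c(0, 0, -5, -10),
                                   upper = c(1, 20, 5, 10)),
                     seed = NULL) {
  sessions <- normalise_sessions(sessions)
  n_trials <- sum(vapply(sessions, function(s) length(s$choices), 1L))
  if (n_trials < 2) stop("need at least 2 trials")
  if (!is.null(seed)) set.seed(seed)

  obj <- function(par) {
    sum(vapply(sessions,
               function(s) rlck_nll_cpp(par, s$choices, s$rewards), 0))
  }
  lo <- bounds$lower
  hi <- bounds$upper
  starts <- lapply(seq_len(n_restarts), function(i) {
    # beta starts in a moderate range; extreme temperatures make poor seeds
    c(runif(1, lo[1], hi[1]), runif(1, 0, min(hi[2], 10)),
      runif(1, max(lo[3], -2), min(hi[3], 2)),
      runif(1, max(lo[4], -3), min(hi[4], 3)))
  })
  fits <- lapply(starts, function(p0) {
    tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all restarts failed")
  best <- fits[[which.min(vapply(fits, function(f) f$value, 0))]]
  tol <- 1e-6
  at_bound <- abs(best$par - lo) < tol | abs(best$par - hi) < tol
  names(at_bound) <- c("alpha", "beta", "bias", "kappa")
  restarts <- data.frame(
    restart = seq_along(fits),
    nll = vapply(fits, function(f) f$value, 0),
    convergence = vapply(fits, function(f) f$convergence, 0L))
  structure(
    list(par = rlck_params(best$par[1], best$par[2], best$par[3], best$par[4]),
         nll = best$value, converged = best$convergence == 0,
         at_bound = at_bound, n_trials = n_trials,
         n_sessions = length(sessions), restarts = restarts),
    class = "rlck_fit")
}

normalise_sessions <- function(sessions) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  lapply(sessions, function(s) {
    if (is.data.frame(s)) {
      ch <- if ("choice" %in% names(s)) s$choice else s$side
      if (is.null(ch)) stop("session table needs a 'choice' or 'side' column")
      list(choices = as_choice_int(ch), rewards = as.integer(s$reward))
    } else {
      list(choices = as_choice_int(s$choices),
           rewards = as.integer(s$rewards))
    }
  })
}

#' @export
print.rlck_fit <- function(x, ...) {
  cat(sprintf("RLCK fit over %d session(s), %d trials\n",
              x$n_sessions, x$n_trials))
  print(x$par)
  cat(sprintf("  negative log-likelihood: %.3f (%sconverged)\n", x$nll,
              if (x$converged) "" else "NOT "))
  if (any(x$at_bound)) {
    cat("  parameters at a bound:",
        paste(names(x$at_bound)[x$at_bound], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.rlck_fit <- function(object, ...) {
  unlist(object$par[c("alpha", "beta", "bias", "kappa")])
}

#' @export
logLik.rlck_fit <- function(object, ...) {
  structure(-object$nll, df = 4L, nobs = object$n_trials, class = "logLik")
}

#' @export
summary.rlck_fit <- function(object, ...) {
  out <- c(coef(object), nll = object$nll,
           converged = as.numeric(object$converged))
  class(out) <- c("summary.rlck_fit", class(out))
  out
}

#' Serialize fitted RLCK parameters for a set of animals
#'
#' @param fits Named list of `rlck_fit` objects (names are animal ids).
#' @param path Optional CSV path; when given the table is also written.
#' @return A data frame with columns `mouse_id`, `alpha`, `beta`, `bias`,
#'   `kappa`, `nll`, `converged`.
#' @export
rlck_fit_table <- function(fits, path = NULL) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  out <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(mouse_id = id, alpha = f$par$alpha, beta = f$par$beta,
               bias = f$par$bias, kappa = f$par$kappa, nll = f$nll,
               converged = f$converged)
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
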