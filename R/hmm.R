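#' Constrained explore/exploit HMM parameters
#'
#' The three-state hidden Markov model used to label bandit trials:
#' explore, exploit-left and exploit-right. Direct transitions between the
#' two exploit states are structurally forbidden — an animal must pass
#' through exploration to switch the exploited side. Exploit states emit
#' their side deterministically; explore emits left with probability
#' `explore_emit_left`.
#'
#' @param stay_exploit Probability an exploit state persists (shared by both
#'   sides).
#' @param stay_explore Probability explore persists; exits split equally
#'   between the two exploit states.
#' @param explore_emit_left Emission probability of a left choice while
#'   exploring (default 0.5).
#' @param init Initial distribution over (explore, exploit-left,
#'   exploit-right).
#' @return An object of class `hmm_params`.
#' @examples
#' transition_matrix(hmm_params(0.9, 0.7))
#' @export
hmm_params <- function(stay_exploit = 0.8, stay_explore = 0.6,
                       explore_emit_left = 0.5,
                       init = c(1, 1, 1) / 3) {
  for (p in c(stay_exploit, stay_explore, explore_emit_left)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  }
  if (length(init) != 3 || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stop("init must be a length-3 probability vector")
  }
  structure(list(stay_exploit = stay_exploit, stay_explore = stay_explore,
                 explore_emit_left = explore_emit_left, init = init),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Constrained explore/exploit HMM\n")
  cat(sprintf("  stay(exploit) = %.3f, stay(explore) = %.3f, P(left | explore) = %.3f\n",
              x$stay_exploit, x$stay_explore, x$explore_emit_left))
  cat("  initial:", paste(sprintf("%.3f", x$init), collapse = " "), "\n")
  invisible(x)
}

#' @rdname hmm_params
#' @param params An `hmm_params` object.
#' @return `transition_matrix` returns the implied 3x3 matrix (rows/cols
#'   ordered explore, exploit-left, exploit-right) with exact zeros between
#'   the exploit states.
#' @export
transition_matrix <- function(params) {
  sr <- params$stay_explore
  st <- params$stay_exploit
  m <- matrix(c(sr, (1 - sr) / 2, (1 - sr) / 2,
                1 - st, st, 0,
                1 - st, 0, st),
              nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("explore", "exploit-left", "exploit-right"),
                      c("explore", "exploit-left", "exploit-right"))
  m
}

emission_left <- function(params) c(params$explore_emit_left, 1, 0)

#' Forward log-likelihood of a choice sequence
#'
#' Log marginal likelihood of a left/right choice sequence under the
#' constrained HMM, computed by the scaled forward recursion. Sequences
#' impossible under the parameters return `-Inf`.
#'
#' @param params An [hmm_params()] object.
#' @param choices Choice sequence (`"left"`/`"right"` or 1/0).
#' @return Scalar log-likelihood.
#' @examples
#' forward_loglik(hmm_params(0.9, 0.7), c("left", "left", "right"))
#' @export
forward_loglik <- function(params, choices) {
  ci <- as_choice_int(choices)
  if (length(ci) == 0) stop("empty choice sequence")
  hmm_forward_cpp(transition_matrix(params), emission_left(params),
                  params$init, ci)
}

normalise_choice_sequences <- function(choices) {
  if (!is.list(choices)) choices <- list(choices)
  seqs <- lapply(choices, as_choice_int)
  if (any(vapply(seqs, length, 1L) == 0)) stop("empty choice sequence")
  seqs
}

hmm_em_once <- function(seqs, par, tol, max_iter, fit_emission, fit_init) {
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    trans <- transition_matrix(par)
    el <- emission_left(par)
    xi <- matrix(0, 3, 3)
    g1 <- numeric(3)
    g_expl <- 0
    g_expl_left <- 0
    ll <- 0
    for (s in seqs) {
      e <- hmm_estep_cpp(trans, el, par$init, s)
      ll <- ll + e$loglik
      xi <- xi + e$xi
      g1 <- g1 + e$gamma[1, ]
      g_expl <- g_expl + sum(e$gamma[, 1])
      g_expl_left <- g_expl_left + sum(e$gamma[s == 1L, 1])
    }
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    # constrained M-step: structural zeros never receive mass
    den_t <- xi[2, 2] + xi[2, 1] + xi[3, 3] + xi[3, 1]
    if (den_t > 0) par$stay_exploit <- (xi[2, 2] + xi[3, 3]) / den_t
    den_r <- sum(xi[1, ])
    if (den_r > 0) par$stay_explore <- xi[1, 1] / den_r
    if (fit_init) {
      pi0 <- g1 / sum(g1)
      pi0 <- pmax(pi0, 1e-10)
      par$init <- pi0 / sum(pi0)
    }
    if (fit_emission && g_expl > 0) {
      par$explore_emit_left <-
        min(max(g_expl_left / g_expl, 1e-6), 1 - 1e-6)
    }
  }
  list(par = par, loglik = trace[length(trace)], trace = trace,
       iterations = length(trace), converged = converged)
}

#' Fit the constrained HMM by Baum-Welch EM
#'
#' Expectation-maximisation restricted to the free parameters (the two stay
#' probabilities, the initial distribution and — optionally — the explore
#' emission probability); the forbidden exploit-to-exploit transitions stay
#' exactly zero throughout. The log-likelihood is non-decreasing across
#' iterations. Multiple jittered restarts guard against local optima.
#'
#' @param choices One choice sequence or a list of sequences (e.g. one per
#'   session of the same animal).
#' @param init Starting [hmm_params()] (default stay probabilities 0.8 /
#'   0.6, uniform initial distribution).
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param fit_emission Also fit `explore_emit_left` (default `FALSE`).
#' @param fit_init Fit the initial distribution (default `TRUE`).
#' @param n_restarts Jittered restarts around `init` (default 5).
#' @param seed Optional integer seed for the jitters.
#' @return An object of class `bandit_hmm` with the fitted `params`,
#'   `loglik`, the per-iteration `trace`, `iterations`, `converged`,
#'   and `n_seq`.
#' @examples
#' \donttest{
#' seqs <- simulate_states(hmm_params(0.9, 0.7), n_trials = 300,
#'                         n_seq = 5, seed = 1)
#' fit <- fit_hmm(seqs$choices, seed = 1)
#' coef(fit)
#' }
#' @export
fit_hmm <- function(choices, init = hmm_params(0.8, 0.6), tol = 1e-6,
                    max_iter = 500, fit_emission = FALSE, fit_init = TRUE,
                    n_restarts = 5, seed = NULL) {
  seqs <- normalise_choice_sequences(choices)
  if (!is.null(seed)) set.seed(seed)
  jitter_par <- function(k) {
    if (k == 1) return(init)
    hmm_params(
      stay_exploit = min(max(init$stay_exploit + runif(1, -0.15, 0.15),
                             0.05), 0.95),
      stay_explore = min(max(init$stay_explore + runif(1, -0.15, 0.15),
                             0.05), 0.95),
      explore_emit_left = init$explore_emit_left,
      init = init$init)
  }
  runs <- lapply(seq_len(max(1, n_restarts)), function(k) {
    hmm_em_once(seqs, jitter_par(k), tol, max_iter, fit_emission, fit_init)
  })
  best <- runs[[which.max(vapply(runs, function(r) r$loglik, 0))]]
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best iterate")
  }
  structure(
    list(params = best$par, loglik = best$loglik, trace = best$trace,
         iterations = best$iterations, converged = best$converged,
         n_seq = length(seqs),
         n_trials = sum(vapply(seqs, length, 1L))),
    class = "bandit_hmm")
}

#' @export
print.bandit_hmm <- function(x, ...) {
  cat(sprintf("Constrained explore/exploit HMM fit (%d sequence(s), %d trials)\n",
              x$n_seq, x$n_trials))
  print(x$params)
  cat(sprintf("  log-likelihood %.3f after %d EM iterations (%sconverged)\n",
              x$loglik, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.bandit_hmm <- function(object, ...) {
  c(stay_exploit = object$params$stay_exploit,
    stay_explore = object$params$stay_explore,
    explore_emit_left = object$params$explore_emit_left)
}

#' @export
logLik.bandit_hmm <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = object$n_trials,
            class = "logLik")
}

#' Decode explore/exploit states for a choice sequence
#'
#' Hard labels come from the Viterbi path under the constrained transition
#' matrix, which guarantees the label sequence never steps directly between
#' the two exploit states; `p_explore` is the forward-backward posterior
#' probability of the explore state at each trial.
#'
#' @param params An [hmm_params()] object or a fitted [fit_hmm()] object.
#' @param choices Choice sequence (`"left"`/`"right"` or 1/0).
#' @return A data frame with columns `trial`, `state`
#'   (`"explore"`/`"exploit"`), `state_side` (`"explore"`,
#'   `"exploit-left"`, `"exploit-right"`) and `p_explore`.
#' @examples
#' decode_states(hmm_params(0.9, 0.7), rep("left", 10))
#' @export
decode_states <- function(params, choices) {
  if (inherits(params, "bandit_hmm")) params <- params$params
  ci <- as_choice_int(choices)
  if (length(ci) == 0) stop("empty choice sequence")
  trans <- transition_matrix(params)
  el <- emission_left(params)
  path <- hmm_viterbi_cpp(trans, el, params$init, ci)
  post <- hmm_estep_cpp(trans, el, params$init, ci)$gamma
  labels <- c("explore", "exploit-left", "exploit-right")[path]
  data.frame(
    trial = seq_along(ci),
    state = ifelse(path == 1L, "explore", "exploit"),
    state_side = labels,
    p_explore = post[, 1])
}

#' @export
predict.bandit_hmm <- function(object, choices, ...) {
  decode_states(object$params, choices)
}

#' Simulate latent state chains and emitted choices
#'
#' Draws state sequences from the constrained transition matrix and emits
#' choices from the model's own emission law (exploit states emit their
#' side; explore emits left with `explore_emit_left`). This is the HMM's
#' generative process, used for parameter- and label-recovery studies.
#'
#' @param params An [hmm_params()] object.
#' @param n_trials Trials per sequence.
#' @param n_seq Number of sequences.
#' @param seed Optional integer seed.
#' @return A list with `choices` (list of integer sequences, 1 = left) and
#'   `states` (list of label vectors).
#' @export
simulate_states <- function(params, n_trials = 300, n_seq = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trans <- transition_matrix(params)
  labels <- c("explore", "exploit-left", "exploit-right")
  choices <- vector("list", n_seq)
  states <- vector("list", n_seq)
  for (k in seq_len(n_seq)) {
    # the session simulator draws the chain and the emissions; the walk and
    # agent arguments are inert under the uniform explore policy
    sim <- simulate_session_cpp(
      n_trials, 0.5, 0.5, 0, 0.1, 0.2, 0.9, TRUE, trans, params$init,
      params$explore_emit_left, c(0.5, 0, 0, 0), FALSE)
    choices[[k]] <- sim$choice
    states[[k]] <- labels[sim$state]
  }
  list(choices = choices, states = states)
}
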