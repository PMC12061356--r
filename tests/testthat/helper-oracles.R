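# Independent brute-force oracles, deliberately written without reference to
# the package's internal recursions.

# trial-by-trial RLCK negative log-likelihood in plain R
oracle_rlck_nll <- function(alpha, beta, bias, kappa, choices, rewards) {
  qL <- 0.5; qR <- 0.5; cL <- 0; cR <- 0
  nll <- 0
  for (t in seq_along(choices)) {
    pL <- 1 / (1 + exp(-(beta * (qL - qR) + bias + kappa * (cL - cR))))
    nll <- nll - log(if (choices[t] == 1) pL else 1 - pL)
    r <- rewards[t]
    if (choices[t] == 1) {
      qL <- qL + alpha * (r - qL)
      cL <- cL + alpha * (1 - cL)
      cR <- cR + alpha * (0 - cR)
    } else {
      qR <- qR + alpha * (r - qR)
      cR <- cR + alpha * (1 - cR)
      cL <- cL + alpha * (0 - cL)
    }
  }
  nll
}

oracle_path_prob <- function(params, path, choices) {
  trans <- transition_matrix(params)
  el <- c(params$explore_emit_left, 1, 0)
  emit <- function(s, ch) if (ch == 1) el[s] else 1 - el[s]
  p <- params$init[path[1]] * emit(path[1], choices[1])
  if (length(choices) > 1) {
    for (t in 2:length(choices)) {
      p <- p * trans[path[t - 1], path[t]] * emit(path[t], choices[t])
    }
  }
  p
}

# exhaustive sum over all 3^T state paths (forbidden transitions contribute 0)
oracle_hmm_loglik <- function(params, choices) {
  T <- length(choices)
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  log(sum(apply(paths, 1, function(s) oracle_path_prob(params, s, choices))))
}

# exhaustive best-path search; ties resolve to the lexicographically first
# path, matching deterministic low-index tie-breaking
oracle_viterbi <- function(params, choices) {
  T <- length(choices)
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  probs <- apply(paths, 1, function(s) oracle_path_prob(params, s, choices))
  ord <- do.call(order, c(list(-probs), as.data.frame(paths)))
  as.integer(paths[ord[1], ])
}

# direct quadratic-form Mahalanobis, no stats::mahalanobis
oracle_mahalanobis <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  Cinv <- solve(cov(points))
  apply(points, 1, function(p) {
    d <- p - ctr
    sqrt(drop(t(d) %*% Cinv %*% d))
  })
}

# small labeled session for metric tests
toy_session <- function(states, sides, x, y, rewards = NULL) {
  n <- length(states)
  data.frame(mouse_id = "F01", sex = "F", session = 1L, trial = seq_len(n),
             side = sides, x = x, y = y,
             reward = if (is.null(rewards)) rep(1L, n) else rewards,
             rt = rep(1, n), state = states)
}
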