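test_that("the choice rule reduces to chance and to the logistic form", {
  s <- agent_state()
  expect_equal(choice_prob_left(rlck_params(0.5, 0), s), 0.5)
  s$q_left <- 1; s$q_right <- 0
  expect_equal(choice_prob_left(rlck_params(0.5, 2), s), plogis(2))
  # mirror symmetry: swapping sides and negating the bias flips p -> 1 - p
  p1 <- choice_prob_left(rlck_params(0.3, 1.5, bias = 0.4, kappa = 0.8),
                         list(q_left = 0.7, q_right = 0.2, ck_left = 0.9,
                              ck_right = 0.1))
  p2 <- choice_prob_left(rlck_params(0.3, 1.5, bias = -0.4, kappa = 0.8),
                         list(q_left = 0.2, q_right = 0.7, ck_left = 0.1,
                              ck_right = 0.9))
  expect_equal(p1, 1 - p2)
})

test_that("the delta-rule update behaves at its limits and in between", {
  s0 <- agent_state()
  frozen <- update_agent(rlck_params(0, 2), s0, "left", 1)
  expect_equal(frozen$q_left, 0.5)
  full <- update_agent(rlck_params(1, 2), s0, "left", 0)
  expect_equal(full$q_left, 0)
  s0$q_left <- 0.4
  half <- update_agent(rlck_params(0.5, 2), s0, "left", 1)
  expect_equal(half$q_left, 0.7)
  expect_equal(half$q_right, 0.5)  # unchosen value untouched
  expect_error(update_agent(rlck_params(0.5, 2), s0, "up", 1), "choices")
})

test_that("the likelihood matches a brute-force trial-by-trial recomputation", {
  expect_equal(rlck_negloglik(rlck_params(0.5, 0), "left", 1), -log(0.5))
  set.seed(31)
  for (k in 1:5) {
    alpha <- runif(1); beta <- runif(1, 0, 5)
    bias <- runif(1, -1, 1); kappa <- runif(1, -2, 2)
    ch <- rbinom(20, 1, 0.5)
    rw <- rbinom(20, 1, 0.6)
    expect_equal(rlck_negloglik(rlck_params(alpha, beta, bias, kappa), ch, rw),
                 oracle_rlck_nll(alpha, beta, bias, kappa, ch, rw),
                 tolerance = 1e-12)
    # appending a trial never decreases the accumulated value
    expect_gte(rlck_negloglik(rlck_params(alpha, beta, bias, kappa), ch, rw),
               rlck_negloglik(rlck_params(alpha, beta, bias, kappa),
                              ch[1:10], rw[1:10]))
  }
  expect_error(rlck_negloglik(rlck_params(0.5, 1), c(1, 0), 1), "mismatch")
})

test_that("the likelihood is invariant under global left/right relabeling with a bias flip", {
  set.seed(9)
  ch <- rbinom(50, 1, 0.5)
  rw <- rbinom(50, 1, 0.5)
  nll1 <- rlck_negloglik(rlck_params(0.4, 2, bias = 0.6, kappa = 1), ch, rw)
  nll2 <- rlck_negloglik(rlck_params(0.4, 2, bias = -0.6, kappa = 1),
                         1L - ch, rw)
  expect_equal(nll1, nll2, tolerance = 1e-12)
})

test_that("fitting recovers generating parameters and never underperforms them", {
  gen <- rlck_params(0.4, 3, bias = 0, kappa = 1)
  sim <- simulate_rlck(gen, walk_params(), n_sessions = 8, seed = 21)
  fit <- fit_rlck(sim, n_restarts = 10, seed = 22)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)["alpha"] - 0.4), 0.1)
  gen_nll <- sum(vapply(sim, function(s)
    rlck_negloglik(gen, s$choice, s$reward), 0))
  expect_lte(fit$nll, gen_nll)
  expect_equal(AIC(logLik(fit)), 2 * 4 + 2 * fit$nll)
})

test_that("an agent that always chooses left drives the bias to its bound, flagged", {
  sessions <- list(data.frame(choice = rep("left", 100),
                              reward = rbinom(100, 1, 0.5)))
  fit <- fit_rlck(sessions, n_restarts = 5, seed = 1)
  expect_true(fit$at_bound[["bias"]] || fit$at_bound[["kappa"]] ||
                fit$at_bound[["beta"]])
})

test_that("learning-rate recovery error shrinks with longer sessions", {
  errs <- function(n_trials, seeds) {
    vapply(seeds, function(sd) {
      sim <- simulate_rlck(rlck_params(0.4, 3, 0, 1),
                           walk_params(n_trials = n_trials),
                           n_sessions = 1, seed = sd)
      abs(coef(fit_rlck(sim, n_restarts = 6, seed = sd + 100))["alpha"] - 0.4)
    }, 0)
  }
  short <- errs(300, 1:5)
  long <- errs(2400, 1:5)
  expect_lt(mean(long), mean(short))
})
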