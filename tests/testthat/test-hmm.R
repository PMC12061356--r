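test_that("the transition matrix carries the structural zeros and valid rows", {
  m <- transition_matrix(hmm_params(0.85, 0.6))
  expect_equal(rowSums(m), setNames(rep(1, 3), rownames(m)))
  expect_identical(m["exploit-left", "exploit-right"], 0)
  expect_identical(m["exploit-right", "exploit-left"], 0)
})

test_that("forward log-likelihood matches the single-step closed form", {
  par <- hmm_params(0.8, 0.6, explore_emit_left = 0.4,
                    init = c(0.5, 0.3, 0.2))
  # initial distribution times emission, summed over states
  expect_equal(forward_loglik(par, "left"),
               log(0.5 * 0.4 + 0.3 * 1 + 0.2 * 0))
  expect_equal(forward_loglik(par, "right"),
               log(0.5 * 0.6 + 0.2 * 1))
  expect_error(forward_loglik(par, character(0)), "empty")
})

test_that("forward log-likelihood equals exhaustive path enumeration up to length 8", {
  set.seed(14)
  for (k in 1:6) {
    p0 <- runif(3)
    par <- hmm_params(runif(1, 0.5, 0.95), runif(1, 0.3, 0.9),
                      explore_emit_left = runif(1, 0.2, 0.8),
                      init = p0 / sum(p0))
    T <- sample(1:8, 1)
    ch <- rbinom(T, 1, 0.5)
    expect_equal(forward_loglik(par, ch), oracle_hmm_loglik(par, ch),
                 tolerance = 1e-10)
  }
})

test_that("forward log-likelihood is mirror symmetric under symmetric parameters", {
  par <- hmm_params(0.9, 0.7, explore_emit_left = 0.5,
                    init = c(0.4, 0.3, 0.3))
  ch <- c(1, 1, 0, 1, 0, 0, 1)
  expect_equal(forward_loglik(par, ch), forward_loglik(par, 1L - ch),
               tolerance = 1e-12)
})

test_that("Viterbi decoding agrees with exhaustive best-path search up to length 8", {
  set.seed(77)
  for (k in 1:6) {
    par <- hmm_params(runif(1, 0.55, 0.95), runif(1, 0.35, 0.85),
                      init = c(0.4, 0.3, 0.3))
    T <- sample(2:8, 1)
    ch <- rbinom(T, 1, 0.5)
    dec <- decode_states(par, ch)
    want <- c("explore", "exploit-left", "exploit-right")[oracle_viterbi(par, ch)]
    expect_equal(dec$state_side, want)
  }
})

test_that("decoded labels respect the constraint, mirror correctly and have sane posteriors", {
  par <- hmm_params(0.9, 0.7)
  dec <- decode_states(par, rep("left", 20))
  expect_true(all(dec$state_side[2:19] == "exploit-left"))
  ch <- c(1, 1, 1, 0, 1, 0, 0, 0, 1, 1)
  d1 <- decode_states(par, ch)
  d2 <- decode_states(par, 1L - ch)
  swap <- c("explore" = "explore", "exploit-left" = "exploit-right",
            "exploit-right" = "exploit-left")
  expect_equal(d2$state_side, unname(swap[d1$state_side]))
  expect_equal(d2$p_explore, d1$p_explore, tolerance = 1e-12)
  # posteriors over the three states are normalised at every trial
  gamma <- touchbandit:::hmm_estep_cpp(transition_matrix(par), c(0.5, 1, 0),
                                       par$init, ch)$gamma
  expect_equal(rowSums(gamma), rep(1, length(ch)), tolerance = 1e-12)
  expect_equal(gamma[, 1], d1$p_explore, tolerance = 1e-12)
  # no decoded path ever steps between the two exploit states
  for (seed in 1:10) {
    sim <- simulate_states(par, 200, seed = seed)
    lab <- decode_states(par, sim$choices[[1]])$state_side
    pairs <- cbind(lab[-200], lab[-1])
    expect_false(any(pairs[, 1] == "exploit-left" &
                       pairs[, 2] == "exploit-right"))
    expect_false(any(pairs[, 1] == "exploit-right" &
                       pairs[, 2] == "exploit-left"))
  }
})

test_that("EM increases the likelihood monotonically and recovers stay probabilities", {
  gen <- hmm_params(0.9, 0.7)
  sim <- simulate_states(gen, n_trials = 300, n_seq = 50, seed = 101)
  fit <- fit_hmm(sim$choices, n_restarts = 2, seed = 102)
  expect_true(all(diff(fit$trace) >= -1e-6))
  expect_lt(abs(coef(fit)["stay_exploit"] - 0.9), 0.05)
  expect_lt(abs(coef(fit)["stay_explore"] - 0.7), 0.05)
  # decoding with the fitted model recovers most true labels
  acc <- mean(unlist(lapply(1:10, function(k) {
    decode_states(fit, sim$choices[[k]])$state_side == sim$states[[k]]
  })))
  expect_gt(acc, 0.85)
})

test_that("strictly alternating choices are explained by exploration, not exploitation", {
  ch <- rep(c(1L, 0L), 60)
  fit <- fit_hmm(list(ch), n_restarts = 3, seed = 5)
  expect_lt(fit$params$stay_exploit, fit$params$stay_explore)
  # coarse grid search agrees on the likelihood ranking
  ll_explorey <- forward_loglik(hmm_params(0.2, 0.9), ch)
  ll_exploity <- forward_loglik(hmm_params(0.9, 0.2), ch)
  expect_gt(ll_explorey, ll_exploity)
})
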