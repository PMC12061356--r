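make_metric_data <- function(n_mice = 8, n_sessions = 4, b_sex = 0,
                             b_state = 0, b_inter = 0, mouse_sd = 0.5,
                             noise_sd = 1, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(mouse = seq_len(2 * n_mice),
                      session = seq_len(n_sessions),
                      state = c("explore", "exploit"))
  grid$mouse_id <- sprintf("m%02d", grid$mouse)
  grid$sex <- factor(ifelse(grid$mouse <= n_mice, "F", "M"),
                     levels = c("F", "M"))
  grid$state <- factor(grid$state, levels = c("explore", "exploit"))
  u <- rnorm(2 * n_mice, 0, mouse_sd)
  grid$y <- 10 + b_sex * (grid$sex == "M") + b_state * (grid$state == "exploit") +
    b_inter * (grid$sex == "M") * (grid$state == "exploit") +
    u[grid$mouse] + rnorm(nrow(grid), 0, noise_sd)
  grid
}

test_that("an intercept-only mixed model estimates the grand mean and the AIC identity holds", {
  d <- make_metric_data(seed = 2)
  fit <- fit_mixed_model(y ~ 1 + (1 | mouse_id), d)
  expect_equal(unname(coef(fit)["(Intercept)"]), mean(d$y), tolerance = 1e-6)
  expect_equal(fit$AIC, 2 * fit$df - 2 * fit$logLik, tolerance = 1e-8)
  # fixed-effects-only formulas fall back to ordinary least squares
  fit_lm <- fit_mixed_model(y ~ 1, d)
  expect_equal(unname(coef(fit_lm)["(Intercept)"]), mean(d$y))
  expect_error(fit_mixed_model(y ~ missing_var + (1 | mouse_id), d),
               "missing")
})

test_that("singular random-slope fits fall back to a random intercept, flagged", {
  d <- make_metric_data(mouse_sd = 0, seed = 3)
  fit <- fit_mixed_model(y ~ sex * state + (state | mouse_id), d)
  expect_true(fit$singular_fallback)
  expect_false(any(grepl("state \\|", deparse(fit$formula))))
})

test_that("stepwise selection descends in AIC and stops at a dominant start", {
  # strong effects everywhere: the full model should win immediately
  d <- make_metric_data(b_sex = 3, b_state = 3, b_inter = 3, noise_sd = 0.5,
                        seed = 4)
  sel <- stepwise_select(y ~ sex * state + (1 | mouse_id), d)
  expect_equal(nrow(sel$trace), 1)
  expect_lte(sel$winner$AIC, sel$start_AIC)

  # pure-noise data: the descent must never increase AIC step to step
  d0 <- make_metric_data(seed = 5)
  sel0 <- stepwise_select(y ~ sex * state + (1 | mouse_id), d0)
  expect_true(all(diff(sel0$trace$AIC) < 0))
  expect_lte(sel0$winner$AIC, sel0$start_AIC)
})

test_that("with only a sex effect, noise terms are dropped before (and never instead of) sex", {
  sex_survives <- 0
  for (seed in 1:10) {
    d <- make_metric_data(b_sex = 1.5, seed = 10 + seed)
    sel <- stepwise_select(y ~ sex * state + (1 | mouse_id), d)
    dropped <- sub("^drop ", "", sel$trace$action[-1])
    # the significant main effect is never the term removed
    expect_false("sex" %in% dropped)
    # marginality: the interaction leaves before either of its main effects
    if (any(dropped %in% c("state", "sex"))) {
      expect_lt(match("sex:state", dropped),
                min(match(c("state", "sex"), dropped), na.rm = TRUE))
    }
    fixed <- attr(terms(lme4::nobars(sel$winner$formula)), "term.labels")
    if ("sex" %in% fixed) sex_survives <- sex_survives + 1
  }
  expect_gte(sex_survives, 9)
})

test_that("significant main effects are protected from dropping", {
  d <- make_metric_data(b_sex = 5, noise_sd = 0.5, seed = 30)
  sel <- stepwise_select(y ~ sex + state + (1 | mouse_id), d)
  fixed <- attr(terms(lme4::nobars(sel$winner$formula)), "term.labels")
  expect_true("sex" %in% fixed)
})

test_that("the winning-model family produces a complete, well-formed report", {
  co <- generate_cohort(cohort_config(n_per_sex = 4, n_sessions = 2), seed = 8)
  tr <- co$trials
  tr$state <- tr$true_state
  alpha_tab <- co$mice[, c("mouse_id", "alpha")]
  pm <- fit_model_family(tr, alpha_table = alpha_tab)
  expect_setequal(
    names(pm$fits),
    c("euclidean", "mahalanobis", "center_distance", "euclidean_reward",
      "mahalanobis_reward", "centroid_shift", "bout_area", "bout_perimeter",
      "latency", "alpha_distance", "n_explore_bouts", "n_exploit_bouts"))
  # one row per fitted coefficient per model
  for (nm in names(pm$fits)) {
    expect_equal(sum(pm$report$model == nm),
                 nrow(pm$fits[[nm]]$coefficients))
  }
  eu <- pm$report[pm$report$model == "euclidean", "term"]
  expect_true(all(c("(Intercept)", "sexM", "stateexploit",
                    "sexM:stateexploit") %in% eu))
  # omitting the learning-rate table omits only that model
  pm2 <- fit_model_family(tr)
  expect_false("alpha_distance" %in% names(pm2$fits))
  expect_error(fit_model_family(tr, alpha_table = data.frame(mouse_id = "x")),
               "alpha")
})
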