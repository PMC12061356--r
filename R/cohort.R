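#' Touch-generation parameters for synthetic cohorts
#'
#' The generative touch model of the synthetic cohort: truncated bivariate
#' Gaussians centered on the chosen aperture. Dispersion is tighter during
#' exploitation than exploration; explore touches are mean-shifted toward
#' the screen midline; male dispersion is scaled up relative to female; the
#' trial after a reward has its dispersion shrunk. Response times are
#' log-normal with a state-dependent location (exploit faster) and a male
#' shift. These defaults are the effect structure the analysis is built to
#' detect, at magnitudes typical of touchscreen nosepoke data.
#'
#' @param sd_exploit_mm,sd_explore_mm Per-axis touch SD (mm) by state;
#'   exploit must be tighter (defaults 5 and 9).
#' @param center_shift_mm Midline-ward mean shift of explore touches (mm,
#'   default 10).
#' @param sex_mult_male Multiplier on touch SD for males (default 1.2).
#' @param reward_mult Multiplier on touch SD after a rewarded trial
#'   (default 0.85).
#' @param mouse_sd_log SD of the per-animal log-normal dispersion
#'   multiplier capturing individual differences (default 0.1).
#' @param rt_meanlog_explore,rt_meanlog_exploit Log-normal location of the
#'   response time (s) by state (defaults `log(1.5)` and `log(1.5) - 0.25`).
#' @param rt_sex_shift_male Additive male shift on the RT meanlog
#'   (default 0.2).
#' @param rt_sdlog Log-normal scale of the RT (default 0.4).
#' @return An object of class `touch_gen_params`.
#' @export
touch_gen_params <- function(sd_exploit_mm = 5, sd_explore_mm = 9,
                             center_shift_mm = 10, sex_mult_male = 1.2,
                             reward_mult = 0.85, mouse_sd_log = 0.1,
                             rt_meanlog_explore = log(1.5),
                             rt_meanlog_exploit = log(1.5) - 0.25,
                             rt_sex_shift_male = 0.2, rt_sdlog = 0.4) {
  if (sd_exploit_mm < 0 || sd_explore_mm < 0) stop("dispersions must be >= 0")
  if (sex_mult_male <= 0 || reward_mult <= 0) stop("multipliers must be > 0")
  structure(list(sd_exploit_mm = sd_exploit_mm, sd_explore_mm = sd_explore_mm,
                 center_shift_mm = center_shift_mm,
                 sex_mult_male = sex_mult_male, reward_mult = reward_mult,
                 mouse_sd_log = mouse_sd_log,
                 rt_meanlog_explore = rt_meanlog_explore,
                 rt_meanlog_exploit = rt_meanlog_exploit,
                 rt_sex_shift_male = rt_sex_shift_male,
                 rt_sdlog = rt_sdlog),
            class = "touch_gen_params")
}

#' Synthetic cohort configuration
#'
#' Study-design parameters of a synthetic cohort: 16 animals per sex, each
#' running 8 sessions of 300 restless-bandit trials, with per-animal RLCK
#' parameters drawn from population distributions and latent
#' explore/exploit chains from a generating constrained HMM.
#'
#' @param n_per_sex Animals per sex (default 16).
#' @param n_sessions Sessions per animal (default 8).
#' @param n_trials Trials per session (default 300).
#' @param walk A [walk_params()] object (per-session walks).
#' @param hmm Generating [hmm_params()] (default stay probabilities
#'   0.9 / 0.7).
#' @param touch A [touch_gen_params()] object.
#' @param agent_draw Function `(sex)` returning one animal's
#'   [rlck_params()]; the default draws `alpha ~ Beta` with mean 0.4,
#'   `beta ~ logNormal(log 3, 0.2)`, `bias ~ N(0, 0.3)`,
#'   `kappa ~ N(1, 0.3)` for both sexes.
#' @param explore_policy How explore-trial choices are emitted:
#'   `"uniform"` (default) treats exploration as re-surveying both options
#'   at random, matching the labeler's emission assumption; `"rlck"` draws
#'   explore choices from the agent's softmax policy, which is stickier and
#'   deliberately harder to decode (useful for robustness studies).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_sex = 16, n_sessions = 8, n_trials = 300,
                          walk = walk_params(n_trials = n_trials),
                          hmm = hmm_params(stay_exploit = 0.9,
                                           stay_explore = 0.7),
                          touch = touch_gen_params(),
                          agent_draw = NULL,
                          explore_policy = c("uniform", "rlck")) {
  explore_policy <- match.arg(explore_policy)
  if (min(n_per_sex, n_sessions, n_trials) < 1) stop("counts must be >= 1")
  if (walk$n_trials != n_trials) {
    stop("walk$n_trials must equal the cohort n_trials")
  }
  if (is.null(agent_draw)) {
    agent_draw <- function(sex) {
      rlck_params(alpha = rbeta(1, 4, 6), beta = rlnorm(1, log(3), 0.2),
                  bias = rnorm(1, 0, 0.3), kappa = rnorm(1, 1, 0.3))
    }
  }
  structure(list(n_per_sex = n_per_sex, n_sessions = n_sessions,
                 n_trials = n_trials, walk = walk, hmm = hmm, touch = touch,
                 agent_draw = agent_draw, explore_policy = explore_policy),
            class = "cohort_config")
}

aperture_center <- function(side) {
  x0 <- .APERTURE_X0[side]
  cbind(x = unname(x0) + .APERTURE_PX / 2,
        y = .APERTURE_Y0 + .APERTURE_PX / 2)
}

generate_touches <- function(side, state, prev_reward, sex, mouse_mult,
                             tp) {
  n <- length(side)
  ctr <- aperture_center(side)
  sd_mm <- ifelse(state == "explore", tp$sd_explore_mm, tp$sd_exploit_mm)
  sd_mm <- sd_mm * mouse_mult
  if (sex == "M") sd_mm <- sd_mm * tp$sex_mult_male
  sd_mm <- sd_mm * ifelse(!is.na(prev_reward) & prev_reward == 1,
                          tp$reward_mult, 1)
  sd_px <- sd_mm / .MM_PER_PX
  shift_px <- tp$center_shift_mm / .MM_PER_PX
  # explore touches drift toward the screen midline
  mu_x <- ctr[, "x"] + ifelse(state == "explore",
                              ifelse(side == "left", shift_px, -shift_px), 0)
  x <- rnorm(n, mu_x, sd_px)
  y <- rnorm(n, ctr[, "y"], sd_px)
  # truncation: touches stay inside the 240 x 240 px aperture mask
  x0 <- .APERTURE_X0[side]
  x <- pmin(pmax(x, unname(x0)), unname(x0) + .APERTURE_PX - 1e-6)
  y <- pmin(pmax(y, .APERTURE_Y0), .APERTURE_Y0 + .APERTURE_PX - 1e-6)
  rt_meanlog <- ifelse(state == "explore", tp$rt_meanlog_explore,
                       tp$rt_meanlog_exploit) +
    if (sex == "M") tp$rt_sex_shift_male else 0
  rt <- rlnorm(n, rt_meanlog, tp$rt_sdlog)
  data.frame(x = x, y = y, rt = rt)
}

#' Generate a full synthetic cohort
#'
#' Simulates every animal and session of a cohort: a fresh probability
#' walk per session, a latent explore/exploit(-side) chain from the
#' generating HMM (direct exploit-to-exploit transitions never occur),
#' choices consistent with the chain, Bernoulli rewards from the walk,
#' RLCK value updates, and touch coordinates / response times drawn from
#' the touch model conditioned on state, sex and the previous trial's
#' outcome. Fully reproducible from the seed.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed.
#' @return A list with `trials` (the trial table: `mouse_id`, `sex`,
#'   `session`, `trial`, `side`, `x`, `y`, `reward`, `prev_reward`, `rt`,
#'   plus ground-truth `true_state`, `true_state_side`, `p_left`,
#'   `p_right`), `mice` (per-animal generating parameters) and the echoed
#'   `config`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_per_sex = 2, n_sessions = 1),
#'                           seed = 1)
#' head(cohort$trials)
#' }
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  wp <- config$walk
  trans <- transition_matrix(config$hmm)
  grid <- seq(wp$p_min, wp$p_max, by = wp$step_size)
  labels <- c("explore", "exploit-left", "exploit-right")
  mice <- list()
  rows <- list()
  k <- 0L
  for (sex in c("F", "M")) {
    for (m in seq_len(config$n_per_sex)) {
      k <- k + 1L
      id <- sprintf("%s%02d", sex, m)
      agent <- config$agent_draw(sex)
      mouse_mult <- rlnorm(1, 0, config$touch$mouse_sd_log)
      mice[[k]] <- data.frame(mouse_id = id, sex = sex,
                              alpha = agent$alpha, beta = agent$beta,
                              bias = agent$bias, kappa = agent$kappa,
                              dispersion_mult = mouse_mult)
      for (s in seq_len(config$n_sessions)) {
        pl <- if (is.null(wp$p_init_left)) sample(grid, 1) else wp$p_init_left
        pr <- if (is.null(wp$p_init_right)) sample(grid, 1) else wp$p_init_right
        sim <- simulate_session_cpp(
          config$n_trials, pl, pr, wp$step_prob, wp$step_size, wp$p_min,
          wp$p_max, wp$boundary == "reflect", trans, config$hmm$init,
          config$hmm$explore_emit_left,
          c(agent$alpha, agent$beta, agent$bias, agent$kappa),
          config$explore_policy == "rlck")
        side <- choice_label(sim$choice)
        state <- ifelse(sim$state == 1L, "explore", "exploit")
        prev_reward <- c(NA_integer_, sim$reward[-config$n_trials])
        touches <- generate_touches(side, state, prev_reward, sex,
                                    mouse_mult, config$touch)
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = id, sex = sex, session = s,
          trial = seq_len(config$n_trials), side = side,
          x = touches$x, y = touches$y, reward = sim$reward,
          prev_reward = prev_reward, rt = touches$rt,
          true_state = state, true_state_side = labels[sim$state],
          p_left = sim$p_left, p_right = sim$p_right)
      }
    }
  }
  list(trials = do.call(rbind, rows), mice = do.call(rbind, mice),
       config = config)
}

#' Deterministic micro-fixtures for tests and examples
#'
#' Small hand-built trial tables used across the package:
#' `"side_switch_6"` is a six-trial constant-state session with a single
#' side switch at trial 4; `"worked_example"` is a single touch at
#' `x = 34` (the midline-distance arithmetic example);
#' `"all_exploit"` is a ten-trial all-left exploit session;
#' `"alternating"` strictly alternates sides under an explore label.
#'
#' @param kind Fixture name.
#' @return A trial-table data frame; identical on every call.
#' @examples
#' make_fixture("side_switch_6")
#' @export
make_fixture <- function(kind = c("side_switch_6", "worked_example",
                                  "all_exploit", "alternating")) {
  kind <- match.arg(kind)
  base <- function(n, side, state, x, y) {
    data.frame(mouse_id = "F01", sex = "F", session = 1L, trial = seq_len(n),
               side = side, x = x, y = y,
               reward = rep(c(1L, 0L), length.out = n),
               rt = rep(1, n), state = state)
  }
  switch(kind,
    side_switch_6 = base(6,
                         side = c("left", "left", "left", "right", "right",
                                  "right"),
                         state = rep("exploit", 6),
                         x = c(100, 103, 100, 650, 653, 650),
                         y = c(300, 304, 300, 300, 304, 300)),
    worked_example = base(1, side = "left", state = "explore",
                          x = 34, y = 208),
    all_exploit = base(10, side = rep("left", 10),
                       state = rep("exploit", 10),
                       x = seq(120, 210, by = 10), y = rep(300, 10)),
    alternating = base(12, side = rep(c("left", "right"), 6),
                       state = rep("explore", 12),
                       x = rep(c(200, 600), 6), y = rep(300, 12)))
}
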