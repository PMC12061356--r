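#' Fit one linear mixed model by maximum likelihood
#'
#' Thin wrapper around [lme4::lmer()] (or [stats::lm()] when the formula
#' has no random terms) fitting by ML — not REML — so AIC values are
#' comparable across fixed-effect structures during model selection.
#' Coefficient p-values are Wald tests on the normal scale. A singular
#' random-effects fit triggers an automatic fallback in which every random
#' slope is reduced to a random intercept, flagged in the result.
#'
#' @param formula Model formula, e.g.
#'   `dist_mm ~ sex * state + (state | mouse_id)`.
#' @param data Tidy metric table containing every variable in the formula.
#' @return An object of class `tb_glmm`: the fitted `model`, `formula`,
#'   `logLik`, `df` (fixed coefficients plus variance parameters), `AIC`,
#'   `coefficients` (term, estimate, std_error, z, p), `converged`,
#'   `singular_fallback`.
#' @examples
#' \donttest{
#' d <- data.frame(y = rnorm(40), g = rep(letters[1:4], 10))
#' fit_mixed_model(y ~ 1 + (1 | g), d)
#' }
#' @export
fit_mixed_model <- function(formula, data) {
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("model variables missing from data: ", paste(miss, collapse = ", "))
  }
  bars <- lme4::findbars(formula)
  singular_fallback <- FALSE
  if (is.null(bars)) {
    fit <- lm(formula, data = data)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], z = sm[, 3], p = sm[, 4],
                        row.names = NULL)
    converged <- TRUE
  } else {
    if (length(unique(data[[deparse(bars[[1]][[3]])]])) < 2) {
      stop("need at least 2 grouping-factor levels")
    }
    fit <- suppressMessages(
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))
    if (lme4::isSingular(fit, tol = 1e-4)) {
      groups <- unique(vapply(bars, function(b) deparse(b[[3]]), ""))
      fx <- deparse_flat(lme4::nobars(formula))
      fb <- paste(sprintf("(1 | %s)", groups), collapse = " + ")
      formula <- as.formula(paste(fx, "+", fb))
      fit <- suppressMessages(
        lme4::lmer(formula, data = data, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))
      singular_fallback <- TRUE
    }
    sm <- summary(fit)$coefficients
    z <- sm[, "t value"]
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        std_error = sm[, "Std. Error"], z = z,
                        p = 2 * pnorm(-abs(z)), row.names = NULL)
    converged <- length(fit@optinfo$conv$lme4$messages) == 0
  }
  ll <- logLik(fit)
  structure(
    list(model = fit, formula = formula, logLik = as.numeric(ll),
         df = attr(ll, "df"), AIC = AIC(fit), coefficients = coefs,
         converged = converged, singular_fallback = singular_fallback),
    class = "tb_glmm")
}

deparse_flat <- function(x) paste(deparse(x), collapse = " ")

#' @export
print.tb_glmm <- function(x, ...) {
  cat("ML mixed-model fit:", deparse_flat(x$formula), "\n")
  cat(sprintf("  AIC %.2f (logLik %.2f, df %d)%s%s\n", x$AIC, x$logLik,
              x$df,
              if (x$converged) "" else " [convergence warning]",
              if (x$singular_fallback) " [singular; random-intercept fallback]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.tb_glmm <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.tb_glmm <- function(object, ...) logLik(object$model)

# internal: decompose a mixed formula into response, fixed term labels and
# random-term strings
formula_parts <- function(formula) {
  fx <- lme4::nobars(formula)
  tt <- terms(fx)
  bars <- lme4::findbars(formula)
  list(response = deparse(formula[[2]]),
       fixed = attr(tt, "term.labels"),
       random = vapply(bars, function(b) paste0("(", deparse_flat(b), ")"),
                       ""))
}

build_formula <- function(response, fixed, random) {
  rhs <- c(if (length(fixed)) fixed else "1", random)
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

# p-value of a fixed term in a fitted tb_glmm: the smallest Wald p over the
# coefficients the term generates (two-level factors give exactly one)
term_p_value <- function(fit, term) {
  X <- if (inherits(fit$model, "merMod")) {
    lme4::getME(fit$model, "X")
  } else {
    stats::model.matrix(fit$model)
  }
  asg <- attr(X, "assign")
  tt <- terms(lme4::nobars(fit$formula))
  labs <- attr(tt, "term.labels")
  idx <- which(asg == match(term, labs))
  if (!length(idx)) return(NA_real_)
  min(fit$coefficients$p[idx])
}

#' Stepwise AIC model selection for mixed models
#'
#' Greedy backward descent over a starting mixed-model specification. At
#' each step every child obtained by removing one droppable term is fitted:
#' fixed interactions are dropped before the main effects they contain
#' (marginality is enforced), fixed main effects with a Wald p-value below
#' `protect_p` in the current parent are never dropped, and each random
#' slope can be reduced to a random intercept. The search moves to the
#' lowest-AIC child while that improves on the parent (ties break toward
#' fewer parameters) and stops otherwise. The grouping factor itself is
#' never removed.
#'
#' @inheritParams fit_mixed_model
#' @param protect_p Significance threshold protecting main effects from
#'   removal (default 0.05).
#' @return An object of class `aic_stepwise`: `winner` (a `tb_glmm`),
#'   `trace` (step, action, formula, AIC, df) and `start_AIC`.
#' @export
stepwise_select <- function(formula, data, protect_p = 0.05) {
  parts <- formula_parts(formula)
  current <- fit_mixed_model(formula, data)
  trace <- data.frame(step = 0L, action = "start",
                      formula = deparse_flat(formula), AIC = current$AIC,
                      df = current$df, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fixed <- parts$fixed
    inter <- fixed[grepl(":", fixed, fixed = TRUE)]
    inter_vars <- unique(unlist(strsplit(inter, ":", fixed = TRUE)))
    mains <- setdiff(fixed, inter)
    candidates <- list()
    for (tm in inter) {
      candidates[[length(candidates) + 1L]] <-
        list(action = paste("drop", tm),
             fixed = setdiff(fixed, tm), random = parts$random)
    }
    for (tm in mains) {
      if (tm %in% inter_vars) next  # marginality: interaction still present
      p <- term_p_value(current, tm)
      if (!is.na(p) && p < protect_p) next  # significant main effects stay
      candidates[[length(candidates) + 1L]] <-
        list(action = paste("drop", tm),
             fixed = setdiff(fixed, tm), random = parts$random)
    }
    for (i in seq_along(parts$random)) {
      rnd <- parts$random[i]
      if (grepl("^\\(1 \\|", rnd)) next
      grp <- sub("^\\(.*\\| *(.*)\\)$", "\\1", rnd)
      new_random <- parts$random
      new_random[i] <- sprintf("(1 | %s)", grp)
      new_random <- unique(new_random)
      candidates[[length(candidates) + 1L]] <-
        list(action = paste("simplify", rnd),
             fixed = fixed, random = new_random)
    }
    if (!length(candidates)) break
    fits <- lapply(candidates, function(cand) {
      f <- build_formula(parts$response, cand$fixed, cand$random)
      tryCatch(fit_mixed_model(f, data), error = function(e) NULL)
    })
    keep <- !vapply(fits, is.null, TRUE)
    fits <- fits[keep]
    candidates <- candidates[keep]
    if (!length(fits)) break
    aics <- vapply(fits, `[[`, 0, "AIC")
    dfs <- vapply(fits, `[[`, 0, "df")
    ord <- order(aics, dfs)  # ties -> fewer parameters
    best <- ord[1]
    if (aics[best] >= current$AIC) break
    step <- step + 1L
    current <- fits[[best]]
    parts <- list(response = parts$response,
                  fixed = candidates[[best]]$fixed,
                  random = candidates[[best]]$random)
    trace <- rbind(trace, data.frame(
      step = step, action = candidates[[best]]$action,
      formula = deparse_flat(current$formula), AIC = current$AIC,
      df = current$df, stringsAsFactors = FALSE))
  }
  structure(list(winner = current, trace = trace,
                 start_AIC = trace$AIC[1]),
            class = "aic_stepwise")
}

#' @export
print.aic_stepwise <- function(x, ...) {
  cat("Stepwise AIC selection:", nrow(x$trace) - 1, "drop step(s)\n")
  print(x$trace[, c("step", "action", "AIC", "df")], row.names = FALSE)
  cat("\nWinning model:\n")
  print(x$winner)
  invisible(x)
}

code_metric_factors <- function(df) {
  # treatment coding: reference female, explore, nonrewarded
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("F", "M"))
  if ("state" %in% names(df)) {
    df$state <- factor(df$state, levels = c("explore", "exploit"))
  }
  if ("prev_reward" %in% names(df) && !is.factor(df$prev_reward)) {
    df$prev_reward <- factor(df$prev_reward,
                             levels = c("nonrewarded", "rewarded"))
  }
  df
}

winning_model_formulas <- function() {
  list(
    euclidean = dist_mm ~ sex * state + (state | mouse_id),
    mahalanobis = mahal ~ state + (state | mouse_id),
    center_distance = center_mm ~ sex * state + (state | mouse_id),
    euclidean_reward =
      dist_mm ~ prev_reward + sex * state + (prev_reward | mouse_id) +
        (state | mouse_id),
    mahalanobis_reward =
      mahal ~ prev_reward + state + (state | mouse_id) +
        (prev_reward | mouse_id),
    centroid_shift = shift_mm ~ state * sex + (1 | mouse_id),
    bout_area = area_mm2 ~ state * sex + (1 | mouse_id),
    bout_perimeter = perimeter_mm ~ state * sex + (1 | mouse_id),
    latency = rt ~ state + sex + (state | mouse_id),
    alpha_distance = dist_mm ~ alpha + sex + (1 | mouse_id),
    n_explore_bouts = n_explore ~ sex + (1 | mouse_id),
    n_exploit_bouts = n_exploit ~ sex + (1 | mouse_id))
}

#' Fit the full winning-model family over a labeled cohort
#'
#' Builds the metric tables (per-session state aggregates, reward-split
#' aggregates, bout geometry, centroid shifts, bout counts and — when RLCK
#' fits are supplied — a learning-rate table) and fits the winning mixed
#' model of each analysis: successive Euclidean distance, Mahalanobis
#' distance, midline distance, their previous-reward variants, centroid
#' shift, bout area and perimeter, response latency, the learning-rate
#' model of touch distance, and the two bout-count models. Responses are
#' mouse-by-session(-by-state) means; coding is treatment contrasts with
#' reference levels female / explore / nonrewarded.
#'
#' @param trials Labeled trial table (columns `mouse_id`, `sex`, `session`,
#'   `trial`, `side`, `x`, `y`, `reward`, `rt`, `state`).
#' @param alpha_table Optional data frame `mouse_id`, `alpha` (e.g. from
#'   [rlck_fit_table()]); when `NULL` the learning-rate model is omitted.
#' @param min_points Minimum touches per bout for contour geometry.
#' @return A list of class `model_family` with `fits` (named `tb_glmm`
#'   list), `report` (tidy data frame: model, term, estimate, std_error,
#'   z, p) and `coding`.
#' @export
fit_model_family <- function(trials, alpha_table = NULL, min_points = 5) {
  require_columns(trials, c("mouse_id", "sex", "session", "trial", "side",
                            "x", "y", "reward", "rt", "state"))
  metrics <- code_metric_factors(session_state_metrics(trials))
  metrics_rw <- code_metric_factors(
    session_state_metrics(trials, by_reward = TRUE))

  bouts <- bout_table(trials, min_points = min_points)
  sex_map <- unique(trials[, c("mouse_id", "sex")])
  agg_bouts <- function(value) {
    ok <- !bouts$degenerate & is.finite(bouts[[value]])
    d <- bouts[ok, ]
    d$.value <- d[[value]]
    out <- aggregate(.value ~ mouse_id + session + state, data = d,
                     FUN = mean)
    names(out)[names(out) == ".value"] <- value
    code_metric_factors(merge(out, sex_map, by = "mouse_id"))
  }
  shifts <- centroid_shift_distances(segment_bouts(trials))
  shift_tab <- aggregate(shift_mm ~ mouse_id + session + state,
                         data = shifts, FUN = mean)
  shift_tab <- code_metric_factors(merge(shift_tab, sex_map, by = "mouse_id"))
  counts <- code_metric_factors(bout_counts(trials))

  tables <- list(
    euclidean = metrics, mahalanobis = metrics, center_distance = metrics,
    euclidean_reward = metrics_rw, mahalanobis_reward = metrics_rw,
    centroid_shift = shift_tab,
    bout_area = agg_bouts("area_mm2"),
    bout_perimeter = agg_bouts("perimeter_mm"),
    latency = metrics,
    n_explore_bouts = counts, n_exploit_bouts = counts)
  if (!is.null(alpha_table)) {
    require_columns(alpha_table, c("mouse_id", "alpha"), "alpha table")
    pairs <- successive_euclidean(trials)
    dist_tab <- aggregate(dist_mm ~ mouse_id + session,
                          data = pairs[pairs$included, ], FUN = mean)
    dist_tab <- merge(merge(dist_tab, sex_map, by = "mouse_id"),
                      alpha_table[, c("mouse_id", "alpha")], by = "mouse_id")
    tables$alpha_distance <- code_metric_factors(dist_tab)
  }

  formulas <- winning_model_formulas()
  formulas <- formulas[names(formulas) %in% names(tables)]
  fits <- lapply(names(formulas), function(nm) {
    fit_mixed_model(formulas[[nm]], tables[[nm]])
  })
  names(fits) <- names(formulas)
  report <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, fits[[nm]]$coefficients)
  }))
  rownames(report) <- NULL
  structure(list(fits = fits, report = report,
                 coding = c(sex = "reference F", state = "reference explore",
                            prev_reward = "reference nonrewarded")),
            class = "model_family")
}

#' @export
print.model_family <- function(x, ...) {
  cat("Winning-model family (", length(x$fits), " models)\n", sep = "")
  cat("Coding:", paste(names(x$coding), x$coding, sep = " = ",
                       collapse = "; "), "\n\n")
  print(x$report, digits = 4)
  invisible(x)
}
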