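TRIAL_COLUMNS <- c("mouse_id", "sex", "session", "trial", "side", "x", "y",
                   "reward", "rt")

validate_trials <- function(df, path = "<data>") {
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  problems <- character(0)
  bad <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(utils::head(which(rows), 5),
                                            collapse = ", "),
                                      if (sum(rows) > 5) ", ..." else "",
                                      ")"))
    }
  }
  bad(!df$sex %in% c("F", "M"), "sex must be F or M")
  bad(!df$side %in% c("left", "right"), "side must be left or right")
  bad(df$x < 0 | df$x >= .SCREEN_W,
      sprintf("x outside [0, %d)", .SCREEN_W))
  bad(df$y < 0 | df$y >= .SCREEN_H,
      sprintf("y outside [0, %d)", .SCREEN_H))
  bad(!df$reward %in% c(0, 1), "reward must be 0/1")
  bad(df$rt < 0, "rt must be >= 0")
  inc <- unlist(lapply(split(df$trial,
                             interaction(df$mouse_id, df$session,
                                         drop = TRUE)),
                       function(tr) c(FALSE, diff(tr) <= 0)))
  if (any(inc)) {
    problems <- c(problems,
                  "trial indices must strictly increase within a session")
  }
  if ("state" %in% names(df)) {
    bad(!is.na(df$state) & !df$state %in% c("explore", "exploit"),
        "state must be explore/exploit")
  }
  if (length(problems)) {
    stop(path, ": invalid trial table:\n  ",
         paste(problems, collapse = "\n  "))
  }
  df
}

#' Read a trial table
#'
#' Reads and validates a trial-level CSV. The `"standard"` dialect uses
#' screen-global pixel coordinates; the `"abet-export"` dialect carries
#' aperture-local coordinates (`x_local`, `y_local` in `[0, 240)` relative
#' to the touched aperture, as the acquisition software logs them) which
#' are converted to global coordinates by adding the aperture offsets
#' (left aperture at x = 40, right at x = 520, both at y = 180).
#'
#' @param path CSV file path.
#' @param dialect `"standard"` (default) or `"abet-export"`.
#' @return A validated trial-table data frame with global `x`, `y`.
#' @export
read_trials <- function(path, dialect = c("standard", "abet-export")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  # sex is pinned to character: a column of only "F" would otherwise be
  # read as logical FALSE
  df <- read.csv(path, comment.char = "#",
                 colClasses = c(sex = "character"))
  if (dialect == "abet-export") {
    need <- c("x_local", "y_local", "side")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(path, ": abet-export needs column(s): ",
           paste(miss, collapse = ", "))
    }
    rng <- df$x_local < 0 | df$x_local >= .APERTURE_PX |
      df$y_local < 0 | df$y_local >= .APERTURE_PX
    if (any(rng)) {
      stop(path, ": aperture-local coordinates outside [0, ", .APERTURE_PX,
           ") at rows ", paste(utils::head(which(rng), 5), collapse = ", "))
    }
    df$x <- df$x_local + unname(.APERTURE_X0[df$side])
    df$y <- df$y_local + .APERTURE_Y0
    df$x_local <- NULL
    df$y_local <- NULL
  }
  validate_trials(df, path)
}

#' @rdname read_trials
#' @param trials A trial table.
#' @return `write_trials` writes the standard dialect and returns `path`
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(as.data.frame(trials))
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Convert global coordinates to the aperture-local frame
#'
#' Inverse of the `"abet-export"` reader conversion; useful for round-trip
#' checks.
#'
#' @param trials Trial table with global `x`, `y` and `side`.
#' @return The table with `x_local`, `y_local` columns added.
#' @export
to_aperture_local <- function(trials) {
  trials$x_local <- trials$x - unname(.APERTURE_X0[trials$side])
  trials$y_local <- trials$y - .APERTURE_Y0
  trials
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a cohort, fit and decode the explore/exploit HMM
#' per animal, compute the spatial precision metrics and bout geometry, fit
#' the winning-model family, and write every stage's table plus a manifest
#' that records the seed and parameters for exact re-runs.
#'
#' @param config A [cohort_config()] for synthetic input, or a path to a
#'   standard-dialect trial CSV (which must then contain pre-computed
#'   `state` labels or be labeled here via `label_states = TRUE`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing every stochastic stage.
#' @param label_states Fit/decode the HMM (default `TRUE`). With `FALSE`
#'   the input must already carry `state` labels.
#' @param fit_alpha Also fit the RLCK model per animal and include the
#'   learning-rate model (default `FALSE`; the fit is the slow stage).
#' @param hmm_restarts,hmm_tol EM restart count and convergence tolerance
#'   passed to [label_trials()].
#' @return Invisibly, a list with the `trials`, `metrics`, `bouts`,
#'   `report` tables and the `manifest`. Files written: `trials.csv`,
#'   `labeled.csv`, `metrics.csv`, `bouts.csv`, `model_report.csv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = 1,
                         label_states = TRUE, fit_alpha = FALSE,
                         hmm_restarts = 3, hmm_tol = 1e-4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) {
    trials <- read_trials(config)
    config_desc <- list(input = config)
  } else {
    cohort <- generate_cohort(config, seed = seed)
    trials <- cohort$trials
    config_desc <- config[setdiff(names(config), "agent_draw")]
  }
  write_trials(trials[, intersect(c(TRIAL_COLUMNS, "prev_reward",
                                    "true_state"), names(trials))],
               file.path(out_dir, "trials.csv"))

  if (label_states) {
    labeled <- label_trials(trials, seed = seed, n_restarts = hmm_restarts,
                            tol = hmm_tol)
  } else {
    if (!"state" %in% names(trials)) {
      stop("stage 'metrics' failed: no state labels and labeling disabled")
    }
    labeled <- trials
  }
  write_trials(labeled[, intersect(c(TRIAL_COLUMNS, "prev_reward", "state",
                                     "state_side", "p_explore"),
                                   names(labeled))],
               file.path(out_dir, "labeled.csv"))

  metrics <- session_state_metrics(labeled)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  bouts <- bout_table(labeled)
  write.csv(bouts, file.path(out_dir, "bouts.csv"), row.names = FALSE)

  alpha_table <- NULL
  if (fit_alpha) {
    fits <- lapply(split(labeled, labeled$mouse_id), function(d) {
      fit_rlck(split(d, d$session), n_restarts = 10, seed = seed)
    })
    alpha_table <- rlck_fit_table(fits)
  }
  models <- fit_model_family(labeled, alpha_table = alpha_table)
  write.csv(models$report, file.path(out_dir, "model_report.csv"),
            row.names = FALSE)

  manifest <- list(
    seed = seed,
    package = "touchbandit",
    version = as.character(packageVersion("touchbandit")),
    r_version = R.version.string,
    config = config_desc,
    tables = c("trials.csv", "labeled.csv", "metrics.csv", "bouts.csv",
               "model_report.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(trials = trials, labeled = labeled, metrics = metrics,
                 bouts = bouts, report = models$report,
                 manifest = manifest))
}

#' Label a trial table with explore/exploit states
#'
#' Fits the constrained HMM per animal (across that animal's sessions) and
#' decodes every session with the animal's fitted parameters.
#'
#' @param trials Trial table.
#' @param per_mouse Fit one HMM per animal (default) or one pooled model.
#' @param seed Optional integer seed for the EM restarts.
#' @param ... Passed to [fit_hmm()].
#' @return The trial table with `state`, `state_side`, `p_explore` columns.
#' @export
label_trials <- function(trials, per_mouse = TRUE, seed = NULL, ...) {
  require_columns(trials, c("mouse_id", "session", "trial", "side"))
  groups <- if (per_mouse) split(trials, trials$mouse_id) else list(trials)
  out <- lapply(groups, function(g) {
    seqs <- lapply(split(g, g$session),
                   function(s) s$side[order(s$trial)])
    fit <- fit_hmm(seqs, seed = seed, ...)
    labeled <- lapply(split(g, g$session), function(s) {
      s <- s[order(s$trial), , drop = FALSE]
      dec <- decode_states(fit, s$side)
      s$state <- dec$state
      s$state_side <- dec$state_side
      s$p_explore <- dec$p_explore
      s
    })
    do.call(rbind, labeled)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
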