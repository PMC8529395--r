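#' Read and write trial tables as CSV
#'
#' Tidy one-row-per-trial CSV with fixed column types; the write/read pair is
#' lossless for tables produced by [generate_session()], [simulate_choices()]
#' and [simulate_cohort()].
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `write_trials_csv()` returns `trials` invisibly;
#'   `read_trials_csv()` returns the tibble.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(trials)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    agent_id = readr::col_character(),
    condition = readr::col_character(),
    pair_id = readr::col_character(),
    run = readr::col_integer(),
    block = readr::col_integer(),
    trial_in_block = readr::col_integer(),
    missed = readr::col_logical(),
    chosen_good = readr::col_logical(),
    .default = readr::col_double()
  ))
}

#' Read and write a task configuration as YAML
#'
#' @param config A [task_config()].
#' @param path File path.
#' @return `write_config_yaml()` returns `config` invisibly;
#'   `read_config_yaml()` returns a validated [task_config()].
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "task_config"))
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path)
  invisible(config)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  task_config(
    n_runs = raw$n_runs,
    blocks_per_condition_per_run = raw$blocks_per_condition_per_run,
    trials_per_block = raw$trials_per_block,
    p_reward_good = raw$p_reward_good,
    outcome_values = c(reward = raw$outcome_values$reward,
                       punishment = raw$outcome_values$punishment),
    point_value_eur = raw$point_value_eur,
    payout_floor_eur = raw$payout_floor_eur,
    payout_ceiling_eur = raw$payout_ceiling_eur,
    response_window_ms = raw$response_window_ms
  )
}

#' Build neuroimaging-ready event rows with model regressors
#'
#' Expands each non-missed trial into two zero-duration events — the decision
#' phase, carrying the chosen expected value (EV) as parametric modulator,
#' and the outcome phase, carrying the prediction error (PE) — and each
#' missed trial into a single modulator-free `missed` event (a regressor of
#' no interest). When per-condition fits are supplied, the modulators are
#' recomputed by replaying the agent's own fitted parameters over the
#' observed choice/outcome sequence; otherwise the `chosen_q`/`pe` columns
#' already present are used.
#'
#' @param trials One agent's trial table (simulated or observed), in
#'   experienced order.
#' @param fits Optional tibble with columns `condition`, `alpha` (or
#'   `alpha_gain`/`alpha_loss`) and `beta` — e.g. rows of [fit_cohort()]
#'   output. Must cover every condition present in `trials`.
#' @param q0 Initial option value at each block start (used when replaying).
#' @param config A [task_config()].
#' @param mean_center Center each modulator within run (non-missed events)?
#' @return Tibble of event rows: `onset`, `duration`, `trial_type`
#'   (`decision`/`outcome`/`missed`), `condition`, `modulator` (`EV`/`PE` or
#'   `NA`), `value`, `run`, `agent_id`, ordered by run and onset.
#' @export
build_events <- function(trials, fits = NULL, q0 = 0, config = task_config(),
                         mean_center = FALSE) {
  if (!is.null(fits)) {
    present <- unique(trials$condition)
    missing_cond <- setdiff(present, fits$condition)
    if (length(missing_cond) > 0L) {
      stop("no fitted parameters for condition(s): ",
           paste(missing_cond, collapse = ", "), call. = FALSE)
    }
    par_list <- stats::setNames(lapply(fits$condition, function(cond) {
      row <- fits[fits$condition == cond, , drop = FALSE]
      if (!is.null(row$alpha) && !is.na(row$alpha)) {
        rl_params(alpha = row$alpha, beta = row$beta)
      } else {
        rl_params(alpha_gain = row$alpha_gain, alpha_loss = row$alpha_loss,
                  beta = row$beta)
      }
    }), fits$condition)
    trials <- replay_trajectory(trials, par_list, q0 = q0, config = config)
  }
  needed <- c("chosen_q", "pe", "onset_choice_s", "onset_outcome_s")
  if (!all(needed %in% names(trials))) {
    stop("trials lack model trajectory or onset columns; supply `fits` or ",
         "a table from simulate_choices()/replay_trajectory()",
         call. = FALSE)
  }
  miss <- vapply(trials$missed, isTRUE, TRUE)
  if (any(!miss & (is.na(trials$chosen_q) | is.na(trials$pe)))) {
    stop("trajectory/trial misalignment: non-missed trial without EV/PE",
         call. = FALSE)
  }
  ok <- trials[!miss, , drop = FALSE]
  mi <- trials[miss, , drop = FALSE]
  events <- dplyr::bind_rows(
    tibble::tibble(onset = ok$onset_choice_s, duration = 0,
                   trial_type = "decision", condition = ok$condition,
                   modulator = "EV", value = ok$chosen_q,
                   run = ok$run, agent_id = ok$agent_id),
    tibble::tibble(onset = ok$onset_outcome_s, duration = 0,
                   trial_type = "outcome", condition = ok$condition,
                   modulator = "PE", value = ok$pe,
                   run = ok$run, agent_id = ok$agent_id),
    tibble::tibble(onset = mi$onset_choice_s, duration = 0,
                   trial_type = "missed", condition = mi$condition,
                   modulator = NA_character_, value = NA_real_,
                   run = mi$run, agent_id = mi$agent_id)
  )
  events <- dplyr::arrange(events, .data$run, .data$onset)
  if (mean_center) {
    events <- dplyr::mutate(
      dplyr::group_by(events, .data$run, .data$modulator),
      value = .data$value - mean(.data$value))
    events <- dplyr::ungroup(events)
  }
  events
}

#' Write and read event tables as BIDS-style TSV
#'
#' Tab-separated event files with `onset` and `duration` as the first
#' columns. Onsets are serialized with 4 decimal places (0.1 ms resolution,
#' the resolution at which sessions are generated), so the write/read pair is
#' lossless.
#'
#' @param events Event tibble from [build_events()].
#' @param path File path.
#' @return `write_events_tsv()` returns `events` invisibly;
#'   `read_events_tsv()` returns the tibble.
#' @export
write_events_tsv <- function(events, path) {
  out <- dplyr::mutate(events,
                       onset = sprintf("%.4f", .data$onset),
                       duration = sprintf("%.4f", .data$duration))
  readr::write_tsv(out, path, na = "n/a")
  invisible(events)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, na = "n/a", col_types = readr::cols(
    onset = readr::col_double(),
    duration = readr::col_double(),
    trial_type = readr::col_character(),
    condition = readr::col_character(),
    modulator = readr::col_character(),
    value = readr::col_double(),
    run = readr::col_integer(),
    agent_id = readr::col_character()
  ))
}
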