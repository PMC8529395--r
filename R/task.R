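#' Task configuration for the prosocial learning task
#'
#' Describes the structure and reinforcement contingencies of a two-choice
#' probabilistic learning task with three beneficiary conditions (`self`,
#' `other`, `no_one`). The defaults reproduce the published design: 3 scanner
#' runs, one 16-trial block per condition per run (144 trials, 48 per
#' condition), a 75/25 reward contingency with outcomes of +1/-1 point, and a
#' point-to-money conversion of 0.25 EUR per point clamped to [1, 12] EUR.
#'
#' @param n_runs Number of runs.
#' @param blocks_per_condition_per_run Blocks of each condition within a run.
#' @param trials_per_block Trials per block.
#' @param p_reward_good Probability that choosing the high-contingency
#'   stimulus is rewarded; must lie in (0.5, 1]. The low-contingency stimulus
#'   is rewarded with probability `1 - p_reward_good`.
#' @param outcome_values Numeric pair `c(reward, punishment)`.
#' @param point_value_eur Money per point for the payout conversion.
#' @param payout_floor_eur,payout_ceiling_eur Clamp bounds of the payout.
#' @param response_window_ms Response window (only used for event timing).
#' @return A `task_config` object (a validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' payout(20, cfg)
task_config <- function(n_runs = 3L,
                        blocks_per_condition_per_run = 1L,
                        trials_per_block = 16L,
                        p_reward_good = 0.75,
                        outcome_values = c(reward = 1, punishment = -1),
                        point_value_eur = 0.25,
                        payout_floor_eur = 1,
                        payout_ceiling_eur = 12,
                        response_window_ms = 2500) {
  cfg <- list(
    n_runs = as.integer(n_runs),
    blocks_per_condition_per_run = as.integer(blocks_per_condition_per_run),
    trials_per_block = as.integer(trials_per_block),
    p_reward_good = as.numeric(p_reward_good),
    outcome_values = c(reward = as.numeric(outcome_values[[1]]),
                       punishment = as.numeric(outcome_values[[2]])),
    point_value_eur = as.numeric(point_value_eur),
    payout_floor_eur = as.numeric(payout_floor_eur),
    payout_ceiling_eur = as.numeric(payout_ceiling_eur),
    response_window_ms = as.numeric(response_window_ms)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  counts <- c(cfg$n_runs, cfg$blocks_per_condition_per_run, cfg$trials_per_block)
  if (any(!is.finite(counts)) || any(counts < 1L)) {
    stop("n_runs, blocks_per_condition_per_run and trials_per_block must be positive counts",
         call. = FALSE)
  }
  if (!(cfg$p_reward_good > 0.5 && cfg$p_reward_good <= 1)) {
    stop("p_reward_good must lie in (0.5, 1]", call. = FALSE)
  }
  if (cfg$outcome_values[["reward"]] <= cfg$outcome_values[["punishment"]]) {
    stop("reward outcome must exceed punishment outcome", call. = FALSE)
  }
  if (cfg$payout_floor_eur > cfg$payout_ceiling_eur) {
    stop("payout floor exceeds ceiling", call. = FALSE)
  }
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d run(s) x 3 conditions x %d block(s) x %d trials = %d trials\n",
              x$n_runs, x$blocks_per_condition_per_run, x$trials_per_block,
              x$n_runs * 3L * x$blocks_per_condition_per_run * x$trials_per_block))
  cat(sprintf("  contingency %.0f/%.0f%%, outcomes %+g/%+g points\n",
              100 * x$p_reward_good, 100 * (1 - x$p_reward_good),
              x$outcome_values[["reward"]], x$outcome_values[["punishment"]]))
  cat(sprintf("  payout %.2f EUR/point, clamped to [%.2f, %.2f] EUR\n",
              x$point_value_eur, x$payout_floor_eur, x$payout_ceiling_eur))
  invisible(x)
}

#' Generate the trial skeleton of one session
#'
#' Lays out runs, blocks and trials (no choices yet). Within each run every
#' condition appears in `blocks_per_condition_per_run` blocks; the order of
#' conditions across runs follows a seeded cyclic Latin square, so across the
#' default 3 runs each condition occupies each serial position exactly once.
#' Every block introduces a fresh stimulus pair (`pair_id`), which is also the
#' unit at which learned values are reset. Onset times are generated with the
#' task's jittered fixation (1--2 s before the outcome) and inter-trial
#' intervals (1--8 s); they matter only for event-file export.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param agent_id Identifier stored in the `agent_id` column.
#' @return A tibble with one row per trial: `agent_id`, `run`, `block`
#'   (serial block number of that condition across the session), `condition`,
#'   `trial_in_block`, `pair_id`, `onset_choice_s`, `onset_outcome_s`.
#' @export
generate_session <- function(config = task_config(), seed = 1L,
                             agent_id = "agent_01") {
  stopifnot(inherits(config, "task_config"))
  validate_task_config(config)
  conds <- condition_levels()
  withr::with_seed(seed, {
    base <- sample(conds)
    rows <- vector("list",
                   config$n_runs * 3L * config$blocks_per_condition_per_run)
    pair_counter <- 0L
    block_counter <- stats::setNames(integer(3), conds)
    k <- 0L
    for (run in seq_len(config$n_runs)) {
      # cyclic rotation of the seeded base order -> Latin square over runs
      rot <- ((seq_along(conds) + run - 2L) %% 3L) + 1L
      run_order <- rep(base[rot], times = config$blocks_per_condition_per_run)
      t_cursor <- 0
      for (cond in run_order) {
        pair_counter <- pair_counter + 1L
        block_counter[[cond]] <- block_counter[[cond]] + 1L
        t_cursor <- t_cursor + 2.0 # beneficiary instruction screen
        n <- config$trials_per_block
        onset_choice <- numeric(n)
        onset_outcome <- numeric(n)
        for (j in seq_len(n)) {
          onset_choice[j] <- t_cursor
          # choice window + selection frame + jittered fixation
          t_cursor <- t_cursor + config$response_window_ms / 1000 + 0.5 +
            runif(1, 1, 2)
          onset_outcome[j] <- t_cursor
          t_cursor <- t_cursor + 1.0 + runif(1, 1, 8) # outcome + ITI
        }
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          agent_id = agent_id,
          run = run,
          block = block_counter[[cond]],
          condition = cond,
          trial_in_block = seq_len(n),
          pair_id = sprintf("pair_%02d", pair_counter),
          onset_choice_s = round(onset_choice, 4),
          onset_outcome_s = round(onset_outcome, 4)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Sample trial outcomes under the reinforcement contingency
#'
#' Outcomes are i.i.d. Bernoulli draws: choosing the high-contingency stimulus
#' yields the reward value with probability `p_reward_good`, the
#' low-contingency stimulus with probability `1 - p_reward_good`; otherwise
#' the punishment value is delivered. Uses the current RNG state; seed the
#' caller for reproducibility.
#'
#' @param chosen_good Logical vector; `TRUE` when the high-contingency
#'   stimulus was chosen.
#' @param config A [task_config()].
#' @return Numeric vector of outcomes (points), one per element.
#' @export
sample_outcome <- function(chosen_good, config = task_config()) {
  stopifnot(is.logical(chosen_good), !anyNA(chosen_good))
  p <- ifelse(chosen_good, config$p_reward_good, 1 - config$p_reward_good)
  ifelse(runif(length(chosen_good)) < p,
         config$outcome_values[["reward"]],
         config$outcome_values[["punishment"]])
}

#' Convert a point total to money
#'
#' `clamp(point_value_eur * total_points, floor, ceiling)`; with the defaults,
#' 0.25 EUR per point bounded to [1, 12] EUR.
#'
#' @param total_points Integer point total(s).
#' @param config A [task_config()].
#' @return Payout(s) in EUR.
#' @export
payout <- function(total_points, config = task_config()) {
  pmin(pmax(config$point_value_eur * total_points, config$payout_floor_eur),
       config$payout_ceiling_eur)
}
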