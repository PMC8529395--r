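#' Rescorla-Wagner parameter set
#'
#' Bundles the parameters of one agent in one condition. The one-rate variant
#' (`one_alpha`) has a single learning rate `alpha`; the two-rate variant
#' (`two_alpha`) applies `alpha_gain` after reward outcomes and `alpha_loss`
#' after punishment outcomes. All learning rates must lie strictly in (0, 1);
#' the inverse temperature `beta` may be any finite real (negative values
#' produce value-averse choice, `beta = 0` random choice).
#'
#' @param alpha Learning rate (one-rate variant).
#' @param beta Softmax inverse temperature.
#' @param alpha_gain,alpha_loss Valence-specific learning rates (two-rate
#'   variant). Supply either `alpha` or both `alpha_gain` and `alpha_loss`.
#' @return An `rl_params` object.
#' @export
#' @examples
#' rl_params(alpha = 0.3, beta = 5)
#' rl_params(alpha_gain = 0.4, alpha_loss = 0.1, beta = 5)
rl_params <- function(alpha = NULL, beta, alpha_gain = NULL, alpha_loss = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (!is.null(alpha)) {
    if (!is.null(alpha_gain) || !is.null(alpha_loss)) {
      stop("supply either alpha, or alpha_gain + alpha_loss, not both",
           call. = FALSE)
    }
    check_rate(alpha, "alpha")
    out <- list(variant = "one_alpha", alpha = as.numeric(alpha),
                beta = as.numeric(beta))
  } else {
    if (is.null(alpha_gain) || is.null(alpha_loss)) {
      stop("two-rate variant needs both alpha_gain and alpha_loss",
           call. = FALSE)
    }
    check_rate(alpha_gain, "alpha_gain")
    check_rate(alpha_loss, "alpha_loss")
    out <- list(variant = "two_alpha", alpha_gain = as.numeric(alpha_gain),
                alpha_loss = as.numeric(alpha_loss), beta = as.numeric(beta))
  }
  structure(out, class = "rl_params")
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(name, " must lie strictly in (0, 1)", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.rl_params <- function(x, ...) {
  if (x$variant == "one_alpha") {
    cat(sprintf("<rl_params> one_alpha: alpha = %.4g, beta = %.4g\n",
                x$alpha, x$beta))
  } else {
    cat(sprintf("<rl_params> two_alpha: alpha_gain = %.4g, alpha_loss = %.4g, beta = %.4g\n",
                x$alpha_gain, x$alpha_loss, x$beta))
  }
  invisible(x)
}

#' Rescorla-Wagner value update
#'
#' `Q <- Q + alpha * (outcome - Q)` for the chosen option only; the unchosen
#' option's value is never touched.
#'
#' @param q_chosen Current value of the chosen option.
#' @param outcome Received outcome (points).
#' @param alpha Learning rate.
#' @return Updated value.
#' @export
rw_update <- function(q_chosen, outcome, alpha) {
  q_chosen + alpha * (outcome - q_chosen)
}

#' Learning rate applied to a given outcome
#'
#' For the one-rate variant this is `alpha` regardless of valence; for the
#' two-rate variant, `alpha_gain` when the outcome equals the configured
#' reward value and `alpha_loss` when it equals the punishment value. Gating
#' is by outcome valence, not by the sign of the prediction error (the two
#' coincide for values inside the outcome range).
#'
#' @param outcome Outcome value; must be one of `config$outcome_values`.
#' @param params An [rl_params()].
#' @param config A [task_config()] supplying the outcome values.
#' @return The applicable learning rate.
#' @export
effective_alpha <- function(outcome, params, config = task_config()) {
  stopifnot(inherits(params, "rl_params"))
  if (params$variant == "one_alpha") {
    if (!outcome %in% config$outcome_values) {
      stop("outcome ", outcome, " is not one of the configured outcome values",
           call. = FALSE)
    }
    return(params$alpha)
  }
  if (outcome == config$outcome_values[["reward"]]) {
    params$alpha_gain
  } else if (outcome == config$outcome_values[["punishment"]]) {
    params$alpha_loss
  } else {
    stop("outcome ", outcome, " is not one of the configured outcome values",
         call. = FALSE)
  }
}

#' Softmax choice probabilities
#'
#' `P(i) = exp(beta * q_i) / sum_j exp(beta * q_j)`, computed with max
#' shifting so large `|beta * q|` cannot overflow. `beta = 0` yields the
#' uniform distribution; probabilities are invariant to adding a constant to
#' all values.
#'
#' @param q Numeric vector of option values (two options in this task).
#' @param beta Inverse temperature.
#' @return Probability vector summing to 1.
#' @export
softmax_prob <- function(q, beta) {
  stopifnot(is.numeric(q), all(is.finite(q)), is.finite(beta))
  z <- beta * q
  e <- exp(z - max(z))
  e / sum(e)
}

# single rl_params -> per-condition named list
params_by_condition <- function(params) {
  if (inherits(params, "rl_params")) {
    params <- stats::setNames(rep(list(params), 3L), condition_levels())
  }
  stopifnot(is.list(params), all(vapply(params, inherits, TRUE, "rl_params")))
  params
}

#' Simulate choices and outcomes over a session
#'
#' Plays an agent through a trial skeleton: within each block values start at
#' `q0` for both stimuli (values never carry over across blocks or
#' conditions), each non-missed trial samples a choice from the softmax over
#' current values, draws the outcome under the task contingency, and updates
#' the chosen stimulus's value with the applicable learning rate. The returned
#' trajectory records, per trial, the chosen option's pre-outcome expected
#' value (`chosen_q`), the prediction error (`pe = outcome - chosen_q`) and
#' the probability of the made choice (`choice_prob`). Missed trials (drawn
#' with probability `miss_prob`) carry no choice, outcome, or update.
#'
#' @param session Trial skeleton from [generate_session()].
#' @param params A single [rl_params()] used in all conditions, or a named
#'   list with one `rl_params` per condition (`self`, `other`, `no_one`).
#' @param q0 Initial value of both stimuli at each block start.
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param miss_prob Per-trial probability of a missed ("too late") response.
#' @return The session tibble with added columns `missed`, `chosen_good`,
#'   `outcome`, `chosen_q`, `pe`, `choice_prob`.
#' @export
simulate_choices <- function(session, params, q0 = 0,
                             config = task_config(), seed = 1L,
                             miss_prob = 0) {
  params <- params_by_condition(params)
  missing_cond <- setdiff(unique(session$condition), names(params))
  if (length(missing_cond) > 0L) {
    stop("no parameters supplied for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  stopifnot(miss_prob >= 0, miss_prob <= 1)
  n <- nrow(session)
  missed <- logical(n)
  chosen_good <- rep(NA, n)
  outcome <- rep(NA_real_, n)
  chosen_q <- rep(NA_real_, n)
  pe <- rep(NA_real_, n)
  choice_prob <- rep(NA_real_, n)
  withr::with_seed(seed, {
    q <- c(q0, q0)
    current_pair <- ""
    for (i in seq_len(n)) {
      if (session$pair_id[i] != current_pair) {
        current_pair <- session$pair_id[i]
        q <- c(q0, q0) # new stimulus pair: values reset
      }
      if (miss_prob > 0 && runif(1) < miss_prob) {
        missed[i] <- TRUE
        next
      }
      par_c <- params[[session$condition[i]]]
      p <- softmax_prob(q, par_c$beta)
      idx <- if (runif(1) < p[1]) 1L else 2L
      chosen_good[i] <- idx == 1L
      chosen_q[i] <- q[idx]
      choice_prob[i] <- p[idx]
      outcome[i] <- sample_outcome(idx == 1L, config)
      pe[i] <- outcome[i] - q[idx]
      q[idx] <- rw_update(q[idx], outcome[i],
                          effective_alpha(outcome[i], par_c, config))
    }
  })
  out <- session
  out$missed <- missed
  out$chosen_good <- as.logical(chosen_good)
  out$outcome <- outcome
  out$chosen_q <- chosen_q
  out$pe <- pe
  out$choice_prob <- choice_prob
  out
}

#' Replay a model over observed choices
#'
#' Runs the Rescorla-Wagner/softmax model along an observed choice-outcome
#' sequence without sampling anything: values reset to `q0` at each new
#' stimulus pair, each non-missed trial contributes the model probability of
#' the choice actually made, and the chosen stimulus's value is updated with
#' the observed outcome. This is the deterministic replay underlying both the
#' fit likelihood and the expected-value/prediction-error regressors.
#'
#' @param trials Trial table with `pair_id`, `condition`, `missed`,
#'   `chosen_good`, `outcome`, ordered as experienced.
#' @param params A single [rl_params()] or a per-condition named list.
#' @param q0 Initial value of both stimuli at each block start.
#' @param config A [task_config()].
#' @return `trials` with `chosen_q`, `pe`, `choice_prob` recomputed under
#'   `params` (NA on missed trials).
#' @export
replay_trajectory <- function(trials, params, q0 = 0, config = task_config()) {
  params <- params_by_condition(params)
  n <- nrow(trials)
  chosen_q <- rep(NA_real_, n)
  pe <- rep(NA_real_, n)
  choice_prob <- rep(NA_real_, n)
  q <- c(q0, q0)
  current_pair <- ""
  for (i in seq_len(n)) {
    if (trials$pair_id[i] != current_pair) {
      current_pair <- trials$pair_id[i]
      q <- c(q0, q0)
    }
    if (isTRUE(trials$missed[i])) next
    par_c <- params[[trials$condition[i]]]
    idx <- if (isTRUE(trials$chosen_good[i])) 1L else 2L
    p <- softmax_prob(q, par_c$beta)
    chosen_q[i] <- q[idx]
    choice_prob[i] <- p[idx]
    out_i <- trials$outcome[i]
    pe[i] <- out_i - q[idx]
    q[idx] <- rw_update(q[idx], out_i,
                        effective_alpha(out_i, par_c, config))
  }
  out <- trials
  out$chosen_q <- chosen_q
  out$pe <- pe
  out$choice_prob <- choice_prob
  out
}
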