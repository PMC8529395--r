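#' Priors for MAP estimation
#'
#' Weakly informative priors regularizing per-condition fits: a
#' Beta(`alpha_shape1`, `alpha_shape2`) prior on each learning rate and a
#' Gaussian(`beta_mean`, `beta_sd`) prior on the inverse temperature. The
#' defaults, Beta(1.2, 1.2) and Normal(0, sd 10), pull extreme learning rates
#' gently toward 0.5 and keep the inverse temperature finite without
#' constraining its sign.
#'
#' @param alpha_shape1,alpha_shape2 Beta shape parameters for learning rates.
#' @param beta_mean,beta_sd Mean and standard deviation of the Gaussian prior
#'   on the inverse temperature.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(alpha_shape1 = 1.2, alpha_shape2 = 1.2,
                       beta_mean = 0, beta_sd = 10) {
  stopifnot(alpha_shape1 > 0, alpha_shape2 > 0, beta_sd > 0)
  structure(list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
                 beta_mean = beta_mean, beta_sd = beta_sd),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> alpha ~ Beta(%g, %g), beta ~ Normal(%g, sd %g)\n",
              x$alpha_shape1, x$alpha_shape2, x$beta_mean, x$beta_sd))
  invisible(x)
}

# non-missed rows in experienced order, plus block-reset flags
choice_sequence <- function(trials) {
  keep <- !vapply(trials$missed, isTRUE, TRUE) & !is.na(trials$chosen_good)
  tr <- trials[keep, , drop = FALSE]
  n <- nrow(tr)
  new_block <- if (n == 0L) logical(0) else {
    c(TRUE, tr$pair_id[-1L] != tr$pair_id[-n])
  }
  list(chosen_good = as.logical(tr$chosen_good),
       outcome = as.numeric(tr$outcome),
       new_block = new_block,
       n = n)
}

loglik_fast <- function(seq, params, q0, config) {
  if (seq$n == 0L) return(0)
  ag <- if (params$variant == "one_alpha") params$alpha else params$alpha_gain
  al <- if (params$variant == "one_alpha") params$alpha else params$alpha_loss
  rw_loglik_cpp(seq$chosen_good, seq$outcome, seq$new_block,
                ag, al, params$beta, q0, config$outcome_values[["reward"]])
}

log_prior <- function(params, priors) {
  rates <- if (params$variant == "one_alpha") params$alpha else
    c(params$alpha_gain, params$alpha_loss)
  if (any(rates <= 0) || any(rates >= 1)) return(-Inf)
  sum(dbeta(rates, priors$alpha_shape1, priors$alpha_shape2, log = TRUE)) +
    dnorm(params$beta, priors$beta_mean, priors$beta_sd, log = TRUE)
}

#' Log-likelihood of observed choices under a Rescorla-Wagner model
#'
#' Replays the model along the observed choice/outcome sequence (values reset
#' at every new stimulus pair) and sums the log softmax probability of each
#' made choice. Missed trials contribute nothing. An empty sequence returns 0
#' with a warning (a fit on it is prior-only).
#'
#' @param trials Trial table for one condition (any table is accepted; missed
#'   rows are dropped), in experienced order.
#' @param params An [rl_params()].
#' @param q0 Initial option value at each block start.
#' @param config A [task_config()].
#' @return The log-likelihood (<= 0).
#' @export
log_likelihood <- function(trials, params, q0 = 0, config = task_config()) {
  stopifnot(inherits(params, "rl_params"))
  seq <- choice_sequence(trials)
  if (seq$n == 0L) {
    warning("no non-missed trials: log-likelihood is 0 (prior-only fit)",
            call. = FALSE)
    return(0)
  }
  loglik_fast(seq, params, q0, config)
}

#' Log-posterior (unnormalized) of a parameter set
#'
#' [log_likelihood()] plus the log prior density: Beta on each learning rate,
#' Gaussian on the inverse temperature. Learning rates outside (0, 1) give
#' `-Inf` (a rejected point, not an error).
#'
#' @inheritParams log_likelihood
#' @param priors A [prior_spec()].
#' @return The log-posterior up to the normalizing constant.
#' @export
log_posterior <- function(trials, params, priors = prior_spec(), q0 = 0,
                          config = task_config()) {
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  seq <- choice_sequence(trials)
  loglik_fast(seq, params, q0, config) + lp
}

#' Bayesian Information Criterion
#'
#' `-2 * loglik + k * log(n)`; lower is better.
#'
#' @param loglik Log-likelihood at the fitted point.
#' @param k Number of free parameters.
#' @param n Number of observations (non-missed trials).
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n) {
  if (any(n < 1)) stop("BIC undefined for n < 1", call. = FALSE)
  -2 * loglik + k * log(n)
}

par_to_params <- function(par, variant) {
  if (variant == "one_alpha") {
    rl_params(alpha = par[1], beta = par[2])
  } else {
    rl_params(alpha_gain = par[1], alpha_loss = par[2], beta = par[3])
  }
}

#' MAP fit of one agent's choices in one condition
#'
#' Maximizes the log-posterior by bounded L-BFGS-B from `n_starts` seeded
#' starting points (learning rates drawn from the prior, inverse temperatures
#' from a dispersed grid) and keeps the best optimum. Learning rates are
#' bounded to (1e-6, 1 - 1e-6) and the inverse temperature to (-100, 100).
#' With zero usable trials the posterior equals the prior and the prior modes
#' are returned (alpha = 0.5, beta = 0 under the defaults), with `bic = NA`.
#'
#' @param trials Trial table for one condition, in experienced order.
#' @param variant `"one_alpha"` or `"two_alpha"`.
#' @param priors A [prior_spec()].
#' @param q0 Initial option value at each block start.
#' @param config A [task_config()].
#' @param n_starts Number of multi-starts.
#' @param seed Integer seed for the starting points.
#' @return A one-row tibble: `variant`, `alpha`, `alpha_gain`, `alpha_loss`,
#'   `beta`, `loglik`, `logpost`, `n_trials`, `k`, `bic`, `n_starts`,
#'   `converged`, `best_start`.
#' @export
fit_map <- function(trials, variant = c("one_alpha", "two_alpha"),
                    priors = prior_spec(), q0 = 0, config = task_config(),
                    n_starts = 10L, seed = 1L) {
  variant <- match.arg(variant)
  seq <- choice_sequence(trials)
  k <- if (variant == "one_alpha") 2L else 3L
  if (seq$n == 0L) {
    warning("no non-missed trials: returning prior modes", call. = FALSE)
    a <- priors$alpha_shape1; b <- priors$alpha_shape2
    mode_alpha <- if (a > 1 && b > 1) (a - 1) / (a + b - 2) else 0.5
    params <- par_to_params(
      if (variant == "one_alpha") c(mode_alpha, priors$beta_mean)
      else c(mode_alpha, mode_alpha, priors$beta_mean), variant)
    return(fit_row(params, loglik = 0,
                   logpost = log_prior(params, priors), n_trials = 0L, k = k,
                   bic = NA_real_, n_starts = 0L, converged = TRUE,
                   best_start = NA_integer_))
  }
  reward_value <- config$outcome_values[["reward"]]
  negpost <- function(par) {
    beta <- par[length(par)]
    ag <- par[1]
    al <- if (variant == "one_alpha") par[1] else par[2]
    ll <- rw_loglik_cpp(seq$chosen_good, seq$outcome, seq$new_block,
                        ag, al, beta, q0, reward_value)
    lp <- sum(dbeta(par[-length(par)], priors$alpha_shape1,
                    priors$alpha_shape2, log = TRUE)) +
      dnorm(beta, priors$beta_mean, priors$beta_sd, log = TRUE)
    -(ll + lp)
  }
  n_alpha <- k - 1L
  lower <- c(rep(1e-6, n_alpha), -100)
  upper <- c(rep(1 - 1e-6, n_alpha), 100)
  starts <- withr::with_seed(seed, {
    betas <- seq(-15, 15, length.out = n_starts)
    lapply(seq_len(n_starts), function(s) {
      a <- pmin(pmax(rbeta(n_alpha, priors$alpha_shape1, priors$alpha_shape2),
                     1e-4), 1 - 1e-4)
      c(a, betas[s])
    })
  })
  best <- NULL
  best_start <- NA_integer_
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[[s]], negpost, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_start <- s
    }
  }
  if (is.null(best)) {
    stop("all optimization starts failed", call. = FALSE)
  }
  params <- par_to_params(best$par, variant)
  ll <- loglik_fast(seq, params, q0, config)
  fit_row(params, loglik = ll, logpost = -best$value, n_trials = seq$n, k = k,
          bic = bic(ll, k, seq$n), n_starts = as.integer(n_starts),
          converged = best$convergence == 0,
          best_start = best_start)
}

fit_row <- function(params, loglik, logpost, n_trials, k, bic, n_starts,
                    converged, best_start) {
  tibble::tibble(
    variant = params$variant,
    alpha = if (params$variant == "one_alpha") params$alpha else NA_real_,
    alpha_gain = if (params$variant == "two_alpha") params$alpha_gain else NA_real_,
    alpha_loss = if (params$variant == "two_alpha") params$alpha_loss else NA_real_,
    beta = params$beta,
    loglik = loglik, logpost = logpost,
    n_trials = as.integer(n_trials), k = as.integer(k), bic = bic,
    n_starts = n_starts, converged = converged, best_start = best_start
  )
}

#' Fit every agent x condition in a trial table
#'
#' Runs [fit_map()] independently on each agent's trials in each condition
#' (three separate optimizations per agent), as in per-condition model
#' fitting.
#'
#' @param trials Cohort trial table (must carry `agent_id` and `condition`).
#' @inheritParams fit_map
#' @return A tibble with one row per agent x condition, the [fit_map()]
#'   columns prefixed by `agent_id` and `condition`.
#' @export
fit_cohort <- function(trials, variant = c("one_alpha", "two_alpha"),
                       priors = prior_spec(), q0 = 0, config = task_config(),
                       n_starts = 10L, seed = 1L) {
  variant <- match.arg(variant)
  assert_conditions(trials$condition)
  agents <- unique(trials$agent_id)
  rows <- list()
  for (aid in agents) {
    for (cond in condition_levels()) {
      sub <- trials[trials$agent_id == aid & trials$condition == cond, ,
                    drop = FALSE]
      if (nrow(sub) == 0L) next
      fit <- fit_map(sub, variant, priors, q0, config, n_starts,
                     seed = derive_seed(seed, length(rows) + 1L))
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(agent_id = aid, condition = cond), fit)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare one- vs two-learning-rate models by BIC
#'
#' Fits both variants to every agent x condition and reports per-fit BICs,
#' their difference, and the preferred model (ties go to the simpler,
#' one-rate model), plus the per-condition fraction of agents preferring the
#' one-rate model.
#'
#' @inheritParams fit_cohort
#' @return A `comparison_report`: list with `by_agent` (one row per agent x
#'   condition: `bic_one`, `bic_two`, `delta_bic = bic_one - bic_two`,
#'   `preferred`, convergence flags) and `by_condition`
#'   (`fraction_preferring_one`).
#' @export
compare_models <- function(trials, priors = prior_spec(), q0 = 0,
                           config = task_config(), n_starts = 10L, seed = 1L) {
  one <- fit_cohort(trials, "one_alpha", priors, q0, config, n_starts,
                    seed = derive_seed(seed, 1L))
  two <- fit_cohort(trials, "two_alpha", priors, q0, config, n_starts,
                    seed = derive_seed(seed, 2L))
  by_agent <- tibble::tibble(
    agent_id = one$agent_id,
    condition = one$condition,
    bic_one = one$bic,
    bic_two = two$bic,
    delta_bic = one$bic - two$bic,
    preferred = ifelse(one$bic <= two$bic, "one_alpha", "two_alpha"),
    converged_one = one$converged,
    converged_two = two$converged
  )
  by_condition <- dplyr::summarise(
    dplyr::group_by(by_agent, condition),
    fraction_preferring_one = mean(preferred == "one_alpha"),
    n_agents = dplyr::n(),
    .groups = "drop"
  )
  structure(list(by_agent = by_agent, by_condition = by_condition),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> one- vs two-learning-rate model (BIC)\n")
  print(x$by_condition)
  invisible(x)
}
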