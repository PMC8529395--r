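#' Specification of a synthetic age-structured cohort
#'
#' Defines the generative model for synthetic participants whose learning
#' parameters vary with age the way the developmental effects of interest do:
#' learning rates decrease with age (most strongly when learning for an
#' unknown other), value-guidedness (inverse temperature) increases with age,
#' and a cognitive-empathy score correlates with age at about 0.31 on a 0-4
#' Likert-mean scale. Learning rates live on the logit scale
#' (`plogis(intercept + slope * z_age + noise)`); slopes are per SD of age.
#' The defaults give the self condition the lowest mean learning rate and the
#' other condition the steepest age-related decline, a single inverse
#' temperature per agent shared across conditions, and a negative link from
#' the age-orthogonal empathy component to the other-condition learning rate
#' (set `empathy_alpha_slope = 0` to switch that link off).
#'
#' @param n_agents Cohort size.
#' @param age_range Minimum and maximum age in years (ages drawn uniformly).
#' @param alpha_intercept Named logit-scale intercepts per condition.
#' @param alpha_age_slope Named logit-scale slopes per SD of age.
#' @param alpha_noise_sd Logit-scale SD of agent-level learning-rate noise.
#' @param beta_intercept,beta_age_slope,beta_noise_sd Inverse-temperature
#'   generative model (natural scale, slope per SD of age).
#' @param empathy_age_corr Target age-empathy correlation (Gaussian copula).
#' @param empathy_mean,empathy_sd Marginal mean/SD of the empathy score
#'   before clipping to the 0-4 Likert range.
#' @param empathy_alpha_slope Logit-scale effect of the age-orthogonal
#'   empathy component on the other-condition learning rate.
#' @param miss_prob Per-trial miss probability given to every agent.
#' @param seed Integer seed used by [generate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_agents = 74L,
                        age_range = c(9.03, 21.77),
                        alpha_intercept = c(self = qlogis(0.30),
                                            other = qlogis(0.42),
                                            no_one = qlogis(0.40)),
                        alpha_age_slope = c(self = -0.35,
                                            other = -0.70,
                                            no_one = -0.10),
                        alpha_noise_sd = 0.5,
                        beta_intercept = 3.0,
                        beta_age_slope = 0.8,
                        beta_noise_sd = 0.6,
                        empathy_age_corr = 0.309,
                        empathy_mean = 2.2,
                        empathy_sd = 0.6,
                        empathy_alpha_slope = -0.25,
                        miss_prob = 0,
                        seed = 1L) {
  stopifnot(n_agents >= 2L, length(age_range) == 2L,
            age_range[1] < age_range[2],
            all(condition_levels() %in% names(alpha_intercept)),
            all(condition_levels() %in% names(alpha_age_slope)),
            alpha_noise_sd >= 0, beta_noise_sd >= 0,
            abs(empathy_age_corr) < 1, empathy_sd > 0,
            miss_prob >= 0, miss_prob < 1)
  structure(list(
    n_agents = as.integer(n_agents), age_range = as.numeric(age_range),
    alpha_intercept = alpha_intercept[condition_levels()],
    alpha_age_slope = alpha_age_slope[condition_levels()],
    alpha_noise_sd = alpha_noise_sd,
    beta_intercept = beta_intercept, beta_age_slope = beta_age_slope,
    beta_noise_sd = beta_noise_sd,
    empathy_age_corr = empathy_age_corr, empathy_mean = empathy_mean,
    empathy_sd = empathy_sd, empathy_alpha_slope = empathy_alpha_slope,
    miss_prob = miss_prob, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d agents, ages %.2f-%.2f, seed %d\n",
              x$n_agents, x$age_range[1], x$age_range[2], x$seed))
  invisible(x)
}

#' Generate a synthetic cohort of agents
#'
#' Draws ages uniformly over the configured range, builds per-condition
#' learning rates and a shared inverse temperature from the age-graded
#' generative model in the [cohort_spec()], and attaches an empathy score
#' whose age correlation is induced by a Gaussian copula. Learning rates come
#' out of an inverse-logit and are therefore always inside (0, 1).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per agent: `agent_id`, `age`, `empathy`,
#'   `alpha_self`, `alpha_other`, `alpha_no_one`, `beta`, `miss_prob`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_agents
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    z_age <- as.numeric(scale(age))
    # Gaussian copula: empathy = rho * z_age + sqrt(1-rho^2) * residual
    rho <- spec$empathy_age_corr
    e_resid <- rnorm(n)
    z_emp <- rho * z_age + sqrt(1 - rho^2) * e_resid
    empathy <- pmin(pmax(spec$empathy_mean + spec$empathy_sd * z_emp, 0), 4)
    alphas <- sapply(condition_levels(), function(cond) {
      lin <- spec$alpha_intercept[[cond]] +
        spec$alpha_age_slope[[cond]] * z_age +
        rnorm(n, 0, spec$alpha_noise_sd)
      if (cond == "other") lin <- lin + spec$empathy_alpha_slope * e_resid
      plogis(lin)
    })
    beta <- spec$beta_intercept + spec$beta_age_slope * z_age +
      rnorm(n, 0, spec$beta_noise_sd)
    tibble::tibble(
      agent_id = sprintf("agent_%03d", seq_len(n)),
      age = age,
      empathy = empathy,
      alpha_self = alphas[, "self"],
      alpha_other = alphas[, "other"],
      alpha_no_one = alphas[, "no_one"],
      beta = beta,
      miss_prob = spec$miss_prob
    )
  })
}

agent_param_list <- function(agent_row) {
  list(
    self = rl_params(alpha = agent_row$alpha_self, beta = agent_row$beta),
    other = rl_params(alpha = agent_row$alpha_other, beta = agent_row$beta),
    no_one = rl_params(alpha = agent_row$alpha_no_one, beta = agent_row$beta)
  )
}

#' Simulate one agent's full session
#'
#' Generates a session skeleton and plays the agent through it with their
#' per-condition parameters. [simulate_cohort()] calls this once per agent
#' with `derive_seed(seed, i)`, so any agent's sub-table can be reproduced in
#' isolation.
#'
#' @param agent One row of a [generate_cohort()] tibble.
#' @param config A [task_config()].
#' @param seed Integer seed for this agent.
#' @param q0 Initial option value at each block start.
#' @return A simulated trial tibble (see [simulate_choices()]) with `age` and
#'   `empathy` columns joined.
#' @export
simulate_agent <- function(agent, config = task_config(), seed = 1L, q0 = 0) {
  session <- generate_session(config, seed = derive_seed(seed, 1L),
                              agent_id = agent$agent_id)
  sim <- simulate_choices(session, agent_param_list(agent), q0 = q0,
                          config = config, seed = derive_seed(seed, 2L),
                          miss_prob = agent$miss_prob)
  dplyr::mutate(sim, age = agent$age, empathy = agent$empathy,
                .after = "agent_id")
}

#' Simulate a whole cohort
#'
#' Batches [simulate_agent()] over every agent, giving agent `i` the sub-seed
#' `derive_seed(seed, i)`.
#'
#' @param agents Tibble from [generate_cohort()].
#' @param config A [task_config()].
#' @param seed Master integer seed.
#' @param q0 Initial option value at each block start.
#' @return Concatenated trial tibble across agents.
#' @export
simulate_cohort <- function(agents, config = task_config(), seed = 1L,
                            q0 = 0) {
  dplyr::bind_rows(lapply(seq_len(nrow(agents)), function(i) {
    simulate_agent(agents[i, , drop = FALSE], config,
                   seed = derive_seed(seed, i), q0 = q0)
  }))
}
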