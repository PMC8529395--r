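# Independent oracles and tiny fixture builders, deliberately implemented
# against different primitives than the package code they check.

# Exhaustive grid-search MAP for the one-rate model. For a fixed learning
# rate the value-difference trajectory of the observed sequence does not
# depend on beta, so the grid factorizes: replay once per alpha, then score
# all betas against the same trajectory.
grid_search_map <- function(trials, priors = prior_spec(), q0 = 0,
                            config = task_config(),
                            alpha_grid = seq(0.005, 0.995, length.out = 101),
                            beta_grid = seq(-20, 20, length.out = 201)) {
  tr <- trials[!trials$missed & !is.na(trials$chosen_good), , drop = FALSE]
  reward <- config$outcome_values[["reward"]]
  best <- list(lp = -Inf)
  for (alpha in alpha_grid) {
    qg <- q0; qb <- q0; cur <- ""
    d <- numeric(nrow(tr)) # signed value difference, chosen minus unchosen
    for (i in seq_len(nrow(tr))) {
      if (tr$pair_id[i] != cur) { cur <- tr$pair_id[i]; qg <- q0; qb <- q0 }
      good <- tr$chosen_good[i]
      d[i] <- if (good) qg - qb else qb - qg
      qc <- if (good) qg else qb
      qn <- qc + alpha * (tr$outcome[i] - qc)
      if (good) qg <- qn else qb <- qn
    }
    # log P(choice) = -log(1 + exp(-beta * d)), all betas at once
    ll <- -colSums(log1p(exp(-outer(d, beta_grid))))
    lp <- ll + dbeta(alpha, priors$alpha_shape1, priors$alpha_shape2,
                     log = TRUE) +
      dnorm(beta_grid, priors$beta_mean, priors$beta_sd, log = TRUE)
    j <- which.max(lp)
    if (lp[j] > best$lp) {
      best <- list(alpha = alpha, beta = beta_grid[j], lp = lp[j])
    }
  }
  best$alpha_step <- diff(alpha_grid[1:2])
  best$beta_step <- diff(beta_grid[1:2])
  best
}

# Partial Spearman by explicit residualization: regress ranks of x and y on
# covariate ranks with lm(), correlate the residuals.
partial_spearman_residual_oracle <- function(x, y, covariates) {
  z <- as.matrix(as.data.frame(covariates))
  rx <- rank(x); ry <- rank(y); rz <- apply(z, 2, rank)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  cor(ex, ey)
}

# Hand-built trial table (one condition, one block) from explicit
# choice/outcome vectors.
toy_trials <- function(chosen_good, outcome, condition = "self",
                       pair_id = "pair_01", agent_id = "toy") {
  n <- length(chosen_good)
  tibble::tibble(
    agent_id = agent_id,
    run = 1L, block = 1L, condition = condition,
    trial_in_block = seq_len(n), pair_id = pair_id,
    onset_choice_s = seq_len(n) * 10,
    onset_outcome_s = seq_len(n) * 10 + 4,
    missed = FALSE, chosen_good = chosen_good, outcome = outcome
  )
}
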