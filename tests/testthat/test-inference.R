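test_that("log-likelihood reduces to known closed forms", {
  s <- generate_session(task_config(), seed = 3)
  sim <- simulate_choices(s, rl_params(alpha = 0.4, beta = 4), seed = 8)
  tr <- sim[sim$condition == "self", ]
  # beta = 0: every choice has probability 1/2 regardless of alpha
  expect_equal(log_likelihood(tr, rl_params(alpha = 0.7, beta = 0)),
               48 * log(0.5))
  # a single trial from symmetric initial values is always 50/50
  expect_equal(log_likelihood(tr[1, ], rl_params(alpha = 0.2, beta = 9)),
               log(0.5))
})

test_that("log-likelihood matches a step-by-step hand replay", {
  tr <- toy_trials(chosen_good = c(TRUE, FALSE, TRUE),
                   outcome = c(1, -1, 1))
  # alpha = 0.3, beta = 2, q0 = 0, replayed by hand:
  # t1: q = (0, 0), chose good: p = 1/2; q_good <- 0.3
  # t2: chose bad: drive = 2 * (0 - 0.3); q_bad <- -0.3
  # t3: chose good: drive = 2 * (0.3 - (-0.3))
  ll_hand <- log(0.5) +
    log(1 / (1 + exp(2 * 0.3))) +
    log(1 / (1 + exp(-2 * 0.6)))
  p <- rl_params(alpha = 0.3, beta = 2)
  expect_equal(log_likelihood(tr, p), ll_hand, tolerance = 1e-12)
  # and the pure-R replay agrees with the compiled path
  rt <- replay_trajectory(tr, p)
  expect_equal(sum(log(rt$choice_prob)), ll_hand, tolerance = 1e-12)
})

test_that("compiled likelihood agrees with the R replay on random cases", {
  s <- generate_session(task_config(), seed = 21)
  sim <- simulate_choices(s, rl_params(alpha = 0.5, beta = 2), seed = 22,
                          miss_prob = 0.1)
  withr::with_seed(30, {
    for (i in 1:8) {
      p <- if (i %% 2 == 0) {
        rl_params(alpha = runif(1, 0.05, 0.95), beta = rnorm(1, 0, 6))
      } else {
        rl_params(alpha_gain = runif(1, 0.05, 0.95),
                  alpha_loss = runif(1, 0.05, 0.95), beta = rnorm(1, 0, 6))
      }
      for (cond in c("self", "other", "no_one")) {
        tr <- sim[sim$condition == cond, ]
        rt <- replay_trajectory(tr, p)
        expect_equal(log_likelihood(tr, p),
                     sum(log(rt$choice_prob), na.rm = TRUE),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("log-posterior adds the stated prior densities", {
  tr <- toy_trials(chosen_good = c(TRUE, TRUE, FALSE, TRUE),
                   outcome = c(1, -1, -1, 1))
  p <- rl_params(alpha = 0.5, beta = 3)
  flat <- prior_spec(alpha_shape1 = 1, alpha_shape2 = 1)
  # Beta(1,1) contributes zero: difference is the Gaussian term only
  expect_equal(log_posterior(tr, p, flat) - log_likelihood(tr, p),
               dnorm(3, 0, 10, log = TRUE))
  # Beta(1.2, 1.2) at 0.5 evaluated in closed form
  def <- prior_spec()
  beta_term_hand <- -lbeta(1.2, 1.2) + 0.2 * log(0.5) + 0.2 * log(0.5)
  expect_equal(log_posterior(tr, p, def) - log_likelihood(tr, p),
               beta_term_hand + dnorm(3, 0, 10, log = TRUE),
               tolerance = 1e-12)
  # learning rate outside (0, 1) is a rejected point, not an exception
  bad <- structure(list(variant = "one_alpha", alpha = 1.5, beta = 0),
                   class = "rl_params")
  expect_identical(log_posterior(tr, bad, def), -Inf)
})

test_that("empty choice sequences fall back to the prior", {
  empty <- toy_trials(logical(0), numeric(0))
  expect_warning(ll <- log_likelihood(empty, rl_params(alpha = 0.3, beta = 1)),
                 "prior-only")
  expect_equal(ll, 0)
  expect_warning(fit <- fit_map(empty, "one_alpha"), "prior modes")
  # modes of Beta(1.2, 1.2) and Normal(0, 10)
  expect_equal(fit$alpha, 0.5)
  expect_equal(fit$beta, 0)
  expect_true(is.na(fit$bic))
  expect_equal(fit$n_trials, 0L)
})

test_that("BIC follows its definition", {
  expect_equal(bic(48 * log(0.5), 2, 48), 74.28, tolerance = 1e-3)
  expect_equal(round(bic(48 * log(0.5), 2, 48), 2), 74.28)
  expect_equal(bic(-10, 0, 30), 20)             # no penalty without parameters
  expect_equal(bic(-10, 4, 30) - bic(-10, 2, 30), 2 * log(30))
  expect_error(bic(-10, 2, 0), "n < 1")
})

test_that("MAP fit matches the exhaustive grid-search oracle", {
  cfg <- task_config()
  withr::with_seed(60, {
    for (i in 1:3) {
      truth <- rl_params(alpha = runif(1, 0.2, 0.7), beta = runif(1, 2, 8))
      s <- generate_session(cfg, seed = sample.int(1e6, 1))
      sim <- simulate_choices(s, truth, seed = sample.int(1e6, 1))
      tr <- sim[sim$condition == "other", ]
      fit <- fit_map(tr, "one_alpha", seed = i)
      oracle <- grid_search_map(tr)
      expect_gte(fit$logpost, oracle$lp - 1e-8)
      agrees <- abs(fit$alpha - oracle$alpha) <= oracle$alpha_step &&
        abs(fit$beta - oracle$beta) <= oracle$beta_step
      expect_true(agrees || fit$logpost > oracle$lp)
      # no local-optimum regression: optimum at least as good as the truth
      expect_gte(fit$logpost,
                 log_posterior(tr, truth) - 1e-6)
      # BIC identity holds for the stored fields
      expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n_trials))
    }
  })
})

test_that("MAP is consistent at large trial counts", {
  big <- task_config(blocks_per_condition_per_run = 34) # 34*3*16 = 1632/cond
  truth <- rl_params(alpha = 0.3, beta = 5)
  s <- generate_session(big, seed = 71)
  sim <- simulate_choices(s, truth, seed = 72)
  # pool all three conditions: 4896 trials under one generating process
  fit <- fit_map(sim, "one_alpha", seed = 73)
  expect_lt(abs(fit$alpha - 0.3), 0.05)
  expect_lt(abs(fit$beta - 5) / 5, 0.15)
})

test_that("shrinking the beta prior pulls the estimate to its location", {
  s <- generate_session(task_config(), seed = 81)
  sim <- simulate_choices(s, rl_params(alpha = 0.4, beta = 6), seed = 82)
  tr <- sim[sim$condition == "self", ]
  sds <- c(10, 1, 0.1)
  betas <- vapply(sds, function(sd) {
    fit_map(tr, "one_alpha", priors = prior_spec(beta_sd = sd), seed = 1)$beta
  }, numeric(1))
  expect_true(all(diff(abs(betas - 0)) < 0)) # monotone shrinkage toward 0
})

test_that("model comparison is deterministic and prefers the simpler model on ties", {
  cohort <- dplyr::bind_rows(lapply(1:3, function(i) {
    s <- generate_session(task_config(), seed = 200 + i,
                          agent_id = sprintf("a%02d", i))
    simulate_choices(s, rl_params(alpha = 0.4, beta = 4), seed = 300 + i)
  }))
  rep1 <- compare_models(cohort, n_starts = 5, seed = 9)
  rep2 <- compare_models(cohort, n_starts = 5, seed = 9)
  expect_identical(rep1$by_agent, rep2$by_agent)
  expect_true(all(rep1$by_agent$preferred[
    rep1$by_agent$bic_one == rep1$by_agent$bic_two] == "one_alpha"))
  expect_equal(rep1$by_agent$delta_bic,
               rep1$by_agent$bic_one - rep1$by_agent$bic_two)
  expect_equal(nrow(rep1$by_condition), 3L)
})
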