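test_that("learning curves match hand counts on a toy table", {
  # 2 agents x 2 blocks x 2 trial positions, correctness laid out by hand
  toy <- tibble::tibble(
    agent_id = rep(c("a", "b"), each = 4),
    condition = "self",
    block = rep(c(1L, 2L, 1L, 2L), each = 2),
    trial_in_block = rep(1:2, 4),
    pair_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    missed = FALSE,
    chosen_good = c(TRUE, TRUE, FALSE, TRUE,   # agent a
                    TRUE, FALSE, TRUE, FALSE)  # agent b
  )
  lc <- learning_curves(toy)
  # position 1: a -> (1+0)/2 = 0.5, b -> (1+1)/2 = 1.0 -> mean 0.75
  # position 2: a -> (1+1)/2 = 1.0, b -> (0+0)/2 = 0.0 -> mean 0.5
  expect_equal(lc$fraction_correct[lc$trial_in_block == 1], 0.75)
  expect_equal(lc$fraction_correct[lc$trial_in_block == 2], 0.5)
  expect_equal(lc$n, c(2L, 2L))
  expect_equal(lc$sem[lc$trial_in_block == 1], sd(c(0.5, 1)) / sqrt(2))
})

test_that("all-correct input gives curves at one; missed trials are excluded", {
  toy <- tibble::tibble(
    agent_id = "a", condition = "other", block = 1L,
    trial_in_block = 1:4, pair_id = "p1",
    missed = c(FALSE, FALSE, TRUE, FALSE),
    chosen_good = c(TRUE, TRUE, NA, TRUE))
  lc <- learning_curves(toy)
  expect_equal(nrow(lc), 3L) # the missed position drops out entirely
  expect_true(all(lc$fraction_correct == 1))
})

test_that("value-blind agents sit at chance across the curve", {
  agents <- generate_cohort(cohort_spec(n_agents = 20, seed = 2))
  agents$beta <- 0
  trials <- simulate_cohort(agents, task_config(), seed = 3)
  lc <- learning_curves(trials)
  # every cell within 4 standard errors of chance, grand mean tight
  expect_true(all(abs(lc$fraction_correct - 0.5) < 4 * lc$sem))
  expect_lt(abs(mean(lc$fraction_correct) - 0.5), 0.02)
})

test_that("above-chance test reproduces the closed-form t statistic", {
  x <- c(0.6, 0.55, 0.7, 0.5, 0.65)
  res <- above_chance_test(x)
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(5))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 4))
  expect_equal(above_chance_test(runif(74))$df, 73)
  # zero-variance inputs are flagged, not raised
  flat <- above_chance_test(rep(0.5, 6))
  expect_equal(flat$t, 0)
  expect_true(flat$degenerate)
  high <- above_chance_test(rep(0.8, 6))
  expect_equal(high$t, Inf)
  expect_true(high$degenerate)
})

test_that("partial Spearman reduces to Spearman without covariates", {
  withr::with_seed(5, {
    x <- rnorm(30); y <- x + rnorm(30)
    expect_equal(partial_spearman(x, y)$rho,
                 cor(x, y, method = "spearman"))
  })
})

test_that("partial Spearman matches the rank-residualization oracle", {
  # fixed 8-point fixture
  x <- c(2.1, 5.3, 1.2, 9.9, 4.4, 7.7, 3.3, 6.6)
  y <- c(1.0, 4.1, 2.2, 8.8, 3.3, 9.1, 2.9, 5.5)
  z <- c(0.5, 3.8, 1.2, 0.9, 2.1, 1.8, 3.3, 2.6)
  res <- partial_spearman(x, y, z)
  expect_equal(res$rho, partial_spearman_residual_oracle(x, y, z),
               tolerance = 1e-10)
  expect_equal(res$df, 8 - 2 - 1)
  # two covariates
  z2 <- cbind(z, c(5, 2, 7, 1, 9, 3, 8, 4))
  res2 <- partial_spearman(x, y, z2)
  expect_equal(res2$rho, partial_spearman_residual_oracle(x, y, z2),
               tolerance = 1e-10)
  expect_equal(res2$df, 8 - 2 - 2)
})

test_that("partial Spearman is symmetric and rank-invariant", {
  withr::with_seed(9, {
    x <- rnorm(25); y <- rnorm(25); z <- rnorm(25)
  })
  a <- partial_spearman(x, y, z)
  expect_equal(a$rho, partial_spearman(y, x, z)$rho)
  # strictly monotone transforms leave every rank (hence rho) unchanged
  b <- partial_spearman(exp(x), y^3 + 2 * y, 5 * z - 1)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("degenerate partial-correlation inputs are flagged or rejected", {
  x <- c(2.1, 5.3, 1.2, 9.9, 4.4, 7.7, 3.3, 6.6)
  z <- c(0.5, 1.8, 0.2, 3.9, 1.1, 2.8, 0.9, 2.2)
  # y identical to the covariate: perfectly explained, degenerate limit
  res <- partial_spearman(x, z, z)
  expect_true(res$degenerate)
  expect_equal(res$rho, 0)
  expect_error(partial_spearman(x, z, rep(1, 8)), "constant covariate")
  expect_error(partial_spearman(rep(1, 8), z), "constant")
})

test_that("age trends recover exact and null relations", {
  age <- seq(9, 21, length.out = 20)
  res <- age_trend(2 * age + 1, age)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$spearman_rho, 1)
  # null calibration: independent quantity, large n
  hits <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      q <- rnorm(1000); a <- runif(1000, 9, 22)
    })
    abs(age_trend(q, a)$pearson_r) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # constant input flagged
  expect_true(age_trend(rep(2, 10), runif(10))$degenerate)
})
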