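#' Group learning curves
#'
#' Fraction of high-contingency ("correct") choices per trial position,
#' averaged across blocks within agents and then across agents, per
#' condition. Correctness is defined by which stimulus was chosen, not by the
#' realized outcome; missed trials are excluded.
#'
#' @param trials Trial table with `agent_id`, `condition`, `trial_in_block`,
#'   `chosen_good`, `missed`.
#' @return A tibble per condition x trial position: `fraction_correct`
#'   (grand mean over agents), `n` (agents contributing), `sem` (standard
#'   error of the mean over agents).
#' @export
learning_curves <- function(trials) {
  ok <- trials[!vapply(trials$missed, isTRUE, TRUE) &
                 !is.na(trials$chosen_good), , drop = FALSE]
  per_agent <- dplyr::summarise(
    dplyr::group_by(ok, .data$condition, .data$trial_in_block,
                    .data$agent_id),
    frac = mean(.data$chosen_good), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_agent, .data$condition, .data$trial_in_block),
    fraction_correct = mean(.data$frac),
    n = dplyr::n(),
    sem = sd(.data$frac) / sqrt(dplyr::n()),
    .groups = "drop")
}

#' Plot learning curves
#'
#' @param curves Output of [learning_curves()].
#' @return A ggplot object with one line per condition, ribbons of +/- 1 SEM,
#'   and a dashed chance line at 0.5.
#' @export
plot_learning_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$trial_in_block,
                               y = .data$fraction_correct,
                               colour = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fraction_correct - .data$sem,
                                      ymax = .data$fraction_correct + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial within block",
                  y = "fraction high-contingency choices") +
    ggplot2::theme_minimal()
}

#' Per-agent performance per condition
#'
#' @param trials Trial table.
#' @return Tibble per agent x condition with `fraction_correct` over all
#'   non-missed trials and `n_trials`.
#' @export
performance_summary <- function(trials) {
  ok <- trials[!vapply(trials$missed, isTRUE, TRUE) &
                 !is.na(trials$chosen_good), , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(ok, .data$agent_id, .data$condition),
    fraction_correct = mean(.data$chosen_good),
    n_trials = dplyr::n(), .groups = "drop")
}

#' One-sample t-test of performance against chance
#'
#' Tests per-agent correct-choice fractions against the chance level with a
#' two-sided one-sample t-test (`df = n - 1`). A zero-variance input is
#' degenerate: `t` is 0 when the common value equals the chance level and
#' signed infinity otherwise, flagged rather than raised.
#'
#' @param fractions Per-agent correct-choice fractions for one condition.
#' @param mu Chance level (default 0.5).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean`, `n`, `degenerate`.
#' @export
above_chance_test <- function(fractions, mu = 0.5) {
  stopifnot(is.numeric(fractions), length(fractions) >= 2L,
            !anyNA(fractions))
  n <- length(fractions)
  if (sd(fractions) == 0) {
    m <- fractions[1]
    t_val <- if (m == mu) 0 else sign(m - mu) * Inf
    return(tibble::tibble(t = t_val, df = n - 1L,
                          p_value = if (m == mu) 1 else 0,
                          mean = m, n = n, degenerate = TRUE))
  }
  tt <- t.test(fractions, mu = mu)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean = mean(fractions), n = n,
                 degenerate = FALSE)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables and computes the partial correlation of `x`
#' and `y` given the covariates from the inverse of the rank correlation
#' matrix. With no covariates this is the ordinary Spearman correlation. The
#' two-sided p-value uses the t approximation with
#' `df = n - 2 - n_covariates`. If a covariate (nearly) perfectly explains
#' `x` or `y`, the partial correlation is returned as 0 with
#' `degenerate = TRUE` rather than raising.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric vector, matrix, or data frame of
#'   control variables.
#' @return One-row tibble: `rho`, `statistic`, `df`, `p_value`, `n`,
#'   `n_covariates`, `degenerate`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
  }
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L, !anyNA(x), !anyNA(y))
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (k > 0L) {
    stopifnot(nrow(covariates) == n, !anyNA(covariates))
    if (any(apply(covariates, 2, sd) == 0)) {
      stop("constant covariate: partial correlation undefined", call. = FALSE)
    }
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant x or y: correlation undefined", call. = FALSE)
  }
  ranks <- cbind(rank(x), rank(y),
                 if (k > 0L) apply(covariates, 2, rank))
  r_mat <- cor(ranks)
  degenerate <- FALSE
  if (k == 0L) {
    rho <- r_mat[1, 2]
  } else {
    # near-collinearity of x or y with the covariates -> degenerate limit
    aux <- abs(r_mat[1:2, -(1:2), drop = FALSE])
    if (any(aux > 1 - 1e-10) || abs(det(r_mat)) < 1e-12) {
      degenerate <- TRUE
      rho <- 0
    } else {
      p_mat <- solve(r_mat)
      rho <- -p_mat[1, 2] / sqrt(p_mat[1, 1] * p_mat[2, 2])
    }
  }
  df <- n - 2L - k
  stat <- if (abs(rho) >= 1) sign(rho) * Inf else
    rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(stat), df)
  tibble::tibble(rho = rho, statistic = stat, df = df, p_value = p, n = n,
                 n_covariates = k, degenerate = degenerate)
}

#' Correlation of a per-agent quantity with age
#'
#' Screening statistic for developmental trends: Pearson and Spearman
#' correlations of a quantity against age, with p-values. Constant inputs
#' are flagged (`NA` coefficients) rather than raised.
#'
#' @param quantity Per-agent numeric vector.
#' @param age Per-agent ages (same length, >= 4).
#' @return One-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`, `degenerate`.
#' @export
age_trend <- function(quantity, age) {
  n <- length(quantity)
  stopifnot(length(age) == n, n >= 4L, !anyNA(quantity), !anyNA(age))
  if (sd(quantity) == 0 || sd(age) == 0) {
    return(tibble::tibble(pearson_r = NA_real_, pearson_p = NA_real_,
                          spearman_rho = NA_real_, spearman_p = NA_real_,
                          n = n, degenerate = TRUE))
  }
  pr <- cor.test(quantity, age, method = "pearson")
  sr <- suppressWarnings(cor.test(quantity, age, method = "spearman"))
  tibble::tibble(pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
                 spearman_rho = unname(sr$estimate), spearman_p = sr$p.value,
                 n = n, degenerate = FALSE)
}
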