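#' Moderated regression with bootstrap confidence intervals
#'
#' Tests whether a moderator `m` changes the strength of the `x` to `y`
#' relationship: ordinary least squares of `y` on mean-centred `x`, `m` and
#' their product, with a case-resampling percentile bootstrap confidence
#' interval for the interaction coefficient and simple slopes of `y` on `x`
#' evaluated at the moderator mean +/- 1 SD. Both the raw and the
#' standardized interaction coefficient (the coefficient the model would
#' have on z-scored variables) are reported, so either convention can be
#' read off.
#'
#' @param data Data frame holding the three variables.
#' @param y,x,m Column names of the dependent variable, the focal predictor
#'   and the moderator.
#' @param n_boot Number of bootstrap resamples (>= 1000; 5000 is the
#'   conventional default).
#' @param rng_seed Integer seed; identical seeds give bit-identical
#'   confidence intervals.
#' @param conf_level Confidence level for the bootstrap interval.
#' @return A `hippnet_moderation` with elements `coefficients` (tibble:
#'   intercept, x, m, interaction rows with OLS estimate/SE/p; the
#'   interaction row carries the bootstrap CI), `interaction` (list with
#'   `estimate`, `std_estimate`, `conf_low`, `conf_high`), `simple_slopes`
#'   (at moderator mean -1 SD, mean, +1 SD), `n`, `n_boot`, `rng_seed`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200), m = rnorm(200))
#' d$y <- d$x + 0.5 * d$x * d$m + rnorm(200, 0, 0.3)
#' fit <- moderation_analysis(d, "y", "x", "m", n_boot = 1000, rng_seed = 9)
#' tidy(fit)
#' @export
moderation_analysis <- function(data, y, x, m, n_boot = 5000,
                                rng_seed = NULL, conf_level = 0.95) {
  data <- tibble::as_tibble(data)
  require_columns(data, c(y, x, m), "`data`")
  dat <- data[complete.cases(data[, c(y, x, m)]), c(y, x, m)]
  n <- nrow(dat)
  if (n < 20) stop_schema("moderation analysis requires n >= 20 complete cases")
  if (!is_count(n_boot) || n_boot < 1000) stop_range("`n_boot` must be >= 1000")

  yy <- dat[[y]]
  xc <- dat[[x]] - mean(dat[[x]])
  mc <- dat[[m]] - mean(dat[[m]])
  X <- cbind(`(Intercept)` = 1, x = xc, m = mc, `x:m` = xc * mc)
  if (qr(X)$rank < 4L) stop_collinear("near-singular moderation design (x, m, x*m)")

  fit <- lm(yy ~ xc + mc + xc:mc)
  b <- coef(fit); V <- vcov(fit); dfres <- df.residual(fit)
  se <- sqrt(diag(V))
  pvals <- 2 * pt(-abs(b / se), dfres)

  # percentile bootstrap (case resampling) for the interaction coefficient
  boot_est <- with_rng(rng_seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    vapply(seq_len(n_boot), function(j) {
      ii <- idx[, j]
      cf <- tryCatch(.lm.fit(X[ii, , drop = FALSE], yy[ii])$coefficients,
                     error = function(e) rep(NA_real_, 4))
      cf[4]
    }, numeric(1))
  })
  boot_est <- boot_est[is.finite(boot_est)]
  alpha2 <- (1 - conf_level) / 2
  ci <- unname(quantile(boot_est, c(alpha2, 1 - alpha2), names = FALSE))

  sd_m <- sd(mc)
  std_int <- b[[4]] * sd(xc) * sd_m / sd(yy)
  slopes <- tibble::tibble(
    at = c("mean - 1 SD", "mean", "mean + 1 SD"),
    moderator_value = mean(dat[[m]]) + c(-sd_m, 0, sd_m),
    slope = b[[2]] + b[[4]] * c(-sd_m, 0, sd_m),
    std_error = sqrt(V[2, 2] + c(-sd_m, 0, sd_m)^2 * V[4, 4] +
                       2 * c(-sd_m, 0, sd_m) * V[2, 4])
  )
  slopes$statistic <- slopes$slope / slopes$std_error
  slopes$p_value <- 2 * pt(-abs(slopes$statistic), dfres)

  coefs <- tibble::tibble(
    term = c("(Intercept)", x, m, paste0(x, ":", m)),
    estimate = unname(b), std_error = unname(se),
    statistic = unname(b / se), p_value = unname(pvals),
    conf_low = c(NA, NA, NA, ci[1]),
    conf_high = c(NA, NA, NA, ci[2])
  )

  structure(list(
    coefficients = coefs,
    interaction = list(estimate = b[[4]], std_estimate = std_int,
                       conf_low = ci[1], conf_high = ci[2],
                       n_boot_effective = length(boot_est)),
    simple_slopes = slopes,
    variables = c(y = y, x = x, m = m),
    r_squared = summary(fit)$r.squared,
    n = n, n_boot = as.integer(n_boot), rng_seed = rng_seed,
    conf_level = conf_level
  ), class = "hippnet_moderation")
}

#' @export
print.hippnet_moderation <- function(x, ...) {
  v <- x$variables
  cat(sprintf("<hippnet_moderation> %s ~ %s moderated by %s (n = %d, %d bootstrap draws)\n",
              v["y"], v["x"], v["m"], x$n, x$n_boot))
  cat(sprintf("  interaction: %.4f (std. %.4f), %g%% bootstrap CI [%.4f, %.4f]\n",
              x$interaction$estimate, x$interaction$std_estimate,
              100 * x$conf_level, x$interaction$conf_low, x$interaction$conf_high))
  invisible(x)
}

#' @rdname moderation_analysis
#' @param x A `hippnet_moderation` object.
#' @param ... Unused.
#' @method tidy hippnet_moderation
#' @export
tidy.hippnet_moderation <- function(x, ...) x$coefficients

#' @rdname moderation_analysis
#' @method glance hippnet_moderation
#' @export
glance.hippnet_moderation <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, n_boot = x$n_boot,
                 conf_level = x$conf_level,
                 std_interaction = x$interaction$std_estimate)
}
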