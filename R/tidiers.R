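# broom-style tidiers for fitted result objects.

#' @describeIn meta_analyze one-row tibble of the pooled estimate.
#' @param x a `meta_result`.
#' @param ... unused.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble(
    model = x$model, estimate = x$pooled_log_or, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p_value
  )
}

#' @describeIn meta_analyze one-row model summary (heterogeneity).
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble(k = x$k, Q = x$Q, tau2 = x$tau2, model = x$model)
}

#' @describeIn group_prs_test one-row tibble of the test.
#' @param x a `group_test`.
#' @param ... unused.
#' @method tidy group_test
#' @export
tidy.group_test <- function(x, ...) {
  tibble(
    test = x$test, statistic = x$statistic, p.value = x$p_value,
    df = x$df, degenerate = x$degenerate
  )
}

#' @describeIn group_prs_test per-group summary tibble.
#' @method glance group_test
#' @export
glance.group_test <- function(x, ...) x$groups

#' @describeIn ancestry_prs_regression term estimates of the fit.
#' @param x an `ancestry_regression`.
#' @param ... unused.
#' @method tidy ancestry_regression
#' @export
tidy.ancestry_regression <- function(x, ...) {
  tibble(
    term = c("intercept", x$ancestry),
    estimate = c(x$intercept, x$slope)
  )
}

#' @describeIn ancestry_prs_regression one-row fit summary.
#' @method glance ancestry_regression
#' @export
glance.ancestry_regression <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, p.value = x$p_value, n = x$n)
}

#' @describeIn bootstrap_meta one-row tibble of the replicate summary.
#' @param x a `null_distribution`.
#' @param ... unused.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(
    kind = x$kind, n_replicates = x$n_replicates, observed = x$observed,
    null_mean = x$z_test$mean, null_sd = x$z_test$sd,
    z = x$z_test$z, p.value = x$z_test$p
  )
}
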