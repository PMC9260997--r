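# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a difference-in-differences fit
#'
#' @param x A `did_fit` from [fit_did()].
#' @param ... Unused.
#' @returns One row per coefficient (`intercept`, `condition`, `assessment`,
#'   `did`) with estimate, standard error, t statistic, p-value, and
#'   confidence bounds.
#' @export
tidy.did_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.did_fit
#' @export
glance.did_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(r_squared = s$r.squared, sigma = s$sigma, n = x$n,
         df_residual = x$lm$df.residual, conf_level = x$conf_level)
}

#' Tidy a plausibility model fit
#'
#' @param x A `model_fit` from [backward_stepwise()] or
#'   [select_plausibility_model()].
#' @param ... Unused.
#' @returns Coefficient rows / model-level summary.
#' @export
tidy.model_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.model_fit
#' @export
glance.model_fit <- function(x, ...) {
  tibble(outcome = x$outcome,
         predictors = paste(x$predictors, collapse = "+"),
         r_squared = x$r_squared, aic = x$aic, n = x$n,
         df_residual = x$df_residual)
}

#' Tidy a moderated-mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @returns `tidy()`: one row per path coefficient of both equations, with
#'   bootstrap intervals joined for the derived effects when available.
#'   `glance()`: one row with component R-squared, F tests, AIC, and n.
#' @export
tidy.mediation_fit <- function(x, ...) {
  eqs <- list()
  if (!is.null(x$mediator_eq)) {
    eqs$mediator <- mutate(x$mediator_eq$coefficients, equation = "mediator",
                           .before = 1)
  }
  eqs$outcome <- mutate(x$outcome_eq$coefficients, equation = "outcome",
                        .before = 1)
  paths <- bind_rows(eqs)
  effects <- x$effects |>
    transmute(equation = "effects", term = .data$effect,
              estimate = .data$estimate)
  if (!is.null(x$boot)) {
    effects <- effects |>
      left_join(select(x$boot$intervals, term = "effect",
                       "conf_low", "conf_high"),
                by = "term")
  }
  bind_rows(paths, effects)
}

#' @rdname tidy.mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble(
    type = x$type,
    r_squared_mediator = unname(x$r_squared["mediator"]),
    r_squared_outcome = unname(x$r_squared[length(x$r_squared)]),
    f_p_mediator = if ("mediator" %in% x$f_tests$equation)
      x$f_tests$p_value[x$f_tests$equation == "mediator"] else NA_real_,
    f_p_outcome = x$f_tests$p_value[x$f_tests$equation == "outcome"],
    aic_total = unname(x$aic["total"]),
    n = x$n)
}
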