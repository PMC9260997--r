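# Moderated mediation: change in brain activity (an EEG composite) mediates
# the effect of change in ferritin on change in behavior, with change in
# hemoglobin moderating both ferritin paths. Two OLS equations:
#   M ~ X + W + X:W                     (mediator equation, paths a0..a3)
#   Y ~ X + W + X:W + M                 (outcome equation, b0, c1..c3, b_M)
# The mediator-to-outcome path carries no moderation. Effects: direct = c1
# (at W = 0), indirect = a1 * b_M (at W = 0), index of moderated mediation =
# a3 * b_M, conditional indirect IE(w) = (a1 + a3 * w) * b_M.

#' Specify a moderated-mediation model
#'
#' @param x Predictor column (default: Z change in serum ferritin).
#' @param m Mediator column (an EEG composite).
#' @param w Moderator column (default: Z change in hemoglobin).
#' @param y Outcome column (a behavioral composite).
#' @returns A `mediation_spec` list.
#' @export
mediation_spec <- function(x = "z_dsft", m, w = "z_dhb", y) {
  cols <- c(x = x, m = m, w = w, y = y)
  if (anyDuplicated(cols)) abort("x, m, w, y must be distinct columns.")
  structure(as.list(cols), class = "mediation_spec")
}

# Build a design matrix from role columns: terms drawn from
# c("x", "w", "xw", "m").
med_design <- function(dat, terms) {
  cols <- lapply(terms, function(t) {
    switch(t, x = dat$x, w = dat$w, xw = dat$x * dat$w, m = dat$m,
           abort(sprintf("unknown mediation term '%s'", t)))
  })
  mm <- cbind(1, do.call(cbind, cols))
  colnames(mm) <- c("(Intercept)", terms)
  mm
}

# OLS with coefficient table; errors on rank deficiency.
med_ols <- function(mm, y, label) {
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    abort(sprintf("rank-deficient design in the %s equation.", label))
  }
  beta <- qr.coef(qr_, y)
  res <- y - drop(mm %*% beta)
  n <- length(y)
  k <- ncol(mm)
  rss <- sum(res^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tstat <- beta / se
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  f_stat <- ((tss - rss) / (k - 1)) / sigma2
  list(
    coefficients = tibble(
      term = colnames(mm), estimate = unname(beta), std_error = unname(se),
      statistic = unname(tstat),
      p_value = 2 * pt(abs(unname(tstat)), n - k, lower.tail = FALSE)),
    r_squared = r2, rss = rss, n = n, k = k,
    f_statistic = f_stat, f_df = c(k - 1, n - k),
    f_p = pf(f_stat, k - 1, n - k, lower.tail = FALSE),
    aic = ols_aic(rss, n, k))
}

coef_of <- function(eq, term) {
  i <- match(term, eq$coefficients$term)
  if (is.na(i)) 0 else eq$coefficients$estimate[i]
}

#' Fit a moderated-mediation model
#'
#' Fits the two least-squares equations by QR decomposition and derives the
#' direct, indirect, and moderated (index) effects. Columns are optionally
#' standardized to mean 0 / SD 1 first (the default, matching the
#' Z-transformed pipeline inputs); set `standardize = FALSE` to estimate
#' path coefficients on the columns' native scale.
#'
#' @param data A data frame holding the spec's columns (e.g. the output of
#'   [build_composites()]).
#' @param spec A [mediation_spec()].
#' @param standardize Standardize the four columns before fitting.
#' @param mediator_terms Terms of the mediator equation (subset of
#'   `c("x", "w", "xw")`, always containing `"x"`).
#' @param outcome_terms Terms of the outcome equation (subset of
#'   `c("x", "w", "xw", "m")`, always containing `"x"` and `"m"`).
#' @returns A `mediation_fit` with the coefficient tables of both equations,
#'   effects (`direct`, `indirect`, `index`), the conditional indirect
#'   effect at moderator values -1, 0, +1, per-equation R-squared, overall F
#'   tests, and AIC (per equation and total).
#' @export
fit_mediation <- function(data, spec, standardize = TRUE,
                          mediator_terms = c("x", "w", "xw"),
                          outcome_terms = c("x", "w", "xw", "m")) {
  if (!inherits(spec, "mediation_spec")) abort("`spec` must be a mediation_spec.")
  if (!"x" %in% mediator_terms) abort("the mediator equation must contain x.")
  if (!all(c("x", "m") %in% outcome_terms)) {
    abort("the outcome equation must contain x and m.")
  }
  missing_cols <- setdiff(unlist(spec), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns absent from `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat <- tibble(x = data[[spec$x]], w = data[[spec$w]],
                m = data[[spec$m]], y = data[[spec$y]])
  dat <- dat[complete.cases(dat), ]
  n_par <- length(outcome_terms) + 1L
  if (nrow(dat) < n_par + 10) abort("insufficient complete cases.")
  if (standardize) {
    dat <- mutate(dat, across(everything(),
                              \(v) (v - mean(v)) / sd(v)))
  }
  eq_m <- med_ols(med_design(dat, mediator_terms), dat$m, "mediator")
  eq_y <- med_ols(med_design(dat, outcome_terms), dat$y, "outcome")
  a1 <- coef_of(eq_m, "x"); a3 <- coef_of(eq_m, "xw")
  b_m <- coef_of(eq_y, "m")
  effects <- tibble(
    effect = c("direct", "indirect", "index"),
    estimate = c(coef_of(eq_y, "x"), a1 * b_m, a3 * b_m))
  conditional <- tibble(w = c(-1, 0, 1),
                        indirect = (a1 + a3 * c(-1, 0, 1)) * b_m)
  structure(
    list(spec = spec, type = "mediation",
         mediator_terms = mediator_terms, outcome_terms = outcome_terms,
         mediator_eq = eq_m, outcome_eq = eq_y,
         effects = effects, conditional_indirect = conditional,
         r_squared = c(mediator = eq_m$r_squared, outcome = eq_y$r_squared),
         f_tests = tibble(
           equation = c("mediator", "outcome"),
           statistic = c(eq_m$f_statistic, eq_y$f_statistic),
           df1 = c(eq_m$f_df[1], eq_y$f_df[1]),
           df2 = c(eq_m$f_df[2], eq_y$f_df[2]),
           p_value = c(eq_m$f_p, eq_y$f_p)),
         aic = c(mediator = eq_m$aic, outcome = eq_y$aic,
                 total = eq_m$aic + eq_y$aic),
         n = nrow(dat), standardize = standardize, data = dat),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    "Moderated mediation: %s -> %s -> %s (moderator %s), n = %d\n",
    x$spec$x, x$spec$m, x$spec$y, x$spec$w, x$n))
  cat(sprintf("R^2 mediator %.3f, outcome %.3f; total AIC %.2f\n",
              x$r_squared["mediator"], x$r_squared["outcome"],
              x$aic["total"]))
  print(x$effects, ...)
  invisible(x)
}

#' Fit the direct-effect-only falsification model
#'
#' `Y ~ X` with no mediator or moderator, fitted on the same cases and with
#' the same standardization as the mediated model it is compared against.
#'
#' @inheritParams fit_mediation
#' @returns A `mediation_fit` of type `"direct_only"` (mediator-equation
#'   fields absent).
#' @export
fit_direct_only <- function(data, spec, standardize = TRUE) {
  if (!inherits(spec, "mediation_spec")) abort("`spec` must be a mediation_spec.")
  dat <- tibble(x = data[[spec$x]], w = data[[spec$w]],
                m = data[[spec$m]], y = data[[spec$y]])
  dat <- dat[complete.cases(dat), ]
  if (standardize) {
    dat <- mutate(dat, across(everything(), \(v) (v - mean(v)) / sd(v)))
  }
  eq_y <- med_ols(med_design(dat, "x"), dat$y, "outcome")
  structure(
    list(spec = spec, type = "direct_only", outcome_terms = "x",
         outcome_eq = eq_y,
         effects = tibble(effect = c("direct", "indirect", "index"),
                          estimate = c(coef_of(eq_y, "x"), 0, 0)),
         r_squared = c(outcome = eq_y$r_squared),
         f_tests = tibble(equation = "outcome",
                          statistic = eq_y$f_statistic,
                          df1 = eq_y$f_df[1], df2 = eq_y$f_df[2],
                          p_value = eq_y$f_p),
         aic = c(outcome = eq_y$aic, total = eq_y$aic),
         n = nrow(dat), standardize = standardize, data = dat),
    class = "mediation_fit")
}

#' Build the falsification alternatives of a mediation specification
#'
#' The direct-only model drops the mediator and moderator entirely; the
#' scrambled model cyclically rotates the variable roles of the best-fitting
#' model (the outcome takes the predictor role, the predictor the mediator
#' role, the mediator the outcome role; the moderator is unchanged) and is
#' refitted with the same machinery. A causally correct mediation structure
#' should describe the data better than its rotation.
#'
#' @inheritParams fit_mediation
#' @returns A list with elements `direct_only` and `scrambled` (both
#'   `mediation_fit` objects) and `scrambled_spec`.
#' @export
mediation_alternatives <- function(data, spec, standardize = TRUE) {
  scrambled_spec <- mediation_spec(x = spec$y, m = spec$x, w = spec$w,
                                   y = spec$m)
  list(
    direct_only = fit_direct_only(data, spec, standardize = standardize),
    scrambled = fit_mediation(data, scrambled_spec,
                              standardize = standardize),
    scrambled_spec = scrambled_spec)
}

#' Percentile bootstrap confidence intervals for mediation effects
#'
#' Nonparametric case resampling of subjects: both equations are refitted on
#' each resample and the 2.5/97.5 (for `conf = 0.95`) percentiles of the
#' direct, indirect, and index-of-moderated-mediation distributions are
#' taken. Percentile (not bias-corrected) intervals are used; they are
#' asymmetric, as product-of-coefficients sampling distributions require.
#'
#' @param fit A `mediation_fit` from [fit_mediation()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; resampling is fully reproducible.
#' @param conf Confidence level.
#' @returns `fit` with an added `boot` element: tibble of effect, estimate,
#'   `conf_low`, `conf_high`, plus the replicate matrix dimensions and the
#'   count of degenerate replicates.
#' @export
bootstrap_mediation <- function(fit, n_boot = 5000, seed = 1, conf = 0.95) {
  if (!inherits(fit, "mediation_fit") || fit$type != "mediation") {
    abort("`fit` must be a mediated model from fit_mediation().")
  }
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  dat <- fit$data
  n <- nrow(dat)
  mm_m <- med_design(dat, fit$mediator_terms)
  mm_y <- med_design(dat, fit$outcome_terms)
  i_a1 <- match("x", fit$mediator_terms) + 1L
  i_a3 <- match("xw", fit$mediator_terms) + 1L
  i_c1 <- match("x", fit$outcome_terms) + 1L
  i_bm <- match("m", fit$outcome_terms) + 1L
  m_vec <- dat$m
  y_vec <- dat$y
  xw_col <- match("xw", fit$outcome_terms) + 1L # refresh m column below
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  out <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                dimnames = list(NULL, c("direct", "indirect", "index")))
  bad <- 0L
  for (b in seq_len(n_boot)) {
    idx <- draws[, b]
    fm <- stats::.lm.fit(mm_m[idx, , drop = FALSE], m_vec[idx])
    fy <- stats::.lm.fit(mm_y[idx, , drop = FALSE], y_vec[idx])
    if (fm$rank < ncol(mm_m) || fy$rank < ncol(mm_y)) {
      bad <- bad + 1L
      next
    }
    a1 <- fm$coefficients[i_a1]
    a3 <- if (is.na(i_a3)) 0 else fm$coefficients[i_a3]
    out[b, ] <- c(fy$coefficients[i_c1],
                  a1 * fy$coefficients[i_bm],
                  a3 * fy$coefficients[i_bm])
  }
  if (bad / n_boot > 0.01) {
    abort(sprintf(
      "%d of %d bootstrap replicates were rank deficient (> 1%%); the design is too fragile to bootstrap.",
      bad, n_boot))
  }
  alpha <- (1 - conf) / 2
  qs <- apply(out, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  fit$boot <- list(
    intervals = tibble(
      effect = c("direct", "indirect", "index"),
      estimate = fit$effects$estimate,
      conf_low = unname(qs[1, ]), conf_high = unname(qs[2, ])),
    n_boot = n_boot, n_bad = bad, conf = conf, seed = seed)
  fit
}

#' Prune non-significant moderation terms and refit
#'
#' Iteratively removes the least significant moderation term (the moderator
#' main effect or the predictor-by-moderator interaction, in either
#' equation) with p-value at or above `alpha` and refits, keeping the
#' structural paths (predictor and mediator) in place — their significance
#' is judged by the selection criteria, not removed silently.
#'
#' @param fit A `mediation_fit`.
#' @param data The data frame the fit was built from.
#' @param alpha Per-term significance threshold.
#' @returns A refitted `mediation_fit` (possibly unchanged).
#' @export
prune_mediation <- function(fit, data, alpha = 0.05) {
  mt <- fit$mediator_terms
  ot <- fit$outcome_terms
  repeat {
    f <- fit_mediation(data, fit$spec, standardize = fit$standardize,
                       mediator_terms = mt, outcome_terms = ot)
    cand <- bind_rows(
      f$mediator_eq$coefficients |>
        filter(.data$term %in% c("w", "xw")) |> mutate(eq = "m"),
      f$outcome_eq$coefficients |>
        filter(.data$term %in% c("w", "xw")) |> mutate(eq = "y"))
    cand <- filter(cand, .data$p_value >= alpha)
    if (nrow(cand) == 0) return(f)
    worst <- cand[which.max(cand$p_value), ]
    if (worst$eq == "m") mt <- setdiff(mt, worst$term)
    else ot <- setdiff(ot, worst$term)
  }
}

#' Select the best mediation model
#'
#' Applies the selection criteria to a set of candidate fits: (a) the
#' overall F statistic of every component equation must be significant at
#' `alpha`; (b) every component R-squared must be at least `r2_floor`; (c)
#' every non-intercept parameter must differ significantly from zero; and
#' (d) the chosen model must outperform all alternatives — lower total AIC
#' than every other two-equation candidate, and a lower outcome-equation AIC
#' than every direct-only candidate (whose single equation shares the same
#' response). Exact AIC ties are broken by fewer parameters.
#'
#' @param candidates Named list of `mediation_fit` objects (mediated,
#'   direct-only, scrambled).
#' @param alpha Significance threshold for criteria (a) and (c).
#' @param r2_floor Minimum component R-squared for criterion (b).
#' @returns A list of class `mediation_selection`: `best` (a
#'   `mediation_fit`, or `NULL` when no candidate meets all criteria),
#'   `best_name`, and `verdicts` (per-candidate criterion table).
#' @export
select_mediation_model <- function(candidates, alpha = 0.05,
                                   r2_floor = 0.10) {
  if (length(candidates) == 0) abort("empty candidate list.")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("model_", seq_along(candidates))
  }
  ns <- vapply(candidates, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) {
    abort("candidates were fitted on different case sets.")
  }
  verdicts <- purrr::imap_dfr(candidates, function(f, nm) {
    coefs <- bind_rows(
      if (!is.null(f$mediator_eq)) f$mediator_eq$coefficients,
      f$outcome_eq$coefficients) |>
      filter(.data$term != "(Intercept)")
    n_params <- nrow(coefs) +
      length(f$f_tests$equation) # intercepts
    tibble(
      model = nm, type = f$type,
      f_ok = all(f$f_tests$p_value < alpha),
      r2_ok = all(f$r_squared >= r2_floor),
      terms_ok = all(coefs$p_value < alpha),
      r2_outcome = unname(f$r_squared[length(f$r_squared)]),
      aic_outcome = unname(f$aic["outcome"]),
      aic_total = unname(f$aic["total"]),
      n_params = n_params)
  })
  mediated <- verdicts |>
    filter(.data$type == "mediation",
           .data$f_ok, .data$r2_ok, .data$terms_ok)
  best <- NULL
  best_name <- NA_character_
  if (nrow(mediated)) {
    ord <- order(mediated$aic_total, mediated$n_params)
    cand_row <- mediated[ord[1], ]
    others <- filter(verdicts, .data$model != cand_row$model)
    two_eq <- filter(others, .data$type != "direct_only")
    one_eq <- filter(others, .data$type == "direct_only")
    outperforms <-
      (nrow(two_eq) == 0 || all(cand_row$aic_total < two_eq$aic_total |
                                  (cand_row$aic_total == two_eq$aic_total &
                                     cand_row$n_params < two_eq$n_params))) &&
      (nrow(one_eq) == 0 || all(cand_row$aic_outcome < one_eq$aic_outcome))
    if (outperforms) {
      best_name <- cand_row$model
      best <- candidates[[best_name]]
    }
  }
  structure(list(best = best, best_name = best_name, verdicts = verdicts),
            class = "mediation_selection")
}

#' @export
print.mediation_selection <- function(x, ...) {
  if (is.null(x$best)) {
    cat("Mediation model selection: no candidate meets all criteria.\n")
  } else {
    cat(sprintf("Mediation model selection: best = '%s'.\n", x$best_name))
  }
  print(x$verdicts, ...)
  invisible(x)
}
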