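# Plausibility regressions: change in each behavioral/EEG variable regressed
# on change in the iron biomarkers, with a constrained candidate space
# (ferritin and sTfR never co-occur with body iron, which is derived from
# them), backward stepwise pruning, and AIC + R-squared selection criteria.

#' Gaussian OLS AIC
#'
#' `n * log(RSS / n) + 2 * (k + 1)` where `k` counts estimated mean
#' parameters (including the intercept) and the extra 1 is the error
#' variance. Constant terms are dropped, so only AIC differences between
#' models on the same cases are meaningful.
#'
#' @param rss Residual sum of squares.
#' @param n Number of cases.
#' @param k Number of mean parameters including the intercept.
#' @returns The AIC value.
#' @export
ols_aic <- function(rss, n, k) {
  check_number(rss, "rss")
  if (rss < 0) abort("`rss` must be non-negative.")
  n * log(rss / n) + 2 * (k + 1)
}

#' Enumerate allowable biomarker predictor subsets
#'
#' All subsets of the requested biomarkers, including the empty (null-model)
#' set, excluding any subset that contains body iron (`bdfe`) together with
#' ferritin (`sft`) or sTfR (`stfr`) — body iron is computed from those two
#' markers, so mixing them would double-count the same assays.
#'
#' @param predictors Character vector drawn from
#'   `c("hb", "sft", "stfr", "bdfe")`.
#' @returns A list of character vectors (the first is the empty set).
#' @examples
#' length(enumerate_allowable(c("hb", "sft", "stfr", "bdfe"))) # 10
#' @export
enumerate_allowable <- function(predictors = c("hb", "sft", "stfr", "bdfe")) {
  known <- c("hb", "sft", "stfr", "bdfe")
  bad <- setdiff(predictors, known)
  if (length(bad)) {
    abort(paste0("unknown predictor name(s): ", paste(bad, collapse = ", ")))
  }
  predictors <- unique(predictors)
  subsets <- list(character(0))
  for (k in seq_along(predictors)) {
    subsets <- c(subsets,
                 combn(predictors, k, simplify = FALSE))
  }
  keep <- vapply(subsets, function(s) {
    !("bdfe" %in% s && any(c("sft", "stfr") %in% s))
  }, logical(1))
  subsets[keep]
}

# Fit one OLS model of `outcome` on `terms` (columns of `data`) and return a
# model_fit record. Complete cases only; `data` must already be restricted
# to the common case set when models are to be compared.
fit_change_model <- function(data, outcome, terms) {
  stopifnot(outcome %in% names(data))
  y <- data[[outcome]]
  if (length(terms) == 0) {
    fit <- lm(y ~ 1)
  } else {
    fml <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
    fit <- lm(fml, data = data)
  }
  n <- length(y)
  k <- length(coef(fit))
  rss <- sum(resid(fit)^2)
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
  structure(
    list(outcome = outcome, predictors = terms, coefficients = coefs,
         r_squared = summary(fit)$r.squared, aic = ols_aic(rss, n, k),
         rss = rss, n = n, df_residual = fit$df.residual, lm = fit),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s  (n = %d, R^2 = %.3f, AIC = %.2f)\n",
              x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1",
              x$n, x$r_squared, x$aic))
  print(x$coefficients, ...)
  invisible(x)
}

#' Backward stepwise elimination
#'
#' Starting from `start_set` plus any covariates, repeatedly refits after
#' dropping the least significant term whose p-value is at or above `alpha`,
#' until every retained non-intercept term is significant. The body-iron
#' exclusion constraint holds throughout because terms are only ever removed
#' from an allowable starting set.
#'
#' @param data A data frame of per-subject change scores; column names are
#'   used as terms.
#' @param outcome Name of the outcome column.
#' @param start_set Character vector of starting predictor columns (must be
#'   an allowable subset for biomarker predictors).
#' @param covariates Optional covariate columns (e.g. age, sex) subject to
#'   the same retain-if-significant rule.
#' @param alpha Per-term retention threshold.
#' @returns A `model_fit` (possibly intercept-only).
#' @export
backward_stepwise <- function(data, outcome, start_set,
                              covariates = character(0), alpha = 0.05) {
  biomarkers <- intersect(start_set, c("hb", "sft", "stfr", "bdfe"))
  if ("bdfe" %in% biomarkers && any(c("sft", "stfr") %in% biomarkers)) {
    abort("`start_set` violates the body-iron exclusion constraint.")
  }
  terms <- unique(c(start_set, covariates))
  data <- data[complete.cases(data[c(outcome, terms)]), , drop = FALSE]
  if (nrow(data) <= length(terms) + 3) abort("insufficient cases for stepwise fit.")
  num_terms <- terms[vapply(data[terms], is.numeric, logical(1))]
  if (length(num_terms)) {
    mm <- as.matrix(data[num_terms])
    if (qr(cbind(1, mm))$rank < length(num_terms) + 1) {
      abort("collinear predictors in `start_set`.")
    }
  }
  repeat {
    fit <- fit_change_model(data, outcome, terms)
    ps <- fit$coefficients |> filter(.data$term != "(Intercept)")
    if (nrow(ps) == 0 || all(ps$p_value < alpha)) return(fit)
    drop_term <- ps$term[which.max(ps$p_value)]
    # factor covariates expand to dummy names; map back to the column
    drop_col <- terms[vapply(terms, function(t) startsWith(drop_term, t),
                             logical(1))][1]
    terms <- setdiff(terms, drop_col)
  }
}

#' Select the best plausibility model for one outcome
#'
#' Candidates are the null (intercept-only) model, each maximal allowable
#' biomarker set (`hb + sft + stfr`, and `hb + bdfe`), and a backward
#' stepwise fit from each maximal set. The chosen model must (i) have a
#' strictly lower AIC than the null model, (ii) have the lowest AIC among
#' all candidates, and (iii) account for at least `r2_floor` of the
#' variance; otherwise the verdict is "none acceptable". Exact AIC ties are
#' broken by fewer parameters.
#'
#' @inheritParams backward_stepwise
#' @param predictors Biomarker change columns available as predictors.
#' @param r2_floor Minimum acceptable R-squared.
#' @returns A list of class `selection_result` with elements `chosen` (a
#'   `model_fit` or `NULL`), `acceptable` (logical), and `candidates` (tibble
#'   of predictor sets with AIC and R-squared).
#' @export
select_plausibility_model <- function(data, outcome,
                                      predictors = c("hb", "sft", "stfr",
                                                     "bdfe"),
                                      covariates = character(0),
                                      alpha = 0.05, r2_floor = 0.10) {
  predictors <- intersect(predictors, names(data))
  keep <- complete.cases(data[c(outcome, predictors)])
  data <- data[keep, , drop = FALSE]
  allowable <- enumerate_allowable(predictors)
  sizes <- vapply(allowable, length, integer(1))
  maximal <- allowable[vapply(allowable, function(s) {
    !any(vapply(allowable, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))]
  cands <- list(null = fit_change_model(data, outcome, character(0)))
  for (i in seq_along(maximal)) {
    nm <- paste0("full_", paste(maximal[[i]], collapse = "_"))
    cands[[nm]] <- fit_change_model(data, outcome, maximal[[i]])
    sw <- backward_stepwise(data, outcome, maximal[[i]],
                            covariates = covariates, alpha = alpha)
    cands[[paste0("stepwise_", i)]] <- sw
  }
  info <- purrr::imap_dfr(cands, function(f, nm) {
    tibble(candidate = nm,
           predictors = paste(f$predictors, collapse = "+"),
           n_params = length(f$predictors) + 1L,
           r_squared = f$r_squared, aic = f$aic)
  })
  aics <- info$aic
  best_aic <- min(aics)
  in_tie <- which(aics <= best_aic + 1e-9)
  best_i <- in_tie[which.min(info$n_params[in_tie])]
  best <- cands[[best_i]]
  acceptable <- info$candidate[best_i] != "null" &&
    best$aic < cands$null$aic &&
    best$r_squared >= r2_floor
  structure(
    list(chosen = if (acceptable) best else NULL,
         acceptable = acceptable, candidates = info, outcome = outcome),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Model selection for '%s': %s\n", x$outcome,
              if (x$acceptable) "acceptable model found" else "none acceptable"))
  print(x$candidates, ...)
  invisible(x)
}

#' Plausibility regression table across outcomes
#'
#' Runs [select_plausibility_model()] on the change score of every requested
#' variable, regressing on the biomarker changes (`hb`, `sft`, `stfr`,
#' `bdfe`), and reports one row per retained predictor for every outcome
#' with an acceptable model — outcomes without one are omitted, mirroring
#' the published table's convention.
#'
#' @inheritParams did_table
#' @param outcomes Variables whose change scores are modelled (default: all
#'   non-biomarker variables).
#' @param include_covariates If `TRUE`, age and sex enter the stepwise
#'   procedure as candidate covariates.
#' @inheritParams select_plausibility_model
#' @returns A tibble: `outcome`, `predictor`, `intercept`, `beta`,
#'   `r_squared`, `n`.
#' @export
plausibility_table <- function(cohort, outcomes = NULL,
                               include_covariates = FALSE,
                               alpha = 0.05, r2_floor = 0.10) {
  changes <- change_scores(cohort)
  wide <- changes |>
    tidyr::pivot_wider(id_cols = c("subject_id", "group", "sex", "age"),
                       names_from = "variable", values_from = "delta")
  biomarkers <- intersect(c("hb", "sft", "stfr", "bdfe"), names(wide))
  if (is.null(outcomes)) {
    outcomes <- setdiff(unique(changes$variable), biomarkers)
  }
  wide$sex_male <- as.numeric(wide$sex == "male")
  covars <- if (include_covariates) c("age", "sex_male") else character(0)
  purrr::map_dfr(outcomes, function(v) {
    sel <- select_plausibility_model(wide, v, predictors = biomarkers,
                                     covariates = covars, alpha = alpha,
                                     r2_floor = r2_floor)
    if (!sel$acceptable) return(tibble())
    fit <- sel$chosen
    intercept <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
    fit$coefficients |>
      filter(.data$term != "(Intercept)") |>
      transmute(outcome = v, predictor = .data$term,
                intercept = intercept, beta = .data$estimate,
                r_squared = fit$r_squared, n = fit$n)
  })
}
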