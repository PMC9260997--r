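# 2x2 group-by-assessment difference-in-differences contrasts, baseline
# comparison tests, and normalized change-difference summaries.

#' Difference-in-differences contrasts from the four cell means
#'
#' Given the CPM/BPM x BL/EL cell means of one variable, returns the three
#' contrasts of a saturated 2x2 model with BPM and BL as reference levels:
#' `condition = CPM_BL - BPM_BL` (group difference at baseline),
#' `assessment = BPM_EL - BPM_BL` (change in the reference group), and
#' `did = (CPM_EL - CPM_BL) - (BPM_EL - BPM_BL)` (the interaction). These
#' reference levels reproduce the Condition / Assessment / Differences
#' columns of the trial's published contrast tables.
#'
#' @param cpm_bl,bpm_bl,cpm_el,bpm_el Cell means.
#' @returns A tibble with columns `condition`, `assessment`, `did`.
#' @examples
#' did_from_cells(cpm_bl = 627, bpm_bl = 661, cpm_el = 592, bpm_el = 546)
#' @export
did_from_cells <- function(cpm_bl, bpm_bl, cpm_el, bpm_el) {
  args <- list(cpm_bl = cpm_bl, bpm_bl = bpm_bl,
               cpm_el = cpm_el, bpm_el = bpm_el)
  for (nm in names(args)) check_number(args[[nm]], nm)
  tibble(
    condition = cpm_bl - bpm_bl,
    assessment = bpm_el - bpm_bl,
    did = (cpm_el - cpm_bl) - (bpm_el - bpm_bl)
  )
}

#' Fit the 2x2 difference-in-differences model to subject-level data
#'
#' Ordinary least squares of `value ~ group * assessment` with dummy coding
#' (`CPM = 1` vs. reference `BPM`; `EL = 1` vs. reference `BL`), pooled
#' residual variance, and t-based 95% confidence intervals. Both assessments
#' of a subject enter as observations (the published analysis treats the 2x2
#' as a between-cells contrast, not a repeated-measures model). The saturated
#' model reconstructs the four cell means exactly.
#'
#' @param values Numeric measurements.
#' @param group `"CPM"`/`"BPM"` labels, one per measurement.
#' @param assessment `"BL"`/`"EL"` labels, one per measurement.
#' @param conf_level Confidence level for the coefficient intervals.
#' @returns An object of class `did_fit`: see [tidy.did_fit()] for the
#'   coefficient table and [glance.did_fit()] for model-level summaries.
#' @export
fit_did <- function(values, group, assessment, conf_level = 0.95) {
  check_number(values, "values")
  group <- factor(group, levels = c("BPM", "CPM"))
  assessment <- factor(assessment, levels = c("BL", "EL"))
  if (anyNA(group) || anyNA(assessment)) {
    abort("`group` must be CPM/BPM and `assessment` BL/EL.")
  }
  cell_n <- table(group, assessment)
  if (any(cell_n < 2)) abort("every group x assessment cell needs >= 2 values.")
  dat <- tibble(value = values, group = group, assessment = assessment)
  fit <- lm(value ~ group * assessment, data = dat)
  if (fit$df.residual <= 0) abort("zero residual degrees of freedom.")
  est <- coef(fit)
  ci <- confint(fit, level = conf_level)
  cells <- dat |>
    group_by(.data$group, .data$assessment) |>
    summarise(mean = mean(.data$value), n = n(), .groups = "drop")
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = c("intercept", "condition", "assessment", "did"),
    estimate = unname(est),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  ) |>
    mutate(significant = .data$conf_low > 0 | .data$conf_high < 0)
  structure(
    list(coefficients = coefs, cell_means = cells, lm = fit,
         conf_level = conf_level, n = nrow(dat)),
    class = "did_fit")
}

#' @export
print.did_fit <- function(x, ...) {
  cat("2x2 difference-in-differences fit (reference: BPM, BL)\n")
  print(x$coefficients, ...)
  invisible(x)
}

# Sign-aligned Z of per-subject change, averaged by group, reported as
# mean(Z BPM) - mean(Z CPM): positive means the biofortified group improved
# more. Used for the normalized change-difference summaries.
normalized_change_difference <- function(delta, group, sign = 1) {
  z <- sign * as.numeric(scale(delta))
  mean(z[group == "BPM"]) - mean(z[group == "CPM"])
}

#' Per-variable difference-in-differences table
#'
#' Fits [fit_did()] to every requested variable of a long cohort table and
#' appends the normalized change difference: the per-subject change scores
#' are Z-transformed, sign-aligned so that positive values indicate
#' improvement, and summarized as mean(Z change, BPM) - mean(Z change, CPM).
#'
#' @param cohort A long cohort table (see [validate_cohort()]).
#' @param variables Variables to analyse (default: all except the
#'   inflammation markers).
#' @param sign_map Named vector of +1/-1 improvement orientations (see
#'   [default_sign_map()]).
#' @param conf_level Confidence level.
#' @returns A tibble with one row per variable: the four cell means, the
#'   three contrasts with confidence intervals and significance flags, and
#'   `z_change_difference`.
#' @export
did_table <- function(cohort, variables = NULL,
                      sign_map = default_sign_map(), conf_level = 0.95) {
  cohort <- validate_cohort(cohort, require_el_biomarkers = FALSE)
  if (is.null(variables)) {
    variables <- setdiff(unique(cohort$variable), c("crp", "agp"))
  }
  purrr::map_dfr(variables, function(v) {
    sub <- filter(cohort, .data$variable == v)
    if (!all(c("BL", "EL") %in% sub$assessment)) {
      abort(sprintf("variable '%s' is missing an assessment.", v))
    }
    fit <- fit_did(sub$value, sub$group, sub$assessment,
                   conf_level = conf_level)
    cells <- fit$cell_means
    cell <- function(g, a) cells$mean[cells$group == g & cells$assessment == a]
    wide <- fit$coefficients |>
      filter(.data$term != "intercept") |>
      select("term", "estimate", "conf_low", "conf_high", "significant") |>
      tidyr::pivot_wider(names_from = "term",
                         values_from = c("estimate", "conf_low",
                                         "conf_high", "significant"))
    deltas <- sub |>
      tidyr::pivot_wider(id_cols = c("subject_id", "group"),
                         names_from = "assessment", values_from = "value") |>
      mutate(delta = .data$EL - .data$BL)
    sgn <- if (v %in% names(sign_map)) sign_map[[v]] else 1
    tibble(
      variable = v,
      cpm_bl = cell("CPM", "BL"), bpm_bl = cell("BPM", "BL"),
      cpm_el = cell("CPM", "EL"), bpm_el = cell("BPM", "EL")
    ) |>
      bind_cols(wide) |>
      mutate(z_change_difference =
               normalized_change_difference(deltas$delta, deltas$group, sgn))
  })
}

#' Baseline comparison tests
#'
#' For each baseline biomarker, a 2 (treatment group) x 2 (sex) analysis of
#' variance with type-II sums of squares (unbalanced cells); for each
#' iron-status condition, a chi-squared test of association between group and
#' condition (no continuity correction).
#'
#' @inheritParams prevalence_table
#' @param biomarkers Biomarker variables to test at baseline.
#' @returns A list of two tibbles: `anova` (variable, term, F, df, p) and
#'   `chisq` (condition, statistic, df, p).
#' @export
baseline_tests <- function(cohort, biomarkers = c("hb", "sft", "stfr"),
                           sft_cutoff = 15) {
  panel <- biomarker_panel(cohort, "BL")
  if (nrow(panel) == 0) abort("empty cohort.")
  if (length(unique(panel$group)) < 2 || length(unique(panel$sex)) < 2) {
    abort("both groups and both sexes must be present.")
  }
  flags <- classify_iron_status(panel, sft_cutoff = sft_cutoff)
  aov_tab <- purrr::map_dfr(biomarkers, function(v) {
    dat <- tibble(value = panel[[v]],
                  group = factor(panel$group), sex = factor(panel$sex))
    fit <- lm(value ~ group * sex, data = dat)
    a2 <- car::Anova(fit, type = 2)
    tibble(
      variable = v,
      term = rownames(a2)[seq_len(3)],
      statistic = a2$`F value`[seq_len(3)],
      df = a2$Df[seq_len(3)],
      df_residual = a2$Df[4],
      p_value = a2$`Pr(>F)`[seq_len(3)]
    )
  })
  conditions <- c(anemic = "anemic", ida = "ida", idna = "idna",
                  iron_deficient = "iron_deficient")
  chi_tab <- purrr::imap_dfr(conditions, function(col, cond) {
    tab <- table(flags$group, factor(flags[[col]], levels = c(FALSE, TRUE)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(condition = cond, statistic = unname(ct$statistic),
           df = unname(ct$parameter), p_value = ct$p.value)
  })
  list(anova = aov_tab, chisq = chi_tab)
}
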