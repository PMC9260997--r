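# Independent oracles used across the suite.

# Brute-force least squares via the normal equations; intentionally a
# different code path from the package's lm()/QR fits.
ls_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Exhaustive best-AIC search over the allowable biomarker subsets.
exhaustive_best_aic <- function(data, outcome) {
  subsets <- enumerate_allowable(intersect(c("hb", "sft", "stfr", "bdfe"),
                                           names(data)))
  aics <- vapply(subsets, function(s) {
    X <- cbind(1, as.matrix(data[s]))
    y <- data[[outcome]]
    beta <- ls_oracle(X, y)
    rss <- sum((y - drop(X %*% beta))^2)
    ols_aic(rss, length(y), ncol(X))
  }, numeric(1))
  min(aics)
}

# Small wide change-score data set with known structure.
make_change_data <- function(n = 74, beta = c(hb = 0, sft = 0, stfr = 0),
                             noise_sd = 1) {
  dat <- tibble::tibble(hb = rnorm(n), sft = rnorm(n), stfr = rnorm(n))
  dat$y <- drop(as.matrix(dat[names(beta)]) %*% beta) + rnorm(n, 0, noise_sd)
  dat$bdfe <- 0.4 * dat$sft - 0.4 * dat$stfr + rnorm(n, 0, 0.3)
  dat
}

# Tiny deterministic cohort: 2 groups x 2 sexes. The hb column varies by sex
# and by within-group position (identically in both groups), so the group
# sum of squares is exactly zero while the residual is not.
toy_cohort <- function() {
  subjects <- tibble::tibble(
    subject_id = sprintf("T%02d", 1:8),
    group = rep(c("CPM", "BPM"), each = 4),
    sex = rep(c("female", "male"), 4),
    age = c(13, 14, 15, 16, 13, 14, 15, 16),
    pos = rep(1:4, 2)) # position within group, mirrored across groups
  tidyr::expand_grid(subjects,
                     assessment = c("BL", "EL"),
                     variable = c("hb", "sft", "stfr")) |>
    dplyr::mutate(value = dplyr::case_when(
      variable == "hb" ~
        12 + (sex == "male") * 1.2 + (assessment == "EL") * 0.1 + pos * 0.01,
      variable == "sft" ~
        14 + (group == "BPM") * 3 + (assessment == "EL") * 2 + pos * 0.1,
      variable == "stfr" ~ 7 - (group == "BPM") * 0.5 + pos * 0.05
    )) |>
    dplyr::select(-pos)
}
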