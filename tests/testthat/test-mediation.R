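spec_xy <- mediation_spec(x = "x", m = "m", w = "w", y = "y")

test_that("a noiseless chain is recovered exactly", {
  # with no disturbance anywhere, a mediator that is a linear function of
  # the moderated design is collinear with the full outcome equation, so the
  # noiseless chain is fitted with the pruned outcome equation Y ~ X + M
  # (the moderator path a2 lends the mediator variation of its own)
  set.seed(71)
  d <- simulate_mediation_data(
    60, paths = list(a1 = 0.5, a2 = 0.3, a3 = 0, c1 = 0, c2 = 0, c3 = 0,
                     b_m = 0.4),
    noise_sd = 0)
  f <- fit_mediation(d, spec_xy, standardize = FALSE,
                     outcome_terms = c("x", "m"))
  eff <- setNames(f$effects$estimate, f$effects$effect)
  expect_equal(unname(eff["indirect"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(eff["direct"]), 0, tolerance = 1e-10)
  expect_equal(unname(eff["index"]), 0, tolerance = 1e-10)
  expect_equal(f$r_squared[["mediator"]], 1, tolerance = 1e-10)
})

test_that("identical predictor and mediator columns raise a rank error", {
  set.seed(72)
  d <- simulate_mediation_data(40)
  d$m <- d$x
  expect_error(fit_mediation(d, spec_xy, standardize = FALSE),
               "rank-deficient")
})

test_that("path coefficients match a brute-force normal-equation oracle", {
  set.seed(73)
  for (i in 1:20) {
    d <- simulate_mediation_data(40, noise_sd = runif(1, 0.5, 2))
    f <- fit_mediation(d, spec_xy, standardize = FALSE)
    Xm <- cbind(1, d$x, d$w, d$x * d$w)
    expect_equal(f$mediator_eq$coefficients$estimate,
                 unname(ls_oracle(Xm, d$m)), tolerance = 1e-10)
    Xy <- cbind(Xm, d$m)
    expect_equal(f$outcome_eq$coefficients$estimate,
                 unname(ls_oracle(Xy, d$y)), tolerance = 1e-10)
    # point indirect effect is the product of its factor estimates
    a1 <- f$mediator_eq$coefficients$estimate[2]
    bm <- f$outcome_eq$coefficients$estimate[5]
    expect_equal(f$effects$estimate[f$effects$effect == "indirect"],
                 a1 * bm, tolerance = 1e-12)
  }
})

test_that("standardization invariance: positive rescaling leaves Z effects unchanged", {
  set.seed(74)
  d <- simulate_mediation_data(60)
  f1 <- fit_mediation(d, spec_xy, standardize = TRUE)
  d2 <- dplyr::mutate(d, x = 123 * x, m = 0.04 * m, y = 7 * y)
  f2 <- fit_mediation(d2, spec_xy, standardize = TRUE)
  expect_equal(f1$effects$estimate, f2$effects$estimate, tolerance = 1e-10)
})

test_that("without moderation or noise, total effect = direct + indirect", {
  set.seed(75)
  d <- simulate_mediation_data(
    50, paths = list(a1 = 0.6, a2 = 0.3, a3 = 0, c1 = 0.3, c2 = 0, c3 = 0,
                     b_m = 0.5),
    noise_sd = 0)
  f <- fit_mediation(d, spec_xy, standardize = FALSE,
                     outcome_terms = c("x", "m"))
  # the total effect of x holding the moderator channel fixed
  total <- unname(ls_oracle(cbind(1, d$x, d$w), d$y)[2])
  eff <- setNames(f$effects$estimate, f$effects$effect)
  expect_equal(unname(eff["direct"] + eff["indirect"]), total,
               tolerance = 1e-10)
})

test_that("the conditional indirect effect follows (a1 + a3 w) * b_m", {
  set.seed(76)
  d <- simulate_mediation_data(80)
  f <- fit_mediation(d, spec_xy, standardize = FALSE)
  a1 <- f$mediator_eq$coefficients$estimate[2]
  a3 <- f$mediator_eq$coefficients$estimate[4]
  bm <- f$outcome_eq$coefficients$estimate[5]
  expect_equal(f$conditional_indirect$indirect,
               (a1 + a3 * c(-1, 0, 1)) * bm, tolerance = 1e-12)
})

test_that("bootstrap is seeded and degenerates correctly at zero noise", {
  set.seed(77)
  d <- simulate_mediation_data(
    50, paths = list(a1 = 0.5, a2 = 0.3, a3 = 0, c1 = 0, c2 = 0, c3 = 0,
                     b_m = 0.4),
    noise_sd = 0)
  f <- fit_mediation(d, spec_xy, standardize = FALSE,
                     outcome_terms = c("x", "m"))
  b1 <- bootstrap_mediation(f, n_boot = 200, seed = 5)
  b2 <- bootstrap_mediation(f, n_boot = 200, seed = 5)
  expect_identical(b1$boot$intervals, b2$boot$intervals)
  ind <- b1$boot$intervals[b1$boot$intervals$effect == "indirect", ]
  expect_equal(ind$conf_low, 0.2, tolerance = 1e-10)
  expect_equal(ind$conf_high, 0.2, tolerance = 1e-10)
  expect_true(all(b1$boot$intervals$conf_low <= b1$boot$intervals$conf_high))
  expect_error(bootstrap_mediation(f, n_boot = 50), "at least 100")
})

test_that("alternatives implement the role rotation and nesting bound", {
  set.seed(78)
  co <- simulate_cohort(seed = 14)
  comp <- build_composites(change_scores(co))
  spec <- mediation_spec(m = "eeg_capture", y = "beh_capture")
  alts <- mediation_alternatives(comp, spec)
  expect_equal(alts$scrambled_spec$x, "beh_capture")
  expect_equal(alts$scrambled_spec$m, "z_dsft")
  expect_equal(alts$scrambled_spec$y, "eeg_capture")
  expect_equal(alts$scrambled_spec$w, "z_dhb")
  fit <- fit_mediation(comp, spec)
  # direct-only is nested in the mediated outcome equation
  expect_lte(alts$direct_only$r_squared[["outcome"]],
             fit$r_squared[["outcome"]])
})

test_that("model selection applies criteria (a)-(d) and tie-breaks", {
  set.seed(79)
  # weak data: outcome R^2 under the floor -> none selected
  d_weak <- simulate_mediation_data(
    74, paths = list(a1 = 0.05, b_m = 0.05, a2 = 0, a3 = 0, c1 = 0, c2 = 0,
                     c3 = 0), noise_sd = 2)
  f_weak <- fit_mediation(d_weak, spec_xy)
  sel_weak <- select_mediation_model(list(only = f_weak))
  expect_null(sel_weak$best)
  # strong data: the true mediation wins over its falsification models
  # every path strong enough that criterion (c) (all terms significant)
  # is satisfiable at this n
  d <- simulate_mediation_data(
    200, paths = list(a1 = 0.7, a2 = 0.4, a3 = 0.4, c1 = 0.4, c2 = 0.3,
                      c3 = 0.35, b_m = 0.7))
  f <- fit_mediation(d, spec_xy)
  alts <- mediation_alternatives(d, spec_xy)
  sel <- select_mediation_model(list(mediated = f,
                                     direct_only = alts$direct_only,
                                     scrambled = alts$scrambled))
  expect_equal(sel$best_name, "mediated")
  expect_true(all(c("f_ok", "r2_ok", "terms_ok", "aic_total") %in%
                    names(sel$verdicts)))
  expect_error(select_mediation_model(list()), "empty")
})

test_that("pruning removes only non-significant moderation terms", {
  set.seed(80)
  d <- simulate_mediation_data(
    150, paths = list(a1 = 0.6, a2 = 0, a3 = 0, c1 = 0.3, c2 = 0, c3 = 0,
                      b_m = 0.5))
  f <- fit_mediation(d, spec_xy)
  pruned <- prune_mediation(f, d)
  expect_true("x" %in% pruned$mediator_terms)
  expect_true(all(c("x", "m") %in% pruned$outcome_terms))
  # core paths are never pruned even in this moderation-free world
  coefs <- dplyr::filter(pruned$outcome_eq$coefficients,
                         term != "(Intercept)")
  expect_true(all(coefs$term %in% c("x", "w", "xw", "m")))
})
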