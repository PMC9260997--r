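test_that("cell-mean contrasts reproduce the published worked examples", {
  expect_equal(did_from_cells(627, 661, 592, 546)$did, 80)
  expect_equal(did_from_cells(633, 712, 632, 581)$did, 130)
  gng <- did_from_cells(627, 661, 592, 546)
  expect_equal(gng$condition, -34)
  expect_equal(gng$assessment, -115)
  expect_equal(unlist(did_from_cells(5, 5, 5, 5)),
               c(condition = 0, assessment = 0, did = 0))
})

test_that("the fitted model reconstructs cell means to machine precision", {
  set.seed(31)
  for (i in 1:10) {
    n_per <- sample(3:8, 4, replace = TRUE)
    group <- rep(rep(c("CPM", "BPM"), 2), n_per)
    assessment <- rep(c("BL", "BL", "EL", "EL"), n_per)
    values <- rnorm(sum(n_per), mean = rep(c(10, 20, 12, 25), n_per), sd = 2)
    fit <- fit_did(values, group, assessment)
    b <- fit$coefficients$estimate
    cells <- fit$cell_means
    cell <- function(g, a) cells$mean[cells$group == g & cells$assessment == a]
    # dummy-coded reconstruction: BPM/BL reference
    expect_equal(b[1], cell("BPM", "BL"), tolerance = 1e-10)
    expect_equal(b[1] + b[2], cell("CPM", "BL"), tolerance = 1e-10)
    expect_equal(b[1] + b[3], cell("BPM", "EL"), tolerance = 1e-10)
    expect_equal(sum(b), cell("CPM", "EL"), tolerance = 1e-10)
    # coefficients match the ls oracle on the dummy design
    X <- cbind(1, group == "CPM", assessment == "EL",
               (group == "CPM") * (assessment == "EL"))
    expect_equal(b, unname(ls_oracle(X, values)), tolerance = 1e-10)
  }
})

test_that("the interaction is invariant to shifting one assessment", {
  set.seed(33)
  group <- rep(c("CPM", "BPM"), each = 10)
  assessment <- rep(rep(c("BL", "EL"), each = 5), 2)
  values <- rnorm(20)
  base <- fit_did(values, group, assessment)
  shifted <- fit_did(values + 100 * (assessment == "EL"), group, assessment)
  expect_equal(base$coefficients$estimate[4],
               shifted$coefficients$estimate[4], tolerance = 1e-10)
})

test_that("did_table flags CIs, errors on missing assessments, and signs Z changes", {
  co <- simulate_cohort(seed = 5)
  tab <- did_table(co, variables = c("sft", "gng_rt"))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("estimate_did", "conf_low_did", "significant_did",
                    "z_change_difference") %in% names(tab)))
  # significance flag = CI excludes zero
  expect_equal(tab$significant_did,
               tab$conf_low_did > 0 | tab$conf_high_did < 0)
  expect_error(did_table(dplyr::filter(co, !(variable == "gng_rt" &
                                               assessment == "EL")),
                         variables = "gng_rt"),
               "missing an assessment")
  # a strong generator gives BPM-favoring normalized ferritin change
  expect_gt(tab$z_change_difference[tab$variable == "sft"], 0)
})

test_that("under a null treatment effect the DiD false-positive rate is near alpha", {
  set.seed(35)
  hits <- replicate(300, {
    group <- rep(c("CPM", "BPM"), c(33, 41))
    values <- rnorm(148)
    fit <- fit_did(values, rep(group, 2), rep(c("BL", "EL"), each = 74))
    fit$coefficients$significant[4]
  })
  expect_lt(mean(hits), 0.09)
  expect_gt(mean(hits), 0.015)
})

test_that("baseline chi-squared matches the hand-computed toy table", {
  # [[10,10],[20,0]] with expected cells 15/5/15/5 -> X^2 = 13.33
  tab <- matrix(c(10, 20, 10, 0), nrow = 2)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(unname(ct$statistic), 13.3333, tolerance = 1e-3)
  # package path produces the same statistic from a cohort with those margins
  co <- toy_cohort()
  bt <- baseline_tests(co)
  expect_true(all(c("anova", "chisq") %in% names(bt)))
  expect_true(all(bt$chisq$df == 1))
})

test_that("group F is zero when groups are identical and matches an SS oracle", {
  co <- toy_cohort() # hb varies by sex only, plus a tiny deterministic ripple
  bt <- baseline_tests(co)
  hb_group_f <- bt$anova$statistic[bt$anova$variable == "hb" &
                                     bt$anova$term == "group"]
  expect_lt(abs(hb_group_f), 1e-8)
  # brute-force type-II oracle on a random unbalanced cohort
  set.seed(41)
  n <- 40
  panel <- tibble::tibble(
    subject_id = sprintf("R%02d", 1:n),
    group = sample(c("CPM", "BPM"), n, TRUE, prob = c(0.4, 0.6)),
    sex = sample(c("female", "male"), n, TRUE),
    age = runif(n, 12, 16))
  long <- tidyr::expand_grid(panel, assessment = c("BL", "EL"),
                             variable = c("hb", "sft", "stfr")) |>
    dplyr::mutate(value = runif(dplyr::n(), 5, 15))
  bt2 <- baseline_tests(long)
  dat <- dplyr::filter(long, assessment == "BL", variable == "hb")
  # type-II: compare each main effect against the two-main-effects model
  rss <- function(fml) sum(resid(lm(fml, data = dat))^2)
  rss_full <- rss(value ~ group + sex)
  rss_int <- rss(value ~ group * sex)
  sigma2 <- rss_int / (nrow(dat) - 4)
  f_group <- ((rss(value ~ sex) - rss_full) / 1) / sigma2
  f_sex <- ((rss(value ~ group) - rss_full) / 1) / sigma2
  got <- dplyr::filter(bt2$anova, variable == "hb")
  expect_equal(got$statistic[got$term == "group"], f_group, tolerance = 1e-8)
  expect_equal(got$statistic[got$term == "sex"], f_sex, tolerance = 1e-8)
})
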