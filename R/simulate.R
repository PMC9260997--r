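# Seeded synthetic cohorts with the statistical structure the downstream
# analyses assume: group-dependent baseline biomarkers and ferritin response,
# and a latent structural chain  d(sFt) -> d(EEG) -> d(behavior)  with d(Hb)
# moderating both ferritin paths. The generative model is the
# moderated-mediation model run forward, so parameter recovery by the
# analysis stages is a meaningful test.

#' Variable manifest of the synthetic cohort
#'
#' One row per simulated task/ERP variable: its composite `family` (capture,
#' selection, memory, or none), `tier` (behavior or eeg), improvement
#' orientation `sign` (-1 for reaction times and N1 amplitudes), baseline
#' moments in native units, the `scale` mapping latent improvement to native
#' units, the indicator `loading`, and whether the variable is constrained
#' positive. Baseline moments echo the magnitudes typical of adolescent
#' cohorts on these tasks.
#'
#' @returns A tibble.
#' @export
cohort_variables <- function() {
  tribble(
    ~variable,            ~family,     ~tier,      ~sign, ~bl_mean, ~bl_sd, ~scale, ~positive,
    "srt_rt",             "none",      "behavior",    -1,     1183,     90,     45,      TRUE,
    "gng_rt",             "capture",   "behavior",    -1,      644,     80,     40,      TRUE,
    "ant_rt_2cue",        "capture",   "behavior",    -1,      676,    100,     50,      TRUE,
    "ant_rt_spatial",     "selection", "behavior",    -1,      611,     80,     40,      TRUE,
    "ant_rt_incongruent", "selection", "behavior",    -1,      792,    100,     50,      TRUE,
    "cfe_rt",             "memory",    "behavior",    -1,       48,     60,     30,     FALSE,
    "cfe_sensitivity",    "memory",    "behavior",     1,     0.07,    0.7,   0.35,     FALSE,
    "crt_pcc",            "memory",    "behavior",     1,       33,     20,     10,     FALSE,
    "gng_n1",             "capture",   "eeg",         -1,     -1.6,    1.8,    0.9,     FALSE,
    "gng_p3",             "capture",   "eeg",          1,      1.6,    1.7,   0.85,     FALSE,
    "ant_n1_2cue",        "capture",   "eeg",         -1,     -2.3,    0.8,    0.4,     FALSE,
    "ant_p3_2cue",        "capture",   "eeg",          1,      2.7,    0.7,   0.35,     FALSE,
    "ant_n1_spatial",     "selection", "eeg",         -1,     -2.3,    0.8,    0.4,     FALSE,
    "ant_p3_spatial",     "selection", "eeg",          1,      2.7,    0.7,   0.35,     FALSE,
    "ant_n1_incongruent", "selection", "eeg",         -1,     -2.3,    0.8,    0.4,     FALSE,
    "ant_p3_incongruent", "selection", "eeg",          1,      2.7,    0.7,   0.35,     FALSE,
    "cfe_n1_contrast",    "memory",    "eeg",         -1,     -1.4,    1.4,    0.7,     FALSE,
    "cfe_p3_contrast",    "memory",    "eeg",          1,      1.7,    1.1,   0.55,     FALSE,
    "crt_gamma_power",    "memory",    "eeg",          1,     -0.2,    2.9,    1.5,     FALSE
  )
}

#' Default structural path coefficients
#'
#' Coefficients of the generative chain on the raw change-score scale:
#' `latent_EEG = a0 + a1 * d_sft + a2 * d_hb + a3 * d_sft * d_hb + noise`,
#' `latent_beh = b0 + c1 * d_sft + c2 * d_hb + c3 * d_sft * d_hb +
#' b_m * latent_EEG + noise`. Defaults put the ferritin path at about half a
#' latent SD per SD of ferritin change, a positive hemoglobin moderation on
#' both ferritin paths (the model form the trial analysis selects), and a
#' mediator path of 0.4.
#'
#' @returns Named list `a0, a1, a2, a3, b0, c1, c2, c3, b_m`.
#' @export
default_paths <- function() {
  list(a0 = 0, a1 = 0.06, a2 = 0.3, a3 = 0.02,
       b0 = 0, c1 = 0.03, c2 = 0.15, c3 = 0.01, b_m = 0.4)
}

#' Simulation configuration
#'
#' Study-design defaults follow the trial: 33 comparison (CPM) and 41
#' biofortified (BPM) subjects aged 12-16, baseline biomarker moments from
#' the trial's baseline characteristics (SDs recovered from printed standard
#' errors), a ferritin response of +1.55 ng/mL (CPM) vs +5.26 ng/mL (BPM),
#' and small hemoglobin/sTfR drifts. Baseline biomarkers are drawn from
#' normals truncated at zero. Changes in ferritin and hemoglobin are
#' correlated (default 0.3) so that moderation is exercised on correlated
#' predictors.
#'
#' @param n_cpm,n_bpm Group sizes (>= 2).
#' @param sex_ratio Proportion female.
#' @param age_range Age range in years.
#' @param baseline Tibble of per-group baseline biomarker moments.
#' @param delta_mean Named list of per-group change means for `sft`, `hb`,
#'   `stfr` (each a `c(CPM = , BPM = )` vector).
#' @param delta_sd Named vector of change-score SDs.
#' @param cor_sft_hb Correlation between ferritin and hemoglobin change.
#' @param paths Structural path coefficients, see [default_paths()].
#' @param noise_structural SD of the latent-equation disturbances.
#' @param noise_indicator SD (in latent units; scaled per variable) of the
#'   indicator-level noise.
#' @param variables Variable manifest, see [cohort_variables()].
#' @returns A `sim_config` list.
#' @export
sim_config <- function(n_cpm = 33, n_bpm = 41, sex_ratio = 0.5,
                       age_range = c(12, 16),
                       baseline = default_baseline_biomarkers(),
                       delta_mean = list(sft = c(CPM = 1.55, BPM = 5.26),
                                         hb = c(CPM = -0.07, BPM = 0.32),
                                         stfr = c(CPM = 0.57, BPM = -0.09)),
                       delta_sd = c(sft = 8, hb = 1, stfr = 2),
                       cor_sft_hb = 0.3,
                       paths = default_paths(),
                       noise_structural = 1,
                       noise_indicator = 0.3,
                       variables = cohort_variables()) {
  if (n_cpm < 2 || n_bpm < 2) abort("group sizes must be >= 2.")
  if (any(delta_sd < 0) || noise_structural < 0 || noise_indicator < 0) {
    abort("standard deviations must be non-negative.")
  }
  if (any(baseline$cpm_sd < 0) || any(baseline$bpm_sd < 0)) {
    abort("baseline SDs must be non-negative.")
  }
  if (abs(cor_sft_hb) >= 1) abort("`cor_sft_hb` must be in (-1, 1).")
  paths <- utils::modifyList(default_paths(), as.list(paths))
  structure(
    list(n_cpm = n_cpm, n_bpm = n_bpm, sex_ratio = sex_ratio,
         age_range = age_range, baseline = baseline,
         delta_mean = delta_mean, delta_sd = delta_sd,
         cor_sft_hb = cor_sft_hb, paths = paths,
         noise_structural = noise_structural,
         noise_indicator = noise_indicator, variables = variables),
    class = "sim_config")
}

#' Default baseline biomarker moments
#'
#' Group means from the trial's baseline table; SDs are the printed standard
#' errors multiplied by the square root of the group size. CRP and AGP have
#' no printed moments; low-inflammation adolescent values are used.
#'
#' @returns A tibble with columns `variable`, `cpm_mean`, `cpm_sd`,
#'   `bpm_mean`, `bpm_sd`.
#' @export
default_baseline_biomarkers <- function() {
  tribble(
    ~variable, ~cpm_mean,            ~cpm_sd, ~bpm_mean,            ~bpm_sd,
    "hb",          12.18, 0.19 * sqrt(33),        12.09, 0.19 * sqrt(41),
    "sft",         13.38, 1.69 * sqrt(33),        17.05, 2.45 * sqrt(41),
    "stfr",         7.35, 0.71 * sqrt(33),         6.98, 0.40 * sqrt(41),
    "crp",          1.00,            1.00,          1.00,            1.00,
    "agp",          0.60,            0.15,          0.60,            0.15
  )
}

# Truncated-normal draw by inverse CDF: one uniform per value, so draw
# counts (and hence the seed stream) do not depend on the data.
rtnorm <- function(n, mean, sd, lower = -Inf) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  if (length(lower) == 1) lower <- rep(lower, n)
  out <- numeric(n)
  fixed <- sd == 0
  out[fixed] <- pmax(mean[fixed], lower[fixed])
  if (any(!fixed)) {
    plo <- pnorm((lower[!fixed] - mean[!fixed]) / sd[!fixed])
    u <- runif(sum(!fixed), plo, 1)
    out[!fixed] <- mean[!fixed] + sd[!fixed] * qnorm(pmin(u, 1 - 1e-12))
  }
  out
}

#' Simulate raw mediation-scale data
#'
#' The structural core shared by the cohort generator and the recovery /
#' falsification simulations: draws correlated predictor `x` and moderator
#' `w`, then the mediator and outcome from the moderated-mediation
#' equations. With `noise_sd = 0` the chain is deterministic given `x` and
#' `w`.
#'
#' @param n Number of subjects.
#' @param paths Structural coefficients, see [default_paths()].
#' @param x_mean,x_sd,w_mean,w_sd Moments of predictor and moderator
#'   (scalars or length-`n` vectors for group-dependent means).
#' @param cor_xw Correlation between predictor and moderator.
#' @param noise_sd Disturbance SD of both structural equations.
#' @param x_lower,w_lower Optional lower truncation bounds (vectors allowed);
#'   used by the cohort generator to keep endline biomarkers positive.
#' @returns A tibble with columns `x`, `w`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, paths = default_paths(),
                                    x_mean = 0, x_sd = 1,
                                    w_mean = 0, w_sd = 1,
                                    cor_xw = 0.3, noise_sd = 1,
                                    x_lower = -Inf, w_lower = -Inf) {
  if (n < 2) abort("`n` must be >= 2.")
  p <- utils::modifyList(default_paths(), as.list(paths))
  x_mean <- unname(x_mean); x_sd <- unname(x_sd)
  w_mean <- unname(w_mean); w_sd <- unname(w_sd)
  e1 <- if (all(is.infinite(x_lower))) rnorm(n) else {
    (rtnorm(n, x_mean, x_sd, x_lower) - x_mean) / ifelse(x_sd == 0, 1, x_sd)
  }
  e2 <- rnorm(n)
  x <- x_mean + x_sd * e1
  w_shift <- w_sd * (cor_xw * e1 + sqrt(1 - cor_xw^2) * e2)
  w <- w_mean + w_shift
  if (!all(is.infinite(w_lower))) w <- pmax(w, w_lower)
  m <- p$a0 + p$a1 * x + p$a2 * w + p$a3 * x * w + rnorm(n, 0, noise_sd)
  y <- p$b0 + p$c1 * x + p$c2 * w + p$c3 * x * w + p$b_m * m +
    rnorm(n, 0, noise_sd)
  tibble(x = x, w = w, m = m, y = y)
}

#' Generate a synthetic trial cohort
#'
#' Draws subjects, baseline biomarkers, treatment-dependent biomarker
#' changes, one latent EEG / behavior pair per composite family (capture,
#' selection, memory) from the structural chain, and maps latents to the
#' individual task and ERP variables of [cohort_variables()] via loadings
#' plus indicator noise; endline = baseline + change. Identical `config` and
#' `seed` give byte-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @returns A long cohort table (see [validate_cohort()]) with attributes
#'   `latents` (per-subject biomarker changes and latent scores) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  vars <- config$variables
  bad_fam <- setdiff(unique(vars$family),
                     c("capture", "selection", "memory", "none"))
  if (length(bad_fam)) {
    abort(paste0("unknown composite family in the variable manifest: ",
                 paste(bad_fam, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  n <- config$n_cpm + config$n_bpm
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("CPM", "BPM"), c(config$n_cpm, config$n_bpm)),
    sex = ifelse(runif(n) < config$sex_ratio, "female", "male"),
    age = runif(n, config$age_range[1], config$age_range[2])
  )
  gi <- match(subjects$group, c("CPM", "BPM"))

  # baseline biomarkers, truncated at zero
  bl <- purrr::pmap(config$baseline, function(variable, cpm_mean, cpm_sd,
                                              bpm_mean, bpm_sd) {
    rtnorm(n, c(cpm_mean, bpm_mean)[gi], c(cpm_sd, bpm_sd)[gi], lower = 0)
  })
  names(bl) <- config$baseline$variable

  # biomarker changes; ferritin/hemoglobin correlated, endline kept positive
  p <- config$paths
  dm <- config$delta_mean
  ds <- config$delta_sd
  xw <- simulate_mediation_data(
    n, paths = p,
    x_mean = dm$sft[gi], x_sd = ds[["sft"]],
    w_mean = dm$hb[gi], w_sd = ds[["hb"]],
    cor_xw = config$cor_sft_hb,
    noise_sd = config$noise_structural,
    x_lower = -bl$sft + 0.05, w_lower = -bl$hb + 0.05)
  d_sft <- xw$x
  d_hb <- xw$w
  d_stfr <- rtnorm(n, unname(dm$stfr[gi]), ds[["stfr"]],
                   lower = -bl$stfr + 0.05)

  # latent EEG/behavior pair per composite family; the capture pair reuses
  # the structural draw above so the chain has exactly one source of truth
  families <- c("capture", "selection", "memory")
  latents <- list(capture = list(eeg = xw$m, beh = xw$y))
  for (fam in c("selection", "memory")) {
    eeg <- p$a0 + p$a1 * d_sft + p$a2 * d_hb + p$a3 * d_sft * d_hb +
      rnorm(n, 0, config$noise_structural)
    beh <- p$b0 + p$c1 * d_sft + p$c2 * d_hb + p$c3 * d_sft * d_hb +
      p$b_m * eeg + rnorm(n, 0, config$noise_structural)
    latents[[fam]] <- list(eeg = eeg, beh = beh)
  }

  # map latents to indicators
  long_vars <- purrr::pmap_dfr(
    vars,
    function(variable, family, tier, sign, bl_mean, bl_sd, scale, positive) {
      bl_v <- if (positive) rtnorm(n, bl_mean, bl_sd, lower = 1)
              else rnorm(n, bl_mean, bl_sd)
      lat <- if (family == "none") 0
             else latents[[family]][[if (tier == "eeg") "eeg" else "beh"]]
      delta <- sign * scale * lat +
        rnorm(n, 0, config$noise_indicator * scale)
      el_v <- bl_v + delta
      if (positive) el_v <- pmax(el_v, 1)
      bind_rows(
        tibble(subject_id = subjects$subject_id, variable = variable,
               assessment = "BL", value = bl_v),
        tibble(subject_id = subjects$subject_id, variable = variable,
               assessment = "EL", value = el_v))
    })

  bio_long <- purrr::imap_dfr(bl, function(v_bl, nm) {
    delta <- switch(nm, sft = d_sft, hb = d_hb, stfr = d_stfr,
                    rnorm(n, 0, 0.05)) # inflammation markers: stable
    el <- pmax(v_bl + delta, 0.01)
    bind_rows(
      tibble(subject_id = subjects$subject_id, variable = nm,
             assessment = "BL", value = v_bl),
      tibble(subject_id = subjects$subject_id, variable = nm,
             assessment = "EL", value = el))
  })

  cohort <- bind_rows(bio_long, long_vars) |>
    left_join(subjects, by = "subject_id") |>
    select("subject_id", "group", "sex", "age", "assessment",
           "variable", "value") |>
    arrange(.data$subject_id, .data$variable, .data$assessment)
  lat_tab <- tibble(
    subject_id = subjects$subject_id, group = subjects$group,
    d_sft = d_sft, d_hb = d_hb, d_stfr = d_stfr)
  for (fam in families) {
    lat_tab[[paste0("eeg_", fam)]] <- latents[[fam]]$eeg
    lat_tab[[paste0("beh_", fam)]] <- latents[[fam]]$beh
  }
  attr(cohort, "latents") <- lat_tab
  attr(cohort, "config") <- config
  validate_cohort(cohort)
}

#' Simulate trial-level ERP epochs
#'
#' Epochs at `fs` Hz spanning `tlim` seconds around stimulus onset. The
#' deterministic waveform is a negative Gaussian bump centred at 150 ms
#' (N1-like, SD 25 ms), a positive bump at 400 ms (P3-like, SD 60 ms), and
#' sinusoids at 10 Hz and 40 Hz; white noise is added per trial.
#'
#' @param n_trials Number of trials (>= 1).
#' @param n1_amp,p3_amp Bump peak amplitudes, microvolts.
#' @param alpha_amp,gamma_amp Sinusoid amplitudes, microvolts.
#' @param noise_sd White-noise SD, microvolts (>= 0).
#' @param fs Sampling rate, Hz.
#' @param tlim Epoch span in seconds.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @returns An object of class `erp_epochs`: list with `data` (trials x
#'   samples matrix), `times` (seconds), and `fs`.
#' @export
simulate_erp_epochs <- function(n_trials, n1_amp = -3, p3_amp = 2,
                                alpha_amp = 1, gamma_amp = 0.5,
                                noise_sd = 1, fs = 250,
                                tlim = c(-0.2, 0.8), seed = NULL) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  for (nm in c("n1_amp", "p3_amp", "alpha_amp", "gamma_amp")) {
    check_number(get(nm), nm)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  times <- seq(tlim[1], tlim[2], by = 1 / fs)
  wave <- n1_amp * exp(-(times - 0.15)^2 / (2 * 0.025^2)) +
    p3_amp * exp(-(times - 0.40)^2 / (2 * 0.060^2)) +
    alpha_amp * sin(2 * pi * 10 * times) +
    gamma_amp * sin(2 * pi * 40 * times)
  data <- matrix(rep(wave, each = n_trials), nrow = n_trials) +
    matrix(rnorm(n_trials * length(times), 0, noise_sd), nrow = n_trials)
  structure(list(data = data, times = times, fs = fs),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("ERP epochs: %d trial(s) x %d samples at %g Hz (%.0f..%.0f ms)\n",
              nrow(x$data), ncol(x$data), x$fs,
              1000 * min(x$times), 1000 * max(x$times)))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys mirror the [sim_config()] arguments; any omitted key keeps
#' its default. `delta_mean` entries and `delta_sd` are given as named
#' mappings (`CPM:`/`BPM:` and `sft:`/`hb:`/`stfr:`); `baseline` and
#' `variables` as lists of records with the same fields as the default
#' tibbles.
#'
#' @param path Path to a YAML file.
#' @returns A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$delta_mean)) raw$delta_mean <- lapply(raw$delta_mean, unlist)
  if (!is.null(raw$delta_sd)) raw$delta_sd <- unlist(raw$delta_sd)
  if (!is.null(raw$age_range)) raw$age_range <- unlist(raw$age_range)
  if (!is.null(raw$baseline)) {
    raw$baseline <- dplyr::bind_rows(lapply(raw$baseline, tibble::as_tibble))
  }
  if (!is.null(raw$variables)) {
    raw$variables <- dplyr::bind_rows(lapply(raw$variables, tibble::as_tibble))
  }
  do.call(sim_config, raw)
}
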