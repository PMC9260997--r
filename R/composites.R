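# Change scores, sign-aligned Z transformation, and the behavioral / EEG
# composite scores used as mediation inputs.

#' Default improvement-orientation sign map
#'
#' Signs applied to Z-transformed change scores so that positive values
#' always mean improvement from baseline to endline: reaction-time changes
#' and N1-amplitude changes are negated (faster responses and
#' larger-magnitude negative N1 components indicate improvement); hit rates,
#' sensitivity, capacity change, P3 amplitude and band power are kept
#' positive; false-alarm rate and bias are negated. Blood biomarkers improve
#' upward except sTfR, which falls with repletion.
#'
#' @returns Named numeric vector of +1/-1 per variable.
#' @export
default_sign_map <- function() {
  v <- cohort_variables()
  c(c(hb = 1, sft = 1, stfr = -1, bdfe = 1),
    setNames(v$sign, v$variable))
}

#' Default composite definitions
#'
#' Component variables of the three behavioral composites (low-level
#' attentional capture, high-level attentional selection, memory-retrieval
#' efficiency) and their EEG mediator counterparts. Behavioral: capture =
#' go/no-go RT + 2-cue RT; selection = spatial-cue RT + incongruent-flanker
#' RT; memory = composite-face RT and sensitivity + percent change in
#' recognition capacity. EEG: N1 and P3 amplitudes of the corresponding task
#' conditions, plus gamma-band power for the memory family. The exact
#' condition-to-composite mapping is a convention and fully overridable.
#'
#' @returns Named list of character vectors of component variables.
#' @export
default_composite_map <- function() {
  list(
    beh_capture = c("gng_rt", "ant_rt_2cue"),
    beh_selection = c("ant_rt_spatial", "ant_rt_incongruent"),
    beh_memory = c("cfe_rt", "cfe_sensitivity", "crt_pcc"),
    eeg_capture = c("gng_n1", "gng_p3", "ant_n1_2cue", "ant_p3_2cue"),
    eeg_selection = c("ant_n1_spatial", "ant_p3_spatial",
                      "ant_n1_incongruent", "ant_p3_incongruent"),
    eeg_memory = c("cfe_n1_contrast", "cfe_p3_contrast", "crt_gamma_power")
  )
}

#' Sign-aligned Z transformation of change scores
#'
#' Centers and scales a vector of endline-minus-baseline changes to mean 0,
#' SD 1, then multiplies by `sign` so that positive values indicate
#' improvement (e.g. `sign = -1` for reaction times: a faster endline gives a
#' positive score).
#'
#' @param deltas Per-subject change scores; at least two, non-constant.
#' @param sign `+1` or `-1`.
#' @returns Numeric Z scores, mean 0 and SD 1 over the input.
#' @export
z_change <- function(deltas, sign = 1) {
  check_number(deltas, "deltas")
  if (!sign %in% c(-1, 1)) abort("`sign` must be +1 or -1.")
  if (length(deltas) < 2) abort("need >= 2 change scores.")
  s <- sd(deltas)
  if (!is.finite(s) || s == 0) abort("change scores have zero variance.")
  sign * (deltas - mean(deltas)) / s
}

#' Per-subject change scores from a long cohort table
#'
#' Computes `EL - BL` per subject and variable; appends the derived body-iron
#' change (`bdfe`) computed per subject at each assessment when ferritin and
#' sTfR are present.
#'
#' @inheritParams did_table
#' @returns A long tibble: `subject_id`, `group`, `sex`, `age`, `variable`,
#'   `delta`.
#' @export
change_scores <- function(cohort, variables = NULL) {
  cohort <- validate_cohort(cohort, require_el_biomarkers = FALSE)
  if (all(c("sft", "stfr") %in% cohort$variable) &&
      !"bdfe" %in% cohort$variable) {
    bdfe <- cohort |>
      filter(.data$variable %in% c("sft", "stfr")) |>
      tidyr::pivot_wider(
        id_cols = c("subject_id", "group", "sex", "age", "assessment"),
        names_from = "variable", values_from = "value") |>
      mutate(variable = "bdfe", value = body_iron(.data$sft, .data$stfr)) |>
      select(-"sft", -"stfr")
    cohort <- bind_rows(cohort, bdfe)
  }
  if (is.null(variables)) {
    variables <- setdiff(unique(cohort$variable), c("crp", "agp"))
  }
  cohort |>
    filter(.data$variable %in% variables) |>
    tidyr::pivot_wider(
      id_cols = c("subject_id", "group", "sex", "age", "variable"),
      names_from = "assessment", values_from = "value") |>
    mutate(delta = .data$EL - .data$BL) |>
    select("subject_id", "group", "sex", "age", "variable", "delta")
}

#' Sign-aligned Z change matrix
#'
#' Applies [z_change()] to every variable's change scores, using the pooled
#' cohort (both treatment groups) as the Z reference population.
#'
#' @param changes Output of [change_scores()].
#' @param sign_map Named +1/-1 vector; variables absent from the map keep
#'   sign +1 with a warning.
#' @returns `changes` with a `z_delta` column added.
#' @export
z_change_matrix <- function(changes, sign_map = default_sign_map()) {
  unmapped <- setdiff(unique(changes$variable), names(sign_map))
  if (length(unmapped)) {
    warn(paste0("variables missing from the sign map (sign +1 assumed): ",
                paste(unmapped, collapse = ", ")))
  }
  changes |>
    group_by(.data$variable) |>
    mutate(z_delta = z_change(
      .data$delta,
      sign = if (.data$variable[1] %in% names(sign_map))
        sign_map[[.data$variable[1]]] else 1)) |>
    ungroup()
}

#' Build behavioral and EEG composite scores
#'
#' Each composite is the arithmetic mean of its configured sign-aligned Z
#' change components. When a subject is missing some (but not all) components
#' of a composite, the mean of the available components is used and a
#' warning is issued.
#'
#' @param changes Output of [change_scores()] (or a cohort table, which is
#'   converted first).
#' @param composite_map Named list of component variables per composite.
#' @param sign_map Named +1/-1 orientation vector.
#' @returns A wide tibble: one row per subject with `subject_id`, `group`,
#'   `sex`, `age`, the Z-scored biomarker changes (`z_dhb`, `z_dsft`,
#'   `z_dstfr`, `z_dbdfe` when present) and one column per composite.
#' @export
build_composites <- function(changes,
                             composite_map = default_composite_map(),
                             sign_map = default_sign_map()) {
  if ("assessment" %in% names(changes)) changes <- change_scores(changes)
  needed <- unique(unlist(composite_map))
  missing_vars <- setdiff(needed, unique(changes$variable))
  if (length(missing_vars)) {
    abort(paste0("composite components absent from the data: ",
                 paste(missing_vars, collapse = ", ")))
  }
  zc <- z_change_matrix(changes, sign_map = sign_map)
  wide <- zc |>
    tidyr::pivot_wider(id_cols = c("subject_id", "group", "sex", "age"),
                       names_from = "variable", values_from = "z_delta")
  out <- wide |> select("subject_id", "group", "sex", "age")
  for (bm in c("hb", "sft", "stfr", "bdfe")) {
    if (bm %in% names(wide)) out[[paste0("z_d", bm)]] <- wide[[bm]]
  }
  for (cmp in names(composite_map)) {
    comp_cols <- as.matrix(wide[composite_map[[cmp]]])
    n_avail <- rowSums(!is.na(comp_cols))
    if (any(n_avail == 0)) {
      abort(sprintf("all components of %s missing for subject %s", cmp,
                    wide$subject_id[which(n_avail == 0)[1]]))
    }
    if (any(n_avail < ncol(comp_cols))) {
      warn(sprintf("%d subject(s) missing components of %s; using the mean of available components",
                   sum(n_avail < ncol(comp_cols)), cmp))
    }
    out[[cmp]] <- rowMeans(comp_cols, na.rm = TRUE)
  }
  out
}
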