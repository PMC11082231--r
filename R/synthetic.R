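.MEASURE_SIGN <- c(LS = -1, CS = -1, RS = +1)

#' Smooth strain waveform template
#'
#' A continuously differentiable deformation-and-recovery waveform over
#' one cardiac cycle: zero at both ends, magnitude peaking at the
#' end-systolic fraction `t_es` with value `amplitude`, raised-cosine
#' contraction and a recovery limb shaped by `recovery_rate` (>= 1; 1 is
#' symmetric). Longitudinal and circumferential strain are negative at
#' peak, radial strain positive.
#'
#' @param t Cycle fraction(s) in `[0, 1]`.
#' @param amplitude Peak magnitude `|A|` (percent strain).
#' @param t_es End-systolic cycle fraction (peak position), in (0.2, 0.6).
#' @param recovery_rate Shape exponent of the recovery limb (default 1).
#' @param measure `"LS"`, `"CS"` or `"RS"` (controls the sign).
#' @return Strain value(s) in percent.
#' @export
strain_template <- function(t, amplitude, t_es = 0.35, recovery_rate = 1,
                            measure = "LS") {
  .assert(all(t >= 0 & t <= 1), "t must be a cycle fraction in [0, 1]")
  .assert(t_es > 0.2 && t_es < 0.6, "t_es must lie in (0.2, 0.6)")
  .assert(recovery_rate >= 1, "recovery_rate must be >= 1")
  sign <- .MEASURE_SIGN[[substr(measure, 1, 2)]]
  m <- ifelse(t <= t_es,
              amplitude * (1 - cos(pi * t / t_es)) / 2,
              amplitude * (1 + cos(pi * ((t - t_es) / (1 - t_es))^recovery_rate)) / 2)
  sign * m
}

#' Analytic strain-rate template
#'
#' The exact time derivative of [strain_template] (per unit cycle
#' fraction), rescaled by the cycle length in seconds and by 1/100 so
#' that percent strain yields strain rate in 1/s.
#'
#' @inheritParams strain_template
#' @param cycle_s Cycle duration in seconds (default 1).
#' @return Strain-rate value(s) in 1/s.
#' @export
strain_rate_template <- function(t, amplitude, t_es = 0.35, recovery_rate = 1,
                                 measure = "LS", cycle_s = 1) {
  .assert(all(t >= 0 & t <= 1), "t must be a cycle fraction in [0, 1]")
  sign <- .MEASURE_SIGN[[substr(measure, 1, 2)]]
  r <- recovery_rate
  u <- (t - t_es) / (1 - t_es)
  dm <- ifelse(t <= t_es,
               amplitude * pi / (2 * t_es) * sin(pi * t / t_es),
               -amplitude / 2 * sin(pi * pmax(u, 0)^r) * pi * r *
                 pmax(u, 0)^(r - 1) / (1 - t_es))
  sign * dm / (100 * cycle_s)
}

#' Class presets for the synthetic cohort generator
#'
#' Invented, config-exposed presets chosen from textbook strain ranges —
#' they define qualitative class contrasts (globally low-amplitude,
#' tightly clustered dynamics in restrictive cardiomyopathy; a
#' lateral-wall sparing pattern in constrictive pericarditis; normal
#' amplitudes in controls), not any real cohort's values.
#'
#' Fields per class: `amp` / `amp_sd` (between-patient peak-strain mean
#' and SD, %, for LS/RS/CS; strain rates are derived analytically),
#' `regional` (per-view multiplicative region modifiers), `t_es_mean` /
#' `t_es_sd` (end-systolic fraction), `noise_sd` (additive per-sample
#' noise, % strain), `het_sd` (within-patient between-segment amplitude
#' SD), `n_samples_range` (raw samples per exported cycle),
#' `cycle_ms_range` (cycle length, ms).
#'
#' @param label `"NL"`, `"RCM"` or `"CP"`.
#' @return A list of class `class_preset`.
#' @export
class_preset <- function(label = c("NL", "RCM", "CP")) {
  label <- match.arg(label)
  base <- list(
    label = label,
    amp = c(LS = 20, RS = 38, CS = 20),
    amp_sd = c(LS = 2, RS = 3, CS = 2),
    regional = list(
      A4C = c(sept = 1, apex = 1, lat = 1),
      SAX_MID = c(ant_sept = 1, inf_sept = 1, lat = 1)),
    t_es_mean = 0.35, t_es_sd = 0.02,
    recovery_rate = 1,
    noise_sd = 0.5, het_sd = 1.0,
    n_samples_range = c(55L, 70L),
    cycle_ms_range = c(850, 950))
  over <- switch(label,
    NL = list(),
    RCM = list(amp = c(LS = 8, RS = 16, CS = 9), t_es_mean = 0.32),
    CP = list(amp = c(LS = 18, RS = 30, CS = 18), t_es_mean = 0.36,
              regional = list(
                A4C = c(sept = 1, apex = 0.8, lat = 0.55),
                SAX_MID = c(ant_sept = 1, inf_sept = 1, lat = 0.55))))
  structure(modifyList(base, over), class = "class_preset")
}

#' Specification of a synthetic cohort
#'
#' @param n_per_class Named counts, e.g. `c(CP = 50, RCM = 50, NL = 50)`.
#' @param seed Master integer seed; each patient gets an independent
#'   substream drawn from it, so a patient's data is reproducible
#'   regardless of generation order.
#' @param presets Named list of [class_preset]s (defaults per class).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(CP = 50L, RCM = 50L, NL = 50L),
                           seed = 1L, presets = NULL) {
  .assert(all(names(n_per_class) %in% c("CP", "RCM", "NL")) &&
            length(n_per_class) >= 1L, "n_per_class must name CP/RCM/NL")
  .assert(all(n_per_class >= 1L), "counts must be >= 1")
  if (is.null(presets))
    presets <- lapply(setNames(names(n_per_class), names(n_per_class)), class_preset)
  structure(list(n_per_class = n_per_class, seed = as.integer(seed),
                 presets = presets), class = "synthetic_spec")
}

#' Simulate one patient's full segmental trace set
#'
#' Draws patient-level amplitude, timing and cycle parameters from the
#' class preset, then per segment applies the regional modifier plus a
#' heterogeneity draw and adds Gaussian sample noise. Produces 49 A4C
#' segments (LS, LSR) and 48 short-axis segments (RS, RSR, CS, CSR) —
#' 290 series on a shared per-patient sampling grid of cycle fractions
#' (the cycle length in ms only scales the strain-rate traces).
#'
#' @param patient_id Identifier for the generated patient.
#' @param preset A [class_preset].
#' @param seed Integer substream seed; fixed seed gives a bit-identical
#'   patient.
#' @return List of [strain_trace] objects.
#' @export
simulate_patient <- function(patient_id, preset, seed = 1L) {
  set.seed(seed)
  amp_p <- pmax(preset$amp + rnorm(3, 0, preset$amp_sd), 1)
  names(amp_p) <- names(preset$amp)
  t_es <- min(max(rnorm(1, preset$t_es_mean, preset$t_es_sd), 0.22), 0.58)
  n_choices <- seq(preset$n_samples_range[1], preset$n_samples_range[2])
  n_samp <- n_choices[sample.int(length(n_choices), 1)]
  cycle_ms <- runif(1, preset$cycle_ms_range[1], preset$cycle_ms_range[2])
  traces <- list()
  for (view in .VIEWS) {
    regions <- segment_region(view, seq_len(.VIEW_NSEG[[view]]))
    measures <- names(.MEASURE_VIEW)[.MEASURE_VIEW == view]
    times_ms <- seq(0, cycle_ms, length.out = n_samp)
    tfrac <- times_ms / cycle_ms
    for (m in measures) {
      strain_of <- substr(m, 1, 2)
      is_rate <- nchar(m) == 3L
      for (seg in seq_len(.VIEW_NSEG[[view]])) {
        a <- amp_p[[strain_of]] * preset$regional[[view]][[regions[seg]]] +
          rnorm(1, 0, preset$het_sd)
        a <- max(a, 0.5)
        clean <- if (is_rate) {
          strain_rate_template(tfrac, a, t_es, preset$recovery_rate,
                               measure = strain_of, cycle_s = cycle_ms / 1000)
        } else {
          strain_template(tfrac, a, t_es, preset$recovery_rate, measure = strain_of)
        }
        noise_sd <- if (is_rate) preset$noise_sd / 10 else preset$noise_sd
        vals <- clean + rnorm(n_samp, 0, noise_sd)
        traces[[length(traces) + 1L]] <- strain_trace(
          patient_id, view, seg, m, tfrac, vals)
      }
    }
  }
  traces
}

#' Simulate a labelled synthetic cohort
#'
#' @param spec A [synthetic_spec] (or arguments to build one).
#' @return A [strain_cohort]; the generating spec is attached as
#'   attribute `"spec"` for provenance.
#' @export
simulate_cohort <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  classes <- names(spec$n_per_class)
  pids <- unlist(lapply(classes, function(cl)
    sprintf("%s%03d", cl, seq_len(spec$n_per_class[[cl]]))))
  labels <- setNames(rep(classes, spec$n_per_class), pids)
  sub_seeds <- sample.int(.Machine$integer.max, length(pids))
  traces <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    traces[[i]] <- simulate_patient(pids[i], spec$presets[[labels[[pids[i]]]]],
                                    seed = sub_seeds[i])
  }
  cohort <- strain_cohort(do.call(c, traces), labels)
  attr(cohort, "spec") <- spec
  cohort
}

#' Two-class regional-sparing scenario
#'
#' A designed scenario in which the global longitudinal strain baseline
#' is blind by construction: both classes share the same patient-level
#' amplitude distribution, but the "sparing" class redistributes it
#' regionally (septal accentuation, lateral sparing) with modifiers whose
#' segment-weighted mean is exactly 1, so the per-patient mean peak
#' strain — the GLS feature — is identically distributed across classes
#' while regional curves differ.
#'
#' @param n_per_class Patients per class (default 50).
#' @param seed Master seed.
#' @return A [synthetic_spec] with classes `CP` (regional sparing) and
#'   `NL` (uniform), both with LS amplitude 15 +/- 2.
#' @export
regional_sparing_spec <- function(n_per_class = 50L, seed = 1L) {
  uni <- class_preset("NL")
  uni$amp <- c(LS = 15, RS = 30, CS = 15)
  spar <- class_preset("CP")
  spar$amp <- uni$amp
  spar$t_es_mean <- uni$t_es_mean
  # A4C: 16 sept, 17 apex, 16 lat; (16*4/3 + 17*1 + 16*2/3)/49 = 1 exactly
  spar$regional <- list(
    A4C = c(sept = 4 / 3, apex = 1, lat = 2 / 3),
    SAX_MID = c(ant_sept = 4 / 3, inf_sept = 1, lat = 2 / 3))
  synthetic_spec(n_per_class = c(CP = n_per_class, NL = n_per_class),
                 seed = seed, presets = list(CP = spar, NL = uni))
}

#' Write a synthetic cohort to the on-disk dialect
#'
#' Emits the long-format strain TSV, the two-column labels CSV and, when
#' the cohort carries its generating spec, a JSON provenance file.
#'
#' @param cohort A [strain_cohort].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(strain = file.path(dir, "strain.tsv"),
             labels = file.path(dir, "labels.csv"))
  write_strain_table(cohort$data, paths[["strain"]])
  fwrite(data.table(patient_id = names(cohort$labels),
                    label = unname(cohort$labels)), paths[["labels"]])
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    paths[["spec"]] <- file.path(dir, "cohort_spec.json")
    jsonlite::write_json(unclass(spec), paths[["spec"]], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  paths
}
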