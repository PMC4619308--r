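fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "myelotitr")
  if (p == "") stop("packaging error: bundled fixture ", file, " not found")
  p
}

verify_fixture <- function(file) {
  mf <- utils::read.csv(fixture_path("manifest.csv"),
                        colClasses = "character")
  want <- mf$checksum[mf$file == file]
  txt <- paste(readLines(fixture_path(file)), collapse = "\n")
  if (length(want) != 1L || !identical(text_checksum(txt), want))
    stop("packaging error: checksum mismatch for bundled fixture ", file)
  invisible(TRUE)
}

#' Per-subject per-cycle dose records of the clinical study
#'
#' The bundled transcription of the published dose table: 16 subjects in 5
#' cohorts of 3 (cohort 1 enrolled a replacement after an early dropout),
#' doses in mg/m2/day for cycles 1-4, with flags for cycles where
#' model-based individual dose titration (IDT) was not applied and cycles
#' with grade-4 (dose-limiting) toxicity. The early-dropout subject
#' (subject 3, no PD sampling) is marked `included_in_accounting = FALSE`;
#' excluding that subject reproduces the published cycle accounting
#' (58 administered cycles, 39 IDT / 19 non-IDT).
#'
#' @return data.frame of class `subject_cycle_records` with columns
#'   `cohort`, `subject`, `cycle`, `dose`, `no_idt`, `dlt`, `idt`,
#'   `included_in_accounting` plus clinical annotation columns
#' @export
load_table2 <- function() {
  verify_fixture("table2_doses.csv")
  df <- utils::read.csv(fixture_path("table2_doses.csv"))
  df$no_idt <- as.logical(df$no_idt)
  df$dlt <- as.logical(df$dlt)
  # IDT means a model-titrated dose: only possible from cycle 2 onward
  df$idt <- !df$no_idt & df$cycle >= 2 & !is.na(df$dose)
  df$included_in_accounting <- df$subject != 3L
  given <- df$dose[!is.na(df$dose)]
  if (any(abs(given / 0.5 - round(given / 0.5)) > 1e-9))
    stop("packaging error: administered doses must be multiples of 0.5")
  class(df) <- c("subject_cycle_records", "data.frame")
  df
}

#' Published population parameter estimates
#'
#' The bundled final population PK-PD parameter estimates (typical values,
#' between-subject variability as CV%, residual-error variances), returned
#' as a ready-to-use [population_model()]. Bootstrap medians and 95% CIs
#' are attached as the `"bootstrap"` attribute (metadata only).
#'
#' @param cv_convention passed to [population_model()]
#' @return a [population_model()]
#' @export
load_table3 <- function(cv_convention = "approx") {
  verify_fixture("table3_parameters.csv")
  df <- utils::read.csv(fixture_path("table3_parameters.csv"))
  v <- stats::setNames(df$typical, df$parameter)
  pk <- pk_parameters(v[["cl"]], v[["vc"]], v[["vp"]], v[["q"]])
  pd_anc <- pd_parameters(v[["ktr_anc"]], v[["slope_anc"]], v[["base_anc"]],
                          v[["gamma_anc"]], marker = "ANC")
  pd_pc <- pd_parameters(v[["ktr_pc"]], v[["slope_pc"]], v[["base_pc"]],
                         v[["gamma_pc"]], v[["imp"]], v[["imk"]],
                         marker = "PC")
  cv <- stats::setNames(df$bsv_cv, df$parameter)
  cv <- cv[!is.na(cv) & names(cv) %in% .mt_par_names]
  pop <- population_model(pk, pd_anc, pd_pc, bsv_cv = cv,
                          sigma2_pk_prop = v[["sigma2_pk_prop"]],
                          sigma2_anc_add = v[["sigma2_anc_add"]],
                          sigma2_pc_add = v[["sigma2_pc_add"]],
                          cv_convention = cv_convention)
  attr(pop, "bootstrap") <- df[, c("parameter", "unit", "description",
                                   "boot_median", "boot_lo", "boot_hi")]
  pop
}

#' @rdname load_table3
#' @export
default_population <- function(cv_convention = "approx")
  load_table3(cv_convention)

#' Reproduce the published safety accounting
#'
#' Applies [summarize_safety()] to the bundled dose records (with the
#' dropout exclusion), yielding the stratified dose-limiting-toxicity
#' summary as published.
#'
#' @return a `safety_summary` list
#' @export
reproduce_reported_safety <- function() summarize_safety(load_table2())

#' The study's PK/PD sampling design
#'
#' Seven PK samples on Cycle-1 Day-1 (pre-dose and 20/40/60/90/120/180 min
#' after the start of the first infusion) and blood-count monitoring weekly
#' until the end of Cycle 4, biweekly thereafter.
#'
#' @param pk_times_min PK sampling times, minutes from first-infusion start
#' @param pd_interval_days visit interval during cycles 1-4
#' @param pd_interval_late_days visit interval after Cycle 4
#' @return an object of class `sampling_design`
#' @export
study_sampling_design <- function(pk_times_min = c(0, 20, 40, 60, 90, 120, 180),
                                  pd_interval_days = 7,
                                  pd_interval_late_days = 14) {
  if (is.unsorted(pk_times_min)) stop_input("PK times must be ascending")
  structure(list(pk_times_min = pk_times_min,
                 pd_interval_days = pd_interval_days,
                 pd_interval_late_days = pd_interval_late_days),
            class = "sampling_design")
}

pd_visit_times <- function(design, n_cycles, cycle_interval_days = 28,
                           tail_weeks = 6) {
  end4 <- min(n_cycles, 4) * cycle_interval_days * 24
  tt <- seq(0, end4, by = design$pd_interval_days * 24)
  if (n_cycles > 4) {
    end <- (n_cycles - 1) * cycle_interval_days * 24 + tail_weeks * 168
    tt <- c(tt, seq(end4 + design$pd_interval_late_days * 24, end,
                    by = design$pd_interval_late_days * 24))
  } else {
    end <- end4 + (tail_weeks * 168 - cycle_interval_days * 24)
    if (end > end4)
      tt <- c(tt, seq(end4 + design$pd_interval_days * 24, end,
                      by = design$pd_interval_days * 24))
  }
  tt
}

#' Generate a synthetic study dataset from a population model
#'
#' Draws virtual subjects (BSA ~ Normal(1.7, 0.2) m2 truncated positive,
#' lognormal BSV), simulates their true concentration and blood-count
#' trajectories under the protocol regimen, applies the residual-error
#' model, and flags concentrations below the quantification limit. The
#' sampling schedule follows [study_sampling_design()].
#'
#' @param truth generating [population_model()]
#' @param n_subjects number of virtual subjects
#' @param seed integer seed (mandatory: the generator is stochastic)
#' @param design a [study_sampling_design()]
#' @param daily_dose mg/m2/day
#' @param n_cycles number of treatment cycles simulated
#' @param cycle_interval_days days between cycle starts
#' @param lloq ng/mL; concentration observations below this are flagged
#' @param count_floor lower bound for simulated counts, cells/mm3
#' @return list of [subject_data()] (class `mt_study`), with the drawn
#'   `individual_parameters` attached as attribute `"individuals"`
#' @export
generate_synthetic_study <- function(truth, n_subjects, seed,
                                     design = study_sampling_design(),
                                     daily_dose = 5, n_cycles = 4,
                                     cycle_interval_days = 28, lloq = 0.5,
                                     count_floor = 0) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    subjects <- vector("list", n_subjects)
    indivs <- vector("list", n_subjects)
    pk_times <- design$pk_times_min / 60
    pd_times <- pd_visit_times(design, n_cycles, cycle_interval_days)
    for (i in seq_len(n_subjects)) {
      repeat {
        bsa <- stats::rnorm(1, 1.7, 0.2)
        if (bsa > 0) break
      }
      ind <- draw_individual(truth, bsa = bsa, id = i)
      reg <- standard_regimen(daily_dose, n_cycles = n_cycles,
                              cycle_interval_days = cycle_interval_days,
                              bsa = bsa)
      conc <- predict_concentration(ind$pk, reg, pk_times)
      counts <- sim_counts(ind, reg, sort(unique(c(0, pd_times))))
      anc <- counts$anc[match(pd_times, counts$times)]
      pc <- counts$pc[match(pd_times, counts$times)]
      dv_c <- apply_residual_error(conc, "conc", truth)
      dv_a <- apply_residual_error(anc, "ANC", truth, floor = count_floor)
      dv_p <- apply_residual_error(pc, "PC", truth, floor = count_floor)
      obs <- rbind(
        data.frame(time = pk_times, kind = "conc", value = dv_c,
                   bql = dv_c < lloq),
        data.frame(time = pd_times, kind = "ANC", value = dv_a, bql = FALSE),
        data.frame(time = pd_times, kind = "PC", value = dv_p, bql = FALSE))
      obs <- obs[order(obs$time, obs$kind), ]
      rownames(obs) <- NULL
      subjects[[i]] <- subject_data(obs, reg, bsa = bsa, id = i)
      indivs[[i]] <- ind
    }
    structure(subjects, class = c("mt_study", "list"), individuals = indivs,
              seed = seed)
  })
}

# joint true ANC/PC trajectories at given times for one individual
sim_counts <- function(ind, regimen, times, rtol = 1e-6, atol = 0.01) {
  pdm <- rbind(pd_vec(ind$pd_anc), pd_vec(ind$pd_pc))
  y0 <- c(rep(ind$pd_anc$base, 5), rep(ind$pd_pc$base, 5))
  st <- cpp_simulate(times, events_matrix(regimen), pk_vec(ind$pk, ind$bsa),
                     pdm, y0, rtol, atol)
  list(times = times, anc = st[, 5], pc = st[, 10])
}
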