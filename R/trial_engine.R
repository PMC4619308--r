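#' Configuration of the virtual adaptive trial
#'
#' Mirrors the phase-I design: cohorts of three on a fixed Cycle-1 dose
#' (5 mg/m2/day for cohort 1, model-estimated for later cohorts),
#' individual dose titration for Cycles 2-4, the Cycle-4 dose maintained
#' thereafter, dosing suspended while blood counts are insufficiently
#' recovered (PC < 30,000/mm3 or ANC < 1000/mm3, rechecked weekly), and a
#' new cohort starting only after the previous cohort's last subject
#' completes Cycle 1.
#'
#' @param n_cohorts number of cohorts
#' @param cohort_size subjects per cohort
#' @param initial_dose_cohort1 mg/m2/day
#' @param days_per_cycle consecutive dosing days per cycle
#' @param cycle_interval_days protocol interval between cycle starts
#' @param max_cycles cycles simulated per subject
#' @param idt_cycles cycles whose dose is selected by individual titration
#' @param suspend_pc,suspend_anc suspension thresholds, cells/mm3
#' @param recheck_days re-evaluation interval while suspended
#' @param max_delay_days a subject whose counts have not recovered after
#'   this delay discontinues
#' @param cde use cohort dose estimation for cohorts 2+ (fixed initial dose
#'   otherwise)
#' @param interval_jitter_sd optional SD (days) of lognormal-free jitter
#'   added to the protocol cycle interval, reflecting the observed mean
#'   34.5 +/- 8.7-day spacing; 0 keeps the protocol interval
#' @param dlt_from_labs flag dose-limiting toxicity from the simulated
#'   weekly labs only, instead of the continuous true trajectory
#' @param fit_starts optimisation starts per within-trial refit (warm
#'   started at the previous cycle's estimate)
#' @param titration a [titration_config()]
#' @return an object of class `trial_config`
#' @export
trial_config <- function(n_cohorts = 5, cohort_size = 3,
                         initial_dose_cohort1 = 5, days_per_cycle = 5,
                         cycle_interval_days = 28, max_cycles = 4,
                         idt_cycles = 2:4, suspend_pc = 30000,
                         suspend_anc = 1000, recheck_days = 7,
                         max_delay_days = 84, cde = TRUE,
                         interval_jitter_sd = 0, dlt_from_labs = FALSE,
                         fit_starts = 1,
                         titration = titration_config(search = "bisect")) {
  if (cohort_size < 1) stop_input("cohort_size must be >= 1")
  if (suspend_pc <= 0 || suspend_anc <= 0)
    stop_input("suspension thresholds must be positive")
  if (!all(idt_cycles %in% 2:max_cycles))
    stop_input("idt_cycles must lie within 2..max_cycles")
  structure(list(n_cohorts = n_cohorts, cohort_size = cohort_size,
                 initial_dose_cohort1 = initial_dose_cohort1,
                 days_per_cycle = days_per_cycle,
                 cycle_interval_days = cycle_interval_days,
                 max_cycles = max_cycles, idt_cycles = idt_cycles,
                 suspend_pc = suspend_pc, suspend_anc = suspend_anc,
                 recheck_days = recheck_days,
                 max_delay_days = max_delay_days, cde = cde,
                 interval_jitter_sd = interval_jitter_sd,
                 dlt_from_labs = dlt_from_labs, fit_starts = fit_starts,
                 titration = titration),
            class = "trial_config")
}

# observed (noisy) counts at a visit time, given the true event history
observe_counts <- function(ind, events, t, truth, floor = 1) {
  reg <- dose_regimen(events)
  tt <- sort(unique(c(0, t)))
  cnt <- sim_counts(ind, reg, tt)
  i <- match(t, tt)
  c(anc = apply_residual_error(cnt$anc[i], "ANC", truth, floor = floor),
    pc = apply_residual_error(cnt$pc[i], "PC", truth, floor = floor))
}

draw_eligible_individual <- function(truth, cfg, id) {
  tries <- 0
  repeat {
    repeat {
      bsa <- stats::rnorm(1, 1.7, 0.2)
      if (bsa > 0) break
    }
    ind <- draw_individual(truth, bsa = bsa, id = id)
    if (ind$pd_pc$base > cfg$suspend_pc && ind$pd_anc$base > cfg$suspend_anc)
      return(ind)
    if ((tries <- tries + 1) > 1000)
      stop_input("truth population incompatible with enrolment screen")
  }
}

#' Run a virtual replication of the adaptive trial
#'
#' Draws each subject from the truth population (screened by the study's
#' enrolment criteria), generates observations per the study sampling
#' design, refits and titrates exactly as [select_cycle_dose()] prescribes,
#' delays cycle starts while the observed counts violate the suspension
#' thresholds, and gates each cohort on the previous cohort's Cycle-1
#' completion. Observed (noisy) counts drive suspension and refitting;
#' true (noise-free) trajectories define the dose-limiting-toxicity flags.
#' Fully deterministic given `seed`.
#'
#' @param truth generating [population_model()]
#' @param cfg [trial_config()]
#' @param seed integer seed
#' @return a `virtual_trial_record`: `cycles` (per subject-cycle rows with
#'   planned/actual start day, dose, flags and true nadirs),
#'   `observations`, the per-cohort `cohort_doses`, the drawn
#'   `individuals`, `config` and `seed`
#' @export
run_virtual_trial <- function(truth, cfg = trial_config(), seed = 1L) {
  tcfg <- cfg$titration
  cyc_rows <- list()
  obs_rows <- list()
  indivs <- list()
  cohort_doses <- numeric(cfg$n_cohorts)
  cohort_start_day <- 0
  sid <- 0
  rngs <- function(i) child_seed(seed, i)
  rng_i <- 0
  cycle1_data <- list()   # per subject: cycle-1 subject_data (for CDE)
  all_data <- list()
  for (co in seq_len(cfg$n_cohorts)) {
    if (co == 1 || !cfg$cde) {
      start_dose <- cfg$initial_dose_cohort1
    } else {
      pool <- if (co == 2) all_data else cycle1_data
      pfit <- fit_population_two_stage(pool, truth,
                                       fit_starts = cfg$fit_starts,
                                       rtol = 1e-5, atol = 0.1)
      dec <- estimate_cohort_start_dose(pfit, tcfg,
                                        seed = rngs(rng_i <- rng_i + 1))
      start_dose <- dec$selected
    }
    cohort_doses[co] <- start_dose
    last_c1_end <- cohort_start_day
    for (s in seq_len(cfg$cohort_size)) {
      sid <- sid + 1
      set.seed(rngs(rng_i <- rng_i + 1))
      ind <- draw_eligible_individual(truth, cfg, sid)
      indivs[[sid]] <- ind
      res <- simulate_subject(ind, start_dose, truth, cfg, co,
                              base_seed = rngs(rng_i <- rng_i + 1))
      res$cycles$cohort <- co
      res$cycles$subject <- sid
      res$cycles$calendar_start_day <- res$cycles$actual_start_day +
        cohort_start_day
      res$observations$subject <- sid
      cyc_rows[[sid]] <- res$cycles
      obs_rows[[sid]] <- res$observations
      cycle1_data[[sid]] <- res$cycle1_data
      all_data[[sid]] <- res$all_data
      last_c1_end <- max(last_c1_end,
                         cohort_start_day + res$cycles$actual_start_day[1] +
                           cfg$cycle_interval_days)
    }
    cohort_start_day <- last_c1_end
  }
  cycles <- do.call(rbind, cyc_rows)
  rownames(cycles) <- NULL
  structure(list(cycles = cycles,
                 observations = do.call(rbind, obs_rows),
                 cohort_doses = cohort_doses, individuals = indivs,
                 config = cfg, seed = seed),
            class = "virtual_trial_record")
}

# one subject's course through the trial
simulate_subject <- function(ind, start_dose, truth, cfg, cohort,
                             base_seed) {
  tcfg <- cfg$titration
  design <- study_sampling_design()
  events <- data.frame(start_time = numeric(), duration = numeric(),
                       dose_per_bsa = numeric(), bsa = numeric())
  obs <- data.frame(time = numeric(), kind = character(),
                    value = numeric(), bql = logical())
  rows <- list()
  dose <- start_dose
  last_pos_dose <- start_dose  # cap base: the last positive dose given
  fit <- NULL
  day <- 0
  withdrawn <- FALSE
  rix <- 0
  for (cycle in seq_len(cfg$max_cycles)) {
    planned <- day
    # ---- suspension: delay while the latest observed counts are low ----
    delayed <- 0
    if (cycle > 1) {
      repeat {
        set.seed(child_seed(base_seed, rix <- rix + 1))
        cnt <- observe_counts(ind, events, day * 24, truth)
        obs <- rbind(obs, data.frame(
          time = day * 24, kind = c("ANC", "PC"), value = cnt,
          bql = FALSE))
        if (cnt[["anc"]] >= cfg$suspend_anc && cnt[["pc"]] >= cfg$suspend_pc)
          break
        day <- day + cfg$recheck_days
        delayed <- delayed + cfg$recheck_days
        if (delayed > cfg$max_delay_days) { withdrawn <- TRUE; break }
      }
    }
    if (withdrawn) break
    # ---- dose decision -------------------------------------------------
    idt <- FALSE; capped <- FALSE; no_safe <- FALSE
    if (cycle %in% cfg$idt_cycles) {
      set.seed(child_seed(base_seed, rix <- rix + 1))
      data_now <- subject_data(obs[obs$time <= day * 24, ], events,
                               bsa = ind$bsa, id = ind$id)
      fit <- tryCatch(
        fit_individual_map(data_now, truth, init = fit,
                           n_starts = cfg$fit_starts,
                           seed = child_seed(base_seed, rix),
                           rtol = 1e-5, atol = 0.1),
        error = function(e) NULL)
      if (is.null(fit)) {
        # clinical fallback: repeat the previous dose
        idt <- FALSE
      } else {
        dec <- select_cycle_dose(fit, last_pos_dose, truth, tcfg,
                                 cycle_start = day * 24, history = events,
                                 seed = child_seed(base_seed, rix))
        idt <- TRUE
        capped <- dec$cap_applied
        no_safe <- dec$no_safe_dose
        dose <- dec$selected
      }
    } else if (cycle > 1 && !cycle %in% cfg$idt_cycles &&
               cycle > max(cfg$idt_cycles)) {
      # maintenance: keep the Cycle-4 dose (already in `dose`)
    }
    # ---- administer the cycle ------------------------------------------
    reg <- standard_regimen(dose, n_days = cfg$days_per_cycle,
                            n_cycles = 1, bsa = ind$bsa,
                            cycle_starts = day * 24)
    events <- rbind(events, as.data.frame(reg))
    if (dose > 0) last_pos_dose <- dose
    # weekly labs during the cycle (biweekly after cycle 4)
    vis_int <- if (cycle <= 4) design$pd_interval_days else
      design$pd_interval_late_days
    cycle_end_day <- day + cfg$cycle_interval_days
    visits <- seq(day + vis_int, cycle_end_day - 1e-9, by = vis_int)
    if (length(visits)) {
      set.seed(child_seed(base_seed, rix <- rix + 1))
      for (vd in visits) {
        cnt <- observe_counts(ind, events, vd * 24, truth)
        obs <- rbind(obs, data.frame(
          time = vd * 24, kind = c("ANC", "PC"), value = cnt, bql = FALSE))
      }
    }
    if (cycle == 1) {  # PK sampling on Cycle-1 Day 1
      set.seed(child_seed(base_seed, rix <- rix + 1))
      pk_t <- day * 24 + design$pk_times_min / 60
      conc <- predict_concentration(ind$pk, dose_regimen(events), pk_t)
      dv <- apply_residual_error(conc, "conc", truth)
      obs <- rbind(obs, data.frame(time = pk_t, kind = "conc", value = dv,
                                   bql = dv < 0.5))
    }
    rows[[cycle]] <- data.frame(
      cycle = cycle, planned_start_day = planned, actual_start_day = day,
      dose = dose, idt = idt, cap_applied = capped, no_safe_dose = no_safe)
    if (cycle == 1)
      cycle1_snapshot <- subject_data(obs, events, bsa = ind$bsa,
                                      id = ind$id)
    # next cycle start (protocol interval, optional realistic jitter)
    gap <- cfg$cycle_interval_days
    if (cfg$interval_jitter_sd > 0) {
      set.seed(child_seed(base_seed, rix <- rix + 1))
      gap <- max(gap, stats::rnorm(1, 34.5, cfg$interval_jitter_sd))
    }
    day <- day + gap
  }
  cycles <- do.call(rbind, rows)
  # ---- true nadirs and DLT flags per administered cycle ----------------
  n_cyc <- nrow(cycles)
  horizon <- (max(cycles$actual_start_day) + 42) * 24
  tr_t <- seq(0, horizon, by = tcfg$grid_dt_h)
  tr <- sim_counts(ind, dose_regimen(events), tr_t, rtol = tcfg$sim_rtol,
                   atol = tcfg$sim_atol)
  cycles$anc_nadir <- NA_real_; cycles$pc_nadir <- NA_real_
  cycles$dlt <- NA
  for (k in seq_len(n_cyc)) {
    w0 <- cycles$actual_start_day[k] * 24
    w1 <- if (k < n_cyc) cycles$actual_start_day[k + 1] * 24 else
      w0 + 6 * 168
    if (cfg$dlt_from_labs) {
      lab <- obs[obs$time >= w0 & obs$time < w1 & obs$kind != "conc", ]
      a <- min(lab$value[lab$kind == "ANC"], Inf)
      p <- min(lab$value[lab$kind == "PC"], Inf)
    } else {
      keep <- tr_t >= w0 & tr_t < w1
      a <- min(tr$anc[keep])
      p <- min(tr$pc[keep])
    }
    cycles$anc_nadir[k] <- a
    cycles$pc_nadir[k] <- p
    cycles$dlt[k] <- a < tcfg$anc_threshold | p < tcfg$pc_threshold
  }
  obs$subject <- ind$id
  list(cycles = cycles, observations = obs,
       cycle1_data = cycle1_snapshot,
       all_data = subject_data(obs[, c("time", "kind", "value", "bql")],
                               events, bsa = ind$bsa, id = ind$id))
}

#' @export
print.virtual_trial_record <- function(x, ...) {
  cat(sprintf("<virtual_trial_record> %d subjects, %d cycles, seed %d\n",
              length(x$individuals), nrow(x$cycles), x$seed))
  print(summarize_safety(x))
  invisible(x)
}

#' Stratified safety summary
#'
#' Cycle counts and dose-limiting-toxicity (grade-4) counts stratified by
#' whether the cycle's dose was individually titrated, with percentages
#' rounded half-up to one decimal as in the published report. Accepts
#' either a [run_virtual_trial()] record or the bundled
#' `subject_cycle_records` (where the dropout-excluded accounting applies).
#'
#' @param rec a `virtual_trial_record` or `subject_cycle_records`
#' @return a `safety_summary` list: `n_cycles`, `n_idt`, `n_non_idt`,
#'   `dlt_total`, `dlt_idt`, `dlt_non_idt`, `pct_dlt_idt`,
#'   `pct_dlt_non_idt`, and `median_nadir_idt` when nadirs are available
#' @export
summarize_safety <- function(rec) {
  if (inherits(rec, "virtual_trial_record")) {
    df <- rec$cycles
    df$included <- TRUE
  } else {
    df <- as.data.frame(rec)
    if (is.null(df$included)) df$included <- df$included_in_accounting
  }
  df <- df[df$included & !is.na(df$dose), , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no completed cycles")
    return(structure(list(n_cycles = 0L), class = "safety_summary"))
  }
  idt <- df$idt
  dlt <- df$dlt
  out <- list(
    n_cycles = nrow(df),
    n_idt = sum(idt), n_non_idt = sum(!idt),
    dlt_total = sum(dlt), dlt_idt = sum(dlt & idt),
    dlt_non_idt = sum(dlt & !idt),
    pct_dlt_idt = if (sum(idt)) round_half_up(100 * sum(dlt & idt) /
                                                sum(idt), 1) else NA_real_,
    pct_dlt_non_idt = if (sum(!idt))
      round_half_up(100 * sum(dlt & !idt) / sum(!idt), 1) else NA_real_)
  if (!is.null(df$anc_nadir))
    out$median_nadir_idt <- stats::median(df$anc_nadir[idt])
  structure(out, class = "safety_summary")
}

#' @export
print.safety_summary <- function(x, ...) {
  cat(sprintf("<safety_summary> %d cycles (%d IDT / %d non-IDT)\n",
              x$n_cycles, x$n_idt %||% 0, x$n_non_idt %||% 0))
  if (!is.null(x$dlt_total))
    cat(sprintf("  DLT: %d total; IDT %d (%.1f%%), non-IDT %d (%.1f%%)\n",
                x$dlt_total, x$dlt_idt, x$pct_dlt_idt, x$dlt_non_idt,
                x$pct_dlt_non_idt))
  invisible(x)
}
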