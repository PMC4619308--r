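#' Configuration of the simulation-based dose selection
#'
#' Encodes the trial's titration rule: among a 0.5 mg/m2/day candidate
#' grid, the selected dose is the largest whose lower 50% prediction bound
#' (the 25th percentile over 500 simulated replicates) of the predicted
#' nadir avoids grade-4 toxicity for both markers (ANC >= 500/mm3 and
#' platelets >= 25,000/mm3), with the next-cycle dose additionally capped
#' at 150% of the previous dose.
#'
#' @param dose_grid candidate doses, mg/m2/day, ascending
#' @param n_sim simulation replicates per candidate dose
#' @param percentile lower prediction bound, in (0, 50)
#' @param anc_threshold,pc_threshold grade-4 thresholds, cells/mm3
#' @param cap_fraction maximum dose increment as a fraction of the previous
#'   dose (> 1)
#' @param window_weeks nadir evaluation window after the next cycle's first
#'   dose
#' @param uncertainty replicate source for individual titration:
#'   `"estimation"` (draws from the fit's approximate covariance, the
#'   default), `"bsv"` (population variability) or `"none"`
#' @param search `"grid"` evaluates every candidate up to one step beyond
#'   the cap (full decision table); `"bisect"` exploits the monotonicity of
#'   the percentile nadir in dose to locate the qualifying boundary in
#'   O(log) probes (used inside virtual trials)
#' @param sim_rtol,sim_atol,grid_dt_h integration tolerances and nadir-scan
#'   resolution used inside the simulations
#' @param eligibility named limits (`pc`, `anc`) applied when drawing fresh
#'   virtual subjects for cohort dose estimation, mirroring the study's
#'   enrolment criteria; set to NULL to disable
#' @return an object of class `titration_config`
#' @export
titration_config <- function(dose_grid = seq(0, 15, by = 0.5), n_sim = 500,
                             percentile = 25, anc_threshold = 500,
                             pc_threshold = 25000, cap_fraction = 1.5,
                             window_weeks = 6,
                             uncertainty = c("estimation", "bsv", "none"),
                             search = c("grid", "bisect"),
                             sim_rtol = 1e-5, sim_atol = 0.1,
                             grid_dt_h = 6,
                             eligibility = c(pc = 30000, anc = 1000)) {
  uncertainty <- match.arg(uncertainty)
  search <- match.arg(search)
  if (!length(dose_grid) || is.unsorted(dose_grid, strictly = TRUE))
    stop_input("dose_grid must be strictly ascending")
  if (any(dose_grid < 0)) stop_input("doses must be non-negative")
  if (percentile <= 0 || percentile >= 50)
    stop_input("percentile must be in (0, 50)")
  if (anc_threshold <= 0 || pc_threshold <= 0)
    stop_input("toxicity thresholds must be positive")
  if (cap_fraction <= 1) stop_input("cap_fraction must exceed 1")
  structure(list(dose_grid = dose_grid, n_sim = as.integer(n_sim),
                 percentile = percentile, anc_threshold = anc_threshold,
                 pc_threshold = pc_threshold, cap_fraction = cap_fraction,
                 window_weeks = window_weeks, uncertainty = uncertainty,
                 search = search,
                 sim_rtol = sim_rtol, sim_atol = sim_atol,
                 grid_dt_h = grid_dt_h, eligibility = eligibility),
            class = "titration_config")
}

# parameter-matrix row for the compiled batch simulator (BSA-invariant
# per-m2 basis): ncmt, CL, V1, Q, V2, 6 ANC values, 6 PC values
par_row <- function(pk, pd_anc, pd_pc) {
  c(pk_vec(pk), pd_vec(pd_anc), pd_vec(pd_pc))
}

# n_sim parameter rows for an individual fit under the configured
# uncertainty source
draw_replicate_pars <- function(fit, pop, cfg) {
  point <- c(fit$eta)
  free <- fit$free
  base_row <- par_row(fit$individual$pk, fit$individual$pd_anc,
                      fit$individual$pd_pc)
  if (cfg$uncertainty == "none" || !length(free))
    return(matrix(base_row, cfg$n_sim, length(base_row), byrow = TRUE))
  if (cfg$uncertainty == "estimation") {
    if (is.null(fit$cov)) {
      warning("fit covariance unavailable; falling back to BSV draws")
      dr <- sapply(free, function(p)
        stats::rnorm(cfg$n_sim, 0, pop$omega[p]))
    } else {
      dr <- rmvnorm_chol(cfg$n_sim, point[free], fit$cov[free, free])
      colnames(dr) <- free
    }
  } else {  # conditional BSV around the point estimate
    dr <- sapply(free, function(p) stats::rnorm(cfg$n_sim, point[p],
                                                pop$omega[p]))
  }
  dr <- matrix(dr, nrow = cfg$n_sim, dimnames = list(NULL, free))
  t(apply(dr, 1, function(e) {
    ind <- individual_from_eta(pop, stats::setNames(e, free))
    par_row(ind$pk, ind$pd_anc, ind$pd_pc)
  }))
}

# 25th-percentile (type-7) nadir per marker for one candidate dose
nadir_quantiles <- function(par_mat, events, cfg, cycle_start, q) {
  nd <- cpp_nadir_batch(par_mat, events, cycle_start,
                        cycle_start + cfg$window_weeks * 168,
                        cfg$grid_dt_h, cfg$sim_rtol, cfg$sim_atol)
  c(anc = unname(stats::quantile(nd[, 2], q / 100, type = 7)),
    pc = unname(stats::quantile(nd[, 4], q / 100, type = 7)))
}

candidate_events <- function(history, dose, cycle_start, n_days = 5,
                             infusion_hours = 1) {
  # the replicate simulations run on the BSA-invariant per-m2 basis, so the
  # realised history is normalised to BSA = 1 to match the candidate cycle
  nxt <- standard_regimen(dose, n_days = n_days, n_cycles = 1,
                          infusion_hours = infusion_hours,
                          cycle_starts = cycle_start)
  hist_ev <- matrix(numeric(0), 0, 3)
  if (!is.null(history) && nrow(history)) {
    h <- as.data.frame(history)
    h$bsa <- 1
    hist_ev <- events_matrix(dose_regimen(h))
  }
  rbind(hist_ev, events_matrix(nxt))
}

#' Predicted nadir distribution for a candidate dose
#'
#' Draws `n_sim` parameter vectors from the individual's estimation
#' uncertainty (multivariate normal on the log-parameter deviations, using
#' the fit's curvature-based covariance), appends the candidate cycle to
#' the subject's realised dosing history, and records the nadir of each
#' marker over the evaluation window. Residual error is excluded: nadirs
#' are model states, not noisy observations.
#'
#' @param fit an `mt_fit` from [fit_individual_map()]
#' @param pop [population_model()] (fallback variability source)
#' @param dose candidate dose, mg/m2/day
#' @param cfg [titration_config()]
#' @param cycle_start start of the upcoming cycle, h since first dose
#' @param history realised dosing history (data.frame of dose events);
#'   defaults to the fitted subject's own events
#' @param seed integer seed
#' @return list with per-replicate `anc` and `pc` nadirs (cells/mm3) and
#'   their times (`t_anc`, `t_pc`, h)
#' @export
nadir_distribution <- function(fit, pop, dose, cfg = titration_config(),
                               cycle_start = NULL, history = NULL,
                               seed = 1L) {
  history <- history %||% fit$data$events
  cycle_start <- cycle_start %||%
    (if (nrow(history)) max(history$start_time) + 24 else 0)
  ev <- candidate_events(history, dose, cycle_start)
  par_mat <- with_seed(seed, draw_replicate_pars(fit, pop, cfg))
  nd <- cpp_nadir_batch(par_mat, ev, cycle_start,
                        cycle_start + cfg$window_weeks * 168,
                        cfg$grid_dt_h, cfg$sim_rtol, cfg$sim_atol)
  list(anc = nd[, 2], t_anc = nd[, 1], pc = nd[, 4], t_pc = nd[, 3])
}

select_from_grid <- function(par_mat, cfg, cycle_start, history, cap) {
  grid <- cfg$dose_grid
  eval_max <- min(max(grid), cap)
  # candidates above the cap can never be selected; evaluate one grid step
  # beyond the cap so the cap_applied flag is decided by simulation
  idx <- which(grid <= eval_max)
  above <- which(grid > eval_max)
  if (length(above)) idx <- c(idx, above[1])
  env <- new.env()
  env$qs <- matrix(NA_real_, length(grid), 2,
                   dimnames = list(NULL, c("anc", "pc")))
  eval_dose <- function(i) {
    if (is.na(env$qs[i, 1])) {
      ev <- candidate_events(history, grid[i], cycle_start)
      env$qs[i, ] <- nadir_quantiles(par_mat, ev, cfg, cycle_start,
                                     cfg$percentile)
    }
    env$qs[i, "anc"] >= cfg$anc_threshold &&
      env$qs[i, "pc"] >= cfg$pc_threshold
  }
  if (cfg$search == "grid") {
    for (i in idx) eval_dose(i)
  } else {
    # the percentile nadir is non-increasing in dose, so the qualifying set
    # is downward-closed: locate its upper boundary by bisection
    l <- 0L
    r <- length(idx) + 1L
    while (r - l > 1L) {
      m <- (l + r) %/% 2L
      if (eval_dose(idx[m])) l <- m else r <- m
    }
  }
  qualifies <- env$qs[, "anc"] >= cfg$anc_threshold &
    env$qs[, "pc"] >= cfg$pc_threshold
  list(qs = env$qs, qualifies = qualifies,
       evaluated = which(!is.na(env$qs[, 1])))
}

#' Select the next-cycle dose by individual dose titration
#'
#' Implements the trial's per-cycle rule: the maximum candidate dose whose
#' lower prediction bound of the nadir avoids grade-4 toxicity for both
#' markers, clipped to `cap_fraction` times the previous dose. If no
#' candidate qualifies the grid minimum is returned with a no-safe-dose
#' flag (the clinical-fallback policy hook of the trial engine then takes
#' over).
#'
#' @inheritParams nadir_distribution
#' @param previous_dose the subject's previous cycle dose, mg/m2/day (> 0)
#' @return a `titration_decision`: the per-candidate percentile `table`,
#'   `selected` dose, `limiting_marker`, `cap_applied`, `no_safe_dose`,
#'   `seed` and `n_sim`
#' @export
select_cycle_dose <- function(fit, previous_dose, pop,
                              cfg = titration_config(), cycle_start = NULL,
                              history = NULL, seed = 1L) {
  if (!length(cfg$dose_grid)) stop_input("empty dose grid")
  if (previous_dose <= 0) stop_input("previous_dose must be positive")
  history <- history %||% fit$data$events
  cycle_start <- cycle_start %||%
    (if (nrow(history)) max(history$start_time) + 24 else 0)
  cap <- cfg$cap_fraction * previous_dose
  par_mat <- with_seed(seed, draw_replicate_pars(fit, pop, cfg))
  sel <- select_from_grid(par_mat, cfg, cycle_start, history, cap)
  finalize_decision(sel, cfg, cap, seed)
}

finalize_decision <- function(sel, cfg, cap, seed) {
  grid <- cfg$dose_grid
  ok <- which(sel$qualifies)
  no_safe <- length(ok) == 0
  d_star <- if (no_safe) grid[1] else grid[max(ok)]
  selected <- if (no_safe) grid[1] else min(d_star, cap)
  cap_applied <- !no_safe && cap < d_star
  limiting <- NA_character_
  nxt <- if (!no_safe) max(ok) + 1 else 1
  if (nxt <= length(grid) && !is.na(sel$qs[nxt, "anc"])) {
    viol <- c(anc = sel$qs[nxt, "anc"] < cfg$anc_threshold,
              pc = sel$qs[nxt, "pc"] < cfg$pc_threshold)
    rel <- c(anc = sel$qs[nxt, "anc"] / cfg$anc_threshold,
             pc = sel$qs[nxt, "pc"] / cfg$pc_threshold)
    if (any(viol))
      limiting <- c("ANC", "PC")[which.min(replace(rel, !viol, Inf))]
  }
  tab <- data.frame(dose = grid, anc_q = sel$qs[, "anc"],
                    pc_q = sel$qs[, "pc"], qualifies = sel$qualifies)
  structure(list(table = tab[sel$evaluated, ], selected = selected,
                 uncapped = d_star, limiting_marker = limiting,
                 cap_applied = cap_applied, no_safe_dose = no_safe,
                 seed = seed, n_sim = cfg$n_sim,
                 percentile = cfg$percentile),
            class = "titration_decision")
}

#' @export
print.titration_decision <- function(x, ...) {
  cat(sprintf(paste0("<titration_decision> selected %.1f mg/m2/day",
                     " (uncapped %.1f%s%s), %d sims, P%d\n"),
              x$selected, x$uncapped,
              if (x$cap_applied) ", cap applied" else "",
              if (x$no_safe_dose) ", NO SAFE DOSE" else "",
              x$n_sim, x$percentile))
  if (!is.na(x$limiting_marker))
    cat("  limiting marker:", x$limiting_marker, "\n")
  invisible(x)
}

#' Estimate a cohort's starting dose
#'
#' Cohort dose estimation: the titration criterion applied to fresh virtual
#' subjects drawn with full between-subject variability from a population
#' model fitted to the previous cohorts' data, for a single first cycle.
#' No dose cap applies. Virtual subjects are screened by the study's
#' enrolment criteria (baseline counts above the suspension limits) when
#' `cfg$eligibility` is set.
#'
#' @param pop_fit pooled-population fit: a [population_model()] or an
#'   `mt_pop_fit`
#' @param cfg [titration_config()]
#' @param seed integer seed
#' @param n_days,infusion_hours cycle-1 regimen shape
#' @return a `titration_decision` (no cap; `selected` is the starting dose)
#' @export
estimate_cohort_start_dose <- function(pop_fit, cfg = titration_config(),
                                       seed = 1L, n_days = 5,
                                       infusion_hours = 1) {
  pop <- if (inherits(pop_fit, "mt_pop_fit")) pop_fit$pop else pop_fit
  if (!length(cfg$dose_grid)) stop_input("empty dose grid")
  par_mat <- with_seed(seed, {
    rows <- vector("list", cfg$n_sim)
    for (i in seq_len(cfg$n_sim)) {
      tries <- 0
      repeat {
        ind <- draw_individual(pop, id = i)
        el <- cfg$eligibility
        if (is.null(el) ||
            (ind$pd_pc$base > el[["pc"]] && ind$pd_anc$base > el[["anc"]]))
          break
        if ((tries <- tries + 1) > 1000)
          stop_input("population is incompatible with the eligibility screen")
      }
      rows[[i]] <- par_row(ind$pk, ind$pd_anc, ind$pd_pc)
    }
    do.call(rbind, rows)
  })
  sel <- select_from_grid(par_mat, cfg, cycle_start = 0, history = NULL,
                          cap = Inf)
  finalize_decision(sel, cfg, cap = Inf, seed)
}
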