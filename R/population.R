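# canonical parameter order shared by the population machinery
.mt_par_names <- c("cl", "vc", "vp", "q",
                   "ktr_anc", "slope_anc", "base_anc", "gamma_anc",
                   "ktr_pc", "slope_pc", "base_pc", "gamma_pc", "imp", "imk")

#' Population PK-PD model
#'
#' Typical parameter values together with lognormal between-subject
#' variability (BSV) and residual-error variances, i.e. everything needed to
#' simulate virtual individuals and noisy observations. Individual
#' parameters follow `P_ij = TVP_j exp(eta_i)` with `eta_i ~ N(0, omega_j^2)`
#' independently per parameter; observations follow
#' `DV = IPRED (1 + eps_prop) + eps_add`, with only the proportional term
#' used for concentrations and only the additive term for cell counts
#' (matching the final reported error model).
#'
#' @param pk typical [pk_parameters()]
#' @param pd_anc,pd_pc typical [pd_parameters()] per marker
#' @param bsv_cv named numeric, BSV per parameter as CV% (names among
#'   `cl, vc, vp, q, ktr_anc, slope_anc, base_anc, gamma_anc, ktr_pc,
#'   slope_pc, base_pc, gamma_pc, imp, imk`); omit or set 0 where no BSV
#'   was estimated
#' @param sigma2_pk_prop variance of the proportional residual for
#'   concentrations
#' @param sigma2_anc_add,sigma2_pc_add additive residual variances for the
#'   counts, (cells/mm3)^2
#' @param cv_convention how CV% maps to the lognormal scale parameter:
#'   `"approx"` (the common pharmacometric shorthand omega = CV/100, the
#'   default) or `"exact"` (omega^2 = log(1 + (CV/100)^2))
#' @return an object of class `population_model`
#' @export
population_model <- function(pk, pd_anc, pd_pc, bsv_cv = numeric(),
                             sigma2_pk_prop = 0, sigma2_anc_add = 0,
                             sigma2_pc_add = 0,
                             cv_convention = c("approx", "exact")) {
  cv_convention <- match.arg(cv_convention)
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd_anc, "pd_parameters"),
            inherits(pd_pc, "pd_parameters"))
  if (pd_anc$marker != "ANC" || pd_pc$marker != "PC")
    stop_input("pd_anc/pd_pc markers must be ANC and PC")
  if (length(bsv_cv) && is.null(names(bsv_cv)))
    stop_input("bsv_cv must be named")
  bad <- setdiff(names(bsv_cv), .mt_par_names)
  if (length(bad)) stop_input("unknown BSV parameter(s): ",
                              paste(bad, collapse = ", "))
  if (any(bsv_cv < 0)) stop_input("CV% must be non-negative")
  if (sigma2_pk_prop < 0 || sigma2_anc_add < 0 || sigma2_pc_add < 0)
    stop_input("residual variances must be non-negative")
  omega <- stats::setNames(numeric(length(.mt_par_names)), .mt_par_names)
  cv <- bsv_cv[bsv_cv > 0] / 100
  omega[names(cv)] <- if (cv_convention == "approx") cv else
    sqrt(log(1 + cv^2))
  structure(list(pk = pk, pd_anc = pd_anc, pd_pc = pd_pc, omega = omega,
                 sigma2_pk_prop = sigma2_pk_prop,
                 sigma2_anc_add = sigma2_anc_add,
                 sigma2_pc_add = sigma2_pc_add,
                 cv_convention = cv_convention),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  nb <- sum(x$omega > 0)
  cat(sprintf(paste0(
    "<population_model> %d-cmt PK + transit ANC/PC; BSV on %d parameter(s)",
    " [%s convention]\n"), x$pk$n_compartments, nb, x$cv_convention))
  cat(sprintf("  residual: prop var %.3g (conc), add var %.4g (ANC), %.4g (PC)\n",
              x$sigma2_pk_prop, x$sigma2_anc_add, x$sigma2_pc_add))
  invisible(x)
}

# typical values as a named vector in canonical order
typical_vector <- function(pop) {
  c(cl = pop$pk$cl, vc = pop$pk$vc, vp = pop$pk$vp, q = pop$pk$q,
    ktr_anc = pop$pd_anc$ktr, slope_anc = pop$pd_anc$slope,
    base_anc = pop$pd_anc$base, gamma_anc = pop$pd_anc$gamma,
    ktr_pc = pop$pd_pc$ktr, slope_pc = pop$pd_pc$slope,
    base_pc = pop$pd_pc$base, gamma_pc = pop$pd_pc$gamma,
    imp = pop$pd_pc$imp, imk = pop$pd_pc$imk)
}

# rebuild structured parameter objects from a full named vector
params_from_vector <- function(v, n_compartments = 2) {
  pk <- pk_parameters(v[["cl"]], v[["vc"]],
                      if (n_compartments == 2) v[["vp"]] else NULL,
                      if (n_compartments == 2) v[["q"]] else NULL,
                      n_compartments)
  pd_anc <- pd_parameters(v[["ktr_anc"]], v[["slope_anc"]], v[["base_anc"]],
                          v[["gamma_anc"]], marker = "ANC")
  pd_pc <- pd_parameters(v[["ktr_pc"]], v[["slope_pc"]], v[["base_pc"]],
                         v[["gamma_pc"]], v[["imp"]], v[["imk"]],
                         marker = "PC")
  list(pk = pk, pd_anc = pd_anc, pd_pc = pd_pc)
}

#' Realised parameters from log-scale deviations
#'
#' Applies `P = TVP exp(eta)` to a population model for a named vector of
#' log-scale deviations (missing parameters get eta = 0).
#'
#' @param pop [population_model()]
#' @param eta named numeric, log-scale deviations
#' @param bsa body surface area, m2
#' @param id subject identifier
#' @return an `individual_parameters` object: realised `pk`, `pd_anc`,
#'   `pd_pc`, the `eta` used, `bsa` and `id`
#' @export
individual_from_eta <- function(pop, eta = numeric(), bsa = 1, id = 1L) {
  v <- typical_vector(pop)
  if (length(eta)) {
    bad <- setdiff(names(eta), .mt_par_names)
    if (length(bad)) stop_input("unknown eta parameter(s): ",
                                paste(bad, collapse = ", "))
    v[names(eta)] <- v[names(eta)] * exp(eta)
  }
  full_eta <- stats::setNames(numeric(length(.mt_par_names)), .mt_par_names)
  full_eta[names(eta)] <- eta
  p <- params_from_vector(v, pop$pk$n_compartments)
  structure(c(p, list(eta = full_eta, bsa = bsa, id = id)),
            class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf("<individual_parameters> id %s, BSA %.2f m2\n", x$id, x$bsa))
  nz <- x$eta[x$eta != 0]
  if (length(nz))
    cat("  eta:", paste(sprintf("%s=%.3f", names(nz), nz), collapse = ", "),
        "\n")
  invisible(x)
}

#' Draw a virtual individual from the population model
#'
#' Independent lognormal BSV per parameter; parameters without estimated BSV
#' are returned at their typical values. Reproducible given `seed`.
#'
#' @param pop [population_model()]
#' @param seed optional integer seed (uses the current RNG stream when NULL)
#' @param bsa body surface area, m2
#' @param id subject identifier
#' @return an `individual_parameters` object
#' @export
draw_individual <- function(pop, seed = NULL, bsa = 1, id = 1L) {
  with_seed(seed, {
    free <- names(pop$omega)[pop$omega > 0]
    eta <- stats::setNames(stats::rnorm(length(free), 0, pop$omega[free]),
                           free)
    individual_from_eta(pop, eta, bsa = bsa, id = id)
  })
}

#' Apply the residual-error model to model predictions
#'
#' Concentrations receive proportional error only, cell counts additive
#' error only, per the final reported error model. Simulated counts that
#' fall below `floor` are set to `floor`.
#'
#' @param prediction numeric vector of individual predictions (IPRED)
#' @param kind `"conc"`, `"ANC"` or `"PC"`
#' @param pop [population_model()]
#' @param seed optional integer seed
#' @param floor lower bound applied to simulated counts (cells/mm3)
#' @return simulated observed values (DV), same length as `prediction`
#' @export
apply_residual_error <- function(prediction, kind = c("conc", "ANC", "PC"),
                                 pop, seed = NULL, floor = 0) {
  kind <- match.arg(kind)
  if (any(!is.finite(prediction))) stop_input("predictions must be finite")
  with_seed(seed, {
    n <- length(prediction)
    if (kind == "conc") {
      dv <- prediction * (1 + stats::rnorm(n, 0, sqrt(pop$sigma2_pk_prop)))
      return(dv)
    }
    s2 <- if (kind == "ANC") pop$sigma2_anc_add else pop$sigma2_pc_add
    dv <- prediction + stats::rnorm(n, 0, sqrt(s2))
    pmax(dv, floor)
  })
}
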