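omega_to_cv <- function(omega, convention) {
  if (convention == "approx") 100 * omega else 100 * sqrt(exp(omega^2) - 1)
}

#' Serialise a population model to YAML
#'
#' Round-trippable structured representation mirroring the parameter table
#' field-for-field: typical values, BSV as CV%, residual variances, and the
#' CV convention.
#'
#' @param pop [population_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_population_yaml <- function(pop, path) {
  cv <- omega_to_cv(pop$omega[pop$omega > 0], pop$cv_convention)
  obj <- list(
    schema = "myelotitr/population/v1",
    n_compartments = pop$pk$n_compartments,
    typical = as.list(typical_vector(pop)),
    bsv_cv = as.list(cv),
    residual = list(sigma2_pk_prop = pop$sigma2_pk_prop,
                    sigma2_anc_add = pop$sigma2_anc_add,
                    sigma2_pc_add = pop$sigma2_pc_add),
    cv_convention = pop$cv_convention)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a population model from YAML
#'
#' @param path file written by [write_population_yaml()] (or hand-authored
#'   with the same schema)
#' @return a [population_model()]
#' @export
read_population_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "myelotitr/population/v1"))
    stop_input("unrecognised population config schema in ", path)
  v <- unlist(obj$typical)
  miss <- setdiff(.mt_par_names, names(v))
  if (length(miss))
    stop_input("population config lacks parameter(s): ",
               paste(miss, collapse = ", "))
  p <- params_from_vector(v, obj$n_compartments %||% 2)
  population_model(p$pk, p$pd_anc, p$pd_pc,
                   bsv_cv = unlist(obj$bsv_cv) %||% numeric(),
                   sigma2_pk_prop = obj$residual$sigma2_pk_prop %||% 0,
                   sigma2_anc_add = obj$residual$sigma2_anc_add %||% 0,
                   sigma2_pc_add = obj$residual$sigma2_pc_add %||% 0,
                   cv_convention = obj$cv_convention %||% "approx")
}

trial_config_from_list <- function(lst) {
  targs <- lst$titration %||% list()
  lst$titration <- do.call(titration_config, targs)
  do.call(trial_config, lst)
}
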