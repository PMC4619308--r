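#' Longitudinal data for one subject
#'
#' Container pairing a subject's dosing history with their observations,
#' the unit of analysis for individual fitting and titration.
#'
#' @param observations data.frame with columns `time` (h), `kind`
#'   (`"conc"`, `"ANC"` or `"PC"`), `value` (ng/mL or cells/mm3) and
#'   optionally `bql` (logical, below the quantification limit)
#' @param events dosing events: data.frame with `start_time`, `duration`,
#'   `dose_per_bsa`, `bsa` (a [dose_regimen()] works)
#' @param bsa body surface area, m2
#' @param id subject identifier
#' @return an object of class `subject_data`
#' @export
subject_data <- function(observations, events, bsa = 1, id = 1L) {
  need <- c("time", "kind", "value")
  if (!is.data.frame(observations) || !all(need %in% names(observations)))
    stop_input("observations must have columns time, kind, value")
  if (!all(observations$kind %in% c("conc", "ANC", "PC")))
    stop_input("kind must be conc, ANC or PC")
  if (is.null(observations$bql)) observations$bql <- FALSE
  if (any(observations$value < 0 & !observations$bql, na.rm = TRUE))
    stop_input("observed values must be non-negative")
  events <- as.data.frame(events)[, c("start_time", "duration",
                                      "dose_per_bsa", "bsa")]
  structure(list(observations = observations, events = events,
                 bsa = bsa, id = id),
            class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  tb <- table(x$observations$kind)
  cat(sprintf("<subject_data> id %s, BSA %.2f m2, %d dose events, obs: %s\n",
              x$id, x$bsa, nrow(x$events),
              paste(sprintf("%s=%d", names(tb), tb), collapse = " ")))
  invisible(x)
}

regimen_of <- function(data) dose_regimen(data$events)

.nm_cmt <- c(conc = 1L, ANC = 2L, PC = 3L)

#' Write subjects to a NONMEM-style CSV dataset
#'
#' Columns ID, TIME (h), AMT (ug), RATE (ug/h), EVID, CMT, DV, MDV, BSA.
#' Dose rows carry EVID = 1, CMT = 1 and a blank DV; observation rows carry
#' EVID = 0 with CMT 1/2/3 for concentration/ANC/PC. A pre-dose sample at
#' TIME = 0 is written before the first dose row.
#'
#' @param subjects a `subject_data` or list of them
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_nm_data <- function(subjects, path) {
  if (inherits(subjects, "subject_data")) subjects <- list(subjects)
  rows <- lapply(subjects, function(s) {
    ev <- s$events
    amt <- ev$dose_per_bsa * 1000 * ev$bsa
    dose <- data.frame(ID = s$id, TIME = ev$start_time, AMT = amt,
                       RATE = amt / ev$duration, EVID = 1L, CMT = 1L,
                       DV = NA_real_, MDV = 1L, BSA = s$bsa)
    ob <- s$observations
    obs <- data.frame(ID = s$id, TIME = ob$time, AMT = NA_real_,
                      RATE = NA_real_, EVID = 0L,
                      CMT = .nm_cmt[ob$kind], DV = ob$value, MDV = 0L,
                      BSA = s$bsa)
    out <- rbind(obs, dose)
    # stable ordering: time, then observations before doses at equal times
    out[order(out$TIME, out$EVID), ]
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a NONMEM-style CSV dataset
#'
#' Inverse of [write_nm_data()]. Concentration observations at or below
#' `lloq` are flagged as below the quantification limit.
#'
#' @param path CSV path
#' @param lloq lower limit of quantification for concentrations, ng/mL
#' @return list of [subject_data()] objects, one per ID
#' @export
read_nm_data <- function(path, lloq = 0.5) {
  df <- utils::read.csv(path)
  need <- c("ID", "TIME", "AMT", "RATE", "EVID", "CMT", "DV", "MDV")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("dataset lacks required column(s): ",
               paste(miss, collapse = ", "))
  if (is.null(df$BSA)) df$BSA <- 1
  kinds <- names(.nm_cmt)
  lapply(split(df, factor(df$ID, levels = unique(df$ID))), function(d) {
    bsa <- d$BSA[1]
    dose <- d[d$EVID == 1L, , drop = FALSE]
    obs <- d[d$EVID == 0L & d$MDV == 0L, , drop = FALSE]
    ev <- data.frame(start_time = dose$TIME,
                     duration = dose$AMT / dose$RATE,
                     dose_per_bsa = dose$AMT / 1000 / bsa, bsa = bsa)
    ob <- data.frame(time = obs$TIME, kind = kinds[obs$CMT],
                     value = obs$DV,
                     bql = kinds[obs$CMT] == "conc" & obs$DV < lloq)
    subject_data(ob, ev, bsa = bsa, id = d$ID[1])
  })
}
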