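#' Blank-correct dual-wavelength absorbances for one post-incubation day
#'
#' The optical density of a well is the 650 nm-referenced signal minus the
#' mean blank of the same day: `od = (a450 - a650) - mean((a450 - a650)[blanks])`,
#' the WST-8 solution itself serving as the blank. Blank wells receive their
#' own deviation from the blank mean, so they scatter around zero. Negative
#' ods are retained (clipping would bias viability upward) but flagged below
#' -0.05 absorbance units, where they indicate more than read noise.
#'
#' @param readings data.frame of well readings for a single `pip_day`
#'   (columns `role`, `a450`, `a650`, plus any identifiers, as in the
#'   `readings` element of an `eit_run`).
#' @return the input data.frame with columns `od` and `od_flagged` appended.
#' @examples
#' d <- data.frame(role = c("blank", "treated"), a450 = c(0.10, 0.90),
#'                 a650 = c(0.05, 0.05), pip_day = 1)
#' correct_od(d)$od
#' @export
correct_od <- function(readings) {
  stopifnot(is.data.frame(readings), all(c("role", "a450", "a650") %in% names(readings)))
  if ("pip_day" %in% names(readings) && length(unique(readings$pip_day)) > 1L) {
    stop("correct_od() operates on a single pip_day", call. = FALSE)
  }
  blanks <- readings$role == "blank"
  if (!any(blanks)) {
    stop("no blank well at this pip_day; cannot blank-correct", call. = FALSE)
  }
  signal <- readings$a450 - readings$a650
  blank_mean <- mean(signal[blanks])
  readings$od <- signal - blank_mean
  readings$od_flagged <- readings$od < -0.05
  readings
}

#' Relative viability of each chemical and control for one day
#'
#' Per-well viability is the blank-corrected od as a percentage of the mean
#' od of the reference wells of the same day:
#' `viability_i = 100 * od_i / mean(od[reference])`. Per chemical (and per
#' control role) the replicate viabilities are averaged with an unweighted
#' arithmetic mean; the reference role's mean is exactly 100 by
#' construction.
#'
#' @param ods data.frame from [correct_od()] (needs `role`, `chemical_id`,
#'   `od`).
#' @param reference_role role serving as the 100% reference
#'   (`"untreated_control"` for the day-1 prediction,
#'   `"negative_control"` for recovery days).
#' @param pip_day integer day recorded on the output rows.
#' @return an `eit_viability` data.frame with one row per chemical and per
#'   control role: `chemical_id` (NA for controls), `role`, `pip_day`,
#'   `replicate_viabilities` (list column), `mean_viability`,
#'   `reference_role`, `qc_pass` (NA until QC runs).
#' @export
compute_viability <- function(ods, reference_role = "untreated_control", pip_day = 1L) {
  stopifnot(is.data.frame(ods), all(c("role", "od") %in% names(ods)))
  ref <- ods$od[ods$role == reference_role]
  if (length(ref) < 2L) {
    stop("need at least 2 ", reference_role, " wells at pip_day ", pip_day,
         call. = FALSE)
  }
  ref_mean <- mean(ref)
  if (ref_mean <= 0) {
    stop("mean reference od is not positive at pip_day ", pip_day,
         ": reference tissue dead or missing; run invalid", call. = FALSE)
  }

  viab <- 100 * ods$od / ref_mean
  non_blank <- ods$role != "blank"

  # one record per treated chemical, one per control role
  grp <- ifelse(ods$role == "treated",
                paste0("chem:", ods$chemical_id),
                paste0("role:", ods$role))
  groups <- unique(grp[non_blank])
  rows <- lapply(groups, function(g) {
    sel <- non_blank & grp == g
    vs <- viab[sel]
    data.frame(
      chemical_id = if (startsWith(g, "chem:")) {
        as.integer(sub("chem:", "", g))
      } else NA_integer_,
      role = ods$role[sel][1L],
      pip_day = as.integer(pip_day),
      mean_viability = mean(vs),
      reference_role = reference_role,
      qc_pass = NA,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$replicate_viabilities <- lapply(groups, function(g) viab[non_blank & grp == g])
  out <- out[, c("chemical_id", "role", "pip_day", "replicate_viabilities",
                 "mean_viability", "reference_role", "qc_pass")]
  class(out) <- c("eit_viability", "data.frame")
  out
}

#' Quantify a whole run: blank correction, normalization, QC
#'
#' Applies [correct_od()] and [compute_viability()] day by day. Day 1 is
#' normalized to the protocol's `pip1_reference` (untreated control by
#' default); recovery days use `recovery_reference` (same-day negative
#' control by default). Run-level QC is then evaluated with [qc_run()] and
#' its verdict stamped on every record.
#'
#' @param run an `eit_run`.
#' @param qc_config optional list for [qc_run()].
#' @return an `eit_viability` data.frame covering all days, with attributes
#'   `qc` (the QC report) and `untreated_od` (per-day mean raw od of the
#'   untreated control, used by the batch band check).
#' @export
quantify_run <- function(run, qc_config = list()) {
  stopifnot(inherits(run, "eit_run"))
  validate_eit_run(run)
  protocol <- run$protocol

  days <- sort(unique(run$readings$pip_day))
  per_day <- lapply(days, function(d) {
    ods <- correct_od(run$readings[run$readings$pip_day == d, ])
    ref <- if (d == 1L) protocol$pip1_reference else protocol$recovery_reference
    compute_viability(ods, reference_role = ref, pip_day = d)
  })
  records <- do.call(rbind, per_day)
  class(records) <- c("eit_viability", "data.frame")

  untreated_od <- vapply(days, function(d) {
    ods <- correct_od(run$readings[run$readings$pip_day == d, ])
    mean(ods$od[ods$role == "untreated_control"])
  }, numeric(1L))
  names(untreated_od) <- days

  qc <- qc_run(records, protocol, qc_config, untreated_od = untreated_od)
  records$qc_pass <- qc$pass
  attr(records, "qc") <- qc
  attr(records, "untreated_od") <- untreated_od
  attr(records, "run_id") <- run$run_id
  records
}

#' Run-level quality control
#'
#' A run is accepted when, at post-incubation day 1: the negative control's
#' mean viability is strictly above the EC70 cut-off (it must read as a
#' non-irritant), the positive control's mean viability is at or below the
#' cut-off (it must read as an irritant), and — when a nominal untreated od
#' is configured for the tissue batch — the untreated control's raw mean od
#' lies within the batch band (`nominal * (1 ± od_band_fraction)`).
#'
#' @param records an `eit_viability` data.frame containing day-1 records for
#'   the negative and positive controls.
#' @param protocol an [eit_protocol()].
#' @param qc_config list with optional `nominal_untreated_od` (absorbance
#'   units; `NULL` skips the band check) and `od_band_fraction`
#'   (default 0.3).
#' @param untreated_od named per-day untreated mean od (as attached by
#'   [quantify_run()]); only day 1 is used.
#' @return an `eit_qc` list: `pass`, and a `checks` data.frame with one row
#'   per criterion (name, value, requirement, pass).
#' @export
qc_run <- function(records, protocol = eit_protocol(), qc_config = list(),
                   untreated_od = NULL) {
  stopifnot(is.data.frame(records))
  band_frac <- qc_config$od_band_fraction %||% 0.3
  nominal <- qc_config$nominal_untreated_od

  day1 <- records[records$pip_day == 1L, ]
  neg <- day1$mean_viability[day1$role == "negative_control"]
  pos <- day1$mean_viability[day1$role == "positive_control"]
  if (length(neg) != 1L || length(pos) != 1L) {
    stop("QC requires day-1 negative and positive control records; run invalid",
         call. = FALSE)
  }

  checks <- data.frame(
    check = c("negative_control", "positive_control"),
    value = c(neg, pos),
    requirement = c(sprintf("> %g%%", protocol$ec70_cutoff),
                    sprintf("<= %g%%", protocol$ec70_cutoff)),
    pass = c(neg > protocol$ec70_cutoff, pos <= protocol$ec70_cutoff),
    stringsAsFactors = FALSE
  )
  if (!is.null(nominal)) {
    od1 <- untreated_od[["1"]]
    if (is.null(od1) || is.na(od1)) {
      stop("batch od band configured but no untreated day-1 od available",
           call. = FALSE)
    }
    lo <- nominal * (1 - band_frac)
    hi <- nominal * (1 + band_frac)
    checks <- rbind(checks, data.frame(
      check = "untreated_od_band", value = od1,
      requirement = sprintf("[%g, %g]", lo, hi),
      pass = od1 >= lo && od1 <= hi,
      stringsAsFactors = FALSE
    ))
  }

  structure(list(pass = all(checks$pass), checks = checks), class = "eit_qc")
}

#' @export
print.eit_qc <- function(x, ...) {
  cat("Run QC:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$checks, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
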