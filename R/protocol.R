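#' Protocol configuration for the eye irritation test
#'
#' Bundles the tunable decision thresholds and timepoints of the test
#' protocol for liquid chemicals: a 5-minute exposure, viability measured
#' after a 1-day post-incubation period (PIP), and — for chemicals in the
#' monitoring band — recovery measurements at PIP days 7 and 14.
#'
#' The three cut-offs (percent viability) drive the classification:
#' \describe{
#'   \item{`ec70_cutoff`}{EC70 rule: mean day-1 viability strictly above this
#'     value predicts a non-irritant (No Cat.). Default 70.}
#'   \item{`strong_cutoff`}{day-1 viability at or below this value fast-tracks
#'     the chemical to strong irritant (Cat. 1) with no recovery monitoring.
#'     Default 5.}
#'   \item{`recovery_cutoff`}{a monitored chemical recovers if viability at
#'     PIP day 7 or 14 is strictly above this value (relative to the same-day
#'     negative control). Default 50.}
#' }
#'
#' @param exposure_minutes exposure duration in minutes (liquids: 5).
#' @param pip_days ordered integer vector of post-incubation days; the first
#'   must be 1 (the prediction day), later days are recovery timepoints.
#' @param ec70_cutoff,strong_cutoff,recovery_cutoff decision thresholds in
#'   percent viability; must satisfy 0 < strong < recovery < ec70 < 100.
#' @param pip1_reference role used as the 100% reference at day 1
#'   (`"untreated_control"` or `"negative_control"`).
#' @param recovery_reference role used as the 100% reference at recovery
#'   days (default `"negative_control"`).
#' @param allow_late_noncat if `TRUE`, a monitored chemical whose viability
#'   increases over time and ends strictly above `ec70_cutoff` is classed
#'   non-irritant instead of moderate-or-mild. Off by default.
#' @return an object of class `eit_protocol` (a validated list).
#' @examples
#' cfg <- eit_protocol()
#' cfg$ec70_cutoff
#' @export
eit_protocol <- function(exposure_minutes = 5,
                         pip_days = c(1L, 7L, 14L),
                         ec70_cutoff = 70,
                         strong_cutoff = 5,
                         recovery_cutoff = 50,
                         pip1_reference = c("untreated_control", "negative_control"),
                         recovery_reference = c("negative_control", "untreated_control"),
                         allow_late_noncat = FALSE) {
  pip1_reference <- match.arg(pip1_reference)
  recovery_reference <- match.arg(recovery_reference)
  pip_days <- as.integer(pip_days)

  stopifnot(
    is.numeric(exposure_minutes), length(exposure_minutes) == 1L, exposure_minutes > 0,
    length(pip_days) >= 1L, !anyNA(pip_days),
    is.logical(allow_late_noncat), length(allow_late_noncat) == 1L
  )
  if (pip_days[1L] != 1L || is.unsorted(pip_days, strictly = TRUE)) {
    stop("pip_days must be strictly increasing and start at day 1", call. = FALSE)
  }
  if (!(0 < strong_cutoff && strong_cutoff < recovery_cutoff &&
        recovery_cutoff < ec70_cutoff && ec70_cutoff < 100)) {
    stop("cutoffs must satisfy 0 < strong_cutoff < recovery_cutoff < ec70_cutoff < 100",
         call. = FALSE)
  }

  structure(
    list(
      exposure_minutes = exposure_minutes,
      pip_days = pip_days,
      ec70_cutoff = ec70_cutoff,
      strong_cutoff = strong_cutoff,
      recovery_cutoff = recovery_cutoff,
      pip1_reference = pip1_reference,
      recovery_reference = recovery_reference,
      allow_late_noncat = allow_late_noncat
    ),
    class = "eit_protocol"
  )
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("Eye irritation test protocol\n")
  cat(sprintf("  exposure: %g min; PIP days: %s\n",
              x$exposure_minutes, paste(x$pip_days, collapse = ", ")))
  cat(sprintf("  cutoffs (%% viability): strong <= %g, recovery > %g, EC70 > %g\n",
              x$strong_cutoff, x$recovery_cutoff, x$ec70_cutoff))
  cat(sprintf("  day-1 reference: %s; recovery reference: %s\n",
              x$pip1_reference, x$recovery_reference))
  if (isTRUE(x$allow_late_noncat)) {
    cat("  late non-irritant rule enabled (increasing trajectory ending > EC70)\n")
  }
  invisible(x)
}

#' Read or write a protocol configuration as YAML
#'
#' The YAML file holds any subset of the [eit_protocol()] arguments;
#' unspecified fields take the protocol defaults.
#'
#' @param path path to a YAML file.
#' @return `read_protocol_yaml()` returns an `eit_protocol`;
#'   `write_protocol_yaml()` returns `path` invisibly.
#' @export
read_protocol_yaml <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  fields <- yaml::read_yaml(path)
  if (is.null(fields)) fields <- list()
  allowed <- names(formals(eit_protocol))
  bad <- setdiff(names(fields), allowed)
  if (length(bad)) {
    stop("unknown protocol fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(eit_protocol, fields)
}

#' @rdname read_protocol_yaml
#' @param protocol an `eit_protocol` object.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "eit_protocol"))
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}
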