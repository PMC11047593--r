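#' Day-1 irritancy prediction under the EC70 rule
#'
#' A chemical whose mean viability after exposure and one day of
#' post-incubation is strictly above the EC70 cut-off is predicted
#' non-irritant (no GHS classification required); at or below the cut-off it
#' is predicted irritant. The boundary value itself (70% by default) counts
#' as irritant.
#'
#' @param v1 numeric vector of day-1 mean viabilities (percent).
#' @param protocol an [eit_protocol()].
#' @return character vector, `"irritant"` or `"non_irritant"`.
#' @examples
#' pip1_predict(c(85, 70, 3))
#' @export
pip1_predict <- function(v1, protocol = eit_protocol()) {
  stopifnot(is.numeric(v1), all(is.finite(v1)))
  ifelse(v1 > protocol$ec70_cutoff, "non_irritant", "irritant")
}

#' Classify a viability trajectory into a final irritancy class
#'
#' Implements the multi-timepoint decision framework. Rules fire in order on
#' the day-1 mean viability `v1`:
#' \enumerate{
#'   \item `v1 > 70` (EC70): non-irritant, predicted No Cat.; recovery is
#'     not tested.
#'   \item `v1 <= 5`: strong irritant, predicted Cat. 1, fast-tracked with
#'     no recovery monitoring.
#'   \item otherwise the chemical is in the monitoring band (> 5 and <= 70)
#'     and viability is re-measured at post-incubation days 7 and 14,
#'     normalized to the same-day negative control. If viability at day 7 or
#'     day 14 is strictly above 50%, the damage is reversible: moderate or
#'     mild irritant, predicted Cat. 2. Recovery at day 7 makes the day-14
#'     measurement optional.
#'   \item if neither day exceeds 50%, the damage is irreversible: strong
#'     irritant, predicted Cat. 1.
#' }
#'
#' With `allow_late_noncat` enabled in the protocol, a monitored trajectory
#' that increases strictly over time and ends above the EC70 cut-off is
#' classed non-irritant instead of moderate-or-mild.
#'
#' A chemical in the monitoring band with no day-7/14 measurements is an
#' incomplete trajectory and raises an error rather than defaulting.
#'
#' @param trajectory a list with `chemical_id` and `viability_by_day`, a
#'   numeric vector named by post-incubation day (day `"1"` required), as
#'   produced by [run_trajectories()]; or just the named numeric vector.
#' @param protocol an [eit_protocol()].
#' @return an `eit_verdict` list: `chemical_id`, `pip1_prediction`,
#'   `recoverability`, `final_class`, `predicted_category`, and `rationale`
#'   (ordered rule identifiers that fired).
#' @examples
#' classify_trajectory(c("1" = 40, "7" = 60))$final_class
#' @export
classify_trajectory <- function(trajectory, protocol = eit_protocol()) {
  if (is.numeric(trajectory)) {
    trajectory <- list(chemical_id = NA_integer_, viability_by_day = trajectory)
  }
  v <- trajectory$viability_by_day
  if (is.null(names(v)) || !"1" %in% names(v)) {
    stop("trajectory must contain a day-1 viability", call. = FALSE)
  }
  v1 <- v[["1"]]
  stopifnot(is.finite(v1))
  later_days <- sort(as.integer(setdiff(names(v), "1")))

  verdict <- function(pip1, rec, final, rationale) {
    structure(
      list(chemical_id = trajectory$chemical_id,
           pip1_prediction = pip1, recoverability = rec, final_class = final,
           predicted_category = class_to_category(final), rationale = rationale),
      class = "eit_verdict"
    )
  }

  if (v1 > protocol$ec70_cutoff) {
    if (length(later_days)) {
      stop("trajectory invariant violated: day-1 viability above EC70 but late ",
           "measurements present", call. = FALSE)
    }
    return(verdict("non_irritant", "not_tested", "non_irritant", "ec70_noncat"))
  }
  if (v1 <= protocol$strong_cutoff) {
    return(verdict("irritant", "not_tested", "strong", "fast_track_strong"))
  }

  # monitoring band: recovery measurements required
  if (!length(later_days)) {
    stop("incomplete trajectory for chemical ", trajectory$chemical_id,
         ": day-1 viability ", signif(v1, 4L),
         " is in the monitoring band but no day-7/14 measurements exist",
         call. = FALSE)
  }
  rationale <- "monitoring_band"
  late <- v[as.character(later_days)]

  if (isTRUE(protocol$allow_late_noncat)) {
    traj_all <- c(v1, late)
    if (all(diff(traj_all) > 0) && late[[length(late)]] > protocol$ec70_cutoff) {
      return(verdict("irritant", "reversible", "non_irritant",
                     c(rationale, "late_noncat")))
    }
  }

  recovered_at <- later_days[late > protocol$recovery_cutoff]
  if (length(recovered_at)) {
    return(verdict("irritant", "reversible", "moderate_or_mild",
                   c(rationale, paste0("recovered_day", recovered_at[1L]))))
  }
  # no recovery observed; day 14 must have been measured to conclude
  if (!max(later_days) >= max(protocol$pip_days)) {
    stop("incomplete trajectory for chemical ", trajectory$chemical_id,
         ": no recovery by day ", max(later_days),
         " and no day-", max(protocol$pip_days), " measurement", call. = FALSE)
  }
  verdict("irritant", "irreversible", "strong", c(rationale, "no_recovery"))
}

#' Classify every chemical of a quantified run
#'
#' Gates on run QC (a failed run refuses to classify), assembles one
#' viability trajectory per treated chemical, and applies
#' [classify_trajectory()].
#'
#' @param records an `eit_viability` data.frame from [quantify_run()].
#' @param protocol an [eit_protocol()].
#' @return an `eit_verdicts` data.frame with one row per chemical:
#'   `chemical_id`, `pip1_prediction`, `recoverability`, `final_class`,
#'   `predicted_category`, `rationale` (rule ids joined by `;`).
#' @export
classify_run <- function(records, protocol = eit_protocol()) {
  stopifnot(is.data.frame(records))
  if (!all(records$qc_pass %in% TRUE)) {
    stop("run failed QC (or QC not evaluated); refusing to classify", call. = FALSE)
  }
  trajectories <- run_trajectories(records)
  rows <- lapply(trajectories, function(tr) {
    vd <- classify_trajectory(tr, protocol)
    data.frame(
      chemical_id = tr$chemical_id,
      pip1_prediction = vd$pip1_prediction,
      recoverability = vd$recoverability,
      final_class = vd$final_class,
      predicted_category = vd$predicted_category,
      rationale = paste(vd$rationale, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chemical_id), ]
  rownames(out) <- NULL
  class(out) <- c("eit_verdicts", "data.frame")
  out
}

#' Extract per-chemical viability trajectories from run records
#'
#' @param records an `eit_viability` data.frame.
#' @return a list of trajectories (`chemical_id`, day-named
#'   `viability_by_day`), one per treated chemical, of class
#'   `eit_trajectories`.
#' @export
run_trajectories <- function(records) {
  treated <- records[records$role == "treated" & !is.na(records$chemical_id), ]
  ids <- sort(unique(treated$chemical_id))
  out <- lapply(ids, function(id) {
    rows <- treated[treated$chemical_id == id, ]
    rows <- rows[order(rows$pip_day), ]
    v <- rows$mean_viability
    names(v) <- rows$pip_day
    list(chemical_id = id, viability_by_day = v)
  })
  structure(out, class = "eit_trajectories")
}

#' @export
print.eit_verdict <- function(x, ...) {
  cat(sprintf("chemical %s: %s (day-1 %s, recovery %s) -> %s\n",
              x$chemical_id, x$final_class, x$pip1_prediction,
              x$recoverability, x$predicted_category))
  invisible(x)
}

#' @export
summary.eit_verdicts <- function(object, ...) {
  tab <- table(factor(object$final_class, levels = FINAL_CLASSES))
  cat(sprintf("%d chemicals classified: %d non-irritant, %d moderate/mild, %d strong\n",
              nrow(object), tab[["non_irritant"]], tab[["moderate_or_mild"]],
              tab[["strong"]]))
  invisible(tab)
}

#' Plot viability trajectories against the decision thresholds
#'
#' Base-graphics recovery plot: one line per chemical over post-incubation
#' days, with horizontal reference lines at the EC70, recovery and
#' strong-irritant cut-offs.
#'
#' @param x an `eit_trajectories` list from [run_trajectories()].
#' @param protocol an [eit_protocol()] supplying the threshold lines.
#' @param ... passed to [graphics::matplot()].
#' @return the input, invisibly.
#' @export
plot.eit_trajectories <- function(x, protocol = eit_protocol(), ...) {
  days <- sort(unique(unlist(lapply(x, function(tr) as.integer(names(tr$viability_by_day))))))
  mat <- sapply(x, function(tr) {
    tr$viability_by_day[as.character(days)]
  })
  mat <- matrix(as.numeric(mat), nrow = length(days),
                dimnames = list(days, vapply(x, function(tr) as.character(tr$chemical_id),
                                             character(1L))))
  graphics::matplot(days, mat, type = "b", pch = 16, lty = 1,
                    xlab = "post-incubation day", ylab = "viability (%)",
                    ylim = c(0, max(110, mat, na.rm = TRUE)), ...)
  graphics::abline(h = c(protocol$strong_cutoff, protocol$recovery_cutoff,
                         protocol$ec70_cutoff), lty = c(3, 2, 2),
                   col = c("red3", "purple", "grey40"))
  invisible(x)
}
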