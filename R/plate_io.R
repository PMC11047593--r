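#' Read plate-reader absorbances and a plate layout into a run manifest
#'
#' A run is stored as two CSV files. The readings file holds one row per
#' well and post-incubation day with columns `plate_id`, `well`, `pip_day`,
#' `a450`, `a650` (dual-wavelength absorbances: 450 nm signal, 650 nm
#' reference). The layout file maps each well to its role with columns
#' `well`, `role`, `chemical_id`, `replicate`; the same layout applies to
#' every measured day. Roles are `treated`, `untreated_control`,
#' `negative_control`, `positive_control` and `blank`; `chemical_id` is
#' required for treated wells and must be empty elsewhere.
#'
#' Validation rejects missing columns, non-numeric or negative absorbances,
#' duplicated (well, day) readings, wells present in one file but not the
#' other, days without a blank well, missing day-1 control pairs, and
#' treated chemicals with fewer than two replicates on a measured day.
#'
#' @param readings_path,layout_path CSV file paths.
#' @param protocol an [eit_protocol()].
#' @param run_id identifier stored in the manifest.
#' @return an object of class `eit_run`: a list with `run_id`, `protocol`
#'   and a `readings` data.frame joining layout and absorbances.
#' @export
read_plate_csv <- function(readings_path, layout_path,
                           protocol = eit_protocol(), run_id = "run") {
  for (p in c(readings_path, layout_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  readings <- utils::read.csv(readings_path, stringsAsFactors = FALSE)
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)

  need_r <- c("plate_id", "well", "pip_day", "a450", "a650")
  need_l <- c("well", "role", "chemical_id", "replicate")
  if (length(miss <- setdiff(need_r, names(readings)))) {
    stop("readings CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(miss <- setdiff(need_l, names(layout)))) {
    stop("layout CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("a450", "a650")) {
    v <- readings[[col]]
    if (!is.numeric(v)) stop("non-numeric absorbance in column ", col, call. = FALSE)
  }
  layout$chemical_id <- suppressWarnings(as.integer(layout$chemical_id))

  manifest <- new_eit_run(run_id, protocol, readings, layout)
  validate_eit_run(manifest)
}

# assemble (and join) without validation; shared by read_plate_csv and the simulator
new_eit_run <- function(run_id, protocol, readings, layout) {
  extra <- setdiff(unique(readings$well), layout$well)
  if (length(extra)) {
    stop("wells present in readings but absent from layout: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(layout$well, unique(readings$well))
  if (length(orphan)) {
    stop("wells present in layout but never read: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(layout$well)) {
    stop("duplicate well in layout", call. = FALSE)
  }
  merged <- merge(readings, layout, by = "well", sort = FALSE)
  merged <- merged[order(merged$pip_day, merged$plate_id, merged$well), ]
  rownames(merged) <- NULL
  structure(
    list(run_id = run_id, protocol = protocol,
         readings = merged[, c("plate_id", "well", "role", "chemical_id",
                               "replicate", "pip_day", "a450", "a650")]),
    class = "eit_run"
  )
}

ROLES <- c("treated", "untreated_control", "negative_control",
           "positive_control", "blank")

#' Validate a run manifest
#'
#' Checks the structural invariants a run must satisfy before viability can
#' be computed; called by [read_plate_csv()] and usable on manifests built
#' in code (e.g. by [emit_plates()]).
#'
#' @param run an `eit_run`.
#' @return the run, invisibly classed, or an error naming the violation.
#' @export
validate_eit_run <- function(run) {
  stopifnot(inherits(run, "eit_run"))
  r <- run$readings
  if (!all(r$role %in% ROLES)) {
    stop("unknown well role: ", paste(setdiff(unique(r$role), ROLES), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(r$a450)) || any(!is.finite(r$a650)) ||
      any(r$a450 < 0) || any(r$a650 < 0)) {
    stop("absorbances must be finite and non-negative", call. = FALSE)
  }
  treated <- r$role == "treated"
  if (anyNA(r$chemical_id[treated])) {
    stop("treated wells must carry a chemical_id", call. = FALSE)
  }
  if (any(!is.na(r$chemical_id[!treated]))) {
    stop("chemical_id is only allowed on treated wells", call. = FALSE)
  }
  key <- paste(r$well, r$pip_day)
  if (anyDuplicated(key)) {
    stop("duplicate (well, pip_day) reading: ", key[duplicated(key)][1L], call. = FALSE)
  }

  for (d in sort(unique(r$pip_day))) {
    day <- r[r$pip_day == d, ]
    if (sum(day$role == "blank") < 1L) {
      stop("no blank well at pip_day ", d, call. = FALSE)
    }
    ids <- unique(day$chemical_id[day$role == "treated"])
    for (id in ids) {
      n <- sum(day$role == "treated" & day$chemical_id == id)
      if (n < 2L) {
        stop("chemical ", id, " has fewer than 2 replicates at pip_day ", d,
             call. = FALSE)
      }
    }
  }
  day1 <- r[r$pip_day == 1L, ]
  for (role in c("untreated_control", "negative_control", "positive_control")) {
    if (sum(day1$role == role) < 2L) {
      stop("need at least 2 ", role, " wells at pip_day 1", call. = FALSE)
    }
  }
  invisible(run)
}

#' @export
print.eit_run <- function(x, ...) {
  r <- x$readings
  cat(sprintf("Eye irritation test run '%s': %d well readings\n", x$run_id, nrow(r)))
  cat(sprintf("  PIP days: %s; chemicals: %d\n",
              paste(sort(unique(r$pip_day)), collapse = ", "),
              length(unique(stats::na.omit(r$chemical_id)))))
  invisible(x)
}

#' Write a run manifest back to readings/layout CSV files
#'
#' Inverse of [read_plate_csv()]; useful for persisting simulated runs.
#'
#' @param run an `eit_run`.
#' @param readings_path,layout_path output CSV paths.
#' @return invisibly, a list with the two paths.
#' @export
write_plate_csv <- function(run, readings_path, layout_path) {
  stopifnot(inherits(run, "eit_run"))
  r <- run$readings
  utils::write.csv(r[, c("plate_id", "well", "pip_day", "a450", "a650")],
                   readings_path, row.names = FALSE)
  layout <- unique(r[, c("well", "role", "chemical_id", "replicate")])
  utils::write.csv(layout, layout_path, row.names = FALSE, na = "")
  invisible(list(readings = readings_path, layout = layout_path))
}

#' Write and read viability records
#'
#' Long-format CSV with one row per (chemical or control role) and
#' post-incubation day; replicate viabilities are serialized into a single
#' semicolon-separated column so the table round-trips losslessly.
#'
#' @param records an `eit_viability` data.frame from [quantify_run()].
#' @param path output CSV path.
#' @return `write_viability_csv()` returns `path` invisibly;
#'   `read_viability_csv()` returns the `eit_viability` data.frame.
#' @export
write_viability_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  out$replicate_viabilities <- vapply(
    records$replicate_viabilities,
    function(v) paste(sprintf("%.6f", v), collapse = ";"),
    character(1L)
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_viability_csv
#' @export
read_viability_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- c("chemical_id", "role", "pip_day", "replicate_viabilities",
            "mean_viability", "reference_role", "qc_pass")
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chemical_id = "integer"))
  if (length(miss <- setdiff(cols, names(rec)))) {
    stop("viability CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rec$replicate_viabilities <- lapply(
    strsplit(as.character(rec$replicate_viabilities), ";", fixed = TRUE),
    as.numeric
  )
  rec$qc_pass <- as.logical(rec$qc_pass)
  class(rec) <- c("eit_viability", "data.frame")
  rec
}
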