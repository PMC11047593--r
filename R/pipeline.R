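# djb2 string hash, hex-encoded; used only for config provenance
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on plate files
#'
#' Executes the stages in order — plate reading, viability quantification
#' with QC, trajectory classification, and (when an in vivo reference table
#' is supplied) performance evaluation against both OECD criteria sets. Any
#' stage failure aborts with the stage name and the underlying cause.
#'
#' @param readings_path,layout_path run CSV files, see [read_plate_csv()].
#' @param chemicals optional data.frame with columns `id` and
#'   `in_vivo_category` (the reference classifications); enables the
#'   performance section. [load_liquid_panel()] output works directly.
#' @param protocol an [eit_protocol()].
#' @param qc_config optional QC settings, see [qc_run()].
#' @param run_id identifier recorded in the report.
#' @return an `eit_report` list with sections `qc`, `viability`, `verdicts`,
#'   `performance` (or NULL), and `provenance` (package version, config
#'   hash, run id).
#' @export
run_pipeline <- function(readings_path, layout_path, chemicals = NULL,
                         protocol = eit_protocol(), qc_config = list(),
                         run_id = "run") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  run <- stage("plate_io",
               read_plate_csv(readings_path, layout_path, protocol, run_id))
  records <- stage("viability", quantify_run(run, qc_config))
  verdicts <- stage("classification", classify_run(records, protocol))

  performance <- NULL
  if (!is.null(chemicals)) {
    performance <- stage("performance", {
      ord <- match(verdicts$chemical_id, chemicals$id)
      if (anyNA(ord)) {
        stop("chemicals table lacks ids: ",
             paste(verdicts$chemical_id[is.na(ord)], collapse = ", "))
      }
      in_vivo <- coarsen_category(chemicals$in_vivo_category[ord])
      evaluate_predictions(in_vivo, verdicts$pip1_prediction,
                           verdicts$predicted_category)
    })
  }

  structure(
    list(
      qc = attr(records, "qc"),
      viability = records,
      verdicts = verdicts,
      performance = performance,
      provenance = list(
        package = as.character(utils::packageVersion("eyeirr")),
        run_id = run_id,
        protocol_hash = .config_hash(unclass(protocol)),
        n_chemicals = nrow(verdicts)
      )
    ),
    class = "eit_report"
  )
}

#' Evaluate predictions against in vivo reference categories
#'
#' Computes the day-1 2x2 table with sensitivity/specificity/accuracy and
#' the TG492 PS criteria check, and the final 3x3 table with per-category
#' predictivities, balanced accuracy and the TG492B criteria check.
#'
#' @param in_vivo broad in vivo categories (sub-categories are coarsened).
#' @param pip1_prediction day-1 predictions (`"irritant"`/`"non_irritant"`).
#' @param predicted_category predicted broad categories.
#' @return an `eit_performance` list: `table2`, `binary`, `tg492_ps`,
#'   `table3`, `predictivity`, `tg492b`.
#' @export
evaluate_predictions <- function(in_vivo, pip1_prediction, predicted_category) {
  table2 <- build_2x2(in_vivo, pip1_prediction)
  binary <- binary_metrics(table2)
  table3 <- build_3x3(in_vivo, predicted_category)
  predictivity <- predictivity_and_balance(table3)
  structure(
    list(
      table2 = table2,
      binary = binary,
      tg492_ps = check_criteria(binary, "TG492_PS"),
      table3 = table3,
      predictivity = predictivity,
      tg492b = check_criteria(predictivity, "TG492B")
    ),
    class = "eit_performance"
  )
}

#' @export
print.eit_performance <- function(x, ...) {
  cat("Day-1 prediction (2x2):\n")
  print(x$table2)
  print(x$binary)
  print(x$tg492_ps)
  cat("\nFinal classification (3x3):\n")
  print(unclass(x$table3))
  print(x$predictivity)
  print(x$tg492b)
  invisible(x)
}

#' Recompute the validation statistics from the packaged reference panel
#'
#' Runs the performance module on the 31-chemical liquid panel's recorded
#' outcomes — no plate data involved — reproducing the benchmark numbers of
#' the test method: the day-1 2x2 table and its metrics, the 3x3 table,
#' per-category predictivities and balanced accuracy, both OECD criteria
#' checks, and the outcome stratum counts (fast-tracked, monitored,
#' moderate/mild, non-irritant). Deterministic: repeated calls return
#' identical output.
#'
#' @param panel an `eit_panel`, by default the packaged one.
#' @return an `eit_panel_report` list: `performance` (an
#'   `eit_performance`), `strata` (named integer counts), `panel`.
#' @examples
#' rep <- evaluate_reference_panel()
#' rep$performance$binary
#' @export
evaluate_reference_panel <- function(panel = load_liquid_panel()) {
  stopifnot(inherits(panel, "eit_panel"))
  performance <- evaluate_predictions(panel$in_vivo_broad, panel$pip1_prediction,
                                      panel$predicted_category)
  strata <- c(
    fast_tracked = sum(panel$final_class == "strong" &
                         panel$recoverability == "not_tested"),
    monitored = sum(panel$recoverability %in% c("reversible", "irreversible")),
    moderate_or_mild = sum(panel$final_class == "moderate_or_mild"),
    non_irritant = sum(panel$final_class == "non_irritant")
  )
  structure(list(performance = performance, strata = strata, panel = panel),
            class = "eit_panel_report")
}

#' @export
print.eit_panel_report <- function(x, ...) {
  cat(sprintf("Reference panel evaluation (%d liquid chemicals)\n\n", nrow(x$panel)))
  print(x$performance)
  s <- x$strata
  cat(sprintf(paste0("\nStrata: %d fast-tracked strong (day-1 <= 5%%), ",
                     "%d monitored at days 7/14,\n        %d moderate/mild, ",
                     "%d non-irritant\n"),
              s[["fast_tracked"]], s[["monitored"]],
              s[["moderate_or_mild"]], s[["non_irritant"]]))
  invisible(x)
}

#' @export
print.eit_report <- function(x, ...) {
  cat(sprintf("Pipeline report for run '%s' (%d chemicals)\n",
              x$provenance$run_id, x$provenance$n_chemicals))
  print(x$qc)
  summary(x$verdicts)
  if (!is.null(x$performance)) {
    cat("\n")
    print(x$performance)
  }
  invisible(x)
}

#' Serialize a pipeline or panel report to JSON
#'
#' @param report an `eit_report`, `eit_panel_report` or `eit_performance`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  to_list <- function(x) {
    if (inherits(x, "eit_confusion3")) {
      return(list(counts = unclass(x), categories = GHS_BROAD))
    }
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), to_list))
    x
  }
  skip <- c("viability", "panel", "table")
  payload <- to_list(report[setdiff(names(report), skip)])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
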