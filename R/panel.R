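#' Load the 31-chemical liquid reference panel
#'
#' The package ships the liquid validation panel used to benchmark the test
#' method: 31 liquid chemicals with CAS registry numbers, in vivo GHS
#' reference categories from the Draize-test database (4 Cat. 1, 12 Cat. 2A,
#' 7 Cat. 2B, 8 No Cat.), a marker for the 15 chemicals that belong to the
#' OECD TG 492 performance-standard reference list, and the in vitro test
#' outcomes: the day-1 EC70 prediction, the recoverability judgment
#' (reversible / irreversible / not tested), and the final irritancy class.
#'
#' The loader validates the transcription: row count and per-category
#' tallies, CAS number shape, enum values, and the internal-consistency
#' rules linking the day-1 prediction, recoverability and final class (a
#' chemical never monitored is either a fast-tracked strong irritant or a
#' day-1 non-irritant; a reversible chemical is moderate-or-mild; an
#' irreversible one is strong).
#'
#' @param path path to the panel CSV; defaults to the packaged copy.
#' @return a `data.frame` of class `eit_panel` with columns `id`, `cas_rn`,
#'   `name`, `state`, `in_vivo_category`, `tg492_ps` (logical),
#'   `pip1_prediction`, `recoverability`, `final_class`, and the derived
#'   columns `in_vivo_broad` and `predicted_category`.
#' @examples
#' panel <- load_liquid_panel()
#' table(panel$in_vivo_broad, panel$predicted_category)
#' @export
load_liquid_panel <- function(path = system.file("extdata", "liquid_panel.csv",
                                                 package = "eyeirr")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("liquid panel fixture not found", call. = FALSE)
  }
  panel <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")

  required <- c("id", "cas_rn", "name", "state", "in_vivo_category",
                "tg492_ps", "pip1_prediction", "recoverability", "final_class")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("panel fixture is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  rec_map <- c(R = "reversible", I = "irreversible", NT = "not_tested")
  if (!all(panel$recoverability %in% names(rec_map))) {
    stop("panel fixture invariant violated: recoverability codes must be R, I or NT",
         call. = FALSE)
  }
  panel$recoverability <- unname(rec_map[panel$recoverability])
  panel$tg492_ps <- as.logical(panel$tg492_ps)

  .validate_panel(panel)

  panel$in_vivo_broad <- coarsen_category(panel$in_vivo_category)
  panel$predicted_category <- class_to_category(panel$final_class)
  class(panel) <- c("eit_panel", "data.frame")
  panel
}

.validate_panel <- function(panel) {
  fail <- function(what) {
    stop("panel fixture invariant violated: ", what, call. = FALSE)
  }
  if (nrow(panel) != 31L) fail("expected 31 rows")
  if (anyDuplicated(panel$id) || !setequal(panel$id, 1:31)) fail("ids must be 1..31")
  if (!all(panel$state == "liquid")) fail("all chemicals must be liquid")
  if (!all(grepl("^[0-9]+-[0-9]+-[0-9]$", panel$cas_rn))) {
    fail("CAS numbers must match digits-digits-digit")
  }
  if (!all(panel$in_vivo_category %in% GHS_IN_VIVO)) fail("bad in vivo category")
  if (!all(panel$pip1_prediction %in% PIP1_PREDICTIONS)) fail("bad day-1 prediction")
  if (!all(panel$final_class %in% FINAL_CLASSES)) fail("bad final class")
  if (anyNA(panel$tg492_ps)) fail("tg492_ps must be 0/1")

  tally <- table(factor(panel$in_vivo_category, levels = GHS_IN_VIVO))
  if (!identical(as.integer(tally), c(4L, 12L, 7L, 8L))) {
    fail("in vivo tallies must be 4 Cat1 / 12 Cat2A / 7 Cat2B / 8 NoCat")
  }
  if (sum(panel$tg492_ps) != 15L) fail("expected 15 TG492 PS reference chemicals")

  nt <- panel$recoverability == "not_tested"
  if (!all(panel$final_class[nt] %in% c("strong", "non_irritant"))) {
    fail("not-tested chemicals must be strong or non-irritant")
  }
  rev_ok <- panel$final_class[panel$recoverability == "reversible"] == "moderate_or_mild"
  irr_ok <- panel$final_class[panel$recoverability == "irreversible"] == "strong"
  if (!all(rev_ok)) fail("reversible chemicals must be moderate_or_mild")
  if (!all(irr_ok)) fail("irreversible chemicals must be strong")
  ni <- panel$pip1_prediction == "non_irritant"
  if (!all(panel$recoverability[ni] == "not_tested") ||
      !all(panel$final_class[ni] == "non_irritant")) {
    fail("day-1 non-irritants must be untested and finally non-irritant")
  }
  invisible(panel)
}

#' @export
print.eit_panel <- function(x, ...) {
  cat(sprintf("Liquid reference panel: %d chemicals\n", nrow(x)))
  print(table(`in vivo` = x$in_vivo_category))
  print(table(`final class` = factor(x$final_class, levels = FINAL_CLASSES)))
  invisible(x)
}
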