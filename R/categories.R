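#' GHS ocular-hazard category vocabulary
#'
#' In vivo reference classifications use the four UN GHS labels `CAT1`
#' (irreversible eye damage), `CAT2A`/`CAT2B` (reversible effects, split by
#' recovery time), and `NO_CAT` (no classification required). The in vitro
#' framework predicts only the three broad labels, so 2A and 2B coarsen to
#' `CAT2`.
#'
#' @name ghs-categories
#' @keywords internal
NULL

GHS_IN_VIVO <- c("CAT1", "CAT2A", "CAT2B", "NO_CAT")
GHS_BROAD <- c("CAT1", "CAT2", "NO_CAT")

# final irritancy classes, ordered least to most severe
FINAL_CLASSES <- c("non_irritant", "moderate_or_mild", "strong")

PIP1_PREDICTIONS <- c("irritant", "non_irritant")
RECOVERABILITY <- c("reversible", "irreversible", "not_tested")

#' Coarsen an in vivo GHS category to its broad class
#'
#' `CAT2A` and `CAT2B` both map to `CAT2`; `CAT1` and `NO_CAT` are unchanged.
#'
#' @param category character vector of in vivo categories
#'   (`"CAT1"`, `"CAT2A"`, `"CAT2B"`, `"NO_CAT"`).
#' @return character vector of broad categories (`"CAT1"`, `"CAT2"`, `"NO_CAT"`).
#' @examples
#' coarsen_category(c("CAT2A", "CAT2B", "CAT1", "NO_CAT"))
#' @export
coarsen_category <- function(category) {
  bad <- setdiff(unique(category), c(GHS_IN_VIVO, "CAT2"))
  if (length(bad)) {
    stop("unknown GHS category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ifelse(category %in% c("CAT2A", "CAT2B"), "CAT2", category)
}

#' Map a final irritancy class to its predicted GHS broad category
#'
#' The framework's severity labels correspond one-to-one to broad GHS
#' categories: strong irritant -> Cat. 1, moderate or mild -> Cat. 2,
#' non-irritant -> No Cat.
#'
#' @param final_class character vector of final classes.
#' @return character vector of broad categories.
#' @export
class_to_category <- function(final_class) {
  map <- c(
    strong = "CAT1",
    moderate_or_mild = "CAT2",
    non_irritant = "NO_CAT"
  )
  bad <- setdiff(unique(final_class), names(map))
  if (length(bad)) {
    stop("unknown final class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(map[final_class])
}

# severity rank for monotonicity reasoning: non_irritant(1) < moderate(2) < strong(3)
severity_rank <- function(final_class) {
  match(final_class, FINAL_CLASSES)
}
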