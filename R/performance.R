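#' Round half up, as used for reported percentages
#'
#' Reported metrics are percentages rounded to one decimal with ties going
#' up (87.0, 63.2, 81.3), unlike [round()]'s round-half-even. Criteria
#' comparisons always use the exact fractions, never the rounded values.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Build the day-1 2x2 confusion table
#'
#' Rows are the in vitro day-1 prediction (irritant / non-irritant), columns
#' the in vivo reference coarsened to irritant (Cat. 1 or Cat. 2) versus
#' No Cat. A true positive is an in vivo Cat. 1/2 chemical predicted
#' irritant; a true negative is a No Cat. chemical predicted non-irritant.
#'
#' @param in_vivo character vector of broad in vivo categories
#'   (`"CAT1"`, `"CAT2"`, `"NO_CAT"`); in vivo sub-categories are accepted
#'   and coarsened.
#' @param prediction character vector of day-1 predictions
#'   (`"irritant"` / `"non_irritant"`), same length.
#' @return an `eit_confusion2` list with counts `tp`, `fn`, `fp`, `tn` and
#'   `n`.
#' @examples
#' panel <- load_liquid_panel()
#' build_2x2(panel$in_vivo_broad, panel$pip1_prediction)
#' @export
build_2x2 <- function(in_vivo, prediction) {
  if (!length(in_vivo)) stop("empty input", call. = FALSE)
  stopifnot(length(in_vivo) == length(prediction))
  in_vivo <- coarsen_category(in_vivo)
  if (!all(prediction %in% PIP1_PREDICTIONS)) {
    stop("predictions must be 'irritant' or 'non_irritant'", call. = FALSE)
  }
  positive <- in_vivo %in% c("CAT1", "CAT2")
  predicted_pos <- prediction == "irritant"
  structure(
    list(
      tp = sum(positive & predicted_pos),
      fn = sum(positive & !predicted_pos),
      fp = sum(!positive & predicted_pos),
      tn = sum(!positive & !predicted_pos),
      n = length(in_vivo)
    ),
    class = "eit_confusion2"
  )
}

#' @export
print.eit_confusion2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2L,
              dimnames = list(prediction = c("irritant", "non_irritant"),
                              `in vivo` = c("Cat 1/2", "No Cat")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a 2x2 table
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), accuracy =
#' (tp+tn)/n, reported as percentages rounded half-up to one decimal; the
#' exact fractions are retained in `$fractions` and are what criteria
#' checks consume. A zero denominator yields an `NA` metric together with a
#' reason in `$undefined`, never a silent NaN.
#'
#' @param x an `eit_confusion2` from [build_2x2()].
#' @return an `eit_binary_metrics` list: `sensitivity`, `specificity`,
#'   `accuracy` (rounded percent), `fractions` (exact, on \[0, 1\]),
#'   `undefined` (character), `table`.
#' @examples
#' binary_metrics(build_2x2(c("CAT1", "NO_CAT"), c("irritant", "non_irritant")))
#' @export
binary_metrics <- function(x) {
  stopifnot(inherits(x, "eit_confusion2"))
  undefined <- character(0L)
  frac <- list(
    sensitivity = if (x$tp + x$fn > 0) x$tp / (x$tp + x$fn) else NA_real_,
    specificity = if (x$tn + x$fp > 0) x$tn / (x$tn + x$fp) else NA_real_,
    accuracy = if (x$n > 0) (x$tp + x$tn) / x$n else NA_real_
  )
  if (is.na(frac$sensitivity)) undefined <- c(undefined, "sensitivity: no in vivo positives")
  if (is.na(frac$specificity)) undefined <- c(undefined, "specificity: no in vivo negatives")

  structure(
    list(
      sensitivity = round_half_up(100 * frac$sensitivity),
      specificity = round_half_up(100 * frac$specificity),
      accuracy = round_half_up(100 * frac$accuracy),
      fractions = frac,
      undefined = undefined,
      table = x
    ),
    class = "eit_binary_metrics"
  )
}

#' @export
print.eit_binary_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%% (%d/%d), specificity %.1f%% (%d/%d), accuracy %.1f%% (%d/%d)\n",
              x$sensitivity, x$table$tp, x$table$tp + x$table$fn,
              x$specificity, x$table$tn, x$table$tn + x$table$fp,
              x$accuracy, x$table$tp + x$table$tn, x$table$n))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = "; "), "\n")
  invisible(x)
}

#' Build the 3x3 category confusion table
#'
#' Rows are the predicted GHS broad category, columns the in vivo reference
#' broad category, both ordered Cat. 1, Cat. 2, No Cat.
#'
#' @param in_vivo broad (or in vivo sub-) categories.
#' @param predicted predicted broad categories, same length.
#' @return an `eit_confusion3`: a 3x3 integer matrix with dimnames
#'   `predicted` x `in_vivo`.
#' @export
build_3x3 <- function(in_vivo, predicted) {
  if (!length(in_vivo)) stop("empty input", call. = FALSE)
  stopifnot(length(in_vivo) == length(predicted))
  in_vivo <- coarsen_category(in_vivo)
  if (!all(predicted %in% GHS_BROAD)) {
    stop("predicted categories must be CAT1, CAT2 or NO_CAT", call. = FALSE)
  }
  m <- table(predicted = factor(predicted, levels = GHS_BROAD),
             in_vivo = factor(in_vivo, levels = GHS_BROAD))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  structure(m, class = c("eit_confusion3", class(m)))
}

#' Per-category predictivity and balanced accuracy of a 3x3 table
#'
#' Predictivity of a category is the fraction of its in vivo chemicals
#' predicted into that category (the diagonal cell over the column sum).
#' `balanced_accuracy` is the overall fraction correct, trace/total — the
#' convention used when a test method's multiclass concordance is quoted as
#' a single number (e.g. 21/31). The mean of the three per-category
#' predictivities is also returned, under the distinct name
#' `mean_predictivity`, to keep the two conventions apart.
#'
#' @param x an `eit_confusion3` from [build_3x3()].
#' @return an `eit_predictivity` list: `predictivity` (named rounded
#'   percents), `balanced_accuracy`, `mean_predictivity`, `fractions`
#'   (exact), `undefined`, `table`.
#' @export
predictivity_and_balance <- function(x) {
  stopifnot(inherits(x, "eit_confusion3"))
  totals <- colSums(x)
  n <- sum(x)
  undefined <- character(0L)
  frac <- diag(x) / totals
  for (cat in GHS_BROAD) {
    if (totals[[cat]] == 0L) {
      frac[[cat]] <- NA_real_
      undefined <- c(undefined, paste0(cat, ": no in vivo chemicals"))
    }
  }
  bal <- sum(diag(x)) / n
  structure(
    list(
      predictivity = round_half_up(100 * frac),
      balanced_accuracy = round_half_up(100 * bal),
      mean_predictivity = round_half_up(100 * mean(frac)),
      fractions = list(predictivity = frac, balanced_accuracy = bal),
      undefined = undefined,
      table = x
    ),
    class = "eit_predictivity"
  )
}

#' @export
print.eit_predictivity <- function(x, ...) {
  d <- diag(x$table)
  tot <- colSums(x$table)
  cat(sprintf("predictivity: Cat 1 %.1f%% (%d/%d), Cat 2 %.1f%% (%d/%d), No Cat %.1f%% (%d/%d)\n",
              x$predictivity[["CAT1"]], d[["CAT1"]], tot[["CAT1"]],
              x$predictivity[["CAT2"]], d[["CAT2"]], tot[["CAT2"]],
              x$predictivity[["NO_CAT"]], d[["NO_CAT"]], tot[["NO_CAT"]]))
  cat(sprintf("balanced accuracy (trace/total): %.1f%% (%d/%d)\n",
              x$balanced_accuracy, sum(diag(x$table)), sum(x$table)))
  invisible(x)
}

# regulatory criteria sets; comparisons use exact fractions (percent scale)
CRITERIA_SETS <- list(
  TG492_PS = list(sensitivity = 90, specificity = 60, accuracy = 75),
  TG492B = list(CAT1 = 75, CAT2 = 50, NO_CAT = 70)
)

#' Check metrics against OECD performance criteria
#'
#' Two criteria sets are built in: `"TG492_PS"` requires sensitivity >= 90%,
#' specificity >= 60% and accuracy >= 75% of the day-1 binary prediction;
#' `"TG492B"` requires per-category predictivity of Cat. 1 >= 75%,
#' Cat. 2 >= 50% and No Cat. >= 70%. Comparisons use exact fractions, not
#' the rounded reporting values; an undefined metric fails its criterion
#' with the reason recorded.
#'
#' @param report an `eit_binary_metrics` (for `TG492_PS`) or
#'   `eit_predictivity` (for `TG492B`).
#' @param criteria_set name of the criteria set.
#' @return an `eit_criteria` list: `set`, per-criterion data.frame
#'   (`criterion`, `threshold`, `value`, `pass`), and `overall`
#'   (conjunction).
#' @examples
#' m <- binary_metrics(build_2x2(rep("CAT1", 9), rep("irritant", 9)))
#' check_criteria(m, "TG492_PS")
#' @export
check_criteria <- function(report, criteria_set = c("TG492_PS", "TG492B")) {
  criteria_set <- match.arg(criteria_set)
  thresholds <- CRITERIA_SETS[[criteria_set]]

  values <- if (criteria_set == "TG492_PS") {
    stopifnot(inherits(report, "eit_binary_metrics"))
    100 * unlist(report$fractions[c("sensitivity", "specificity", "accuracy")])
  } else {
    stopifnot(inherits(report, "eit_predictivity"))
    100 * report$fractions$predictivity[GHS_BROAD]
  }
  df <- data.frame(
    criterion = names(thresholds),
    threshold = unlist(thresholds),
    value = as.numeric(values[names(thresholds)]),
    stringsAsFactors = FALSE
  )
  df$pass <- !is.na(df$value) & df$value >= df$threshold
  rownames(df) <- NULL
  structure(list(set = criteria_set, criteria = df, overall = all(df$pass)),
            class = "eit_criteria")
}

#' @export
print.eit_criteria <- function(x, ...) {
  cat(sprintf("%s criteria: %s\n", x$set, if (x$overall) "MET" else "NOT MET"))
  df <- x$criteria
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s >= %g%%: %.1f%% -> %s\n", df$criterion[i], df$threshold[i],
                round_half_up(df$value[i]), if (df$pass[i]) "pass" else "fail"))
  }
  invisible(x)
}
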