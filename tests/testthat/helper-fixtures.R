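# shared fixture builders; everything is generated in code at test time

# minimal single-day readings table around a known blank and reference
make_day_readings <- function(day = 1L,
                              blank = c(0.10),
                              untreated = c(0.90, 0.90),
                              negative = c(0.88, 0.88),
                              positive = c(0.12, 0.12),
                              treated = list(),
                              a650 = 0.05) {
  rows <- list()
  add <- function(role, a450, chemical_id = NA_integer_, replicate = 1L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, a450 = a450, a650 = a650, chemical_id = chemical_id,
      replicate = replicate, pip_day = day, stringsAsFactors = FALSE)
  }
  for (i in seq_along(blank)) add("blank", blank[i], replicate = i)
  for (i in seq_along(untreated)) add("untreated_control", untreated[i], replicate = i)
  for (i in seq_along(negative)) add("negative_control", negative[i], replicate = i)
  for (i in seq_along(positive)) add("positive_control", positive[i], replicate = i)
  for (id in seq_along(treated)) {
    for (i in seq_along(treated[[id]])) {
      add("treated", treated[[id]][i], chemical_id = id, replicate = i)
    }
  }
  out <- do.call(rbind, rows)
  out$well <- paste0(LETTERS[(seq_len(nrow(out)) - 1L) %% 8L + 1L],
                     (seq_len(nrow(out)) - 1L) %/% 8L + 1L)
  out$plate_id <- sprintf("P%02d", day)
  out
}

# write a one-day run to readings/layout CSVs, returning the two paths
write_run_csvs <- function(readings, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  rp <- file.path(dir, "readings.csv")
  lp <- file.path(dir, "layout.csv")
  utils::write.csv(readings[, c("plate_id", "well", "pip_day", "a450", "a650")],
                   rp, row.names = FALSE)
  layout <- unique(readings[, c("well", "role", "chemical_id", "replicate")])
  utils::write.csv(layout, lp, row.names = FALSE, na = "")
  list(readings = rp, layout = lp)
}

# brute-force enumeration oracle for binary metrics: counts by explicit loop
oracle_binary <- function(in_vivo, prediction) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(in_vivo)) {
    pos <- in_vivo[i] != "NO_CAT"
    pred_pos <- prediction[i] == "irritant"
    if (pos && pred_pos) tp <- tp + 1L
    if (pos && !pred_pos) fn <- fn + 1L
    if (!pos && pred_pos) fp <- fp + 1L
    if (!pos && !pred_pos) tn <- tn + 1L
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(in_vivo))
}

# brute-force oracle for the 3x3 table and its summaries
oracle_multiclass <- function(in_vivo, predicted) {
  cats <- c("CAT1", "CAT2", "NO_CAT")
  counts <- matrix(0L, 3L, 3L, dimnames = list(cats, cats))
  for (i in seq_along(in_vivo)) {
    counts[predicted[i], in_vivo[i]] <- counts[predicted[i], in_vivo[i]] + 1L
  }
  predictivity <- vapply(cats, function(ct) {
    tot <- sum(in_vivo == ct)
    if (tot == 0) NA_real_ else sum(in_vivo == ct & predicted == ct) / tot
  }, numeric(1L))
  list(counts = counts, predictivity = predictivity,
       balanced = sum(in_vivo == predicted) / length(in_vivo))
}
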