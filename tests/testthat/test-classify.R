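test_that("the EC70 boundary is inclusive-irritant", {
  expect_identical(pip1_predict(85), "non_irritant")
  expect_identical(pip1_predict(70), "irritant")
  expect_identical(pip1_predict(70.000001), "non_irritant")
  expect_identical(pip1_predict(c(3, 70, 71)),
                   c("irritant", "irritant", "non_irritant"))
})

test_that("trajectories classify by the ordered rule set", {
  # deep damage fast-tracks to strong with no recovery monitoring
  v <- classify_trajectory(c("1" = 3))
  expect_identical(v$final_class, "strong")
  expect_identical(v$predicted_category, "CAT1")
  expect_identical(v$recoverability, "not_tested")
  expect_identical(v$rationale, "fast_track_strong")

  # boundary 5 is inclusive-strong
  expect_identical(classify_trajectory(c("1" = 5))$final_class, "strong")

  # recovery above 50% of the negative control at day 7 -> reversible
  v <- classify_trajectory(c("1" = 40, "7" = 60))
  expect_identical(v$recoverability, "reversible")
  expect_identical(v$final_class, "moderate_or_mild")
  expect_identical(v$predicted_category, "CAT2")

  # no recovery by day 14 -> irreversible strong
  v <- classify_trajectory(c("1" = 40, "7" = 30, "14" = 45))
  expect_identical(v$recoverability, "irreversible")
  expect_identical(v$final_class, "strong")

  # the recovery criterion is strictly greater than 50
  v <- classify_trajectory(c("1" = 40, "7" = 50.0, "14" = 50.0))
  expect_identical(v$final_class, "strong")
  expect_identical(classify_trajectory(c("1" = 40, "7" = 50.0001, "14" = 50))$final_class,
                   "moderate_or_mild")

  # clean day 1 -> non-irritant, nothing else measured
  v <- classify_trajectory(c("1" = 90))
  expect_identical(v$pip1_prediction, "non_irritant")
  expect_identical(v$final_class, "non_irritant")
  expect_identical(v$recoverability, "not_tested")
})

test_that("monitoring-band chemicals without late measurements are an error", {
  expect_error(classify_trajectory(c("1" = 40)), "incomplete trajectory")
  # no recovery at day 7 alone cannot conclude irreversibility
  expect_error(classify_trajectory(c("1" = 40, "7" = 30)), "incomplete trajectory")
  # recovery at day 7 makes day 14 optional
  expect_identical(classify_trajectory(c("1" = 40, "7" = 70))$final_class,
                   "moderate_or_mild")
})

test_that("exactly one rule fires for every finite day-1 viability", {
  set.seed(31)
  v1s <- c(runif(200, -10, 110), 5, 50, 70, 0, 100)
  for (v1 in v1s) {
    tr <- if (v1 > 5 && v1 <= 70) c("1" = v1, "7" = 60, "14" = 80) else c("1" = v1)
    v <- classify_trajectory(tr)
    first <- v$rationale[1]
    expected <- if (v1 > 70) "ec70_noncat" else if (v1 <= 5) "fast_track_strong" else "monitoring_band"
    expect_identical(first, expected)
  }
})

test_that("raising any viability never worsens the verdict", {
  set.seed(32)
  sev <- c(non_irritant = 1L, moderate_or_mild = 2L, strong = 3L)
  classify_full <- function(v1, v7, v14) {
    tr <- if (v1 > 5 && v1 <= 70) c("1" = v1, "7" = v7, "14" = v14) else c("1" = v1)
    sev[[classify_trajectory(tr)$final_class]]
  }
  for (i in 1:300) {
    v1 <- runif(1, 0, 100); v7 <- runif(1, 0, 100); v14 <- runif(1, 0, 100)
    base <- classify_full(v1, v7, v14)
    which_up <- sample(1:3, 1)
    bump <- runif(1, 0, 30)
    up <- c(v1, v7, v14)
    up[which_up] <- up[which_up] + bump
    expect_lte(classify_full(up[1], up[2], up[3]), base)
  }
})

test_that("the optional late non-irritant rule only fires when enabled", {
  cfg_on <- eit_protocol(allow_late_noncat = TRUE)
  tr <- c("1" = 40, "7" = 60, "14" = 85) # strictly increasing, ends above EC70
  expect_identical(classify_trajectory(tr)$final_class, "moderate_or_mild")
  v <- classify_trajectory(tr, cfg_on)
  expect_identical(v$final_class, "non_irritant")
  expect_true("late_noncat" %in% v$rationale)
  # non-monotone trajectory ending high still classifies as reversible
  expect_identical(classify_trajectory(c("1" = 40, "7" = 90, "14" = 85), cfg_on)$final_class,
                   "moderate_or_mild")
})

test_that("the recorded recovery examples reproduce their judgments", {
  # recovering chemicals (reversible): crossing 50% by day 7 or 14
  recovering <- list(c("1" = 35, "7" = 65, "14" = 90),
                     c("1" = 55, "7" = 80),
                     c("1" = 20, "7" = 40, "14" = 75))
  for (tr in recovering) {
    expect_identical(classify_trajectory(tr)$recoverability, "reversible")
  }
  # non-recovering chemicals (irreversible): never above 50%
  stuck <- list(c("1" = 30, "7" = 35, "14" = 40),
                c("1" = 45, "7" = 20, "14" = 10),
                c("1" = 60, "7" = 45, "14" = 48))
  for (tr in stuck) {
    expect_identical(classify_trajectory(tr)$recoverability, "irreversible")
  }
})

test_that("classify_run gates on QC and returns one verdict per chemical", {
  spec <- simulation_spec(n_per_category = 3, noise_sd = 0, seed = 9)
  sim <- simulate_trajectories(spec)
  run <- emit_plates(sim$trajectories, spec)
  records <- quantify_run(run)
  verdicts <- classify_run(records, spec$protocol)
  expect_identical(nrow(verdicts), nrow(sim$truth))
  expect_identical(verdicts$predicted_category[match(sim$truth$chemical_id,
                                                     verdicts$chemical_id)],
                   sim$truth$category)

  failed <- records
  failed$qc_pass <- FALSE
  expect_error(classify_run(failed, spec$protocol), "QC")
})
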