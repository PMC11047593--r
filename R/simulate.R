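#' Category profile for trajectory simulation
#'
#' A profile describes how chemicals of one generating GHS category behave:
#' the distribution of day-1 viability, and — for chemicals damaged into the
#' monitoring band — an exponential approach to a recovery plateau,
#' `v(t) = plateau - (plateau - v1) * exp(-k * (t - 1))`. Reversible
#' profiles carry a plateau above the recovery cut-off, irreversible ones a
#' plateau at or below it; fast-track profiles (`recovery = "none"`) place
#' day-1 mass outside the monitoring band so no late measurement occurs.
#'
#' @param category generating broad category (`"CAT1"`, `"CAT2"`, `"NO_CAT"`).
#' @param v1_range length-2 numeric: day-1 viability drawn uniformly from
#'   this range (percent).
#' @param recovery `"reversible"`, `"irreversible"` or `"none"`.
#' @param rate per-day recovery rate constant k (>= 0).
#' @param plateau asymptotic viability (percent).
#' @return a `category_profile` list.
#' @export
category_profile <- function(category, v1_range, recovery = "none",
                             rate = 0, plateau = NA_real_) {
  stopifnot(category %in% GHS_BROAD,
            length(v1_range) == 2L, v1_range[1L] <= v1_range[2L],
            recovery %in% c("reversible", "irreversible", "none"),
            rate >= 0)
  structure(list(category = category, v1_range = v1_range, recovery = recovery,
                 rate = rate, plateau = plateau),
            class = "category_profile")
}

#' Default simulation profiles
#'
#' Each stratum keeps at least a 10 percentage-point margin from every
#' decision threshold (5, 50, 70), so classification of noiseless
#' trajectories is unambiguous and, at small noise, errors require
#' multi-sigma excursions:
#' no-category chemicals start at 80-95%; Cat. 2 chemicals are damaged into
#' 25-55% and recover towards a plateau of 85-95% (k = 0.3/day, so they pass
#' the 50% criterion by day 7); Cat. 1 chemicals are damaged into 15-35%
#' and plateau at 30-40%, never exceeding 50%.
#'
#' `boundary_profiles()` instead concentrates day-1 viability on the EC70
#' boundary, for stress-testing threshold behaviour under noise.
#'
#' @return a named list of [category_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    NO_CAT = category_profile("NO_CAT", v1_range = c(80, 95), recovery = "none"),
    CAT2 = category_profile("CAT2", v1_range = c(25, 55), recovery = "reversible",
                            rate = 0.3, plateau = 90),
    CAT1 = category_profile("CAT1", v1_range = c(15, 35), recovery = "irreversible",
                            rate = 0.15, plateau = 35)
  )
}

#' @rdname default_profiles
#' @export
boundary_profiles <- function() {
  list(
    NO_CAT = category_profile("NO_CAT", v1_range = c(70, 70), recovery = "none"),
    CAT2 = category_profile("CAT2", v1_range = c(70, 70), recovery = "reversible",
                            rate = 0.3, plateau = 90)
  )
}

#' Specification of a simulated run
#'
#' @param n_per_category integer, chemicals simulated per profile.
#' @param noise_sd additive Gaussian noise on viability (percentage points).
#' @param profiles named list of [category_profile()] objects.
#' @param od_dynamic_range od of a fully viable tissue above blank
#'   (absorbance units).
#' @param blank_od od of the WST-8 blank above the 650 nm baseline.
#' @param a650_baseline reference-wavelength absorbance of every well.
#' @param od_noise_cv multiplicative (coefficient-of-variation) noise on
#'   emitted well od; 0 disables it.
#' @param replicates tissue replicates per chemical and control (>= 2).
#' @param seed integer random seed; mandatory, no hidden global state.
#' @param protocol an [eit_protocol()].
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_per_category = 10L, noise_sd = 0,
                            profiles = default_profiles(),
                            od_dynamic_range = 0.8, blank_od = 0.1,
                            a650_baseline = 0.04, od_noise_cv = 0,
                            replicates = 2L, seed,
                            protocol = eit_protocol()) {
  if (missing(seed)) stop("simulation_spec() requires an explicit seed", call. = FALSE)
  stopifnot(noise_sd >= 0, od_dynamic_range > 0, blank_od >= 0,
            a650_baseline >= 0, od_noise_cv >= 0, replicates >= 2L,
            length(profiles) >= 1L, inherits(protocol, "eit_protocol"))
  structure(list(n_per_category = as.integer(n_per_category), noise_sd = noise_sd,
                 profiles = profiles, od_dynamic_range = od_dynamic_range,
                 blank_od = blank_od, a650_baseline = a650_baseline,
                 od_noise_cv = od_noise_cv, replicates = as.integer(replicates),
                 seed = as.integer(seed), protocol = protocol),
            class = "simulation_spec")
}

# noiseless trajectory value at day t (t = 1 gives v1 exactly)
.trajectory_value <- function(v1, plateau, rate, t) {
  plateau - (plateau - v1) * exp(-rate * (t - 1))
}

#' Simulate labeled viability trajectories
#'
#' Draws day-1 viabilities from each profile, evolves monitored chemicals
#' along the exponential recovery model, and adds additive Gaussian noise
#' (`noise_sd`). As in the real protocol, whether a chemical is monitored at
#' days 7 and 14 is decided from its *measured* (noisy) day-1 value: only
#' chemicals landing in the monitoring band get late measurements.
#' Viabilities are truncated at 0 (a plate cannot report less signal than
#' none, beyond blank noise handled downstream). Deterministic given the
#' spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return a list: `truth` (data.frame `chemical_id`, `category`),
#'   `trajectories` (an `eit_trajectories` list as consumed by
#'   [classify_trajectory()]).
#' @export
simulate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  protocol <- spec$protocol
  late_days <- setdiff(protocol$pip_days, 1L)

  set.seed(spec$seed)

  truth <- list()
  trajectories <- list()
  id <- 0L
  for (profile in spec$profiles) {
    for (i in seq_len(spec$n_per_category)) {
      id <- id + 1L
      v1_true <- stats::runif(1L, profile$v1_range[1L], profile$v1_range[2L])
      v1 <- max(0, v1_true + stats::rnorm(1L, sd = spec$noise_sd))
      v <- c("1" = v1)
      in_band <- v1 > protocol$strong_cutoff & v1 <= protocol$ec70_cutoff
      if (in_band && length(late_days)) {
        if (profile$recovery == "none") {
          # fast-track profile knocked into the band by noise: no kinetic
          # model applies; hold the tissue at its day-1 level
          late_true <- rep(v1_true, length(late_days))
        } else {
          late_true <- .trajectory_value(v1_true, profile$plateau, profile$rate,
                                         late_days)
        }
        late <- pmax(0, late_true + stats::rnorm(length(late_days), sd = spec$noise_sd))
        names(late) <- late_days
        v <- c(v, late)
      }
      truth[[id]] <- data.frame(chemical_id = id, category = profile$category,
                                stringsAsFactors = FALSE)
      trajectories[[id]] <- list(chemical_id = id, viability_by_day = v)
    }
  }
  list(truth = do.call(rbind, truth),
       trajectories = structure(trajectories, class = "eit_trajectories"))
}

#' Emit raw absorbance plates realizing a set of trajectories
#'
#' Inverse of the viability module: builds an `eit_run` whose wells, once
#' blank-corrected and normalized, reproduce the given viabilities. Every
#' well reads `a650 = a650_baseline` and
#' `a450 = a650 + blank_od + (v/100) * od_dynamic_range * (1 + eps)`, with
#' `eps ~ N(0, od_noise_cv)` multiplicative plate noise (0 by default).
#' Each measured day gets 2 blank wells, and untreated, negative
#' (viability 100) and positive (viability 2) control tissues at the
#' configured replicate count; treated chemicals appear on the days their
#' trajectory covers. With all noise off the emit/quantify round trip is the
#' identity to numerical precision.
#'
#' @param trajectories an `eit_trajectories` list.
#' @param spec a [simulation_spec()].
#' @return an `eit_run`.
#' @export
emit_plates <- function(trajectories, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)

  days <- sort(unique(c(1L, unlist(lapply(trajectories, function(tr)
    as.integer(names(tr$viability_by_day)))))))

  # fixed well label per tissue position, shared by every day: row letter
  # A-H cycling, unbounded column numbers (geometry is not enforced)
  well_label <- function(i) paste0(LETTERS[(i - 1L) %% 8L + 1L], (i - 1L) %/% 8L + 1L)
  n_ctl <- 3L * spec$replicates
  ctl_base <- 2L # wells 1-2 are blanks
  chem_base <- ctl_base + n_ctl
  chem_well <- function(chemical_id, replicate) {
    well_label(chem_base + (chemical_id - 1L) * spec$replicates + replicate)
  }

  rows <- list()
  for (d in days) {
    wells <- list()
    add <- function(well, role, v, chemical_id = NA_integer_, replicate = 1L) {
      wells[[length(wells) + 1L]] <<- data.frame(
        well = well, role = role, viability = v, chemical_id = chemical_id,
        replicate = replicate, stringsAsFactors = FALSE)
    }
    for (b in 1:2) add(well_label(b), "blank", NA_real_, replicate = b)
    for (r in seq_len(spec$replicates)) {
      add(well_label(ctl_base + r), "untreated_control", 100, replicate = r)
      add(well_label(ctl_base + spec$replicates + r), "negative_control", 100,
          replicate = r)
      add(well_label(ctl_base + 2L * spec$replicates + r), "positive_control", 2,
          replicate = r)
    }
    for (tr in trajectories) {
      v <- tr$viability_by_day
      if (!as.character(d) %in% names(v)) next
      for (r in seq_len(spec$replicates)) {
        add(chem_well(tr$chemical_id, r), "treated", v[[as.character(d)]],
            chemical_id = tr$chemical_id, replicate = r)
      }
    }
    day <- do.call(rbind, wells)
    day$plate_id <- sprintf("PIP%02d", d)
    day$pip_day <- d

    od <- ifelse(day$role == "blank", 0, day$viability / 100 * spec$od_dynamic_range)
    if (spec$od_noise_cv > 0) {
      od <- od * (1 + stats::rnorm(length(od), sd = spec$od_noise_cv))
    }
    day$a650 <- spec$a650_baseline
    day$a450 <- pmax(0, day$a650 + spec$blank_od + od)
    rows[[length(rows) + 1L]] <- day
  }
  readings <- do.call(rbind, rows)
  layout <- unique(readings[, c("well", "role", "chemical_id", "replicate")])
  run <- new_eit_run(run_id = sprintf("sim-seed%d", spec$seed),
                     protocol = spec$protocol,
                     readings = readings[, c("plate_id", "well", "pip_day",
                                             "a450", "a650")],
                     layout = layout)
  validate_eit_run(run)
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates labeled chemicals, emits raw plates, runs the full
#' quantify-classify pipeline, and scores the predicted category against
#' the generating category.
#'
#' @param spec a [simulation_spec()].
#' @param n_reps number of independent runs to aggregate (seeds
#'   `seed, seed+1000, ...`).
#' @return an `eit_recovery_experiment` list: `overall` accuracy (fraction
#'   correct), `per_category` named accuracies, `n` chemicals scored,
#'   `confusion` (an `eit_confusion3`).
#' @export
recovery_rate_experiment <- function(spec, n_reps = 1L) {
  stopifnot(inherits(spec, "simulation_spec"), n_reps >= 1L)
  truths <- character(0L)
  preds <- character(0L)
  for (rep in seq_len(n_reps)) {
    s <- spec
    s$seed <- spec$seed + (rep - 1L) * 1000L
    sim <- simulate_trajectories(s)
    run <- emit_plates(sim$trajectories, s)
    records <- quantify_run(run)
    verdicts <- classify_run(records, s$protocol)
    ord <- match(sim$truth$chemical_id, verdicts$chemical_id)
    truths <- c(truths, sim$truth$category)
    preds <- c(preds, verdicts$predicted_category[ord])
  }
  correct <- truths == preds
  per_cat <- vapply(unique(truths), function(cat) mean(correct[truths == cat]),
                    numeric(1L))
  structure(
    list(overall = mean(correct), per_category = per_cat, n = length(correct),
         confusion = build_3x3(truths, preds)),
    class = "eit_recovery_experiment"
  )
}

#' @export
print.eit_recovery_experiment <- function(x, ...) {
  cat(sprintf("parameter recovery over %d chemicals: %.1f%% correct\n",
              x$n, 100 * x$overall))
  for (cat_name in names(x$per_category)) {
    cat(sprintf("  %s: %.1f%%\n", cat_name, 100 * x$per_category[[cat_name]]))
  }
  invisible(x)
}
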