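#' Parameters for a simulated compression trace
#'
#' Describes one force-displacement trace from a serial-angle compression
#' test: a smooth power-law indentation ramp with, optionally, an embedded
#' puncture event (a sharp force drop at a known displacement), plus
#' additive Gaussian noise. The ramp exponent defaults to 1.5 (Hertz-like
#' blunt indentation); any convex ramp works for drop detection and the
#' exponent is exposed.
#'
#' @param puncture_force peak force at the puncture event, N; `NA` to embed
#'   no event (plain ramp).
#' @param puncture_displacement displacement of the event, mm; must be below
#'   `travel_limit`.
#' @param pre_stiffness_exponent power-law exponent of the loading ramp
#'   (>= 1).
#' @param drop_fraction fraction of the peak force lost at puncture, in
#'   (0, 1]; the drop completes within one sample step.
#' @param noise_sd standard deviation of additive Gaussian force noise, N.
#' @param rate crosshead speed, mm/min (metadata; default 10).
#' @param travel_limit displacement at which the trace ends, mm (5-15).
#' @param sample_spacing displacement between samples, mm.
#' @param seed integer seed for the noise stream.
#' @return a validated list of class `trace_gen_params`.
#' @export
trace_gen_params <- function(puncture_force = 20, puncture_displacement = 3,
                             pre_stiffness_exponent = 1.5, drop_fraction = 0.4,
                             noise_sd = 0.2, rate = 10, travel_limit = 6,
                             sample_spacing = 0.01, seed = 1L) {
  if (!is.na(puncture_force)) {
    check_number(puncture_force, "puncture_force", lower = 0, strict_lower = TRUE)
    check_number(puncture_displacement, "puncture_displacement", lower = 0,
                 upper = travel_limit, strict_lower = TRUE, strict_upper = TRUE)
    check_number(drop_fraction, "drop_fraction", lower = 0, upper = 1,
                 strict_lower = TRUE)
  }
  check_number(pre_stiffness_exponent, "pre_stiffness_exponent", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(travel_limit, "travel_limit", lower = 5, upper = 15)
  check_number(sample_spacing, "sample_spacing", lower = 0, strict_lower = TRUE)
  structure(list(puncture_force = puncture_force,
                 puncture_displacement = puncture_displacement,
                 pre_stiffness_exponent = pre_stiffness_exponent,
                 drop_fraction = drop_fraction, noise_sd = noise_sd,
                 rate = rate, travel_limit = travel_limit,
                 sample_spacing = sample_spacing, seed = as.integer(seed)),
            class = "trace_gen_params")
}

#' Force trace container
#'
#' Paired displacement/force series from one compression trial, with trial
#' metadata (spine id, approach angle, replicate, crosshead rate, travel
#' limit).
#'
#' @param displacement monotone nondecreasing displacement series, mm.
#' @param force force series, N; same length as `displacement`.
#' @param metadata named list; recognised fields are `spine_id`,
#'   `angle_deg`, `replicate`, `rate`, `travel_limit`.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(displacement, force, metadata = list()) {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force)) {
    stopf("displacement and force must have equal length")
  }
  if (is.unsorted(displacement)) {
    stopf("displacement must be monotone nondecreasing")
  }
  structure(list(displacement = displacement, force = force,
                 metadata = metadata), class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  md <- x$metadata
  id <- if (!is.null(md$spine_id)) {
    sprintf(" [%s, %+d deg, rep %d]", md$spine_id,
            as.integer(md$angle_deg %||% 0), as.integer(md$replicate %||% 1))
  } else ""
  cat(sprintf("force trace%s: %d samples, 0-%.3g mm, max %.3g N\n",
              id, length(x$force), max(x$displacement), max(x$force)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a force-displacement compression trace
#'
#' Force rises as a power-law ramp to the puncture force at the puncture
#' displacement, drops by `drop_fraction` within one sample step (the sudden
#' force drop that marks a successful puncture), then resumes rising with
#' the same ramp shape; Gaussian noise is added throughout and the trace is
#' truncated at the travel limit. With `puncture_force = NA` a plain
#' monotone ramp (no event) is produced.
#'
#' @param params a [trace_gen_params()] object.
#' @param metadata metadata list stored on the trace.
#' @return list with `trace` (a [force_trace()]) and `events`: a data frame
#'   of embedded ground-truth events (displacement, force, drop), empty if
#'   none.
#' @export
simulate_force_trace <- function(params, metadata = list()) {
  stopifnot(inherits(params, "trace_gen_params"))
  p <- params
  d <- seq(0, p$travel_limit, by = p$sample_spacing)
  pexp <- p$pre_stiffness_exponent
  if (is.na(p$puncture_force)) {
    # eventless ramp rising to a nominal force at the travel limit
    f <- 0.7 * 20 * (d / p$travel_limit)^pexp
    events <- data.frame(displacement = numeric(0), force = numeric(0),
                         drop = numeric(0))
  } else {
    dp <- p$puncture_displacement
    f <- numeric(length(d))
    pre <- d <= dp
    f[pre] <- p$puncture_force * (d[pre] / dp)^pexp
    post <- !pre
    # resume rising from the dropped level with the same ramp shape
    f[post] <- (1 - p$drop_fraction) * p$puncture_force *
      (d[post] / dp)^pexp
    events <- data.frame(displacement = dp, force = p$puncture_force,
                         drop = p$drop_fraction * p$puncture_force)
  }
  if (p$noise_sd > 0) {
    f <- f + with_seed(p$seed, stats::rnorm(length(f), 0, p$noise_sd))
  }
  md <- utils::modifyList(list(rate = p$rate, travel_limit = p$travel_limit),
                          metadata)
  list(trace = force_trace(d, f, md), events = events)
}

#' Parameters for a simulated serial-angle puncture experiment
#'
#' Defines the experimental design of serial compression tests: a symmetric
#' angle grid in 10 degree increments, a number of replicates per spine and
#' angle (default 3), and the deterministic success model linking spine
#' shape to performance. A trial succeeds iff the absolute test angle does
#' not exceed the spine's maximum puncture angle; the required force grows
#' linearly with the absolute angle. The default link coefficients encode
#' the qualitative structure observed in puncture experiments: blunter tips
#' (larger tip angle) need more force, and higher structural curvature
#' widens the range of angles at which puncture is possible.
#'
#' @param angle_grid test angles, degrees: multiples of 10, symmetric about
#'   0 (default -30 to 30).
#' @param replicates replicates per spine x angle (default 3).
#' @param force_base baseline puncture force at 0 degrees for a
#'   zero-tip-angle spine, N.
#' @param force_per_tip_deg increase of the 0-degree puncture force per
#'   degree of tip angle, N/deg.
#' @param force_angle_slope increase of required force per degree of
#'   absolute test angle, N/deg.
#' @param max_angle_base baseline maximum puncture angle, degrees.
#' @param max_angle_per_curv_deg increase of the maximum puncture angle per
#'   degree of structural curvature (deg/deg).
#' @param trace_template a [trace_gen_params()] object supplying ramp shape,
#'   noise, travel limit and sampling for all trials.
#' @return a validated list of class `experiment_gen_params`.
#' @export
experiment_gen_params <- function(angle_grid = seq(-30, 30, by = 10),
                                  replicates = 3L,
                                  force_base = 2,
                                  force_per_tip_deg = 0.5,
                                  force_angle_slope = 0.3,
                                  max_angle_base = 5,
                                  max_angle_per_curv_deg = 0.3,
                                  trace_template = trace_gen_params()) {
  if (any(angle_grid %% 10 != 0)) {
    stopf("`angle_grid` must contain multiples of 10 degrees")
  }
  if (!setequal(angle_grid, -angle_grid)) {
    stopf("`angle_grid` must be symmetric about 0")
  }
  if (replicates < 1L) stopf("`replicates` must be >= 1")
  stopifnot(inherits(trace_template, "trace_gen_params"))
  structure(list(angle_grid = sort(unique(angle_grid)),
                 replicates = as.integer(replicates),
                 force_base = force_base,
                 force_per_tip_deg = force_per_tip_deg,
                 force_angle_slope = force_angle_slope,
                 max_angle_base = max_angle_base,
                 max_angle_per_curv_deg = max_angle_per_curv_deg,
                 trace_template = trace_template),
            class = "experiment_gen_params")
}

#' Simulate a full serial-angle puncture experiment
#'
#' Generates one force trace per spine x angle x replicate. Successful
#' trials (|angle| within the spine's maximum puncture angle) embed a drop
#' at the angle-dependent required force; failed trials are plain ramps.
#' Ground truth per spine records the maximum puncture angle, the
#' 0-degree force and the true puncture range on the grid.
#'
#' @param spines list of [spine_gen_params()] objects (the shape parameters
#'   feed the success model; no profiles are built). Names are used as spine
#'   ids, or ids `S1`, `S2`, ... are assigned.
#' @param params an [experiment_gen_params()] object.
#' @param seed integer seed; per-trial noise seeds are derived from it.
#' @return list of class `trial_table` with `trials` (data frame: spine_id,
#'   angle_deg, replicate, success_true, force_true), `traces` (list of
#'   [force_trace()] in row order of `trials`) and `ground_truth` (data
#'   frame per spine: tip_angle, structural_curvature, max_puncture_angle,
#'   force_at_zero, true_range).
#' @export
simulate_experiment <- function(spines, params = experiment_gen_params(),
                                seed = 1L) {
  if (length(spines) == 0L) stopf("`spines` must contain at least one spine")
  stopifnot(all(vapply(spines, inherits, logical(1), "spine_gen_params")))
  stopifnot(inherits(params, "experiment_gen_params"))
  ids <- names(spines)
  if (is.null(ids)) ids <- sprintf("S%d", seq_along(spines))
  grid <- params$angle_grid
  gstep <- min(diff(sort(unique(abs(grid)))))
  gt <- data.frame(
    spine_id = ids,
    tip_angle = vapply(spines, `[[`, numeric(1), "tip_angle"),
    structural_curvature = vapply(spines, `[[`, numeric(1),
                                  "structural_curvature"),
    stringsAsFactors = FALSE
  )
  gt$max_puncture_angle <- params$max_angle_base +
    params$max_angle_per_curv_deg * gt$structural_curvature
  gt$force_at_zero <- params$force_base +
    params$force_per_tip_deg * gt$tip_angle
  pos <- sort(unique(abs(grid)))
  gt$true_range <- vapply(gt$max_puncture_angle, function(ma) {
    reach <- pos[pos <= ma]
    if (length(reach) == 0L) return(NA_real_)  # not even 0 degrees
    2 * max(reach)
  }, numeric(1))

  trials <- expand.grid(replicate = seq_len(params$replicates),
                        angle_deg = grid, spine_id = ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trials <- trials[, c("spine_id", "angle_deg", "replicate")]
  rownames(trials) <- NULL
  gti <- match(trials$spine_id, gt$spine_id)
  trials$success_true <- abs(trials$angle_deg) <= gt$max_puncture_angle[gti]
  trials$force_true <- ifelse(
    trials$success_true,
    gt$force_at_zero[gti] + params$force_angle_slope * abs(trials$angle_deg),
    NA_real_)

  tmpl <- params$trace_template
  traces <- vector("list", nrow(trials))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      nrow(trials)))
  for (i in seq_len(nrow(trials))) {
    tp <- tmpl
    tp$seed <- seeds[i]
    tp$puncture_force <- if (trials$success_true[i]) trials$force_true[i] else NA
    md <- list(spine_id = trials$spine_id[i],
               angle_deg = trials$angle_deg[i],
               replicate = trials$replicate[i])
    traces[[i]] <- simulate_force_trace(tp, md)$trace
  }
  structure(list(trials = trials, traces = traces, ground_truth = gt,
                 grid_step = gstep),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("trial table: %d spines x %d angles x %d replicates (%d traces)\n",
              nrow(x$ground_truth), length(unique(x$trials$angle_deg)),
              max(x$trials$replicate), nrow(x$trials)))
  invisible(x)
}

#' Write / read a force trace as CSV
#'
#' Plain-text interchange mirroring instrument CSV exports: two columns
#' `displacement_mm` and `force_N`.
#'
#' @param trace a [force_trace()].
#' @param path file path.
#' @return `write_force_trace` returns `path` invisibly.
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(data.frame(displacement_mm = trace$displacement,
                              force_N = trace$force),
                   path, row.names = FALSE)
  invisible(path)
}
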