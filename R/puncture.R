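# Puncture-event extraction from force-displacement traces and per-spine
# performance summaries from serial-angle compression tests.

#' Read a force trace from CSV
#'
#' Reads an instrument-style CSV export with displacement and force columns.
#' Column names are resolved through a configurable header map, with a
#' fuzzy fallback (any column containing "disp" / "force", case
#' insensitive). A units row directly under the header (non-numeric, e.g.
#' "mm,N") is skipped. Non-monotone displacement is an error unless
#' `repair = TRUE`, in which case rows are stably sorted by displacement.
#'
#' @param path CSV file path.
#' @param header_map named character vector mapping trace fields to column
#'   names, e.g. `c(displacement = "displacement_mm", force = "force_N")`.
#' @param metadata metadata list attached to the trace.
#' @param repair sort rows by displacement instead of failing on
#'   non-monotone input.
#' @return a [force_trace()].
#' @export
read_force_trace <- function(path,
                             header_map = c(displacement = "displacement_mm",
                                            force = "force_N"),
                             metadata = list(), repair = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("empty trace file '%s'", path)
  find_col <- function(field, pattern) {
    nm <- header_map[[field]]
    if (!is.null(nm) && nm %in% names(df)) return(nm)
    hitn <- grep(pattern, names(df), ignore.case = TRUE, value = TRUE)
    if (length(hitn) >= 1L) return(hitn[[1L]])
    stopf("no %s column found in '%s' (columns: %s)", field, path,
          paste(names(df), collapse = ", "))
  }
  dc <- find_col("displacement", "disp")
  fc <- find_col("force", "force|load")
  # units row: first row non-numeric in either column
  if (is.na(suppressWarnings(as.numeric(df[[dc]][1L]))) ||
      is.na(suppressWarnings(as.numeric(df[[fc]][1L])))) {
    df <- df[-1L, , drop = FALSE]
  }
  d <- suppressWarnings(as.numeric(df[[dc]]))
  f <- suppressWarnings(as.numeric(df[[fc]]))
  if (anyNA(d) || anyNA(f)) {
    stopf("non-numeric rows in trace file '%s'", path)
  }
  if (is.unsorted(d)) {
    if (!repair) {
      stopf("displacement is not monotone nondecreasing in '%s'; pass repair = TRUE to sort", path)
    }
    o <- order(d)   # stable
    d <- d[o]; f <- f[o]
  }
  force_trace(d, f, metadata)
}

#' Detect puncture events in a force trace
#'
#' Puncture shows as a sharp drop in the force-displacement curve. After
#' optional moving-median smoothing, the smoothed trace is scanned for local
#' maxima followed by a force decrease of at least
#' `max(min_drop_abs, min_drop_fraction * peak)` completed within
#' `max_drop_width` of displacement. The reported peak force is the
#' unsmoothed maximum within the smoothing window around the detected peak.
#'
#' @param trace a [force_trace()] with at least 10 samples.
#' @param min_drop_fraction minimum drop as a fraction of the peak force.
#' @param min_drop_abs minimum absolute drop, N.
#' @param max_drop_width maximum displacement over which the drop must
#'   complete, mm.
#' @param smooth_window moving-median window, samples (odd; 1 disables
#'   smoothing).
#' @return data frame of events ordered by displacement with columns
#'   `peak_force`, `peak_displacement`, `drop_magnitude`, `drop_fraction`,
#'   `drop_width`; zero rows when no puncture occurred.
#' @export
detect_puncture <- function(trace, min_drop_fraction = 0.10,
                            min_drop_abs = 0.5, max_drop_width = 0.2,
                            smooth_window = 5L) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$force)
  if (n < 10L) stopf("trace has fewer than 10 samples")
  d <- trace$displacement
  f <- trace$force
  sm <- if (smooth_window > 1L) {
    stats::runmed(f, k = smooth_window + (1L - smooth_window %% 2L),
                  endrule = "median")
  } else f
  events <- list()
  i <- 2L
  half_w <- smooth_window %/% 2L
  while (i < n) {
    if (sm[i] >= sm[i - 1L] && sm[i] > sm[i + 1L]) {
      # candidate local maximum; look ahead within the drop window
      jmax <- i
      while (jmax < n && d[jmax + 1L] - d[i] <= max_drop_width) {
        jmax <- jmax + 1L
      }
      ahead <- sm[(i + 1L):jmax]
      j_min <- i + which.min(ahead)
      # the peak is the highest smoothed point before the trough (a noise
      # shoulder can form a local maximum a few samples early)
      i_pk <- i - 1L + which.max(sm[i:j_min])
      drop <- sm[i_pk] - sm[j_min]
      thr <- max(min_drop_abs, min_drop_fraction * sm[i_pk])
      # a genuine puncture drop is sustained (force resumes from the
      # dropped level); transient noise dips recover immediately
      sustain <- stats::median(sm[j_min:min(n, j_min + 2L * smooth_window)])
      if (drop >= thr && sm[i_pk] - sustain >= thr) {
        lo <- max(1L, i_pk - half_w); hi <- min(n, i_pk + half_w)
        pk <- lo - 1L + which.max(f[lo:hi])
        events[[length(events) + 1L]] <- data.frame(
          peak_force = f[pk],
          peak_displacement = d[pk],
          drop_magnitude = drop,
          drop_fraction = drop / sm[i_pk],
          drop_width = d[j_min] - d[i_pk]
        )
        i <- j_min   # resume after the trough
      }
    }
    i <- i + 1L
  }
  if (length(events) == 0L) {
    return(data.frame(peak_force = numeric(0), peak_displacement = numeric(0),
                      drop_magnitude = numeric(0), drop_fraction = numeric(0),
                      drop_width = numeric(0)))
  }
  do.call(rbind, events)
}

#' Score a single trial
#'
#' A trial is a success iff at least one puncture event is detected; the
#' trial's puncture force is the peak force of the first event.
#'
#' @param trace a [force_trace()] with metadata (`spine_id`, `angle_deg`,
#'   `replicate`).
#' @param ... passed to [detect_puncture()].
#' @return one-row data frame: `spine_id`, `angle_deg`, `replicate`,
#'   `success`, `puncture_force` (`NA` unless successful).
#' @export
score_trial <- function(trace, ...) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- detect_puncture(trace, ...)
  md <- trace$metadata
  data.frame(
    spine_id = md$spine_id %||% NA_character_,
    angle_deg = md$angle_deg %||% NA_real_,
    replicate = md$replicate %||% NA_integer_,
    success = nrow(ev) > 0L,
    puncture_force = if (nrow(ev) > 0L) ev$peak_force[1L] else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Aggregate replicate trials at one spine and angle
#'
#' An angle counts as successful if at least one replicate punctured
#' (`rule = "any"`, the default) or if more than half did
#' (`rule = "majority"`). The mean force averages successful replicates
#' only.
#'
#' @param records data frame of trial records (from [score_trial()]) for
#'   one spine and angle, 1 or more rows.
#' @param rule replicate-disagreement rule.
#' @return one-row data frame: `success`, `mean_force`, `min_force`,
#'   `n_success`, `n_trials`, `replicates_disagree`.
#' @export
aggregate_angle <- function(records, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (nrow(records) == 0L) stopf("no trials to aggregate")
  ns <- sum(records$success)
  succ <- if (rule == "any") ns >= 1L else ns > nrow(records) / 2
  forces <- records$puncture_force[records$success]
  data.frame(
    success = succ,
    mean_force = if (succ && ns > 0L) mean(forces) else NA_real_,
    min_force = if (succ && ns > 0L) min(forces) else NA_real_,
    n_success = ns,
    n_trials = nrow(records),
    replicates_disagree = ns > 0L && ns < nrow(records)
  )
}

#' Summarise puncture performance of one spine
#'
#' The puncture range is the span of test angles at which the spine
#' achieved puncture (max minus min successful angle; 0 when at most one
#' angle succeeded). The lowest force is the minimum over all successful
#' replicate trials; the average force is the mean of the per-angle mean
#' forces over successful angles (per-angle replicate means first, then
#' across angles).
#'
#' @param per_angle data frame with one row per tested angle: `angle_deg`
#'   plus the columns of [aggregate_angle()].
#' @param grid_step angle grid step, degrees (metadata; default 10).
#' @return one-row data frame: `puncture_range`, `lowest_force`,
#'   `average_force`, `n_success_angles`.
#' @export
summarize_performance <- function(per_angle, grid_step = 10) {
  ok <- per_angle$success
  ns <- sum(ok)
  rng <- if (ns >= 2L) {
    max(per_angle$angle_deg[ok]) - min(per_angle$angle_deg[ok])
  } else 0
  data.frame(
    puncture_range = rng,
    lowest_force = if (ns > 0L) min(per_angle$min_force[ok]) else NA_real_,
    average_force = if (ns > 0L) mean(per_angle$mean_force[ok]) else NA_real_,
    n_success_angles = ns
  )
}

#' Performance table for a whole experiment
#'
#' Runs detection, trial scoring, per-angle aggregation and per-spine
#' summaries over a full trial table, producing one row per spine with the
#' standard performance columns (puncture range, lowest force, average
#' force). Spines flagged broken are retained in the output with
#' `broken = TRUE` so downstream analyses can exclude them.
#'
#' @param trials either a `trial_table` from [simulate_experiment()] or a
#'   data frame of trial records as returned by [score_trial()].
#' @param broken character vector of spine ids flagged broken during
#'   testing.
#' @param rule replicate-disagreement rule, see [aggregate_angle()].
#' @param grid_step angle grid step in degrees; taken from the trial table
#'   when available.
#' @param ... passed to [detect_puncture()] when raw traces are supplied.
#' @return data frame with one row per spine: `spine_id`,
#'   `puncture_range`, `lowest_force`, `average_force`,
#'   `n_success_angles`, `broken`.
#' @export
performance_table <- function(trials, broken = character(),
                              rule = "any", grid_step = 10, ...) {
  if (inherits(trials, "trial_table")) {
    grid_step <- trials$grid_step
    recs <- do.call(rbind, lapply(trials$traces, score_trial, ...))
  } else {
    recs <- trials
    need <- c("spine_id", "angle_deg", "replicate", "success",
              "puncture_force")
    if (!all(need %in% names(recs))) {
      stopf("trial records must have columns %s", paste(need, collapse = ", "))
    }
  }
  if (anyNA(recs$spine_id) || anyNA(recs$angle_deg)) {
    stopf("inconsistent trial metadata: missing spine_id or angle_deg")
  }
  out <- lapply(split(recs, recs$spine_id), function(rs) {
    per_angle <- do.call(rbind, lapply(split(rs, rs$angle_deg), function(ra) {
      cbind(angle_deg = ra$angle_deg[1L], aggregate_angle(ra, rule = rule))
    }))
    cbind(spine_id = rs$spine_id[1L],
          summarize_performance(per_angle, grid_step = grid_step))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$broken <- out$spine_id %in% broken
  out[order(match(out$spine_id, unique(recs$spine_id))), , drop = FALSE]
}
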