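make_trace_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("trace CSV dialects are handled", {
  p1 <- make_trace_csv(data.frame(displacement_mm = seq(0, 1, 0.1),
                                  force_N = seq(0, 10, 1)))
  tr <- read_force_trace(p1)
  expect_length(tr$force, 11L)

  # units row under the header
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("displacement_mm,force_N", "mm,N",
               paste(seq(0, 1, 0.1), seq(0, 10, 1), sep = ",")), p2)
  tr2 <- read_force_trace(p2)
  expect_length(tr2$force, 11L)
  expect_equal(tr2$force, tr$force)

  # fuzzy header resolution for instrument-style exports
  p3 <- make_trace_csv(data.frame(Displacement..mm. = seq(0, 1, 0.1),
                                  Load..N. = seq(0, 10, 1)))
  expect_length(read_force_trace(p3)$force, 11L)

  p4 <- make_trace_csv(data.frame(time_s = 1:5, volts = 1:5))
  expect_error(read_force_trace(p4), "displacement")
})

test_that("non-monotone displacement errors unless repair is requested", {
  p <- make_trace_csv(data.frame(displacement_mm = c(0, 0.2, 0.1, 0.3),
                                 force_N = c(0, 2, 1, 3)))
  expect_error(read_force_trace(p), "monotone")
  tr <- read_force_trace(p, repair = TRUE)
  expect_false(is.unsorted(tr$displacement))
})

test_that("a constructed instantaneous drop is detected exactly", {
  d <- seq(0, 6, by = 0.01)
  f <- 20 * (d / 3)^1.5
  f[d > 3] <- 12 * (d[d > 3] / 3)^1.5
  tr <- force_trace(d, f)
  ev <- detect_puncture(tr)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$peak_force, 20, tolerance = 1e-9)
  expect_equal(ev$drop_fraction, 0.4, tolerance = 0.05)
  expect_lt(ev$drop_width, 0.2)
})

test_that("monotone ramps produce no events", {
  st <- simulate_force_trace(trace_gen_params(puncture_force = NA,
                                              noise_sd = 0))
  expect_identical(nrow(detect_puncture(st$trace)), 0L)
})

test_that("events are invariant to baseline offset and re-smoothing", {
  st <- simulate_force_trace(trace_gen_params(puncture_force = 18,
                                              noise_sd = 0.15, seed = 3))
  ev <- detect_puncture(st$trace)
  # baseline subtraction
  tr_off <- force_trace(st$trace$displacement, st$trace$force - 1.0)
  ev_off <- detect_puncture(tr_off)
  expect_identical(nrow(ev_off), nrow(ev))
  expect_equal(ev_off$peak_displacement, ev$peak_displacement)
  expect_equal(ev_off$peak_force, ev$peak_force - 1.0, tolerance = 1e-9)
  # detecting on an already median-smoothed trace finds the same event
  sm <- stats::runmed(st$trace$force, 5, endrule = "median")
  ev_sm <- detect_puncture(force_trace(st$trace$displacement, sm))
  expect_identical(nrow(ev_sm), 1L)
  expect_equal(ev_sm$peak_displacement, ev$peak_displacement,
               tolerance = 0.05)
})

test_that("trials with multiple drops score the first event", {
  d <- seq(0, 6, by = 0.01)
  f <- 10 * (d / 2)^1.5
  f[d > 2] <- 6 * (d[d > 2] / 2)^1.5
  f[d > 4.5] <- 0.5 * f[d > 4.5]
  tr <- force_trace(d, f, list(spine_id = "A", angle_deg = 0, replicate = 1L))
  rec <- score_trial(tr)
  expect_true(rec$success)
  # first-event convention: 10 N, not the whole-trace maximum afterwards
  expect_equal(rec$puncture_force, 10, tolerance = 1e-6)
  expect_gt(max(tr$force[tr$displacement > 2 & tr$displacement < 4.5]), 10)
})

test_that("replicate aggregation follows the chosen rule", {
  recs <- data.frame(success = c(TRUE, TRUE, TRUE),
                     puncture_force = c(10, 12, 14))
  expect_equal(aggregate_angle(recs)$mean_force, 12)
  one <- data.frame(success = c(TRUE, FALSE, FALSE),
                    puncture_force = c(10, NA, NA))
  expect_true(aggregate_angle(one, rule = "any")$success)
  expect_equal(aggregate_angle(one, rule = "any")$mean_force, 10)
  expect_false(aggregate_angle(one, rule = "majority")$success)
  expect_error(aggregate_angle(one[0, ]), "no trials")
})

test_that("performance summaries follow the range and averaging conventions", {
  pa <- data.frame(angle_deg = c(-20, -10, 0, 10, 20, 30),
                   success = TRUE,
                   mean_force = c(5, 4.5, 4, 4.2, 4.8, 5.5),
                   min_force = c(4.8, 4.2, 3.9, 4.0, 4.6, 5.2))
  sp <- summarize_performance(pa)
  expect_equal(sp$puncture_range, 50)
  expect_equal(sp$lowest_force, 3.9)
  expect_equal(sp$average_force, mean(pa$mean_force))

  none <- data.frame(angle_deg = c(-10, 0, 10), success = FALSE,
                     mean_force = NA_real_, min_force = NA_real_)
  sn <- summarize_performance(none)
  expect_equal(sn$puncture_range, 0)
  expect_true(is.na(sn$lowest_force) && is.na(sn$average_force))

  three <- data.frame(angle_deg = c(-10, 0, 10), success = TRUE,
                      mean_force = c(4.0, 4.5, 4.5),
                      min_force = c(4, 4, 4))
  expect_equal(summarize_performance(three)$average_force, 13 / 3)
})

test_that("puncture range is monotone in added successful angles", {
  angles <- seq(-30, 30, 10)
  rng <- numeric(0)
  for (k in seq_along(angles)) {
    pa <- data.frame(angle_deg = angles[seq_len(k)], success = TRUE,
                     mean_force = 5, min_force = 5)
    rng <- c(rng, summarize_performance(pa)$puncture_range)
  }
  expect_true(all(diff(rng) >= 0))
})

test_that("per-angle force bounds hold for random trial tables", {
  set.seed(42)
  for (rep in 1:20) {
    n_ang <- sample(3:7, 1)
    pa <- data.frame(angle_deg = seq(-10 * (n_ang - 1) / 2 * 2,
                                     by = 10, length.out = n_ang),
                     success = sample(c(TRUE, FALSE), n_ang, TRUE,
                                      prob = c(0.8, 0.2)),
                     mean_force = runif(n_ang, 3, 50))
    pa$min_force <- pa$mean_force - runif(n_ang, 0, 2)
    if (!any(pa$success)) pa$success[1] <- TRUE
    sp <- summarize_performance(pa)
    ok <- pa$success
    expect_lte(sp$lowest_force, min(pa$mean_force[ok]))
    expect_gte(sp$average_force, min(pa$mean_force[ok]))
    expect_lte(sp$average_force, max(pa$mean_force[ok]))
  }
})

test_that("performance_table reproduces simulator ground truth and flags broken spines", {
  spines <- list(
    A = spine_gen_params(tip_angle = 30, structural_curvature = 10),
    B = spine_gen_params(tip_angle = 50, structural_curvature = 60),
    C = spine_gen_params(tip_angle = 70, structural_curvature = 110)
  )
  tt <- simulate_experiment(
    spines,
    experiment_gen_params(trace_template = trace_gen_params(
      noise_sd = 0.2, sample_spacing = 0.02)),
    seed = 5
  )
  pt <- performance_table(tt, broken = "B")
  expect_equal(pt$puncture_range, tt$ground_truth$true_range)
  expect_identical(pt$broken, c(FALSE, TRUE, FALSE))

  # single spine, single angle
  one <- data.frame(spine_id = "X", angle_deg = 0, replicate = 1L,
                    success = TRUE, puncture_force = 7)
  p1 <- performance_table(one)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$puncture_range, 0)
})
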