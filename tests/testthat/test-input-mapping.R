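test_that("robust slope estimation recovers known mixing scales", {
  set.seed(1)
  T_ <- 2000
  dend <- dendromap:::transient_trace(T_, 0.03, 10, 60)
  inp <- dendromap:::transient_trace(T_, 0.02, 10, 60)
  spine <- inp + 0.6 * dend + rnorm(T_, 0, 0.05 * max(dend))
  m <- estimate_bap_scale(spine, dend)
  expect_gte(m$slope_fit, 0.54)
  expect_lte(m$slope_fit, 0.66)
  expect_gte(m$n_active_frames, 10)

  # perfect mixing, no noise
  m1 <- estimate_bap_scale(1.0 * dend, dend)
  expect_equal(m1$slope_fit, 1, tolerance = 1e-6)

  # statistical independence gives a near-zero slope
  slopes <- vapply(1:30, function(s) {
    set.seed(s)
    d2 <- dendromap:::transient_trace(T_, 0.03, 10, 60)
    ind <- dendromap:::transient_trace(T_, 0.02, 10, 60) + rnorm(T_, 0, 1)
    estimate_bap_scale(ind, d2)$slope_fit
  }, numeric(1))
  expect_lt(stats::median(abs(slopes)), 0.05)

  expect_error(estimate_bap_scale(spine, rep(1, T_)), "constant")
  expect_error(estimate_bap_scale(spine, dend, active_quantile = 0.9999),
               "active frames")
})

test_that("no-negative-deflection refinement matches a grid search", {
  set.seed(2)
  T_ <- 1500
  dend <- dendromap:::transient_trace(T_, 0.03, 10, 60)
  inp <- dendromap:::transient_trace(T_, 0.02, 10, 60)
  spine <- inp + 0.6 * dend
  tol <- 0.5
  su <- refine_scale_no_negative(spine, dend, 0.6, noise_tol = tol,
                                 smooth_win = 1L)
  expect_gte(su, 0.6)
  expect_gte(min(spine - su * dend), -tol)
  # grid oracle at 1e-4 steps
  grid <- seq(0, 1.2, by = 1e-4)
  feas <- vapply(grid, function(a) min(spine - a * dend) >= -tol,
                 logical(1))
  expect_equal(su, max(grid[feas]), tolerance = 2e-4)

  # all-zero dendrite: any scale feasible, subtraction is a no-op
  expect_equal(refine_scale_no_negative(spine, numeric(T_), 0.6,
                                        noise_tol = tol), 1.2)
  expect_equal(subtract_bap(spine, numeric(T_), 1.2), spine)
})

test_that("batch bAP removal recovers input traces across a spine population", {
  set.seed(3)
  T_ <- 2000
  dend <- dendromap:::transient_trace(T_, 0.03, 10, 60)
  n <- 20
  scales <- runif(n, 0.2, 1.5)
  traces <- matrix(0, n + 1, T_)
  inputs <- matrix(0, n, T_)
  for (i in 1:n) {
    inputs[i, ] <- dendromap:::transient_trace(T_, 0.02, 10, 60)
    # moderate sensor noise: 10% of a unit event amplitude
    traces[i, ] <- inputs[i, ] + scales[i] * dend + rnorm(T_, 0, 6)
  }
  traces[n + 1, ] <- dend
  ts <- structure(list(traces = traces, roi_ids = c(1:n, 1L),
                       kind = c(rep("spine", n), "dendrite"),
                       parent_dendrite = c(rep(1L, n), 1L),
                       frame_clock = seq_len(T_)),
                  class = "TraceSet")
  out <- remove_bap(ts)
  used <- vapply(out$models[1:n], `[[`, numeric(1), "slope_used")
  rel_err <- abs(used - scales) / scales
  expect_lte(stats::median(rel_err), 0.15)
  cors <- vapply(1:n, function(i)
    stats::cor(out$trace_set$traces[i, ], inputs[i, ]), numeric(1))
  expect_gte(stats::median(cors), 0.9)
  sm <- function(x) {
    v <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
    v[!is.na(v)]
  }
  for (i in 1:n) {
    tol <- 3 * stats::mad(diff(traces[i, ])) / sqrt(2) / sqrt(5)
    floor_val <- min(0, min(sm(traces[i, ]))) - tol
    expect_gte(min(sm(out$trace_set$traces[i, ])), floor_val - 1e-9)
  }
  # slope 0 leaves the trace untouched
  expect_equal(subtract_bap(traces[1, ], dend, 0), traces[1, ])
})

test_that("stimulus responses score epochs against the preceding gray", {
  st <- make_stimulus_table(list(n_directions = 8L, repeats = 5L), seed = 1)
  T_ <- length(st$framestamp)
  flat <- structure(list(traces = matrix(2, 1, T_), roi_ids = 1L,
                         kind = "spine", parent_dendrite = NA_integer_,
                         frame_clock = seq_len(T_)), class = "TraceSet")
  resp <- stimulus_responses(flat, st)
  expect_equal(nrow(resp), 40)
  expect_true(all(resp == 0))
  expect_equal(sort(unique(attr(resp, "direction"))), 1:8)
})

test_that("tuning fits recover generator parameters through the movie pipeline", {
  st <- make_stimulus_table(list(n_directions = 8L, repeats = 5L,
                                 stim_frames = 60L, gray_frames = 90L),
                            seed = 1)
  tun <- list(theta_pref = c(90, 200), a1 = c(1, 1.2), a2 = c(0.5, 0.3),
              sigma = c(25, 30), baseline = c(0, 0))
  g <- make_dendrite_movie(list(n_frames = length(st$framestamp),
                                n_spines = 2L, stimulus = st, tuning = tun,
                                tuning_noise_sd = 0.05, event_rate = 0,
                                bap_rate = 0), seed = 2)
  fmap <- feature_map(spines = lapply(1:2, function(i)
    dendromap:::spine_roi(i, g$truth$spine_masks[[i]])),
    image_dim = dim(g$stack$data)[2:3])
  ts <- extract_traces(g$stack, fmap)
  resp <- stimulus_responses(ts, st)
  deg <- codes_to_degrees(attr(resp, "direction"), 8)
  for (i in 1:2) {
    fit <- fit_two_peak_gaussian(deg, resp[, i])
    expect_lt(abs(dendromap:::ang_diff(fit$params$theta_pref,
                                       tun$theta_pref[i])), 5)
    expect_lt(abs(fit$params$sigma - tun$sigma[i]), 5)
    expect_lte(fit$residual, fit$residual_flat)
    expect_gte(fit$params$a1, fit$params$a2)
  }
})

test_that("tuning fit degenerates gracefully and is shift-equivariant", {
  th <- rep(codes_to_degrees(1:8, 8), each = 5)
  flat <- fit_two_peak_gaussian(th, rep(1.5, 40))
  expect_lt(flat$params$a1, 1e-4)
  expect_lt(flat$params$a2, 1e-4)
  expect_equal(flat$residual, flat$residual_flat, tolerance = 1e-12)

  y <- dendromap:::two_peak_gaussian(th, 0.1, 1, 0.4, 45, 30)
  f0 <- fit_two_peak_gaussian(th, y)
  f90 <- fit_two_peak_gaussian((th + 90) %% 360, y)
  expect_equal(dendromap:::ang_diff(f90$params$theta_pref,
                                    f0$params$theta_pref + 90), 0,
               tolerance = 0.5)
  expect_error(fit_two_peak_gaussian(c(0, 90, 180), c(1, 2, 1)),
               "distinct directions")
})

test_that("event-triggered averages find locked transients and group by trial type", {
  st <- make_stimulus_table(list(type = "locomotion", n_trials = 10L,
                                 sample_rate_factor = 2), seed = 3)
  fs <- st$framestamp
  T_ <- length(fs)
  sp <- st$stampinfo$speed; tt <- st$stampinfo$time_s
  up <- which(sp[-1] > 0.5 & sp[-length(sp)] <= 0.5) + 1
  onsets_t <- tt[up][c(TRUE, diff(tt[up]) > 4)]
  ev <- numeric(T_)
  for (ot in onsets_t) ev[which.min(abs(fs - (ot + 0.3)))] <- 1
  trace <- dendromap:::decay_filter(ev, 10)
  eta <- event_triggered_average(trace, fs, st, "speed", 0.5)
  expect_false(eta$empty)
  expect_equal(range(eta$time_axis), c(-2, 2), tolerance = 0.05)
  peak_lat <- eta$time_axis[which.max(eta$groups[["all"]]$mean)]
  expect_gt(peak_lat, 0)
  expect_lt(peak_lat, 0.6)

  grouped <- event_triggered_average(trace, fs, st, "speed", 0.5,
                                     group_column = "trial_type")
  expect_setequal(names(grouped$groups), c("open", "closed"))
  # identical trigger-locked responses: group means agree within sem
  gm <- grouped$groups
  band <- 3 * sqrt(gm$open$sem^2 + gm$closed$sem^2)
  expect_true(all(abs(gm$open$mean - gm$closed$mean) <=
                    band + 1e-9, na.rm = TRUE))

  none <- event_triggered_average(trace, fs, st, "speed", 1e6)
  expect_true(none$empty)
})

test_that("a speed step produces a single trigger with the documented window", {
  info <- data.frame(time_s = seq(0, 20, by = 1 / 30))
  info$speed <- ifelse(info$time_s >= 10, 1, 0)
  stim <- structure(list(framestamp = info$time_s, stampinfo = info,
                         unit = "seconds"), class = "StimulusTable")
  trace <- sin(info$time_s)
  eta <- event_triggered_average(trace, info$time_s, stim, "speed", 0.5,
                                 pre_s = 2, post_s = 2)
  expect_length(eta$events, 1)
  expect_equal(eta$events, 10, tolerance = 0.05)
  expect_equal(eta$groups[["all"]]$mean,
               sin(10 + eta$time_axis), tolerance = 1e-6)
})
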