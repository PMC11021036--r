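#' Estimate the bAP mixing scale of one spine
#'
#' A spine trace is modeled as input-specific signal plus a linearly
#' scaled copy of the global back-propagating action potential (bAP)
#' signal carried by the dendritic shaft. In a scatter of spine against
#' dendrite values, frames where the shaft is active form the diagonal
#' cloud; that cloud is selected as the frames where the dendrite trace
#' exceeds its `active_quantile`, and the scale is the slope of a robust
#' (iteratively reweighted, bisquare) regression of spine on dendrite over
#' those frames, floored at 0.
#'
#' @param spine_trace,dendrite_trace equal-length numeric traces (a.u.).
#' @param active_quantile quantile of the dendrite trace above which a
#'   frame counts as dendrite-active (default 0.75).
#' @return A `BapModel`: list with `slope_fit`, `slope_used` (initialized
#'   to `slope_fit`; see [refine_scale_no_negative()]),
#'   `active_frame_mask`, `n_active_frames`.
#' @export
estimate_bap_scale <- function(spine_trace, dendrite_trace,
                               active_quantile = 0.75) {
  if (length(spine_trace) != length(dendrite_trace))
    stop("traces differ in length")
  if (stats::sd(dendrite_trace) == 0)
    stop("dendrite trace is constant")
  thr <- stats::quantile(dendrite_trace, active_quantile, names = FALSE)
  active <- dendrite_trace > thr
  if (sum(active) < 10)
    stop("fewer than 10 dendrite-active frames; lower active_quantile")
  # rlm warns about non-convergence on exactly collinear traces, where the
  # slope is nonetheless correct
  fit <- suppressWarnings(
    MASS::rlm(spine_trace[active] ~ dendrite_trace[active],
              psi = MASS::psi.bisquare, maxit = 50))
  slope <- max(0, unname(stats::coef(fit)[2]))
  structure(list(slope_fit = slope, slope_used = slope,
                 active_frame_mask = active,
                 n_active_frames = sum(active)),
            class = "BapModel")
}

#' Largest subtraction scale without negative deflections
#'
#' Refines a fitted bAP scale to the largest factor `alpha` in
#' `[0, slope_cap]` whose subtraction generates no negative deflections.
#' A deflection is a sustained dip, not a single noisy sample, so the
#' constraint is evaluated on a `smooth_win`-frame moving average of the
#' corrected trace: its minimum may not fall below
#' `min(-noise_tol, min(smoothed spine))` — the tolerance, or the
#' trace's own observed floor when noise excursions already exceed it.
#' The largest such scale avoids undersubtraction while the
#' no-negative-deflection constraint prevents oversubtraction; on
#' noiseless traces the rule reduces to the plain `-noise_tol` bound,
#' and `alpha = 0` is always feasible. Found by bisection to 1e-4.
#'
#' @param spine_trace,dendrite_trace equal-length traces.
#' @param slope_fit robust-fit slope (>= 0), see [estimate_bap_scale()].
#' @param noise_tol allowed negative excursion of the smoothed corrected
#'   trace; default 3 x the median-absolute-deviation noise estimate of
#'   the spine trace (`mad(diff(x)) / sqrt(2)`) divided by
#'   `sqrt(smooth_win)`.
#' @param slope_cap upper bound on the refined scale (default
#'   `2 * slope_fit`).
#' @param smooth_win moving-average window (frames) used when checking
#'   for deflections; 1 disables smoothing.
#' @return the refined scale `slope_used` (numeric scalar).
#' @export
refine_scale_no_negative <- function(spine_trace, dendrite_trace, slope_fit,
                                     noise_tol = NULL, slope_cap = NULL,
                                     smooth_win = 5L) {
  stopifnot(slope_fit >= 0)
  if (is.null(noise_tol))
    noise_tol <- 3 * stats::mad(diff(spine_trace)) / sqrt(2) /
      sqrt(smooth_win)
  if (is.null(slope_cap)) slope_cap <- 2 * slope_fit
  sm <- function(x) if (smooth_win > 1)
    as.numeric(stats::filter(x, rep(1 / smooth_win, smooth_win),
                             sides = 2)) else x
  sp_s <- sm(spine_trace); dd_s <- sm(dendrite_trace)
  ok <- !is.na(sp_s)
  sp_s <- sp_s[ok]; dd_s <- dd_s[ok]
  # allowed floor: -noise_tol, or the trace's own observed minimum when
  # noise excursions already exceed the tolerance
  floor_val <- min(-noise_tol, min(sp_s))
  feasible <- function(a) min(sp_s - a * dd_s) >= floor_val
  if (feasible(slope_cap)) return(slope_cap)
  if (!feasible(0)) return(0)
  lo <- 0; hi <- slope_cap
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Subtract a scaled dendrite trace from a spine trace
#' @param trace spine (or shaft-subregion) trace.
#' @param dendrite_trace shaft trace used as the bAP proxy.
#' @param slope_used subtraction scale.
#' @return the corrected trace.
#' @export
subtract_bap <- function(trace, dendrite_trace, slope_used) {
  if (length(trace) != length(dendrite_trace))
    stop("traces differ in length")
  trace - slope_used * dendrite_trace
}

#' Batch bAP removal over a trace set
#'
#' Applies [estimate_bap_scale()], [refine_scale_no_negative()] and
#' [subtract_bap()] to every spine and shaft-subregion trace belonging to
#' one long dendrite, using the dendrite trace as the bAP proxy. Can be
#' skipped entirely for indicators that carry no bAP signal (e.g.
#' glutamate sensors) by not calling it. Shaft subregions whose corrected
#' trace still exceeds `5 x` the noise estimate are flagged as exhibiting
#' nonlinear local events, and should not themselves be used as bAP
#' proxies.
#'
#' @param trace_set a `TraceSet` from [extract_traces()].
#' @param dendrite_id id of the dendrite ROI whose trace is the proxy.
#' @param active_quantile,noise_tol,slope_cap see the per-trace functions.
#' @return list with `trace_set` (corrected copy; dendrite traces
#'   untouched), `models` (per-ROI `BapModel` or `NULL`), and
#'   `nonlinear_flags` (logical per ROI; `TRUE` marks subregions with
#'   residual local events).
#' @export
remove_bap <- function(trace_set, dendrite_id = NULL,
                       active_quantile = 0.75, noise_tol = NULL,
                       slope_cap = NULL) {
  kinds <- trace_set$kind
  dend_rows <- which(kinds == "dendrite")
  if (!length(dend_rows)) stop("trace set holds no dendrite trace")
  if (is.null(dendrite_id)) dendrite_id <- trace_set$roi_ids[dend_rows[1]]
  drow <- dend_rows[trace_set$roi_ids[dend_rows] == dendrite_id][1]
  if (is.na(drow)) stop("no dendrite trace with id ", dendrite_id)
  dtr <- trace_set$traces[drow, ]
  out <- trace_set
  models <- vector("list", nrow(trace_set$traces))
  nonlin <- rep(FALSE, nrow(trace_set$traces))
  for (r in seq_len(nrow(trace_set$traces))) {
    if (kinds[r] == "dendrite") next
    if (!is.na(trace_set$parent_dendrite[r]) &&
        trace_set$parent_dendrite[r] != dendrite_id) next
    tr <- trace_set$traces[r, ]
    m <- estimate_bap_scale(tr, dtr, active_quantile)
    m$slope_used <- refine_scale_no_negative(tr, dtr, m$slope_fit,
                                             noise_tol = noise_tol,
                                             slope_cap = slope_cap)
    out$traces[r, ] <- subtract_bap(tr, dtr, m$slope_used)
    models[[r]] <- m
    sigma_hat <- stats::mad(diff(tr)) / sqrt(2)
    if (kinds[r] == "subregion")
      nonlin[r] <- max(out$traces[r, ]) > 5 * max(sigma_hat, 1e-12)
  }
  list(trace_set = out, models = models, nonlinear_flags = nonlin)
}

# ---- stimulus responses ---------------------------------------------------

#' Per-trial stimulus responses
#'
#' Resolves the stimulus table onto the trace frame clock (constant
#' interpolation when the stampinfo is sampled at a different rate),
#' splits the direction-code column into contiguous nonzero epochs, and
#' scores each epoch as mean trace during the epoch minus mean trace
#' during the immediately preceding gray (code 0) period.
#'
#' @param trace_set a `TraceSet`.
#' @param stimulus_table a `StimulusTable` whose parameter column holds
#'   direction codes (0 = gray).
#' @param param_column stampinfo column holding the codes (default 2).
#' @return matrix of responses indexed (trial, roi), with attributes
#'   `direction` (code per trial) and `epochs` (frame ranges).
#' @export
stimulus_responses <- function(trace_set, stimulus_table,
                               param_column = 2L) {
  T_ <- ncol(trace_set$traces)
  fs <- stimulus_table$framestamp
  info_t <- stimulus_table$stampinfo[[1]]
  codes_info <- stimulus_table$stampinfo[[param_column]]
  if (length(fs) != T_)
    warning("framestamp length (", length(fs),
            ") differs from trace length (", T_, "); using the overlap")
  n <- min(T_, length(fs))
  idx <- findInterval(fs[seq_len(n)], info_t)
  idx[idx < 1L] <- 1L
  codes <- codes_info[idx]
  r <- rle(codes != 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  stim_runs <- which(r$values)
  resp <- NULL; trial_dir <- c(); epochs <- list()
  dropped <- 0L
  for (k in stim_runs) {
    if (k == 1) { dropped <- dropped + 1L; next }  # no preceding gray
    ep <- starts[k]:ends[k]
    gray <- starts[k - 1]:ends[k - 1]
    m_ep <- rowMeans(trace_set$traces[, ep, drop = FALSE])
    m_gr <- rowMeans(trace_set$traces[, gray, drop = FALSE])
    resp <- rbind(resp, m_ep - m_gr)
    trial_dir <- c(trial_dir, codes[starts[k]])
    epochs[[length(epochs) + 1]] <- range(ep)
  }
  if (dropped > 0)
    warning(dropped, " stimulus epoch(s) without a preceding gray period ",
            "were dropped")
  attr(resp, "direction") <- trial_dir
  attr(resp, "epochs") <- epochs
  resp
}

#' Direction codes to degrees
#' @param codes integer codes `1..n_directions`.
#' @param n_directions number of directions in the schedule.
#' @return degrees: code k maps to `(k - 1) * 360 / n_directions`.
#' @export
codes_to_degrees <- function(codes, n_directions) {
  (codes - 1) * 360 / n_directions
}

# ---- constrained two-peak Gaussian tuning --------------------------------

# wrapped angular difference in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

two_peak_gaussian <- function(theta, b, a1, a2, theta_pref, sigma) {
  b + a1 * exp(-ang_diff(theta, theta_pref)^2 / (2 * sigma^2)) +
    a2 * exp(-ang_diff(theta, theta_pref + 180)^2 / (2 * sigma^2))
}

#' Fit a constrained two-peak Gaussian tuning curve
#'
#' Fits `R(theta) = b + A1 G(theta - theta_p) + A2 G(theta - theta_p -
#' 180)` with a shared width `sigma`, peaks locked 180 degrees apart and
#' nonnegative amplitudes — the standard direction-tuning model in which
#' `A1 >= A2` picks the preferred direction. Distances on the circle are
#' wrapped. Fitting is multi-start bounded least squares (L-BFGS-B;
#' starts at every observed direction plus a flat start, so the fit
#' residual never exceeds the constant-only model's).
#'
#' @param directions stimulus direction per observation, degrees.
#' @param responses response per observation (same length); multiple
#'   repeats per direction are expected.
#' @param sigma_bounds width bounds in degrees (default `(5, 90]`).
#' @return A `TuningFit`: list with `directions` (unique),
#'   `mean_response`, `sem_response`, `params` (`b`, `a1`, `a2`,
#'   `theta_pref` in `[0, 360)`, `sigma`), `r_squared`, `residual`,
#'   `residual_flat`, `osi`, `dsi`, and `fitted` (per unique direction).
#' @export
fit_two_peak_gaussian <- function(directions, responses,
                                  sigma_bounds = c(5, 90)) {
  stopifnot(length(directions) == length(responses),
            all(is.finite(responses)))
  ud <- sort(unique(directions))
  if (length(ud) < 4) stop("need at least 4 distinct directions")
  mu <- vapply(ud, function(d) mean(responses[directions == d]), numeric(1))
  sem <- vapply(ud, function(d) {
    x <- responses[directions == d]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }, numeric(1))
  y <- responses; th <- directions
  sse <- function(p) sum((y - two_peak_gaussian(th, p[1], p[2], p[3],
                                                p[4], p[5]))^2)
  lower <- c(-Inf, 0, 0, -360, sigma_bounds[1] + 1e-6)
  upper <- c(Inf, Inf, Inf, 720, sigma_bounds[2])
  b0 <- min(mu)
  starts <- lapply(ud, function(d0) {
    a1 <- max(mu[which.min(abs(ang_diff(ud, d0)))] - b0, 1e-3)
    a2 <- max(mu[which.min(abs(ang_diff(ud, d0 + 180)))] - b0, 1e-3)
    c(b0, a1, a2, d0, 30)
  })
  starts <- c(starts, list(c(mean(y), 0, 0, ud[which.max(mu)], 30)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  p <- best$par
  # convention: A1 is the taller peak, at theta_pref
  if (p[3] > p[2]) {
    p[c(2, 3)] <- p[c(3, 2)]
    p[4] <- p[4] + 180
  }
  p[4] <- p[4] %% 360
  residual <- best$value
  residual_flat <- sum((y - mean(y))^2)
  r2 <- if (residual_flat > 0) 1 - residual / residual_flat else 1
  pred <- function(t) two_peak_gaussian(t, p[1], p[2], p[3], p[4], p[5])
  rp <- pred(p[4]); ro <- pred(p[4] + 90); rn <- pred(p[4] + 180)
  osi <- if (rp + ro != 0) (rp - ro) / (rp + ro) else NA_real_
  dsi <- if (rp + rn != 0) (rp - rn) / (rp + rn) else NA_real_
  structure(list(directions = ud, mean_response = mu, sem_response = sem,
                 params = list(b = p[1], a1 = p[2], a2 = p[3],
                               theta_pref = p[4], sigma = p[5]),
                 r_squared = r2, residual = residual,
                 residual_flat = residual_flat, osi = osi, dsi = dsi,
                 fitted = pred(ud)),
            class = "TuningFit")
}

#' @export
print.TuningFit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "TuningFit: theta_pref %.1f deg, sigma %.1f deg, A1 %.3g, A2 %.3g, b %.3g (r^2 = %.3f)\n",
    p$theta_pref, p$sigma, p$a1, p$a2, p$b, x$r_squared))
  cat(sprintf("  OSI %.3f, DSI %.3f\n", x$osi, x$dsi))
  invisible(x)
}

#' Tuning curve with data points
#' @param x a `TuningFit`.
#' @param ... passed to `plot`.
#' @export
plot.TuningFit <- function(x, ...) {
  graphics::plot(x$directions, x$mean_response, pch = 16,
                 xlab = "direction (deg)", ylab = "response (a.u.)", ...)
  if (any(is.finite(x$sem_response)))
    graphics::arrows(x$directions, x$mean_response - x$sem_response,
                     x$directions, x$mean_response + x$sem_response,
                     angle = 90, code = 3, length = 0.03)
  tt <- seq(0, 360, by = 2)
  p <- x$params
  graphics::lines(tt, two_peak_gaussian(tt, p$b, p$a1, p$a2, p$theta_pref,
                                        p$sigma), col = "red")
  invisible(x)
}

# ---- event-triggered averages --------------------------------------------

#' Event-triggered average of a trace around parameter threshold crossings
#'
#' Triggers are upward (below-to-above) crossings of `threshold` in the
#' chosen stampinfo parameter column, thinned so accepted triggers are at
#' least `pre_s + post_s` apart. For every trigger, the trace is sampled
#' at the frame-clock resolution over `[-pre_s, +post_s]` (linear
#' interpolation against the framestamp) and snippets are averaged; when
#' `group_column` is given, triggers are partitioned by that column's
#' value at the trigger time (e.g., open- versus closed-loop trials) and
#' averaged per group.
#'
#' @param trace numeric trace on the frame clock.
#' @param framestamp time of each trace sample, seconds.
#' @param stimulus_table a `StimulusTable` stamped in seconds.
#' @param param_column index or name of the numeric parameter column.
#' @param threshold crossing threshold (same units as the parameter).
#' @param pre_s,post_s window half-lengths in seconds (> 0).
#' @param group_column optional index/name of a trial-type column.
#' @return An `EventTriggeredAverage`: list with `window`, `time_axis`,
#'   `groups` (per group: `mean`, `sem`, `n_events`), `events` (trigger
#'   times) and `empty` (`TRUE` when no trigger was found).
#' @export
event_triggered_average <- function(trace, framestamp, stimulus_table,
                                    param_column, threshold,
                                    pre_s = 2, post_s = 2,
                                    group_column = NULL) {
  stopifnot(pre_s > 0, post_s > 0)
  info <- stimulus_table$stampinfo
  tt <- info[[1]]
  x <- info[[param_column]]
  up <- which(x[-1] > threshold & x[-length(x)] <= threshold) + 1L
  ev <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (tt[i] - last >= pre_s + post_s) { ev <- c(ev, tt[i]); last <- tt[i] }
  }
  # windows must lie inside the trace span
  ev <- ev[ev - pre_s >= framestamp[1] &
           ev + post_s <= framestamp[length(framestamp)]]
  dt <- stats::median(diff(framestamp))
  time_axis <- seq(-pre_s, post_s, by = dt)
  if (!length(ev)) {
    return(structure(list(window = c(pre_s, post_s), time_axis = time_axis,
                          groups = list(), events = numeric(0),
                          empty = TRUE),
                     class = "EventTriggeredAverage"))
  }
  gval <- if (is.null(group_column)) rep("all", length(ev))
  else as.character(info[[group_column]][findInterval(ev, tt)])
  snips <- t(vapply(ev, function(t0)
    stats::approx(framestamp, trace, xout = t0 + time_axis, rule = 2)$y,
    numeric(length(time_axis))))
  groups <- list()
  for (g in unique(gval)) {
    s <- snips[gval == g, , drop = FALSE]
    groups[[g]] <- list(
      mean = colMeans(s),
      sem = if (nrow(s) > 1) apply(s, 2, stats::sd) / sqrt(nrow(s))
            else rep(NA_real_, ncol(s)),
      n_events = nrow(s))
  }
  structure(list(window = c(pre_s, post_s), time_axis = time_axis,
                 groups = groups, events = ev, empty = FALSE),
            class = "EventTriggeredAverage")
}

#' @export
print.EventTriggeredAverage <- function(x, ...) {
  if (x$empty) { cat("EventTriggeredAverage: no triggers\n"); return(invisible(x)) }
  cat(sprintf("EventTriggeredAverage: %d trigger(s), window [-%g, +%g] s\n",
              length(x$events), x$window[1], x$window[2]))
  for (g in names(x$groups))
    cat(sprintf("  group %s: n = %d\n", g, x$groups[[g]]$n_events))
  invisible(x)
}
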