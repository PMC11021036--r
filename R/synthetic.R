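#' Synthetic dendrite movies with ground truth
#'
#' Renders a movie of a sparse dendrite bearing spines, with the signal
#' structure the analysis pipeline assumes: every spine carries an
#' input-specific calcium transient plus a linearly scaled copy of a global
#' back-propagating action potential (bAP) transient that also drives the
#' dendritic shaft; frames undergo integer-pixel motion and sensor noise is
#' added on top. All randomness is controlled by `seed`, so two calls with
#' the same configuration and seed are bit-identical.
#'
#' Transients are Poisson event trains convolved with a single-exponential
#' decay kernel (time constant `tau` frames), a minimal model of GECI
#' kinetics. Spines have Gaussian intensity profiles; the dendrite is a
#' rectangular-profile band along a polyline. Motion is a clipped
#' integer-pixel random walk applied as a wrapped (circular) shift, so
#' un-shifting each frame by the known trajectory recovers the motionless
#' movie exactly.
#'
#' When a grating `stimulus` table and per-spine `tuning` parameters are
#' supplied, each spine additionally receives one event at every stimulus
#' onset whose amplitude follows its two-peak Gaussian tuning curve, so that
#' downstream tuning analysis can be validated against known parameters.
#'
#' @param config named list overriding any of the defaults returned by
#'   `movie_config()`.
#' @param seed integer seed controlling all randomness.
#'
#' @return A list with elements `stack` (a [tstack()] of the rendered movie)
#'   and `truth`, a `GroundTruth` list carrying: `spine_centroids` (n x 2,
#'   (row, col)), `spine_masks` (list of logical images), `dendrite_path`
#'   (polyline vertices), `dendrite_width`, `per_spine_input_trace` (n x T),
#'   `bap_trace` (length T), `bap_scale_per_spine`, `motion_trajectory`
#'   (T x 2, starting at (0, 0)), `tuning_params` (or `NULL`), and the
#'   motionless noiseless `clean_stack`.
#' @seealso [make_stimulus_table()], [make_point_cloud_pair()]
#' @export
make_dendrite_movie <- function(config = list(), seed = 1L) {
  cf <- utils::modifyList(movie_config(), config)
  stopifnot(cf$n_frames >= 200, cf$height >= 64, cf$width >= 64,
            cf$spine_sigma >= 0.5, cf$noise_sd >= 0)
  set.seed(seed)
  T_ <- cf$n_frames; H <- cf$height; W <- cf$width

  # dendrite: horizontal polyline with optional gentle slope
  margin <- ceiling(4 * cf$dendrite_width + 4)
  r0 <- round(H / 2)
  path <- rbind(c(r0, margin), c(r0 + cf$dendrite_slope * (W - 2 * margin),
                                 W - margin))
  usable <- path[2, 2] - path[1, 2]
  need <- (cf$n_spines - 1) * cf$min_spine_sep
  if (cf$n_spines > 1 && need > usable)
    stop(sprintf(paste0("cannot place %d spines with minimum separation ",
                        "%g px on a dendrite of usable length %g px"),
                 cf$n_spines, cf$min_spine_sep, usable))

  # spine positions: jittered regular spacing along the path, offset
  # perpendicular by up to 3x dendrite width (the proximity-gating bound)
  xs <- seq(path[1, 2], path[2, 2], length.out = max(cf$n_spines, 2))
  xs <- xs[seq_len(cf$n_spines)] +
    stats::runif(cf$n_spines, -cf$min_spine_sep / 4, cf$min_spine_sep / 4)
  off_lo <- cf$dendrite_width / 2 + cf$spine_sigma + 1
  off_hi <- max(off_lo + 0.5, 3 * cf$dendrite_width - 0.5)
  offs <- stats::runif(cf$n_spines, off_lo, off_hi) *
    sample(c(-1, 1), cf$n_spines, replace = TRUE)
  rows_on_path <- path[1, 1] + (xs - path[1, 2]) / (path[2, 2] - path[1, 2]) *
    (path[2, 1] - path[1, 1])
  centroids <- cbind(rows_on_path + offs, xs)

  # static structure
  cc <- expand.grid(row = seq_len(H), col = seq_len(W))
  dend_mask <- matrix(FALSE, H, W)
  dmin <- point_polyline_distance(as.matrix(cc), path)
  dend_mask[dmin <= cf$dendrite_width / 2] <- TRUE
  spine_profiles <- vector("list", cf$n_spines)
  spine_masks <- vector("list", cf$n_spines)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(cf$n_spines)) {
    g <- exp(-((rows - centroids[i, 1])^2 + (cols - centroids[i, 2])^2) /
               (2 * cf$spine_sigma^2))
    spine_profiles[[i]] <- g
    spine_masks[[i]] <- g >= exp(-2)   # within 2 sigma of the center
  }

  # temporal signals
  bap <- transient_trace(T_, cf$bap_rate, cf$tau, cf$bap_amp)
  scales <- stats::runif(cf$n_spines, cf$bap_scale_range[1],
                         cf$bap_scale_range[2])
  tuning <- NULL
  input <- matrix(0, cf$n_spines, T_)
  for (i in seq_len(cf$n_spines))
    input[i, ] <- transient_trace(T_, cf$event_rate, cf$tau, cf$event_amp)
  if (!is.null(cf$stimulus)) {
    tuning <- cf$tuning
    if (is.null(tuning)) tuning <- random_tuning(cf$n_spines)
    dirs <- stimulus_direction_codes(cf$stimulus, T_)
    onsets <- which(dirs != 0 & c(0, utils::head(dirs, -1)) == 0)
    deg <- (dirs[onsets] - 1) * 360 / max(dirs)
    for (i in seq_len(cf$n_spines)) {
      amp <- two_peak_gaussian(deg, tuning$baseline[i], tuning$a1[i],
                               tuning$a2[i], tuning$theta_pref[i],
                               tuning$sigma[i])
      amp <- pmax(0, amp + stats::rnorm(length(amp), 0, cf$tuning_noise_sd))
      ev <- numeric(T_); ev[onsets] <- amp * cf$event_amp
      input[i, ] <- input[i, ] + decay_filter(ev, cf$tau)
    }
  }

  # motion: integer random walk clipped to +/- motion_amp, starting at 0
  traj <- matrix(0L, T_, 2)
  if (cf$motion_amp > 0) {
    for (ax in 1:2) {
      steps <- sample(c(-1L, 0L, 1L), T_ - 1, replace = TRUE)
      p <- cumsum(steps)
      traj[-1, ax] <- as.integer(pmin(pmax(p, -cf$motion_amp), cf$motion_amp))
    }
  }

  # render
  static <- cf$baseline + cf$dendrite_brightness * dend_mask
  for (i in seq_len(cf$n_spines))
    static <- static + cf$spine_brightness * spine_profiles[[i]]
  data <- array(0, dim = c(T_, H, W))
  clean <- array(0, dim = c(T_, H, W))
  for (t in seq_len(T_)) {
    fr <- static + dend_mask * bap[t]
    for (i in seq_len(cf$n_spines))
      fr <- fr + spine_profiles[[i]] * (input[i, t] + scales[i] * bap[t])
    clean[t, , ] <- fr
    data[t, , ] <- roll_matrix(fr, traj[t, 1], traj[t, 2])
  }
  if (cf$noise_sd > 0)
    data <- data + array(stats::rnorm(length(data), 0, cf$noise_sd),
                         dim = dim(data))

  truth <- list(spine_centroids = centroids, spine_masks = spine_masks,
                dendrite_path = path, dendrite_width = cf$dendrite_width,
                dendrite_mask = dend_mask,
                per_spine_input_trace = input, bap_trace = bap,
                bap_scale_per_spine = scales, motion_trajectory = traj,
                tuning_params = tuning,
                clean_stack = tstack(clean, frame_rate = cf$frame_rate))
  list(stack = tstack(data, frame_rate = cf$frame_rate), truth = truth)
}

#' Default configuration for [make_dendrite_movie()]
#'
#' Units: frames for times (`tau`, durations), pixels for geometry,
#' arbitrary fluorescence units (a.u.) for brightness. The defaults sketch a
#' GCaMP-like recording: sparse transients (per-frame event probability
#' 0.02 for spines, 0.03 for global bAP events), decay constant 10 frames,
#' and a dim baseline with bright structure.
#'
#' @return named list of generator parameters.
#' @export
movie_config <- function() {
  list(n_frames = 500L, height = 96L, width = 96L,
       n_spines = 10L, min_spine_sep = 7,
       dendrite_width = 3, dendrite_slope = 0,
       spine_sigma = 1.5,
       baseline = 20, dendrite_brightness = 30, spine_brightness = 30,
       event_rate = 0.02, event_amp = 60, tau = 10,
       bap_rate = 0.03, bap_amp = 60, bap_scale_range = c(0.2, 1.5),
       motion_amp = 0, noise_sd = 0, frame_rate = 30,
       stimulus = NULL, tuning = NULL, tuning_noise_sd = 0)
}

# Poisson event train (amplitude ~ amp * Exp(1)) convolved with a
# single-exponential decay kernel
transient_trace <- function(T_, rate, tau, amp) {
  n_ev <- stats::rbinom(T_, 1L, min(rate, 1))
  ev <- n_ev * amp * stats::rexp(T_)
  decay_filter(ev, tau)
}

# x convolved with kernel exp(-k / tau), k = 0, 1, ... ; the recursive form
# y_t = x_t + exp(-1/tau) * y_{t-1} is an exact superposition of kernels
decay_filter <- function(x, tau) {
  as.numeric(stats::filter(x, exp(-1 / tau), method = "recursive"))
}

random_tuning <- function(n) {
  list(theta_pref = stats::runif(n, 0, 360),
       a1 = stats::runif(n, 0.8, 1.5),
       a2 = stats::runif(n, 0.1, 0.8),
       sigma = stats::runif(n, 15, 40),
       baseline = rep(0, n))
}

# direction code per imaging frame from a grating stimulus table
stimulus_direction_codes <- function(stim, T_) {
  dirs <- stim$stampinfo[[2]]
  tt <- stim$stampinfo[[1]]
  idx <- findInterval(stim$framestamp[seq_len(T_)], tt)
  idx[idx < 1L] <- 1L
  dirs[idx]
}

#' Synthetic stimulus / behavior tables
#'
#' Builds a `StimulusTable` (a `framestamp` time vector paired with a
#' `stampinfo` parameter table whose first column is timekeeping).
#'
#' Two variants are supported. `type = "grating"` emits a drifting-grating
#' schedule: direction codes `1..n_directions` (0 = gray screen) presented
#' for `stim_frames` frames separated by `gray_frames` frames of gray, with
#' the whole sweep of directions repeated `repeats` times; the framestamp is
#' in frame indices. `type = "locomotion"` emits a speed trace (cm/s),
#' virtual track position (cm) and an open-/closed-loop `trial_type` column,
#' stamped in seconds and optionally sampled faster than the frame clock
#' (`sample_rate_factor`); each trial holds a stationary interval followed
#' by a running bout, so speed crosses any low threshold once per trial.
#'
#' @param config named list; see `stimulus_config()` for defaults and units.
#' @param seed integer seed.
#' @return A `StimulusTable`: list with `framestamp` (length `T`),
#'   `stampinfo` (data.frame) and `unit` ("frames" or "seconds"), of class
#'   `StimulusTable`.
#' @export
make_stimulus_table <- function(config = list(), seed = 1L) {
  cf <- utils::modifyList(stimulus_config(), config)
  set.seed(seed)
  if (identical(cf$type, "grating")) {
    if (cf$stim_frames <= 0 || cf$gray_frames <= 0)
      stop("stimulus and gray durations must be positive")
    if (cf$n_directions < 2) stop("need at least 2 directions")
    if (cf$repeats < 1) stop("repeats must be >= 1")
    dirs <- integer(0)
    for (r in seq_len(cf$repeats)) for (d in seq_len(cf$n_directions))
      dirs <- c(dirs, rep(0L, cf$gray_frames), rep(d, cf$stim_frames))
    dirs <- c(dirs, rep(0L, cf$gray_frames))
    T_ <- length(dirs)
    framestamp <- seq_len(T_)
    f <- cf$sample_rate_factor
    if (f == 1) {
      info <- data.frame(frame = framestamp, direction = dirs)
    } else {
      tt <- seq(1, T_, by = 1 / f)
      info <- data.frame(frame = tt, direction = dirs[floor(tt)])
    }
    st <- list(framestamp = framestamp, stampinfo = info, unit = "frames")
  } else if (identical(cf$type, "locomotion")) {
    if (cf$trial_dur_s <= 0) stop("trial duration must be positive")
    T_ <- ceiling(cf$n_trials * cf$trial_dur_s * cf$frame_rate)
    framestamp <- (seq_len(T_) - 1) / cf$frame_rate
    sr <- cf$frame_rate * cf$sample_rate_factor
    n <- ceiling(cf$n_trials * cf$trial_dur_s * sr)
    tt <- (seq_len(n) - 1) / sr
    trial <- pmin(floor(tt / cf$trial_dur_s) + 1, cf$n_trials)
    ttype <- ifelse(trial %% 2 == 1, "closed", "open")
    speed <- numeric(n)
    for (tr in seq_len(cf$n_trials)) {
      i <- which(trial == tr)
      t_rel <- tt[i] - (tr - 1) * cf$trial_dur_s
      onset <- stats::runif(1, cf$stationary_min_s,
                            cf$trial_dur_s - cf$run_dur_s)
      run <- t_rel >= onset & t_rel < onset + cf$run_dur_s
      ramp <- pmin(1, (t_rel[run] - onset) / cf$accel_s)
      speed[i][run] <- cf$run_speed * ramp
    }
    speed <- pmax(0, speed + stats::rnorm(n, 0, cf$speed_noise_sd))
    pos <- (cumsum(speed) / sr) %% cf$track_length
    info <- data.frame(time_s = tt, speed = speed, position = pos,
                       trial_type = ttype, stringsAsFactors = FALSE)
    st <- list(framestamp = framestamp, stampinfo = info, unit = "seconds")
  } else stop("unknown stimulus type: ", cf$type)
  class(st) <- "StimulusTable"
  st
}

#' Default configuration for [make_stimulus_table()]
#' @return named list. Grating fields are in frames; locomotion fields in
#'   seconds, cm and cm/s.
#' @export
stimulus_config <- function() {
  list(type = "grating",
       n_directions = 8L, repeats = 5L, stim_frames = 20L, gray_frames = 20L,
       sample_rate_factor = 1,
       # locomotion variant
       n_trials = 8L, trial_dur_s = 12, frame_rate = 30,
       stationary_min_s = 4, run_dur_s = 4, accel_s = 0.5,
       run_speed = 10, speed_noise_sd = 0.05, track_length = 180)
}

#' Paired point clouds under a known rigid transform
#'
#' Generates a source cloud uniformly in a square field, applies a known
#' rigid transform plus Gaussian jitter, removes a fraction of points and
#' appends spurious ones — the standard construction for benchmarking
#' cross-session alignment.
#'
#' @param n_points number of source points (>= 3).
#' @param transform a [rigid_transform()]; applied to the source cloud.
#' @param jitter_sd per-axis Gaussian jitter (px) added after the transform.
#' @param drop_frac fraction of transformed points removed (in `[0, 1)`).
#' @param add_frac fraction of spurious points appended (of `n_points`).
#' @param field_size side of the square field the points live in (px).
#' @param seed integer seed.
#' @return list with `cloud_a`, `cloud_b` (n x 2 matrices of (row, col)) and
#'   `true_transform`.
#' @export
make_point_cloud_pair <- function(n_points, transform, jitter_sd = 0,
                                  drop_frac = 0, add_frac = 0,
                                  field_size = 100, seed = 1L) {
  stopifnot(n_points >= 3, drop_frac >= 0, drop_frac < 1,
            add_frac >= 0, add_frac < 1)
  set.seed(seed)
  a <- cbind(stats::runif(n_points, 0, field_size),
             stats::runif(n_points, 0, field_size))
  b <- apply_rigid(a, transform)
  if (jitter_sd > 0)
    b <- b + matrix(stats::rnorm(length(b), 0, jitter_sd), ncol = 2)
  n_drop <- round(drop_frac * n_points)
  if (n_drop > 0) b <- b[-sample(n_points, n_drop), , drop = FALSE]
  if (nrow(b) < 3) stop("fewer than 3 points survive drop_frac")
  n_add <- round(add_frac * n_points)
  if (n_add > 0)
    b <- rbind(b, cbind(stats::runif(n_add, 0, field_size),
                        stats::runif(n_add, 0, field_size)))
  list(cloud_a = a, cloud_b = b, true_transform = transform)
}
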