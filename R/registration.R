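#' Registration parameters
#'
#' Defaults for motion correction. `corr_floor_init` is the mean
#' registration correlation below which template initialization is re-run
#' with the next most stable chunk; `frame_corr_min`, `signal_min` and
#' `max_disp` are the safeguard thresholds under which a frame is declared
#' inadequately registered and its shift interpolated from neighbors.
#'
#' @param chunk_len frames per candidate initialization chunk (>= 2).
#' @param corr_floor_init mean-correlation floor for accepting a template.
#' @param frame_corr_min minimum frame-to-template correlation.
#' @param signal_min minimum mean frame intensity (a.u.); `NULL` means 10%
#'   of the template mean, resolved at registration time.
#' @param max_disp maximum |shift| per axis in px; `NULL` means 20% of the
#'   smaller image dimension.
#' @param subpixel logical; refine shifts by Fourier upsampling (x10)
#'   around the integer peak. Integer shifts are the default so results are
#'   exactly checkable.
#' @return list of class `RegistrationParams`.
#' @export
registration_params <- function(chunk_len = 200L, corr_floor_init = 0.2,
                                frame_corr_min = 0.2, signal_min = NULL,
                                max_disp = NULL, subpixel = FALSE) {
  stopifnot(chunk_len >= 2, is.finite(corr_floor_init),
            is.finite(frame_corr_min))
  structure(list(chunk_len = as.integer(chunk_len),
                 corr_floor_init = corr_floor_init,
                 frame_corr_min = frame_corr_min, signal_min = signal_min,
                 max_disp = max_disp, subpixel = subpixel),
            class = "RegistrationParams")
}

#' Phase correlation between a frame and a template
#'
#' Computes the normalized cross-power spectrum in the Fourier domain and
#' takes the argmax of its inverse transform, restricted to shifts of at
#' most `max_disp` px per axis. A mild Gaussian taper (`smooth_sigma`) is
#' applied to the normalized spectrum before inversion: for a pure
#' translation this blurs the delta peak without moving its argmax, while
#' under sensor noise it suppresses spurious single-pixel peaks. The
#' returned `(dy, dx)` is the shift to apply to `frame` to align it to
#' `template` (so a frame that is the template moved down by 3 rows
#' yields `dy = -3`). `corr` is the Pearson correlation between the
#' shifted frame and the template over their non-wrapped overlap.
#'
#' @param frame,template equal-sized numeric matrices.
#' @param max_disp maximum |shift| per axis (px).
#' @param subpixel logical; when `TRUE` the integer peak is refined to 0.1
#'   px by evaluating the inverse transform of the normalized cross-power
#'   spectrum on an upsampled (x10) grid around the peak.
#' @param smooth_sigma spatial scale (px) of the Gaussian spectral taper;
#'   0 disables it.
#' @return list with `dy`, `dx`, `corr`, and `peak_in_range` (`FALSE` when
#'   the unrestricted correlation peak lies beyond `max_disp`, which
#'   triggers the safeguard downstream).
#' @export
phase_correlate <- function(frame, template, max_disp = NULL,
                            subpixel = FALSE, smooth_sigma = 1.15) {
  stopifnot(identical(dim(frame), dim(template)))
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(max_disp)) max_disp <- floor(0.2 * min(h, w))
  if (all(frame == 0) || all(template == 0) ||
      stats::sd(frame) == 0 || stats::sd(template) == 0)
    return(list(dy = 0L, dx = 0L, corr = 0, peak_in_range = TRUE))
  ff <- stats::fft(frame)
  ft <- stats::fft(template)
  r <- ff * Conj(ft)
  mag <- Mod(r)
  mag[mag < 1e-15] <- 1e-15
  cps <- r / mag
  if (smooth_sigma > 0) {
    ky <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
    kx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
    cps <- cps * exp(-2 * pi^2 * smooth_sigma^2 * outer(ky^2, kx^2, "+"))
  }
  surf <- Re(stats::fft(cps, inverse = TRUE))
  # surf index (i, j) corresponds to frame = template shifted by
  # s = (i-1, j-1) mod (h, w); correction is -s
  peak <- arrayInd(which.max(surf), dim(surf))
  s_all <- wrap_shift(peak - 1L, c(h, w))
  in_range <- all(abs(s_all) <= max_disp)
  if (!in_range) {
    dys <- seq(-max_disp, max_disp)
    ri <- (dys %% h) + 1L
    ci <- (seq(-max_disp, max_disp) %% w) + 1L
    sub <- surf[ri, ci, drop = FALSE]
    p <- arrayInd(which.max(sub), dim(sub))
    s <- c(dys[p[1]], seq(-max_disp, max_disp)[p[2]])
  } else s <- s_all
  if (subpixel) s <- refine_peak_subpixel(cps, s, c(h, w))
  dy <- -s[1]; dx <- -s[2]
  shifted <- shift_matrix(frame, round(dy), round(dx), fill = NA)
  ok <- !is.na(shifted)
  corr <- if (sum(ok) > 2 && stats::sd(shifted[ok]) > 0 &&
              stats::sd(template[ok]) > 0)
    stats::cor(shifted[ok], template[ok]) else 0
  if (!subpixel) { dy <- as.integer(dy); dx <- as.integer(dx) }
  list(dy = dy, dx = dx, corr = corr, peak_in_range = in_range)
}

# evaluate the phase-correlation surface on a 10x-upsampled grid within
# +/- 1 px of the integer peak (matrix DFT; wrap-aware frequencies)
refine_peak_subpixel <- function(cps, s, dims, upsample = 10L) {
  h <- dims[1]; w <- dims[2]
  ky <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1))
  kx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1))
  uy <- s[1] + seq(-1, 1, by = 1 / upsample)
  ux <- s[2] + seq(-1, 1, by = 1 / upsample)
  ey <- exp(2i * pi * outer(uy, ky) / h)   # |uy| x H
  ex <- exp(2i * pi * outer(kx, ux) / w)   # W x |ux|
  surf <- Re(ey %*% cps %*% ex)
  p <- arrayInd(which.max(surf), dim(surf))
  c(uy[p[1]], ux[p[2]])
}

wrap_shift <- function(idx, dims) {
  s <- idx
  for (k in 1:2) if (s[k] > dims[k] / 2) s[k] <- s[k] - dims[k]
  as.integer(s)
}

#' Choose an initialization template from the most stable chunk
#'
#' Splits the stack into consecutive chunks of `chunk_len` frames and
#' scores each by stability x prominence: (mean correlation of the chunk's
#' frames to the chunk mean image) x (chunk mean intensity / stack mean
#' intensity). The frames of the best chunk are mutually aligned and
#' averaged into a template; if the mean registration correlation of the
#' whole stack (sampled) against that template falls below
#' `corr_floor_init`, initialization is re-run with the next most stable
#' chunk. If every chunk fails the floor, the best-achieving template is
#' returned with `warning_flag = TRUE` rather than failing the run.
#'
#' @param stack a `TStack` with at least `2 * chunk_len` frames.
#' @param params a [registration_params()] list.
#' @param eval_frames number of evenly spaced frames used to estimate the
#'   stack-wide mean registration correlation for each candidate.
#' @return list with `template`, `chunk_index` (rank-1 chunk actually
#'   used), `mean_corr`, `warning_flag`, and `chunk_scores`.
#' @export
select_init_template <- function(stack, params = registration_params(),
                                 eval_frames = 50L) {
  T_ <- n_frames(stack)
  cl <- params$chunk_len
  if (T_ < 2 * cl) stop("need at least 2 * chunk_len frames")
  n_chunks <- T_ %/% cl
  stack_mean_int <- mean(stack$data)
  md <- params$max_disp
  if (is.null(md)) md <- floor(0.2 * min(dim(stack)[2:3]))

  scores <- numeric(n_chunks)
  for (k in seq_len(n_chunks)) {
    idx <- ((k - 1) * cl + 1):(k * cl)
    sub <- stack$data[idx, , , drop = FALSE]
    m <- colMeans(sub, dims = 1)
    mv <- as.vector(m)
    if (stats::sd(mv) == 0) { scores[k] <- 0; next }
    cs <- apply(sub, 1, function(fr) {
      fv <- as.vector(fr)
      if (stats::sd(fv) == 0) 0 else stats::cor(fv, mv)
    })
    scores[k] <- mean(cs) * (mean(sub) / stack_mean_int)
  }
  ord <- order(scores, decreasing = TRUE)
  ev <- unique(round(seq(1, T_, length.out = min(eval_frames, T_))))
  best <- NULL
  for (k in ord) {
    idx <- ((k - 1) * cl + 1):(k * cl)
    m <- colMeans(stack$data[idx, , , drop = FALSE], dims = 1)
    # mutually align chunk frames to the chunk mean, then average
    acc <- 0
    for (t in idx) {
      pc <- phase_correlate(frame_at(stack, t), m, md)
      acc <- acc + roll_matrix(frame_at(stack, t), pc$dy, pc$dx)
    }
    template <- acc / length(idx)
    mc <- mean(vapply(ev, function(t)
      phase_correlate(frame_at(stack, t), template, md)$corr, numeric(1)))
    if (is.null(best) || mc > best$mean_corr)
      best <- list(template = template, chunk_index = k, mean_corr = mc)
    if (mc >= params$corr_floor_init)
      return(list(template = template, chunk_index = k, mean_corr = mc,
                  warning_flag = FALSE, chunk_scores = scores))
  }
  warning("no initialization chunk reached the correlation floor (",
          params$corr_floor_init, "); returning best achieved (",
          signif(best$mean_corr, 3), ")")
  c(best, list(warning_flag = TRUE, chunk_scores = scores))
}

#' Motion-correct a stack by phase correlation with safeguards
#'
#' Registers every frame to a template (computed via
#' [select_init_template()] unless supplied). A frame is flagged invalid
#' when its correlation to the template falls below `frame_corr_min`, its
#' mean intensity falls below `signal_min`, or its correlation peak lies
#' beyond `max_disp`; invalid frames receive shifts linearly interpolated
#' from the nearest valid flanking frames (leading/trailing invalid frames
#' carry the nearest valid shift). Because a fresh template has an
#' arbitrary absolute position, all shifts are re-anchored so the first
#' valid frame has shift (0, 0) and the template is translated to match;
#' reported shifts are therefore displacements relative to the movie start.
#'
#' @param stack a `TStack`.
#' @param params a [registration_params()] list.
#' @param template optional `H x W` template; skips initialization.
#' @return list with `result` (class `RegistrationResult`: `shifts` (T x 2,
#'   (dy, dx)), `frame_corr`, `interpolated_mask`, `template`,
#'   `init_chunk_index`, `init_warning`) and `corrected` (a `TStack`).
#' @export
register_stack <- function(stack, params = registration_params(),
                           template = NULL) {
  T_ <- n_frames(stack)
  if (T_ < 1) stop("empty stack")
  d <- dim(stack)
  md <- params$max_disp
  if (is.null(md)) md <- floor(0.2 * min(d[2], d[3]))
  init_chunk <- NA_integer_; init_warn <- FALSE
  if (is.null(template)) {
    p2 <- params
    p2$chunk_len <- min(params$chunk_len, max(2L, T_ %/% 2L))
    init <- select_init_template(stack, p2)
    template <- init$template
    init_chunk <- init$chunk_index
    init_warn <- init$warning_flag
  }
  sig_min <- params$signal_min
  if (is.null(sig_min)) sig_min <- 0.1 * mean(template)

  shifts <- matrix(0, T_, 2)
  corr <- numeric(T_)
  valid <- logical(T_)
  for (t in seq_len(T_)) {
    fr <- frame_at(stack, t)
    pc <- phase_correlate(fr, template, md, subpixel = params$subpixel)
    shifts[t, ] <- c(pc$dy, pc$dx)
    corr[t] <- pc$corr
    valid[t] <- pc$peak_in_range && pc$corr >= params$frame_corr_min &&
      mean(fr) >= sig_min
  }
  if (!any(valid)) {
    warning("no frame passed the safeguard thresholds; ",
            "returning raw shifts unmodified")
    valid[] <- TRUE
  }
  interpolated <- !valid
  if (any(interpolated)) {
    vi <- which(valid)
    for (ax in 1:2) {
      f <- stats::approx(vi, shifts[vi, ax], xout = seq_len(T_),
                         method = "linear", rule = 2)$y
      shifts[!valid, ax] <- if (params$subpixel) f[!valid]
                            else round(f[!valid])
    }
  }
  # re-anchor to the first valid frame
  anchor <- shifts[which(valid)[1], ]
  if (any(anchor != 0)) {
    shifts <- sweep(shifts, 2, anchor)
    template <- shift_matrix(template, -round(anchor[1]), -round(anchor[2]),
                             fill = stats::median(template))
  }
  corrected <- apply_shifts(stack, shifts,
                            subpixel = isTRUE(params$subpixel))
  result <- structure(
    list(shifts = shifts, frame_corr = corr,
         interpolated_mask = interpolated, template = template,
         init_chunk_index = init_chunk, init_warning = init_warn,
         max_disp = md),
    class = "RegistrationResult")
  list(result = result, corrected = corrected)
}

#' Translate every frame of a stack by per-frame shifts
#'
#' Integer translation with out-of-frame pixels filled with the frame
#' median; with `subpixel = TRUE`, fractional shifts are applied by Fourier
#' phase ramps (wrap-around boundary).
#'
#' @param stack a `TStack`.
#' @param shifts `T x 2` matrix of (dy, dx) shifts in px.
#' @param subpixel logical.
#' @return the shifted `TStack`.
#' @export
apply_shifts <- function(stack, shifts, subpixel = FALSE) {
  T_ <- n_frames(stack)
  shifts <- as.matrix(shifts)
  if (nrow(shifts) != T_) stop("shifts must have one row per frame")
  out <- stack$data
  for (t in seq_len(T_)) {
    fr <- frame_at(stack, t)
    if (subpixel && any(shifts[t, ] != round(shifts[t, ]))) {
      out[t, , ] <- fourier_shift(fr, shifts[t, 1], shifts[t, 2])
    } else {
      out[t, , ] <- shift_matrix(fr, round(shifts[t, 1]), round(shifts[t, 2]),
                                 fill = stats::median(fr))
    }
  }
  tstack(out, bit_depth = "float", frame_rate = stack$frame_rate,
         source_paths = stack$source_paths,
         file_boundaries = stack$file_boundaries)
}

fourier_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ky <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  kx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  ph <- exp(-2i * pi * (outer(ky * dy, kx * dx, "+")))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (h * w)
}

#' Register several stacks, independently or as one ensemble
#'
#' `ensemble = TRUE` concatenates multiple t-stacks of the same field of
#' view and registers them as a single movie against one template;
#' `ensemble = FALSE` registers each stack on its own.
#'
#' @param stacks list of `TStack`s.
#' @param params a [registration_params()] list.
#' @param ensemble logical.
#' @return one `register_stack()` result (ensemble) or a list of results.
#' @export
register_batch <- function(stacks, params = registration_params(),
                           ensemble = FALSE) {
  if (!ensemble) return(lapply(stacks, register_stack, params = params))
  register_stack(concat_tstacks(stacks), params = params)
}

#' Concatenate stacks of one field of view
#' @param stacks list of `TStack`s sharing H x W.
#' @return a single `TStack` with `file_boundaries` recording the joins.
#' @export
concat_tstacks <- function(stacks) {
  dims <- vapply(stacks, function(s) dim(s$data)[2:3], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("stacks disagree on frame size: ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  Ts <- vapply(stacks, n_frames, integer(1))
  data <- array(0, dim = c(sum(Ts), dims[1, 1], dims[2, 1]))
  at <- 0L
  for (s in stacks) {
    data[at + seq_len(n_frames(s)), , ] <- s$data
    at <- at + n_frames(s)
  }
  tstack(data, frame_rate = stacks[[1]]$frame_rate,
         source_paths = unlist(lapply(stacks, function(s) s$source_paths)),
         file_boundaries = cumsum(Ts))
}
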