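test_that("phase correlation matches the exhaustive-shift oracle", {
  set.seed(10)
  for (i in 1:25) {
    tpl <- matrix(runif(64 * 64), 64, 64)
    s <- sample(-10:10, 2, replace = TRUE)
    fr <- dendromap:::roll_matrix(tpl, s[1], s[2])
    pc <- phase_correlate(fr, tpl, max_disp = 10)
    expect_equal(c(pc$dy, pc$dx), c(-s[1], -s[2]))
    expect_equal(c(pc$dy, pc$dx), oracle_shift(fr, tpl, 10))
  }
})

test_that("phase correlation handles identity, zeros and clamping", {
  tpl <- matrix(runif(32 * 32), 32, 32)
  id <- phase_correlate(tpl, tpl, 5)
  expect_equal(c(id$dy, id$dx), c(0L, 0L))
  expect_gt(id$corr, 0.999)

  z <- phase_correlate(matrix(0, 32, 32), tpl, 5)
  expect_equal(c(z$dy, z$dx, z$corr), c(0, 0, 0))

  # true shift beyond max_disp: clamped, low corr, flagged out of range
  fr <- dendromap:::roll_matrix(tpl, 5, 0)
  cl <- phase_correlate(fr, tpl, max_disp = 2)
  expect_false(cl$peak_in_range)
  expect_lte(abs(cl$dy), 2)
  expect_lte(abs(cl$dx), 2)
  expect_lt(cl$corr, 0.5)
})

test_that("subpixel refinement recovers fractional shifts", {
  set.seed(3)
  base <- matrix(0, 64, 64)
  for (k in 1:6) {
    r0 <- runif(1, 20, 44); c0 <- runif(1, 20, 44)
    base <- base + exp(-((row(base) - r0)^2 + (col(base) - c0)^2) / 18)
  }
  sh <- dendromap:::fourier_shift(base, 1.4, -2.3)
  pc <- phase_correlate(sh, base, 10, subpixel = TRUE)
  expect_lt(abs(pc$dy - (-1.4)), 0.15)
  expect_lt(abs(pc$dx - 2.3), 0.15)
})

test_that("template search picks the stable, signal-bearing chunk", {
  set.seed(4)
  T_ <- 200; h <- 64; w <- 64
  noise_half <- array(rnorm(100 * h * w, 10, 3), dim = c(100, h, w))
  g <- make_dendrite_movie(list(n_frames = 200L, height = 64L, width = 64L,
                                n_spines = 4L, noise_sd = 1), seed = 4)
  bright_half <- g$stack$data[1:100, , ]
  st <- tstack(array(c(aperm(noise_half, c(2, 3, 1)),
                       aperm(bright_half, c(2, 3, 1))),
                     dim = c(h, w, 200)) |> aperm(c(3, 1, 2)))
  p <- registration_params(chunk_len = 50L)
  sel <- select_init_template(st, p)
  expect_gt(sel$chunk_index, 2)  # second half of the stack
  expect_false(sel$warning_flag)
  # every bright-half chunk outscores every noise-half chunk
  expect_gt(min(sel$chunk_scores[3:4]), max(sel$chunk_scores[1:2]))

  # degenerate static noiseless stack: correlation 1, first chunk wins
  one <- g$truth$clean_stack$data[1, , ]
  static <- tstack(aperm(array(one, dim = c(64, 64, 200)), c(3, 1, 2)))
  sel2 <- select_init_template(static, registration_params(chunk_len = 50L))
  expect_gt(sel2$mean_corr, 0.999)
  expect_equal(sel2$chunk_index, 1L)

  # unattainable floor: warning flag set, best chunk still returned
  p3 <- registration_params(chunk_len = 50L, corr_floor_init = 1.1)
  expect_warning(sel3 <- select_init_template(st, p3), "floor")
  expect_true(sel3$warning_flag)
  expect_true(is.matrix(sel3$template))
})

test_that("known integer trajectories are recovered exactly without noise", {
  g <- make_dendrite_movie(list(motion_amp = 10, noise_sd = 0), seed = 3)
  reg <- register_stack(g$stack)
  expect_equal(reg$result$shifts, -g$truth$motion_trajectory,
               ignore_attr = TRUE)
  # away from the filled edges, the corrected movie equals the
  # motionless render
  expect_lt(max(abs(reg$corrected$data[, 15:80, 15:80] -
                    g$truth$clean_stack$data[, 15:80, 15:80])), 1e-9)
})

test_that("safeguards flag blanked frames and interpolate within flanking shifts", {
  g <- make_dendrite_movie(list(motion_amp = 6, noise_sd = 0), seed = 8)
  bad <- c(120, 121, 300)
  g$stack$data[bad, , ] <- 0
  reg <- register_stack(g$stack)
  expect_true(all(reg$result$interpolated_mask[bad]))
  expect_equal(sum(reg$result$interpolated_mask), length(bad))
  sh <- reg$result$shifts
  for (t in bad) {
    prev <- max(which(!reg$result$interpolated_mask[1:(t - 1)]))
    nxt <- t + min(which(!reg$result$interpolated_mask[(t + 1):500]))
    for (ax in 1:2) {
      lo <- min(sh[prev, ax], sh[nxt, ax])
      hi <- max(sh[prev, ax], sh[nxt, ax])
      expect_gte(sh[t, ax], lo)
      expect_lte(sh[t, ax], hi)
    }
  }
})

test_that("registration improves mean frame correlation on moving movies", {
  g <- make_dendrite_movie(list(motion_amp = 8, noise_sd = 4), seed = 9)
  reg <- register_stack(g$stack)
  tpl <- reg$result$template
  corr_of <- function(stack) mean(vapply(seq_len(n_frames(stack)),
    function(t) {
      fr <- as.vector(frame_at(stack, t))
      stats::cor(fr, as.vector(tpl))
    }, numeric(1)))
  expect_gte(corr_of(reg$corrected), corr_of(g$stack))
})

test_that("apply_shifts is an inverse-consistent integer translation", {
  st <- tstack(array(runif(5 * 20 * 20), dim = c(5, 20, 20)))
  sh <- matrix(c(1, 0), 5, 2, byrow = TRUE)
  out <- apply_shifts(st, sh)
  expect_equal(out$data[1, 2:20, ], st$data[1, 1:19, ])
  zero <- apply_shifts(st, matrix(0, 5, 2))
  expect_equal(zero$data, st$data)
  back <- apply_shifts(out, -sh)
  expect_equal(back$data[, 2:19, ], st$data[, 2:19, ])
})

test_that("batch mode keeps sessions independent or concatenates one FOV", {
  g1 <- make_dendrite_movie(list(n_frames = 200L, height = 64L, width = 64L,
                                 n_spines = 4L, motion_amp = 4), seed = 1)
  g2 <- make_dendrite_movie(list(n_frames = 200L, height = 64L, width = 64L,
                                 n_spines = 4L, motion_amp = 4), seed = 2)
  p <- registration_params(chunk_len = 50L)
  indep <- register_batch(list(g1$stack, g2$stack), p)
  expect_length(indep, 2)
  expect_equal(nrow(indep[[1]]$result$shifts), 200)
  ens <- register_batch(list(g1$stack, g2$stack), p, ensemble = TRUE)
  expect_equal(nrow(ens$result$shifts), 400)
  expect_equal(ens$corrected$file_boundaries, c(200L, 400L))
})
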