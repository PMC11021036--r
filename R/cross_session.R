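#' 2D rigid transform (rotation + translation)
#'
#' Maps `(row, col)` points by `p' = R(theta) (p - center) + center +
#' translation`, with `R` the counterclockwise rotation by `rotation`
#' degrees in (row, col) coordinates. The linear part has determinant 1
#' (pure rotation, no reflection or scaling).
#'
#' @param rotation angle in degrees.
#' @param translation length-2 `(drow, dcol)` in px.
#' @param center rotation center `(row, col)`; default the origin.
#' @return object of class `RigidTransform2D`.
#' @export
rigid_transform <- function(rotation, translation, center = c(0, 0)) {
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "RigidTransform2D")
}

#' @export
print.RigidTransform2D <- function(x, ...) {
  cat(sprintf("RigidTransform2D: rotation %.3f deg, translation (%.2f, %.2f) px, center (%.1f, %.1f)\n",
              x$rotation, x$translation[1], x$translation[2],
              x$center[1], x$center[2]))
  invisible(x)
}

rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#' @param pts `n x 2` matrix of (row, col) points.
#' @param tf a [rigid_transform()].
#' @return transformed `n x 2` matrix.
#' @export
apply_rigid <- function(pts, tf) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  R <- rotation_matrix(tf$rotation)
  sweep(sweep(pts, 2, tf$center) %*% t(R), 2,
        tf$center + tf$translation, "+")
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `RigidTransform2D` (same center).
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(-tf$rotation)
  # p = R^-1 (p' - c - t) + c  =  R^-1 (p' - c) + c + [R^-1(-t)]... solve:
  # want q(p') = R^-1 (p' - center) + center + t2 with q(apply(p)) = p
  t2 <- -as.numeric(R %*% tf$translation)
  rigid_transform(-tf$rotation, t2, tf$center)
}

# canonical (R, t) form: p' = p %*% t(R) + t
rigid_canonical <- function(tf) {
  R <- rotation_matrix(tf$rotation)
  t0 <- tf$center + tf$translation - as.numeric(R %*% tf$center)
  list(R = R, t = t0)
}

#' Key-point cloud of a feature map
#'
#' The point cloud used for cross-session alignment: spine centroids plus
#' dendrite-path samples every `k` px of arc length (endpoints included).
#'
#' @param fmap a `FeatureMap`.
#' @param k arc-length sampling interval in px.
#' @param include_dendrite logical; `FALSE` restricts the cloud to spine
#'   centroids.
#' @return `n x 2` matrix of (row, col) points (`n >= 3`).
#' @export
extract_key_points <- function(fmap, k = 5, include_dendrite = TRUE) {
  pts <- NULL
  if (length(fmap$spines))
    pts <- t(vapply(fmap$spines, function(s) s$centroid, numeric(2)))
  if (include_dendrite) for (dd in fmap$dendrites) {
    arcs <- unique(c(seq(0, dd$arc_length, by = k), dd$arc_length))
    pts <- rbind(pts, polyline_point_at(dd$path, arcs))
  }
  if (is.null(pts) || nrow(pts) < 3)
    stop("feature map yields fewer than 3 key points")
  unname(pts)
}

# point on a polyline at given arc-length positions
polyline_point_at <- function(path, arcs) {
  seg <- diff(path)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  out <- matrix(0, length(arcs), 2)
  for (i in seq_along(arcs)) {
    a <- min(max(arcs[i], 0), cum[length(cum)])
    s <- findInterval(a, cum, rightmost.closed = TRUE)
    s <- min(s, length(lens))
    t <- if (lens[s] == 0) 0 else (a - cum[s]) / lens[s]
    out[i, ] <- path[s, ] + t * seg[s, ]
  }
  out
}

#' Iterative closest point alignment of two point clouds
#'
#' Alternates (i) mutual-nearest-neighbor correspondence with a distance
#' cap (5 x the target cloud's median nearest-neighbor spacing, resisting
#' dropped/spurious points from turnover) and (ii) a closed-form SVD rigid
#' fit on the correspondences. Initialization aligns the cloud centroids
#' (translation only); because nearest-neighbor correspondence can trap
#' large rotations in local minima, the iteration is additionally
#' restarted from each coarse initial rotation in `init_rotations` and
#' the start reaching the lowest final MSE wins. The correspondence MSE
#' of mutual-NN ICP can fluctuate transiently, so each run keeps the
#' best transform seen so far and stops once no improvement beyond `tol`
#' has occurred for three consecutive iterations (or at
#' `max_iterations`); `per_iteration_mse` reports the best alignment
#' error achieved by each iteration of the winning run, a nonincreasing
#' envelope. Translation magnitude is unrestricted.
#'
#' @param source_cloud,target_cloud `n x 2` matrices (>= 3 points each).
#' @param max_iterations iteration cap.
#' @param tol MSE improvement threshold (px^2).
#' @param cap_factor correspondence distance cap as a multiple of the
#'   target's median nearest-neighbor spacing.
#' @param init_rotations coarse initial rotations (degrees) to restart
#'   from; ignored when `allow_rotation = FALSE`.
#' @param allow_rotation `FALSE` restricts the fit to pure translation
#'   (the baseline the rotation-aware alignment is compared against).
#' @return An `ICPResult`: list with `transform` (a [rigid_transform()]
#'   centered on the source centroid), `per_iteration_mse`,
#'   `n_iterations`, `converged`, `correspondence` (final index pairs) and
#'   `low_rank` (TRUE for degenerate collinear geometry).
#' @export
icp_align <- function(source_cloud, target_cloud, max_iterations = 50L,
                      tol = 1e-6, cap_factor = 5,
                      init_rotations = c(-20, -10, 0, 10, 20),
                      allow_rotation = TRUE) {
  src <- matrix(as.numeric(source_cloud), ncol = 2)
  tgt <- matrix(as.numeric(target_cloud), ncol = 2)
  if (nrow(src) < 3 || nrow(tgt) < 3) stop("both clouds need >= 3 points")
  cap <- cap_factor * median_nn_spacing(tgt)
  if (!allow_rotation) init_rotations <- 0
  winner <- NULL
  for (r0 in init_rotations) {
    run <- icp_run(src, tgt, rotation_matrix(r0), max_iterations, tol,
                   cap, allow_rotation)
    if (is.null(winner) || run$best$mse < winner$best$mse) winner <- run
  }
  best <- winner$best
  mse_seq <- winner$mse_seq
  if (!length(mse_seq)) mse_seq <- NA_real_  # no usable correspondence
  ctr <- colMeans(src)
  theta <- atan2(best$R[2, 1], best$R[1, 1]) * 180 / pi
  trans <- best$t + as.numeric(best$R %*% ctr) - ctr
  structure(list(transform = rigid_transform(theta, trans, center = ctr),
                 per_iteration_mse = mse_seq,
                 n_iterations = length(winner$mse_seq),
                 converged = winner$converged,
                 correspondence = best$corr,
                 low_rank = winner$low_rank),
            class = "ICPResult")
}

# one ICP run from a given initial rotation (centroid-aligned translation)
icp_run <- function(src, tgt, R, max_iterations, tol, cap,
                    allow_rotation) {
  tv <- colMeans(tgt) - as.numeric(R %*% colMeans(src))
  best <- list(mse = Inf, R = R, t = tv,
               corr = matrix(integer(0), 0, 2))
  mse_seq <- numeric(0)
  converged <- FALSE
  low_rank <- FALSE
  stall <- 0L
  for (it in seq_len(max_iterations)) {
    cur <- src %*% t(R) + matrix(tv, nrow(src), 2, byrow = TRUE)
    corr_new <- mutual_nn_pairs(cur, tgt, cap)
    if (nrow(corr_new) < 3) break
    mse <- mean(rowSums((cur[corr_new[, 1], , drop = FALSE] -
                         tgt[corr_new[, 2], , drop = FALSE])^2))
    stall <- if (mse < best$mse - tol) 0L else stall + 1L
    if (mse < best$mse)
      best <- list(mse = mse, R = R, t = tv, corr = corr_new)
    mse_seq <- c(mse_seq, best$mse)
    if (stall >= 3L) { converged <- TRUE; break }
    p <- src[corr_new[, 1], , drop = FALSE]
    q <- tgt[corr_new[, 2], , drop = FALSE]
    fit <- procrustes_rigid(p, q, allow_rotation)
    if (fit$low_rank) low_rank <- TRUE
    R <- fit$R; tv <- fit$t
  }
  list(best = best, mse_seq = mse_seq, converged = converged,
       low_rank = low_rank)
}

median_nn_spacing <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

mutual_nn_pairs <- function(a, b, cap) {
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  i <- which(nn_ba[nn_ab] == seq_len(nrow(a)))
  j <- nn_ab[i]
  ok <- d[cbind(i, j)] <= cap^2
  cbind(i[ok], j[ok])
}

# closed-form least-squares rigid fit q ~ R p + t (SVD, det +1)
procrustes_rigid <- function(p, q, allow_rotation = TRUE) {
  mp <- colMeans(p); mq <- colMeans(q)
  low_rank <- FALSE
  if (!allow_rotation) {
    R <- diag(2)
  } else {
    H <- crossprod(sweep(p, 2, mp), sweep(q, 2, mq))
    sv <- svd(H)
    if (min(sv$d) < 1e-9 * max(sv$d, 1e-300)) low_rank <- TRUE
    D <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
  }
  list(R = R, t = as.numeric(mq - R %*% mp), low_rank = low_rank)
}

#' Transfer a feature map through a rigid transform
#'
#' Maps all centroids, paths and masks of a master map into another
#' session's frame; masks are re-rasterized pixel-by-pixel. Features whose
#' masks land entirely outside the frame are excluded with a warning
#' (large shifts push features out of view).
#'
#' @param fmap a `FeatureMap`.
#' @param transform a [rigid_transform()].
#' @param image_dim target frame size `c(H, W)`; default the source's.
#' @return the transferred `FeatureMap`.
#' @export
transfer_map <- function(fmap, transform, image_dim = fmap$image_dim) {
  lost <- character(0)
  map_mask <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    new_idx <- round(apply_rigid(idx, transform))
    ok <- new_idx[, 1] >= 1 & new_idx[, 1] <= image_dim[1] &
      new_idx[, 2] >= 1 & new_idx[, 2] <= image_dim[2]
    m <- matrix(FALSE, image_dim[1], image_dim[2])
    m[new_idx[ok, , drop = FALSE]] <- TRUE
    m
  }
  spines <- list()
  for (s in fmap$spines) {
    m <- map_mask(s$mask)
    if (!any(m)) { lost <- c(lost, paste0("spine ", s$id)); next }
    s2 <- spine_roi(s$id, m,
                    seed = pmin(pmax(round(apply_rigid(
                      matrix(if (is.null(s$seed)) s$centroid else s$seed, 1),
                      transform)), 1), image_dim),
                    parent_dendrite = s$parent_dendrite)
    spines[[length(spines) + 1]] <- s2
  }
  dendrites <- list()
  for (dd in fmap$dendrites) {
    new_path <- apply_rigid(dd$path, transform)
    new_path[, 1] <- pmin(pmax(new_path[, 1], 1), image_dim[1])
    new_path[, 2] <- pmin(pmax(new_path[, 2], 1), image_dim[2])
    d2 <- tryCatch(build_dendrite(new_path, dd$width, image_dim, id = dd$id),
                   error = function(e) NULL)
    if (is.null(d2) || !any(d2$mask)) {
      lost <- c(lost, paste0("dendrite ", dd$id)); next
    }
    dendrites[[length(dendrites) + 1]] <- d2
  }
  subregions <- list()
  for (sr in fmap$subregions) {
    m <- map_mask(sr$mask)
    if (!any(m)) { lost <- c(lost, paste0("subregion ", sr$id)); next }
    sr2 <- sr; sr2$mask <- m
    subregions[[length(subregions) + 1]] <- sr2
  }
  if (length(lost))
    warning("features mapped outside the frame were excluded: ",
            paste(lost, collapse = ", "))
  feature_map(spines, dendrites, subregions, image_dim)
}
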