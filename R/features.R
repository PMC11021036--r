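#' ROI catalogue for one field of view
#'
#' A `FeatureMap` bundles the segmented features of one session: spine
#' ROIs, long-dendrite ROIs and shaft subregions, plus the image size they
#' live in.
#'
#' @param spines list of `SpineROI` objects.
#' @param dendrites list of `DendriteROI` objects.
#' @param subregions list of `ShaftSubregion` objects.
#' @param image_dim `c(H, W)`.
#' @return object of class `FeatureMap`.
#' @export
feature_map <- function(spines = list(), dendrites = list(),
                        subregions = list(), image_dim) {
  structure(list(spines = spines, dendrites = dendrites,
                 subregions = subregions,
                 image_dim = as.integer(image_dim)),
            class = "FeatureMap")
}

#' @export
print.FeatureMap <- function(x, ...) {
  cat(sprintf("FeatureMap (%d x %d px): %d spines, %d dendrites, %d shaft subregions\n",
              x$image_dim[1], x$image_dim[2], length(x$spines),
              length(x$dendrites), length(x$subregions)))
  invisible(x)
}

# ---- seed detection -------------------------------------------------------

# FFT Gaussian blur with periodic boundary; a constant image stays exactly
# constant, which keeps degenerate no-seed cases exact
gaussian_blur_fft <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  ky <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1)) / h
  kx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1)) / w
  g <- exp(-2 * pi^2 * sigma^2 * outer(ky^2, kx^2, "+"))
  Re(stats::fft(stats::fft(img) * g, inverse = TRUE)) / (h * w)
}

#' Detect candidate spine seeds on a mean image
#'
#' Particle-style detection: a band-pass image is formed as the difference
#' of two Gaussian blurs (the wide blur acting as a background intensity
#' estimate, so smooth gradients cancel), and seeds are local maxima of the
#' band-pass above `min_score`, deduplicated within `min_sep` px (highest
#' score wins). Maxima within `ceiling(2 * sigma_large)` px of the image
#' border are ignored.
#'
#' @param mean_image 2D numeric matrix (typically [mean_image()] of a
#'   registered stack).
#' @param sigma_small,sigma_large Gaussian scales in px,
#'   `sigma_small < sigma_large`.
#' @param min_score detection threshold on the band-pass amplitude; `NULL`
#'   uses `5 * mad(band-pass)`.
#' @param min_sep minimum seed separation in px.
#' @return data.frame with columns `row`, `col`, `score`, `origin`; zero
#'   rows when nothing is detected.
#' @export
detect_seeds <- function(mean_image, sigma_small = 1, sigma_large = 4,
                         min_score = NULL, min_sep = 4) {
  stopifnot(sigma_small < sigma_large)
  bp <- gaussian_blur_fft(mean_image, sigma_small) -
    gaussian_blur_fft(mean_image, sigma_large)
  if (is.null(min_score)) min_score <- 5 * stats::mad(bp)
  h <- nrow(bp); w <- ncol(bp)
  nb_max <- matrix(-Inf, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, roll_matrix(bp, dy, dx))
  }
  is_max <- bp > nb_max & bp > min_score
  m <- ceiling(2 * sigma_large)
  if (h > 2 * m && w > 2 * m) {
    is_max[c(seq_len(m), h - seq_len(m) + 1), ] <- FALSE
    is_max[, c(seq_len(m), w - seq_len(m) + 1)] <- FALSE
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(0), col = integer(0),
                      score = numeric(0), origin = character(0)))
  sc <- bp[is_max]
  ord <- order(sc, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1):nrow(idx)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      keep[j][d2 < min_sep^2] <- FALSE
    }
  }
  data.frame(row = idx[keep, 1], col = idx[keep, 2], score = sc[keep],
             origin = "auto", stringsAsFactors = FALSE)
}

# ---- correlation-map segmentation ----------------------------------------

#' Temporal correlation of pixels around a seed
#'
#' For every pixel within `radius` px (Euclidean) of the seed, the Pearson
#' correlation between its time series and the seed pixel's time series;
#' pixels outside the radius are 0. The neighborhood size is tied to the
#' user's dendrite width by the caller (default radius
#' `3 * dendrite_width`).
#'
#' @param stack a `TStack`.
#' @param seed `(row, col)` seed position.
#' @param radius neighborhood radius in px (>= 1).
#' @return `H x W` correlation image.
#' @export
neighborhood_correlation_map <- function(stack, seed, radius) {
  stopifnot(radius >= 1)
  d <- dim(stack)
  seed <- as.integer(round(seed))
  if (seed[1] < 1 || seed[1] > d[2] || seed[2] < 1 || seed[2] > d[3])
    stop("seed lies outside the image")
  fs <- flatten_stack(stack)
  seed_ts <- fs[, (seed[2] - 1) * d[2] + seed[1]]
  if (stats::sd(seed_ts) == 0)
    stop(sprintf("seed (%d, %d) has a constant time series", seed[1], seed[2]))
  rows <- max(1, seed[1] - radius):min(d[2], seed[1] + radius)
  cols <- max(1, seed[2] - radius):min(d[3], seed[2] + radius)
  grid <- expand.grid(row = rows, col = cols)
  in_r <- (grid$row - seed[1])^2 + (grid$col - seed[2])^2 <= radius^2
  grid <- grid[in_r, ]
  cmap <- matrix(0, d[2], d[3])
  ts <- fs[, (grid$col - 1) * d[2] + grid$row, drop = FALSE]
  cc <- suppressWarnings(stats::cor(seed_ts, ts))
  cc[is.na(cc)] <- 0
  cmap[cbind(grid$row, grid$col)] <- cc
  cmap
}

#' Segment one spine ROI from a seed
#'
#' Thresholds the neighborhood correlation map at its 80% quantile (over
#' in-radius pixels), keeps the connected component containing the seed,
#' rejects components whose area falls outside `size_bounds`, and fits an
#' ellipse (image second central moments) to the accepted component.
#'
#' @param stack a `TStack` (registered movie).
#' @param seed `(row, col)` seed.
#' @param dendrite_width user's dendrite width (px); sets the correlation
#'   neighborhood radius to `3 * dendrite_width` and the default size
#'   bounds `[4, (4 * dendrite_width)^2]` px^2.
#' @param size_bounds length-2 numeric, acceptable area range in px^2.
#' @param corr_quantile segmentation threshold quantile (default 0.8).
#' @param id integer id to assign.
#' @return A `SpineROI` (list with `id`, `mask`, `centroid`, `area`,
#'   `ellipse`, `seed`, `parent_dendrite = NA`), or a `roi_rejection`
#'   object whose `reason` field describes why the seed was rejected.
#' @export
segment_spine <- function(stack, seed, dendrite_width = 3,
                          size_bounds = c(4, (4 * dendrite_width)^2),
                          corr_quantile = 0.8, id = 1L) {
  radius <- max(1L, ceiling(3 * dendrite_width))
  cmap <- neighborhood_correlation_map(stack, seed, radius)
  seed <- as.integer(round(seed))
  vals <- cmap[cmap != 0]
  thr <- stats::quantile(vals, corr_quantile, names = FALSE)
  bw <- cmap >= thr & cmap != 0
  lab <- EBImage::bwlabel(bw)
  seed_lab <- lab[seed[1], seed[2]]
  if (seed_lab == 0)
    return(roi_rejection("seed not inside any supra-threshold component"))
  mask <- lab == seed_lab
  area <- sum(mask)
  if (area < size_bounds[1] || area > size_bounds[2])
    return(roi_rejection(sprintf(
      "component area %d px^2 outside size bounds [%g, %g]",
      area, size_bounds[1], size_bounds[2])))
  spine_roi(id = id, mask = mask, seed = seed)
}

roi_rejection <- function(reason) {
  structure(list(reason = reason), class = "roi_rejection")
}

spine_roi <- function(id, mask, seed = NULL, parent_dendrite = NA_integer_) {
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  ell <- moments_ellipse(idx)
  structure(list(id = as.integer(id), mask = mask,
                 centroid = unname(centroid), area = nrow(idx),
                 ellipse = ell, seed = seed,
                 parent_dendrite = parent_dendrite),
            class = "SpineROI")
}

# ellipse from second central moments of a pixel set
moments_ellipse <- function(idx) {
  mu <- colMeans(idx)
  d <- sweep(idx, 2, mu)
  cv <- crossprod(d) / nrow(idx)
  e <- eigen(cv, symmetric = TRUE)
  list(center = unname(mu),
       major = 2 * sqrt(max(e$values[1], 0)),
       minor = 2 * sqrt(max(e$values[2], 0)),
       angle = atan2(e$vectors[1, 1], e$vectors[2, 1]) * 180 / pi)
}

# ---- dendrite geometry ----------------------------------------------------

#' Build a long-dendrite ROI from a polyline
#'
#' The user-supplied polyline (replacing interactive clicks) is dilated to
#' the given full width: the mask holds every pixel within `width / 2` of
#' the polyline.
#'
#' @param path_points `n x 2` matrix of (row, col) vertices, `n >= 2`.
#' @param width dendrite width in px.
#' @param image_dim `c(H, W)`.
#' @param id integer id.
#' @return A `DendriteROI`: list with `id`, `path`, `width`, `mask`,
#'   `arc_length`.
#' @export
build_dendrite <- function(path_points, width, image_dim, id = 1L) {
  path_points <- as.matrix(path_points)
  if (nrow(path_points) < 2) stop("a dendrite path needs at least 2 points")
  if (any(path_points[, 1] < 1) || any(path_points[, 1] > image_dim[1]) ||
      any(path_points[, 2] < 1) || any(path_points[, 2] > image_dim[2]))
    stop("dendrite path points fall outside the image")
  seg <- diff(path_points)
  arc_length <- sum(sqrt(rowSums(seg^2)))
  grid <- as.matrix(expand.grid(row = seq_len(image_dim[1]),
                                col = seq_len(image_dim[2])))
  dmin <- point_polyline_distance(grid, path_points)
  mask <- matrix(dmin <= width / 2, image_dim[1], image_dim[2])
  structure(list(id = as.integer(id), path = unname(path_points),
                 width = width, mask = mask, arc_length = arc_length),
            class = "DendriteROI")
}

# minimum distance from each point (rows of pts) to a polyline, plus the
# arc-length position of the nearest point on the polyline
point_polyline_project <- function(pts, path) {
  pts <- as.matrix(pts); path <- as.matrix(path)
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_arc <- numeric(n)
  arc0 <- 0
  for (s in seq_len(nrow(path) - 1)) {
    a <- path[s, ]; b <- path[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx1 <- pts[, 1] - (a[1] + t * ab[1])
    dx2 <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- dx1^2 + dx2^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- arc0 + t[upd] * sqrt(len2)
    arc0 <- arc0 + sqrt(len2)
  }
  list(distance = sqrt(best_d2), arc = best_arc)
}

point_polyline_distance <- function(pts, path) {
  point_polyline_project(pts, path)$distance
}

#' Keep spines tangentially proximal to a dendrite
#'
#' Retains spines whose centroid lies within
#' `proximity_factor * dendrite width` of the dendrite polyline (default
#' factor 3) and stamps their `parent_dendrite`.
#'
#' @param spines list of `SpineROI`s.
#' @param dendrite a `DendriteROI` with positive width.
#' @param proximity_factor nonnegative multiplier of the dendrite width.
#' @return the retained (and annotated) sublist of `spines`.
#' @export
filter_by_dendrite_proximity <- function(spines, dendrite,
                                         proximity_factor = 3) {
  stopifnot(dendrite$width > 0, proximity_factor >= 0)
  if (!length(spines)) return(spines)
  cent <- t(vapply(spines, function(s) s$centroid, numeric(2)))
  d <- point_polyline_distance(cent, dendrite$path)
  keep <- d <= proximity_factor * dendrite$width
  out <- spines[keep]
  for (i in seq_along(out)) out[[i]]$parent_dendrite <- dendrite$id
  out
}

#' Subdivide a dendrite into even shaft subregions
#'
#' Cuts the dendrite into consecutive arc-length spans of
#' `segment_length` px (the last span may be shorter); the subregion masks
#' partition the dendrite mask along the path.
#'
#' @param dendrite a `DendriteROI`.
#' @param segment_length span length in px (> 0).
#' @return list of `ShaftSubregion`s (fields `id`, `parent_dendrite`,
#'   `span`, `mask`, `mode`, `linked_spine`).
#' @export
subdivide_dendrite <- function(dendrite, segment_length) {
  stopifnot(segment_length > 0)
  L <- dendrite$arc_length
  starts <- seq(0, L, by = segment_length)
  if (utils::tail(starts, 1) >= L) starts <- starts[starts < L]
  idx <- which(dendrite$mask, arr.ind = TRUE)
  arc <- point_polyline_project(idx, dendrite$path)$arc
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    lo <- starts[k]; hi <- min(lo + segment_length, L)
    mask <- matrix(FALSE, nrow(dendrite$mask), ncol(dendrite$mask))
    sel <- if (k == length(starts)) arc >= lo & arc <= hi
           else arc >= lo & arc < hi
    mask[idx[sel, , drop = FALSE]] <- TRUE
    out[[k]] <- structure(
      list(id = k, parent_dendrite = dendrite$id, span = c(lo, hi),
           mask = mask, mode = "even_subdivision", linked_spine = NA),
      class = "ShaftSubregion")
  }
  out
}

#' Shaft subregion nearest a spine
#'
#' Builds the subregion centered at the arc-length position of the
#' dendrite path nearest the spine centroid, with span `segment_length`
#' clipped to the dendrite's extent.
#'
#' @param dendrite a `DendriteROI`.
#' @param spine a `SpineROI` whose `parent_dendrite` is this dendrite.
#' @param segment_length span length in px.
#' @return a `ShaftSubregion` with `mode = "by_spine"` and `linked_spine`
#'   set.
#' @export
shaft_by_spine <- function(dendrite, spine, segment_length) {
  if (is.na(spine$parent_dendrite) || spine$parent_dendrite != dendrite$id)
    stop("spine ", spine$id, " is not linked to dendrite ", dendrite$id)
  L <- dendrite$arc_length
  ctr <- point_polyline_project(matrix(spine$centroid, 1), dendrite$path)$arc
  lo <- max(0, ctr - segment_length / 2)
  hi <- min(L, ctr + segment_length / 2)
  idx <- which(dendrite$mask, arr.ind = TRUE)
  arc <- point_polyline_project(idx, dendrite$path)$arc
  mask <- matrix(FALSE, nrow(dendrite$mask), ncol(dendrite$mask))
  mask[idx[arc >= lo & arc <= hi, , drop = FALSE]] <- TRUE
  structure(list(id = spine$id, parent_dendrite = dendrite$id,
                 span = c(lo, hi), mask = mask, mode = "by_spine",
                 linked_spine = spine$id),
            class = "ShaftSubregion")
}

# ---- automated pipeline ---------------------------------------------------

#' Automated spine detection on a registered movie
#'
#' Runs seed detection on the mean image, segments every seed by
#' neighborhood correlation, optionally gates candidates by dendrite
#' proximity (strict mode, the low-false-positive setting), and resolves
#' overlapping masks by assigning contested pixels to the nearer seed.
#' In strict mode, seeds falling inside the shaft band itself (within
#' `width / 2` of the dendrite path) are discarded: the shaft carries the
#' global dendritic signal and is analyzed through its own ROI, while
#' spines are protrusions adjacent to it. This is the stringent default
#' that trades recall for few false positives.
#'
#' @param stack a registered `TStack`.
#' @param dendrite optional `DendriteROI`; when given, only spines within
#'   `proximity_factor` x width of it are kept.
#' @param dendrite_width width used for segmentation neighborhoods when no
#'   dendrite object is supplied.
#' @param proximity_factor see [filter_by_dendrite_proximity()].
#' @param size_bounds area bounds in px^2 (default
#'   `[4, (4 * width)^2]`).
#' @param seeds optional data.frame of seeds (columns `row`, `col`)
#'   replacing automatic detection (manual additions).
#' @param drop_ids integer ids to remove from the result (manual
#'   deletions).
#' @param ... passed to [detect_seeds()].
#' @return a `FeatureMap` containing the accepted spines (and the dendrite,
#'   when supplied).
#' @export
detect_spines <- function(stack, dendrite = NULL, dendrite_width = 3,
                          proximity_factor = 3, size_bounds = NULL,
                          seeds = NULL, drop_ids = integer(0), ...) {
  d <- dim(stack)
  width <- if (!is.null(dendrite)) dendrite$width else dendrite_width
  if (is.null(size_bounds)) size_bounds <- c(4, (4 * width)^2)
  if (is.null(seeds)) seeds <- detect_seeds(mean_image(stack), ...)
  if (!is.null(dendrite) && nrow(seeds)) {
    d_path <- point_polyline_distance(cbind(seeds$row, seeds$col),
                                      dendrite$path)
    seeds <- seeds[d_path > dendrite$width / 2, , drop = FALSE]
  }
  spines <- list()
  for (i in seq_len(nrow(seeds))) {
    roi <- tryCatch(
      segment_spine(stack, c(seeds$row[i], seeds$col[i]),
                    dendrite_width = width, size_bounds = size_bounds,
                    id = length(spines) + 1L),
      error = function(e) NULL)
    if (inherits(roi, "SpineROI")) spines[[length(spines) + 1]] <- roi
  }
  if (!is.null(dendrite))
    spines <- filter_by_dendrite_proximity(spines, dendrite,
                                           proximity_factor)
  spines <- resolve_overlaps(spines)
  for (i in seq_along(spines)) spines[[i]]$id <- i
  if (length(drop_ids))
    spines <- spines[!vapply(spines, function(s) s$id %in% drop_ids,
                             logical(1))]
  feature_map(spines = spines,
              dendrites = if (is.null(dendrite)) list() else list(dendrite),
              image_dim = d[2:3])
}

# contested pixels go to the nearer seed; each mask keeps the component
# containing its seed
resolve_overlaps <- function(spines) {
  if (length(spines) < 2) return(spines)
  for (i in seq_along(spines)) for (j in seq_along(spines)) {
    if (j <= i) next
    ov <- spines[[i]]$mask & spines[[j]]$mask
    if (!any(ov)) next
    idx <- which(ov, arr.ind = TRUE)
    si <- spines[[i]]$seed; sj <- spines[[j]]$seed
    di <- (idx[, 1] - si[1])^2 + (idx[, 2] - si[2])^2
    dj <- (idx[, 1] - sj[1])^2 + (idx[, 2] - sj[2])^2
    spines[[i]]$mask[idx[di > dj, , drop = FALSE]] <- FALSE
    spines[[j]]$mask[idx[di <= dj, , drop = FALSE]] <- FALSE
  }
  out <- list()
  for (s in spines) {
    if (!any(s$mask)) next
    lab <- EBImage::bwlabel(s$mask)
    keep_lab <- lab[s$seed[1], s$seed[2]]
    if (keep_lab == 0) keep_lab <- lab[which.max(lab > 0)]
    s2 <- spine_roi(s$id, lab == keep_lab, seed = s$seed,
                    parent_dendrite = s$parent_dendrite)
    out[[length(out) + 1]] <- s2
  }
  out
}

# ---- trace extraction -----------------------------------------------------

#' Extract per-ROI fluorescence traces
#'
#' The trace of ROI `r` at frame `t` is the mean of frame `t` over the
#' ROI's mask. Spines come first, then dendrites, then shaft subregions.
#'
#' @param stack a `TStack`.
#' @param fmap a `FeatureMap`.
#' @return a `TraceSet`: list with `traces` (R x T), `roi_ids`, `kind`
#'   (per-ROI `"spine"`, `"dendrite"` or `"subregion"`), `parent_dendrite`
#'   and `frame_clock`.
#' @export
extract_traces <- function(stack, fmap) {
  rois <- c(fmap$spines, fmap$dendrites, fmap$subregions)
  kind <- c(rep("spine", length(fmap$spines)),
            rep("dendrite", length(fmap$dendrites)),
            rep("subregion", length(fmap$subregions)))
  if (!length(rois)) stop("feature map holds no ROIs")
  fs <- flatten_stack(stack)
  T_ <- nrow(fs)
  traces <- matrix(0, length(rois), T_)
  ids <- integer(length(rois))
  parent <- rep(NA_integer_, length(rois))
  for (r in seq_along(rois)) {
    m <- rois[[r]]$mask
    if (!any(m)) stop("ROI ", rois[[r]]$id, " (", kind[r], ") has an empty mask")
    idx <- which(m)
    traces[r, ] <- if (length(idx) == 1) fs[, idx]
                   else rowMeans(fs[, idx, drop = FALSE])
    ids[r] <- rois[[r]]$id
    if (kind[r] == "dendrite") parent[r] <- rois[[r]]$id
    else if (!is.null(rois[[r]]$parent_dendrite))
      parent[r] <- rois[[r]]$parent_dendrite
  }
  structure(list(traces = traces, roi_ids = ids, kind = kind,
                 parent_dendrite = parent,
                 frame_clock = seq_len(T_)),
            class = "TraceSet")
}

#' Baseline-normalized (dF/F) view of a trace set
#'
#' F0 is a rolling 20th percentile of each raw trace over `window` frames;
#' the raw means remain the stored primary data.
#'
#' @param trace_set a `TraceSet`.
#' @param window rolling window length in frames.
#' @param quantile_p baseline percentile (default 0.2).
#' @return a `TraceSet` whose traces are `(F - F0) / F0`.
#' @export
delta_f_over_f <- function(trace_set, window = 500L, quantile_p = 0.2) {
  tr <- trace_set$traces
  T_ <- ncol(tr)
  half <- window %/% 2
  for (r in seq_len(nrow(tr))) {
    f0 <- numeric(T_)
    for (t in seq_len(T_)) {
      lo <- max(1, t - half); hi <- min(T_, t + half)
      f0[t] <- stats::quantile(tr[r, lo:hi], quantile_p, names = FALSE)
    }
    f0[f0 == 0] <- 1e-12
    tr[r, ] <- (trace_set$traces[r, ] - f0) / f0
  }
  out <- trace_set
  out$traces <- tr
  out
}

#' Apply a master ROI map to another stack
#'
#' Maps every feature of `fmap` through a rigid transform (identity for
#' same-session stacks), re-rasterizes the masks in the new frame, and
#' extracts traces from `new_stack`. ROIs mapped fully outside the frame
#' are excluded with a warning listing their ids.
#'
#' @param fmap the master `FeatureMap`.
#' @param new_stack the `TStack` to extract from.
#' @param transform a [rigid_transform()] (default identity).
#' @return list with `trace_set` and the transferred `feature_map`.
#' @export
apply_master_map <- function(fmap, new_stack,
                             transform = rigid_transform(0, c(0, 0))) {
  fmap2 <- transfer_map(fmap, transform, image_dim = dim(new_stack)[2:3])
  list(trace_set = extract_traces(new_stack, fmap2), feature_map = fmap2)
}
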