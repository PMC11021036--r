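#' Temporal image stack (t-stack)
#'
#' A `TStack` holds a movie of repeated 2D frames of one field of view as a
#' `T x H x W` numeric array, plus acquisition metadata. All pixel
#' coordinates in the package are 1-based `(row, col)` pairs.
#'
#' @param data numeric array with dimensions `c(T, H, W)` (frames, rows,
#'   columns).
#' @param bit_depth one of `8L`, `16L` or `"float"`; must be consistent with
#'   the value range of `data`.
#' @param frame_rate acquisition rate in Hz, or `NULL` if unknown.
#' @param source_paths ordered character vector of source files, or
#'   `character(0)` for in-memory stacks.
#' @param file_boundaries integer vector of cumulative frame counts at which
#'   concatenated source files end (used when several stacks of one field of
#'   view are merged into a single ensemble).
#'
#' @return An object of class `TStack`.
#' @export
tstack <- function(data, bit_depth = "float", frame_rate = NULL,
                   source_paths = character(0), file_boundaries = integer(0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a T x H x W array")
  if (dim(data)[1] < 1L) stop("a TStack needs at least one frame")
  if (!identical(bit_depth, "float")) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 16L))
      stop("bit_depth must be 8, 16 or \"float\"")
    rng <- range(data)
    if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
      stop("data values exceed the declared ", bit_depth, "-bit range")
  }
  structure(list(data = data, bit_depth = bit_depth, frame_rate = frame_rate,
                 source_paths = source_paths,
                 file_boundaries = as.integer(file_boundaries)),
            class = "TStack")
}

#' @export
print.TStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("TStack: %d frames of %d x %d px (%s)\n", d[1], d[2], d[3],
              if (identical(x$bit_depth, "float")) "float"
              else paste0(x$bit_depth, "-bit")))
  if (!is.null(x$frame_rate))
    cat(sprintf("  frame rate: %g Hz\n", x$frame_rate))
  if (length(x$source_paths))
    cat("  sources:", length(x$source_paths), "file(s)\n")
  invisible(x)
}

#' @export
dim.TStack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack a `TStack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' Extract one frame as a matrix
#' @param stack a `TStack`.
#' @param t frame index (1-based).
#' @return `H x W` numeric matrix.
#' @export
frame_at <- function(stack, t) {
  stack$data[t, , , drop = TRUE]
}

#' Mean image over frames
#' @param stack a `TStack`.
#' @param frames optional frame indices (default: all).
#' @return `H x W` numeric matrix.
#' @export
mean_image <- function(stack, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  colMeans(stack$data[frames, , , drop = FALSE], dims = 1)
}

# circular (wrap-around) integer shift of a matrix: content moves by
# (dy, dx), i.e. m2[r + dy, c + dx] = m[r, c] with wrapped indices
roll_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  m[ri, ci, drop = FALSE]
}

# integer shift with constant fill (no wrap-around)
shift_matrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dy):min(h, h + dy)
  cs <- max(1, 1 + dx):min(w, w + dx)
  if (dy <= -h || dy >= h || dx <= -w || dx >= w) return(out)
  out[rs, cs] <- m[rs - dy, cs - dx, drop = FALSE]
  out
}

# movie as a T x (H*W) matrix; column (w-1)*H + h holds pixel (h, w)
flatten_stack <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, nrow = d[1])
}

mask_index <- function(mask) which(mask)
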