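#' Read a t-stack from one or more multipage TIFF files
#'
#' Frames are concatenated in the given file order, so several stacks of
#' one field of view become a single ensemble; the join positions are
#' recorded in `file_boundaries`. 8- and 16-bit integer TIFFs load with
#' their values preserved.
#'
#' @param paths ordered character vector of TIFF files.
#' @param frame_rate optional acquisition rate (Hz) to record.
#' @return a [tstack()].
#' @export
read_tstack <- function(paths, frame_rate = NULL) {
  frames <- list()
  bounds <- integer(0)
  bits <- 0L
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (pg in pages) {
      if (length(dim(pg)) > 2) pg <- pg[, , 1]
      if (length(frames) &&
          !identical(dim(pg), dim(frames[[1]])))
        stop("frame size mismatch in ", p, ": ",
             paste(dim(pg), collapse = "x"), " vs ",
             paste(dim(frames[[1]]), collapse = "x"))
      frames[[length(frames) + 1]] <- pg
    }
    bits <- max(bits, attr(pages[[1]], "bits.per.sample") %||% 0L)
    bounds <- c(bounds, length(frames))
  }
  if (!length(frames)) stop("no frames read")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  data <- array(0, dim = c(length(frames), h, w))
  for (t in seq_along(frames)) data[t, , ] <- frames[[t]]
  if (bits == 0L) bits <- if (max(data) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  tstack(data, bit_depth = bits, frame_rate = frame_rate,
         source_paths = paths, file_boundaries = bounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a t-stack as a multipage TIFF
#' @param stack a `TStack` with integer `bit_depth` (8 or 16).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tstack <- function(stack, path) {
  bits <- stack$bit_depth
  if (identical(bits, "float"))
    stop("TIFF output needs an 8- or 16-bit stack; round/rescale first")
  scale <- 2^bits - 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(t) frame_at(stack, t) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Subsampled average-projection TIFF for quick inspection
#'
#' Picks an evenly strided `percent` of the frames, average-projects them,
#' and writes the projection as a single 32-bit float TIFF.
#'
#' @param stack a `TStack`.
#' @param percent percentage of frames to use, in `(0, 100]`.
#' @param path output TIFF file.
#' @return the projection matrix, invisibly.
#' @export
write_subsample_tiff <- function(stack, percent, path) {
  if (percent <= 0 || percent > 100)
    stop("percent must be in (0, 100]")
  T_ <- n_frames(stack)
  n <- max(1L, round(T_ * percent / 100))
  idx <- unique(round(seq(1, T_, length.out = n)))
  proj <- mean_image(stack, idx)
  rng <- max(proj)
  tiff::writeTIFF(proj / max(rng, 1e-12), path, bits.per.sample = 32L)
  invisible(proj)
}

# ---- raw binary movie store ----------------------------------------------

precision_bytes <- c(uint8 = 1L, uint16 = 2L, float64 = 8L)

#' Write a movie as raw binary chunks with a JSON header
#'
#' The movie is stored as uncompressed little-endian raw samples
#' (row-major scanlines within each frame, frames in order), split into
#' chunks of at most `max_file_bytes`. The JSON header records
#' `image_length` (frames), `raw_precision`, `image_size` as
#' `[width, height]`, byte order and chunking, so external viewers can
#' import the raw payload directly.
#'
#' @param stack a `TStack`.
#' @param dir output directory (created if missing).
#' @param max_file_bytes chunk size limit in bytes.
#' @param precision `"uint8"`, `"uint16"` or `"float64"`; default matches
#'   the stack's bit depth.
#' @return paths of the files written, invisibly.
#' @export
write_binary_movie <- function(stack, dir, max_file_bytes = 2^31,
                               precision = NULL) {
  if (is.null(precision))
    precision <- switch(as.character(stack$bit_depth),
                        "8" = "uint8", "16" = "uint16", "float64")
  bytes <- precision_bytes[[precision]]
  d <- dim(stack)
  frame_bytes <- d[2] * d[3] * bytes
  fpc <- floor(max_file_bytes / frame_bytes)
  if (fpc < 1)
    stop("max_file_bytes (", max_file_bytes,
         ") is smaller than one frame (", frame_bytes, " bytes)")
  n_chunks <- ceiling(d[1] / fpc)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chunk_files <- sprintf("movie_%03d.bin", seq_len(n_chunks))
  frames_per_chunk <- integer(n_chunks)
  for (k in seq_len(n_chunks)) {
    idx <- ((k - 1) * fpc + 1):min(k * fpc, d[1])
    frames_per_chunk[k] <- length(idx)
    con <- file(file.path(dir, chunk_files[k]), "wb")
    for (t in idx) {
      v <- as.vector(t(frame_at(stack, t)))  # row-major scanlines
      if (precision == "float64") {
        writeBin(as.double(v), con, size = 8, endian = "little")
      } else {
        v <- as.integer(round(v))
        if (precision == "uint16") v <- ifelse(v > 32767L, v - 65536L, v)
        if (precision == "uint8") v <- ifelse(v > 127L, v - 256L, v)
        writeBin(v, con, size = bytes, endian = "little")
      }
    }
    close(con)
  }
  header <- list(image_length = d[1], raw_precision = precision,
                 image_size = c(d[3], d[2]),   # [width, height]
                 max_file_bytes = max_file_bytes,
                 frames_per_chunk = frames_per_chunk,
                 chunk_files = chunk_files,
                 byte_order = "little", compression = "none",
                 frame_rate = stack$frame_rate)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, c("header.json", chunk_files)))
}

#' Read a raw binary movie written by [write_binary_movie()]
#' @param dir directory holding `header.json` and the chunk files.
#' @return a [tstack()].
#' @export
read_binary_movie <- function(dir) {
  hd <- jsonlite::read_json(file.path(dir, "header.json"),
                            simplifyVector = TRUE)
  w <- hd$image_size[1]; h <- hd$image_size[2]
  bytes <- precision_bytes[[hd$raw_precision]]
  T_ <- hd$image_length
  data <- array(0, dim = c(T_, h, w))
  at <- 0L
  for (k in seq_along(hd$chunk_files)) {
    con <- file(file.path(dir, hd$chunk_files[k]), "rb")
    nv <- hd$frames_per_chunk[k] * h * w
    v <- if (hd$raw_precision == "float64") {
      readBin(con, "double", n = nv, size = 8, endian = "little")
    } else {
      readBin(con, "integer", n = nv, size = bytes, signed = FALSE,
              endian = "little")
    }
    close(con)
    for (t in seq_len(hd$frames_per_chunk[k])) {
      fr <- matrix(v[((t - 1) * h * w + 1):(t * h * w)], h, w, byrow = TRUE)
      data[at + t, , ] <- fr
    }
    at <- at + hd$frames_per_chunk[k]
  }
  bd <- switch(hd$raw_precision, uint8 = 8L, uint16 = 16L, "float")
  tstack(data, bit_depth = bd,
         frame_rate = hd$frame_rate %||% NULL,
         source_paths = file.path(dir, hd$chunk_files))
}

# ---- stimulus tables ------------------------------------------------------

#' Load a stimulus table from framestamp + stampinfo CSV files
#'
#' The framestamp CSV holds one numeric time column (seconds or frame
#' indices); the stampinfo CSV's first column is timekeeping in the same
#' unit, remaining columns are numeric or categorical parameters, possibly
#' at a different sampling rate than the framestamp. Both time columns
#' must be monotone nondecreasing; when `n_timepoints` is declared, the
#' framestamp length must match it.
#'
#' @param framestamp_path,stampinfo_path CSV files with a header row.
#' @param n_timepoints declared trace length, or `NULL` to skip the check.
#' @return a `StimulusTable`.
#' @export
load_stimulus_table <- function(framestamp_path, stampinfo_path,
                                n_timepoints = NULL) {
  fs <- utils::read.csv(framestamp_path)[[1]]
  if (!is.numeric(fs)) stop("framestamp column must be numeric")
  info <- utils::read.csv(stampinfo_path, stringsAsFactors = FALSE)
  if (!is.numeric(info[[1]]))
    stop("stampinfo column 1 must be numeric timekeeping")
  if (is.unsorted(fs)) stop("framestamp is not monotone nondecreasing")
  if (is.unsorted(info[[1]]))
    stop("stampinfo time column is not monotone nondecreasing")
  if (!is.null(n_timepoints) && length(fs) != n_timepoints)
    stop("framestamp length (", length(fs),
         ") does not match the declared trace length (", n_timepoints, ")")
  structure(list(framestamp = fs, stampinfo = info, unit = "as-given"),
            class = "StimulusTable")
}

#' Write a stimulus table as framestamp + stampinfo CSV files
#' @param st a `StimulusTable`.
#' @param framestamp_path,stampinfo_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_stimulus_table <- function(st, framestamp_path, stampinfo_path) {
  utils::write.csv(data.frame(framestamp = st$framestamp),
                   framestamp_path, row.names = FALSE)
  utils::write.csv(st$stampinfo, stampinfo_path, row.names = FALSE)
  invisible(c(framestamp_path, stampinfo_path))
}

# ---- session archives -----------------------------------------------------

#' Save / load a session archive
#'
#' One structured archive per analysis stage (feature maps, trace sets,
#' registration results, turnover results, ...), stored via R's native
#' serialization. Any of the package's result objects round-trips
#' unchanged.
#'
#' @param object any package result object (or named list of them).
#' @param path archive file path (conventionally `.rds`).
#' @return `read_archive` returns the stored object; `write_archive`
#'   returns `path` invisibly.
#' @export
write_archive <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) readRDS(path)
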