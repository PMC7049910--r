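#' Acquisition geometry of a dynamic series
#'
#' Describes the voxel grid and temporal sampling of a DCE-MRI
#' acquisition.  The default values reproduce the clinical protocol the
#' pipeline was designed around: a 256 x 192 in-plane matrix over a 24 cm
#' field of view (0.9375 mm/voxel), 42 slices of 4 mm, and 21 frames
#' (one pre-contrast volume followed by 20 post-injection acquisitions)
#' at a temporal resolution of 73 s, i.e. about 24 min in total.
#'
#' @param n_rows,n_cols,n_slices Integer grid dimensions (voxels).
#' @param in_plane_spacing In-plane voxel size in mm/voxel.
#' @param slice_thickness Slice thickness in mm.
#' @param n_frames Number of time points (volumes).
#' @param frame_interval Time between consecutive frames in seconds.
#' @return An object of class `acq_geometry`.
#' @seealso [phantom_geometry()] for the smaller grid used by the digital
#'   phantom in tests and examples.
#' @export
acquisition_geometry <- function(n_rows = 256L, n_cols = 192L,
                                 n_slices = 42L,
                                 in_plane_spacing = 240 / 256,
                                 slice_thickness = 4,
                                 n_frames = 21L, frame_interval = 73) {
  g <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            n_slices = as.integer(n_slices),
            in_plane_spacing = in_plane_spacing,
            slice_thickness = slice_thickness,
            n_frames = as.integer(n_frames),
            frame_interval = frame_interval)
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be positive and finite", call. = FALSE)
  structure(g, class = "acq_geometry")
}

#' Default phantom geometry
#'
#' A reduced spatial grid (64 x 64 in-plane, 8 slices, 1.5 mm in-plane
#' spacing) that keeps Fourier transforms and disc placement fast while
#' retaining the temporal protocol (21 frames at 73 s) and the 4 mm slice
#' thickness.  The full clinical grid is available through
#' [acquisition_geometry()].
#'
#' @param ... Overrides passed on to [acquisition_geometry()].
#' @return An `acq_geometry` object.
#' @export
phantom_geometry <- function(...) {
  args <- list(n_rows = 64L, n_cols = 64L, n_slices = 8L,
               in_plane_spacing = 1.5, slice_thickness = 4)
  over <- list(...)
  args[names(over)] <- over
  do.call(acquisition_geometry, args)
}

#' Frame acquisition times
#'
#' @param geometry An `acq_geometry`.
#' @param units `"min"` (default) or `"s"`.
#' @return Numeric vector of length `n_frames`, starting at 0.
#' @export
frame_times <- function(geometry, units = c("min", "s")) {
  units <- match.arg(units)
  t_s <- (seq_len(geometry$n_frames) - 1) * geometry$frame_interval
  if (units == "min") t_s / 60 else t_s
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("DCE-MRI acquisition geometry: %d x %d x %d voxels, %d frames\n",
              x$n_rows, x$n_cols, x$n_slices, x$n_frames))
  cat(sprintf("  in-plane %.4f mm, slices %.1f mm, frame interval %.0f s (%.1f min total)\n",
              x$in_plane_spacing, x$slice_thickness, x$frame_interval,
              (x$n_frames - 1) * x$frame_interval / 60))
  invisible(x)
}

#' Construct a dynamic series object
#'
#' Bundles a 4D intensity array (row, col, slice, frame) with its
#' acquisition geometry.
#'
#' @param data 4D numeric array ordered (row, col, slice, frame).
#' @param geometry Matching `acq_geometry`.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(data, geometry) {
  d <- dim(data)
  if (length(d) != 4L)
    stop("`data` must be a 4D array (row, col, slice, frame)", call. = FALSE)
  expect <- c(geometry$n_rows, geometry$n_cols, geometry$n_slices,
              geometry$n_frames)
  if (!all(d == expect))
    stop(sprintf("data dimensions (%s) do not match geometry (%s)",
                 paste(d, collapse = "x"), paste(expect, collapse = "x")),
         call. = FALSE)
  structure(list(data = data, geometry = geometry), class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat("Dynamic contrast-enhanced series\n")
  print(x$geometry)
  invisible(x)
}
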