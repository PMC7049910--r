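#' Embed a region into a zero-padded cube
#'
#' Places the voxels of a region unit, with their relative spatial
#' arrangement preserved, into an `N x N x N` cube of zeros (the
#' bounding box is centred in the cube).  The cube is the input volume
#' of the 3D discrete Fourier transform.
#'
#' @param values Numeric vector of voxel intensities.
#' @param coords Integer matrix with columns `row`, `col`, `slice`
#'   (0-based), one row per voxel.
#' @param cube_side Cube side `N` (>= 2).
#' @return `N x N x N` numeric array with the region voxels placed and
#'   zeros elsewhere.
#' @export
embed_region <- function(values, coords, cube_side) {
  stopifnot(length(values) == nrow(coords), cube_side >= 2)
  N <- as.integer(cube_side)
  xyz <- coords[, c("row", "col", "slice"), drop = FALSE]
  lo <- apply(xyz, 2, min)
  extent <- apply(xyz, 2, max) - lo + 1L
  if (any(extent > N))
    stop(sprintf("region bounding box (%s) exceeds cube side %d",
                 paste(extent, collapse = "x"), N), call. = FALSE)
  off <- floor((N - extent) / 2) - lo + 1L   # to 1-based cube indices
  cube <- array(0, c(N, N, N))
  cube[cbind(xyz[, 1L] + off[1L], xyz[, 2L] + off[2L],
             xyz[, 3L] + off[3L])] <- values
  cube
}

#' Magnitude of the 3D discrete Fourier transform
#'
#' `|F(u,v,w)| = |sum_{i,j,k} I(i,j,k) exp(-2 pi i (ui + vj + wk)/N)|`
#' for a cubic volume `I` of side `N`.
#'
#' @param cube Cubic numeric array.
#' @return Numeric array of the same dimension holding `|F|` with the DC
#'   component at index (1, 1, 1) (unshifted FFT layout).
#' @export
dft3_magnitude <- function(cube) {
  d <- dim(cube)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("input must be a cubic 3D array", call. = FALSE)
  Mod(stats::fft(cube))
}

# signed centred frequency offsets for an unshifted FFT axis of length N
centered_freq <- function(N) {
  k <- 0:(N - 1)
  ifelse(k > N / 2, k - N, k)
}

#' Radially averaged spectrum
#'
#' Averages a 3D magnitude spectrum over concentric rings of width one:
#' the value at ring `r` is the mean of `|F|` over the frequency voxels
#' whose centred radius `sqrt(u^2 + v^2 + w^2)` rounds to `r`.  Rings
#' run from 0 to `floor(N/2) - 1` (the Nyquist limit); rings with no
#' members are 0.
#'
#' @param mag Cubic array of spectral magnitudes in unshifted FFT
#'   layout, as returned by [dft3_magnitude()].
#' @return Numeric vector of length `floor(N/2)` with names `r0`,
#'   `r1`, ...
#' @export
radial_average <- function(mag) {
  d <- dim(mag)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("input must be a cubic 3D array", call. = FALSE)
  N <- d[1L]
  n_bins <- N %/% 2L
  f <- centered_freq(N)
  m2d <- outer(f^2, f^2, "+")
  sums <- numeric(n_bins); counts <- numeric(n_bins)
  for (w in seq_len(N)) {
    ring <- as.integer(round(sqrt(m2d + f[w]^2))) + 1L
    keep <- ring <= n_bins
    idx <- ring[keep]
    s <- rowsum(mag[, , w][keep], idx)
    sums[as.integer(rownames(s))] <- sums[as.integer(rownames(s))] + s[, 1L]
    counts <- counts + tabulate(idx, nbins = n_bins)
  }
  out <- ifelse(counts > 0, sums / counts, 0)
  names(out) <- paste0("r", seq_len(n_bins) - 1L)
  out
}

#' Number of radial spectrum bins for a cube side
#'
#' @param cube_side Cube side `N`.
#' @return `floor(N/2)`; 128 for the clinical 256 matrix.
#' @export
n_rps_bins <- function(cube_side) as.integer(cube_side) %/% 2L

#' Radial power spectrum trajectory of a region unit
#'
#' For every frame, embeds the unit's voxels in a zero cube, takes the
#' 3D DFT magnitude and ring-averages it, yielding a
#' `floor(cube_side/2) x n_frames` descriptor trajectory.
#'
#' @param series A `dce_series`.
#' @param template A `sampling_template`.
#' @param tier,tissue The region unit.
#' @param cube_side DFT cube side; 256 reproduces the clinical matrix
#'   (128 rings), 64 is the fast default for the phantom grid.
#' @return Numeric matrix (rings x frames) of class
#'   `descriptor_trajectory` with attribute `descriptor = "RPS"`.
#' @export
rps_trajectory <- function(series, template, tier, tissue,
                           cube_side = 64L) {
  stack <- extract_region_stack(series, template, tier, tissue)
  rps_trajectory_from_stack(stack, cube_side)
}

#' @rdname rps_trajectory
#' @param stack A `region_stack` from [extract_region_stack()].
#' @export
rps_trajectory_from_stack <- function(stack, cube_side = 64L) {
  n_t <- ncol(stack$values)
  out <- vapply(seq_len(n_t), function(f) {
    cube <- embed_region(stack$values[, f], stack$coords, cube_side)
    radial_average(dft3_magnitude(cube))
  }, numeric(n_rps_bins(cube_side)))
  descriptor_trajectory(matrix(out, nrow = n_rps_bins(cube_side)), "RPS")
}

# light wrapper marking a D x T feature-by-frame matrix
descriptor_trajectory <- function(m, descriptor) {
  structure(m, descriptor = descriptor, class = c("descriptor_trajectory",
                                                  class(m)))
}
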