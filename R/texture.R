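#' Quantise intensities to grey levels
#'
#' Linear binning of `[min, max]` into `L` equal-width bins (the maximum
#' maps to level `L - 1`).  For dynamic descriptors the bounds are taken
#' over the unit's *entire* time series, so that enhancement shifts the
#' occupied levels over time instead of being normalised away.
#'
#' @param values Numeric vector or matrix (voxels x frames).
#' @param L Number of grey levels (default `2^4`).
#' @param range Optional `c(min, max)` bounds; defaults to the range of
#'   `values`.
#' @return Integer object shaped like `values` with levels in
#'   `0:(L-1)`.  A degenerate (constant) range maps everything to 0.
#' @export
quantize_levels <- function(values, L = 16L, range = NULL) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) {
    lv <- values; lv[] <- 0L; storage.mode(lv) <- "integer"
    return(lv)
  }
  lv <- floor((values - lo) / (hi - lo) * L)
  lv[lv >= L] <- L - 1L
  lv[lv < 0L] <- 0L
  storage.mode(lv) <- "integer"
  lv
}

# 8-connected neighbour offsets (drow, dcol) in the fixed order
# E, NE, N, NW, W, SW, S, SE (rows grow downwards)
lbp_offsets <- function() {
  cbind(drow = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
        dcol = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))
}

#' Grey-level co-occurrence matrix of a region unit
#'
#' Counts co-occurrences of quantised levels over all 8-connected
#' in-plane voxel pairs lying within the *same* circular sample
#' (tissue-pure pairs), accumulated over the unit's discs.  Both
#' orderings of each pair are counted, so the matrix is symmetric by
#' construction; it is then normalised by the total number of pairs.
#'
#' @param levels Integer vector of grey levels (0-based), one per voxel.
#' @param coords Voxel coordinate matrix with columns `row`, `col` and
#'   `sample` (disc id), as produced by the template extraction.
#' @param L Number of grey levels.
#' @param normalise Divide by the total pair count (default `TRUE`).
#' @return `L x L` matrix of class `cooc_matrix` with attribute
#'   `normalised`.
#' @export
glcm <- function(levels, coords, L = 16L, normalise = TRUE) {
  stopifnot(length(levels) == nrow(coords))
  off <- lbp_offsets()
  counts <- numeric(L * L)
  for (sid in unique(coords[, "sample"])) {
    sel <- coords[, "sample"] == sid
    r <- coords[sel, "row"]; c <- coords[sel, "col"]
    lv <- levels[sel]
    K <- max(c(r, c)) + 2L
    key <- r * K + c
    for (o in seq_len(nrow(off))) {
      m <- match((r + off[o, 1L]) * K + (c + off[o, 2L]), key)
      ok <- !is.na(m)
      if (any(ok))
        counts <- counts + tabulate(lv[ok] * L + lv[m[ok]] + 1L,
                                    nbins = L * L)
    }
  }
  tot <- sum(counts)
  if (tot == 0)
    stop("degenerate unit: no 8-connected voxel pairs within a disc",
         call. = FALSE)
  C <- matrix(counts, L, L)
  if (normalise) C <- C / tot
  structure(C, normalised = normalise, class = c("cooc_matrix", "matrix",
                                                 "array"))
}

#' Haralick features of a normalised co-occurrence matrix
#'
#' The nine classical summaries: contrast, correlation, energy,
#' variance, entropy, inverse difference moment, sum average, sum
#' entropy and sum variance.  Logarithms are natural with the
#' `0 * log 0 = 0` convention; correlation is defined as 1 when either
#' marginal is degenerate.  The inverse difference moment uses the
#' standard `1 + (a-b)^2` denominator; `idm_printed_form = TRUE`
#' switches to a `1 + (a+b)^2` variant found in some tabulations.
#'
#' @param C Normalised `cooc_matrix` (entries sum to 1).
#' @param idm_printed_form Use the `(a+b)^2` denominator variant.
#' @return Named numeric vector of length 9.
#' @export
haralick_features <- function(C, idm_printed_form = FALSE) {
  if (!isTRUE(attr(C, "normalised")) || abs(sum(C) - 1) > 1e-8)
    stop("haralick_features() requires a normalised co-occurrence matrix",
         call. = FALSE)
  L <- nrow(C)
  a <- matrix(0:(L - 1), L, L)        # row level
  b <- t(a)                           # col level
  pa <- rowSums(C); pb <- colSums(C)
  lv <- 0:(L - 1)
  mu_a <- sum(lv * pa); mu_b <- sum(lv * pb)
  s_a <- sqrt(sum((lv - mu_a)^2 * pa)); s_b <- sqrt(sum((lv - mu_b)^2 * pb))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  corr <- if (s_a * s_b > 0)
    sum((a - mu_a) * (b - mu_b) * C) / (s_a * s_b) else 1
  idm_den <- if (idm_printed_form) 1 + (a + b)^2 else 1 + (a - b)^2
  # grey-level sum distribution over c = a + b in 0 .. 2L-2
  cs <- 0:(2 * L - 2)
  Pc <- vapply(cs, function(k) sum(C[a + b == k]), 0)
  SA <- sum(cs * Pc)
  c(contrast      = sum((a - b)^2 * C),
    correlation   = corr,
    energy        = sum(C^2),
    variance      = sum((lv - mu_a)^2 * pa),
    entropy       = -sum(xlogx(C)),
    idm           = sum(C / idm_den),
    sum_average   = SA,
    sum_entropy   = -sum(xlogx(Pc)),
    sum_variance  = sum((cs - SA)^2 * Pc))
}

#' Local binary pattern codes of region voxels
#'
#' For each region voxel whose full 8-neighbourhood (at the given
#' radius, in voxels) lies inside the image, compares the centre with
#' its neighbours in the fixed order E, NE, N, NW, W, SW, S, SE and sets
#' bit `p` (weight `2^p`, p = 0 for E) when the neighbour is *strictly
#' below* the centre.  A centre of 4 with neighbours 1..8 therefore
#' yields bits 1,1,1,0,0,0,0,0 (code 7).  Neighbours may lie outside
#' the region's discs: codes are centred on region voxels but read the
#' surrounding image.
#'
#' @param frame 3D numeric array (row, col, slice): one time point.
#' @param coords Voxel coordinates (`row`, `col`, `slice`; 0-based).
#' @param radius Neighbourhood radius in voxels (default 1).
#' @return Integer vector of codes in `0:255`, one per retained voxel,
#'   with attribute `n_excluded` counting border voxels dropped (a
#'   warning is raised when any are).
#' @export
lbp_codes <- function(frame, coords, radius = 1L) {
  nr <- dim(frame)[1L]; nc <- dim(frame)[2L]
  r <- coords[, "row"]; c <- coords[, "col"]; s <- coords[, "slice"]
  inside <- r - radius >= 0L & r + radius < nr &
    c - radius >= 0L & c + radius < nc
  n_excl <- sum(!inside)
  if (n_excl > 0L)
    warning(sprintf("%d voxel(s) without a full neighbourhood excluded",
                    n_excl), call. = FALSE)
  r <- r[inside]; c <- c[inside]; s <- s[inside]
  centre <- frame[cbind(r + 1L, c + 1L, s + 1L)]
  code <- integer(length(centre))
  off <- lbp_offsets() * radius
  for (p in seq_len(8L)) {
    nb <- frame[cbind(r + off[p, 1L] + 1L, c + off[p, 2L] + 1L, s + 1L)]
    code <- code + as.integer(nb < centre) * 2L^(p - 1L)
  }
  structure(code, n_excluded = n_excl)
}

# number of circular 0<->1 transitions of an 8-bit code
lbp_transitions <- function(code) {
  bits <- t(vapply(code, function(x) as.integer(intToBits(x))[1:8],
                   integer(8L)))
  rowSums(bits != bits[, c(2:8, 1), drop = FALSE])
}

# lookup tables: u2 bin (1..59) and riu2 class (0..8 uniform, NA other)
lbp_tables <- function() {
  if (is.null(.dcedyn_cache$lbp)) {
    codes <- 0:255
    tr <- lbp_transitions(codes)
    uniform <- tr <= 2L
    u2 <- integer(256L)
    u2[uniform] <- seq_len(sum(uniform))          # 58 own bins, ascending
    u2[!uniform] <- sum(uniform) + 1L             # pooled bin 59
    ones <- vapply(codes, function(x) sum(as.integer(intToBits(x))[1:8]),
                   integer(1L))
    riu2 <- ifelse(uniform, ones, NA_integer_)
    .dcedyn_cache$lbp <- list(u2 = u2, riu2 = riu2, uniform = uniform)
  }
  .dcedyn_cache$lbp
}

#' Uniform local binary pattern histogram
#'
#' Maps the 256 raw codes through the "uniform-2" table: each of the 58
#' codes with at most two circular 0/1 transitions keeps its own bin
#' (ascending code order) and all remaining codes share one pooled bin,
#' giving 59 bins.  The histogram is normalised to sum to one.
#'
#' @param codes Integer LBP codes in `0:255`.
#' @return Named numeric vector of length 59 summing to 1.
#' @export
ulbp_histogram <- function(codes) {
  if (length(codes) == 0L) stop("empty code vector", call. = FALSE)
  tab <- lbp_tables()
  h <- tabulate(tab$u2[codes + 1L], nbins = 59L)
  names(h) <- c(paste0("ulbp_", sprintf("%03d", which(tab$uniform) - 1L)),
                "ulbp_other")
  h / sum(h)
}

#' Local configuration pattern features
#'
#' Combines rotation-invariant pattern statistics with local
#' configuration coefficients.  Codes are pooled into the nine uniform
#' rotation-invariant classes (0 to 8 set bits).  For each class the
#' descriptor records (i) the class occurrence frequency and (ii) the
#' magnitudes of the discrete Fourier transform of the eight
#' least-squares weights that best reconstruct the centre intensity
#' from its eight neighbours over the class's voxels (taking
#' magnitudes makes the configuration block invariant to rotations of
#' the neighbour ring).  9 classes x (1 + 8) values = 81 features.
#' Rank-deficient normal equations are ridge-regularised with
#' `eps = 1e-8 * mean(diag(X'X))`; empty classes yield zeros.
#'
#' @param frame 3D numeric array (row, col, slice): one time point.
#' @param coords Voxel coordinates (`row`, `col`, `slice`; 0-based).
#' @param radius Neighbourhood radius in voxels.
#' @return Named numeric vector `lcp_000` ... `lcp_080`.
#' @export
lcp_features <- function(frame, coords, radius = 1L) {
  nr <- dim(frame)[1L]; nc <- dim(frame)[2L]
  r <- coords[, "row"]; c <- coords[, "col"]; s <- coords[, "slice"]
  inside <- r - radius >= 0L & r + radius < nr &
    c - radius >= 0L & c + radius < nc
  r <- r[inside]; c <- c[inside]; s <- s[inside]
  if (length(r) == 0L) stop("no voxels with full neighbourhoods",
                            call. = FALSE)
  centre <- frame[cbind(r + 1L, c + 1L, s + 1L)]
  off <- lbp_offsets() * radius
  nbrs <- vapply(seq_len(8L), function(p)
    frame[cbind(r + off[p, 1L] + 1L, c + off[p, 2L] + 1L, s + 1L)],
    numeric(length(r)))
  nbrs <- matrix(nbrs, ncol = 8L)
  code <- integer(length(centre))
  for (p in seq_len(8L))
    code <- code + as.integer(nbrs[, p] < centre) * 2L^(p - 1L)
  cls <- lbp_tables()$riu2[code + 1L]
  out <- numeric(0)
  for (k in 0:8) {
    sel <- !is.na(cls) & cls == k
    occ <- sum(sel) / length(cls)
    if (any(sel)) {
      X <- nbrs[sel, , drop = FALSE]; y <- centre[sel]
      XtX <- crossprod(X); Xty <- crossprod(X, y)
      w <- tryCatch({
        if (rcond(XtX) < 1e-12) stop("ill-conditioned")
        solve(XtX, Xty)
      }, error = function(e) {
        eps <- 1e-8 * mean(diag(XtX)) + 1e-12
        solve(XtX + diag(eps, 8L), Xty)
      })
      mags <- Mod(stats::fft(as.numeric(w)))
    } else mags <- numeric(8L)
    out <- c(out, occ, mags)
  }
  names(out) <- paste0("lcp_", sprintf("%03d", 0:80))
  out
}

#' Texture descriptor trajectories of a region unit
#'
#' Computes, per frame, the GLCM/Haralick vector (9 x T), the uniform
#' LBP histogram (59 x T) and the local configuration pattern vector
#' (81 x T) for one region unit.  Grey-level quantisation bounds are
#' global over the unit's full time series.
#'
#' @param series A `dce_series`.
#' @param template A `sampling_template`.
#' @param tier,tissue The region unit.
#' @param grey_levels Grey levels for the GLCM (default 16).
#' @param lbp_radius LBP/LCP neighbourhood radius in voxels.
#' @param idm_printed_form Passed to [haralick_features()].
#' @return Named list with `GLCM`, `ULBP` and `LCP` descriptor
#'   trajectories (features x frames).
#' @export
texture_trajectories <- function(series, template, tier, tissue,
                                 grey_levels = 16L, lbp_radius = 1L,
                                 idm_printed_form = FALSE) {
  stack <- extract_region_stack(series, template, tier, tissue)
  n_t <- ncol(stack$values)
  levels <- quantize_levels(stack$values, L = grey_levels)
  gl <- vapply(seq_len(n_t), function(f)
    haralick_features(glcm(levels[, f], stack$coords, L = grey_levels),
                      idm_printed_form = idm_printed_form),
    numeric(9L))
  vol <- series$geometry$n_rows * series$geometry$n_cols *
    series$geometry$n_slices
  ul <- matrix(0, 59L, n_t)
  lc <- matrix(0, 81L, n_t)
  for (f in seq_len(n_t)) {
    frame <- array(series$data[seq_len(vol) + (f - 1L) * vol],
                   dim = dim(series$data)[1:3])
    codes <- suppressWarnings(lbp_codes(frame, stack$coords,
                                        radius = lbp_radius))
    ul[, f] <- ulbp_histogram(codes)
    lc[, f] <- lcp_features(frame, stack$coords, radius = lbp_radius)
  }
  gl <- matrix(gl, nrow = 9L)
  rownames(gl) <- paste0("glcm_", c("contrast", "correlation", "energy",
                                    "variance", "entropy", "idm",
                                    "sum_average", "sum_entropy",
                                    "sum_variance"))
  rownames(ul) <- names(ulbp_histogram(0L))
  rownames(lc) <- paste0("lcp_", sprintf("%03d", 0:80))
  list(GLCM = descriptor_trajectory(gl, "GLCM"),
       ULBP = descriptor_trajectory(ul, "ULBP"),
       LCP = descriptor_trajectory(lc, "LCP"))
}
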