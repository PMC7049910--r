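#' Default sampling plan
#'
#' Per-tier, per-tissue counts of circular samples: three vessel samples
#' (carotids, basilar artery, sagittal sinus) on the low slice; sinus,
#' 12 CSF, 12 deep GM, 12 cortical GM and 10 WM samples on the
#' low-middle slice; sinus, 8 CSF, 6 cortical GM and 28 WM on the
#' middle-high slice; and sinus, 6 cortical GM and 28 WM on the high
#' slice.
#'
#' @return A data.frame with columns `tier`, `tissue`, `n`.
#' @export
default_sampling_plan <- function() {
  plan <- rbind(
    data.frame(tier = "low", tissue = "BL", n = 3L),
    data.frame(tier = "low-middle",
               tissue = c("BL", "CSF", "GMD", "GMC", "WM"),
               n = c(1L, 12L, 12L, 12L, 10L)),
    data.frame(tier = "middle-high",
               tissue = c("BL", "CSF", "GMC", "WM"),
               n = c(1L, 8L, 6L, 28L)),
    data.frame(tier = "high",
               tissue = c("BL", "GMC", "WM"),
               n = c(1L, 6L, 28L))
  )
  plan$tier <- factor(plan$tier, levels = SLICE_TIERS)
  plan[order(plan$tier, match(plan$tissue, names(TISSUES))), ]
}

#' Default tier-to-slice assignment
#'
#' Slice tiers are template metadata, not detected anatomy: this helper
#' spreads the four tiers evenly across the slice stack (0-based
#' indices).
#'
#' @param geometry An `acq_geometry`.
#' @return Named integer vector over [SLICE_TIERS].
#' @export
default_tier_slices <- function(geometry) {
  idx <- as.integer(floor(geometry$n_slices * c(1, 3, 5, 7) / 8))
  stats::setNames(pmin(idx, geometry$n_slices - 1L), SLICE_TIERS)
}

#' Default sample radius
#'
#' Radius (mm) such that the disc area is 12 mm^2.
#' @return `sqrt(12 / pi)`, about 1.954 mm.
#' @export
default_sample_radius <- function() sqrt(12 / pi)

#' Rasterise a circular sample
#'
#' A voxel belongs to the disc iff the Euclidean distance from its
#' centre to the disc centre, in mm using the in-plane spacing, is at
#' most the radius.  Coordinates are 0-based voxel indices.
#'
#' @param center_row,center_col Disc centre (0-based voxel units).
#' @param radius_mm Disc radius in mm.
#' @param spacing In-plane voxel spacing in mm.
#' @return Two-column integer matrix of (row, col) voxel indices,
#'   ordered row-major (row, then col).
#' @export
disc_voxels <- function(center_row, center_col, radius_mm, spacing) {
  rv <- radius_mm / spacing
  rows <- seq.int(floor(center_row - rv), ceiling(center_row + rv))
  cols <- seq.int(floor(center_col - rv), ceiling(center_col + rv))
  grid <- expand.grid(col = cols, row = rows)   # row-major ordering
  keep <- (grid$row - center_row)^2 + (grid$col - center_col)^2 <= rv^2
  cbind(row = as.integer(grid$row[keep]), col = as.integer(grid$col[keep]))
}

#' Build a circular sampling template
#'
#' Places the requested number of non-overlapping circular samples per
#' slice tier and tissue by seeded rejection sampling over the voxels
#' carrying the tissue label on the tier's slice.  A candidate centre is
#' accepted when every voxel of the rasterised disc lies inside the
#' image, carries the sample's tissue label, avoids the exclusion mask,
#' and the disc (as a continuous circle) does not overlap any
#' previously accepted disc on the same slice.
#'
#' @param label_map Integer 3D array of [TISSUES] codes (0 background).
#' @param geometry An `acq_geometry` consistent with `label_map`.
#' @param plan Sampling plan data.frame (`tier`, `tissue`, `n`);
#'   defaults to [default_sampling_plan()].
#' @param tier_slices Named 0-based slice index per tier.
#' @param exclusion_mask Optional logical/0-1 3D array of voxels to
#'   avoid (e.g. lesions or partial-volume borders).
#' @param radius_mm Disc radius; default gives 12 mm^2 discs.
#' @param seed Integer seed making the placement reproducible.
#' @return An object of class `sampling_template`: a list with
#'   `samples` (data.frame `tier`, `slice_index`, `center_row`,
#'   `center_col`, `radius_mm`, `tissue`) and `geometry`.
#' @export
build_template <- function(label_map, geometry,
                           plan = default_sampling_plan(),
                           tier_slices = default_tier_slices(geometry),
                           exclusion_mask = NULL,
                           radius_mm = default_sample_radius(),
                           seed = NULL) {
  stopifnot(all(dim(label_map) == c(geometry$n_rows, geometry$n_cols,
                                    geometry$n_slices)))
  if (any(plan$n < 0)) stop("sample counts must be >= 0", call. = FALSE)
  spacing <- geometry$in_plane_spacing
  nr <- geometry$n_rows; nc <- geometry$n_cols
  with_seed(seed, {
    placed <- list()
    for (i in seq_len(nrow(plan))) {
      tier <- as.character(plan$tier[i]); tissue <- plan$tissue[i]
      n_want <- plan$n[i]
      if (n_want == 0L) next
      slice <- tier_slices[[tier]]
      sl <- label_map[, , slice + 1L]
      cand <- which(sl == TISSUES[[tissue]], arr.ind = TRUE) - 1L
      if (nrow(cand) == 0L)
        stop(sprintf("no '%s' voxels on the '%s' slice", tissue, tier),
             call. = FALSE)
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      same_slice <- Filter(function(s) s$slice == slice, placed)
      got <- 0L; j <- 1L
      while (got < n_want && j <= nrow(cand)) {
        cr <- cand[j, 1L]; cc <- cand[j, 2L]; j <- j + 1L
        vox <- disc_voxels(cr, cc, radius_mm, spacing)
        if (any(vox[, 1L] < 0L | vox[, 1L] >= nr |
                vox[, 2L] < 0L | vox[, 2L] >= nc)) next
        lidx <- cbind(vox[, 1L] + 1L, vox[, 2L] + 1L)
        if (any(sl[lidx] != TISSUES[[tissue]])) next
        if (!is.null(exclusion_mask) &&
            any(exclusion_mask[, , slice + 1L][lidx] != 0)) next
        ok <- TRUE
        for (s in same_slice) {
          if (spacing * sqrt((cr - s$row)^2 + (cc - s$col)^2) <
              s$radius + radius_mm) { ok <- FALSE; break }
        }
        if (!ok) next
        rec <- list(tier = tier, slice = slice, row = cr, col = cc,
                    radius = radius_mm, tissue = tissue)
        placed[[length(placed) + 1L]] <- rec
        same_slice[[length(same_slice) + 1L]] <- rec
        got <- got + 1L
      }
      if (got < n_want)
        stop(sprintf(
          "could not place %d '%s' samples on the '%s' slice (placed %d)",
          n_want, tissue, tier, got), call. = FALSE)
    }
    samples <- do.call(rbind, lapply(placed, function(s)
      data.frame(tier = s$tier, slice_index = s$slice,
                 center_row = s$row, center_col = s$col,
                 radius_mm = s$radius, tissue = s$tissue,
                 stringsAsFactors = FALSE)))
    if (is.null(samples))
      samples <- data.frame(tier = character(), slice_index = integer(),
                            center_row = numeric(), center_col = numeric(),
                            radius_mm = numeric(), tissue = character(),
                            stringsAsFactors = FALSE)
    structure(list(samples = samples, geometry = geometry),
              class = "sampling_template")
  })
}

#' @export
print.sampling_template <- function(x, ...) {
  cat(sprintf("Sampling template: %d circular samples (radius %.3f mm)\n",
              nrow(x$samples),
              if (nrow(x$samples)) x$samples$radius_mm[1] else NA))
  if (nrow(x$samples))
    print(table(tier = factor(x$samples$tier, levels = SLICE_TIERS),
                tissue = factor(x$samples$tissue, levels = names(TISSUES))))
  invisible(x)
}

#' Region units of a template
#'
#' A region unit is a (tissue, slice tier) combination; descriptors and
#' statistics are computed at this granularity.  Units are derived from
#' the tissues actually present in each tier of the template; with the
#' default plan this yields 13 units.
#'
#' @param template A `sampling_template`.
#' @return Data.frame with columns `tier`, `tissue`, `n_samples`.
#' @export
region_units <- function(template) {
  s <- template$samples
  if (nrow(s) == 0L)
    return(data.frame(tier = character(), tissue = character(),
                      n_samples = integer()))
  agg <- stats::aggregate(list(n_samples = rep(1L, nrow(s))),
                          by = list(tier = s$tier, tissue = s$tissue),
                          FUN = sum)
  agg <- agg[order(factor(agg$tier, levels = SLICE_TIERS),
                   match(agg$tissue, names(TISSUES))), ]
  rownames(agg) <- NULL
  agg
}

# voxel coordinates (row, col, slice; 0-based) of all discs of a unit,
# in stable order: template row order, then row-major within each disc
unit_voxels <- function(template, tier, tissue) {
  s <- template$samples
  sel <- s$tier == tier & s$tissue == tissue
  if (!any(sel))
    stop(sprintf("unit (%s, %s) not present in template", tissue, tier),
         call. = FALSE)
  spacing <- template$geometry$in_plane_spacing
  out <- lapply(which(sel), function(i) {
    v <- disc_voxels(s$center_row[i], s$center_col[i], s$radius_mm[i],
                     spacing)
    cbind(v, slice = rep(s$slice_index[i], nrow(v)),
          sample = rep(i, nrow(v)))
  })
  do.call(rbind, out)
}

#' Extract the voxel stack of a region unit over time
#'
#' Collects the intensities of every voxel belonging to the unit's
#' discs, in a stable order, for each frame.
#'
#' @param series A `dce_series`.
#' @param template A `sampling_template` built on the same geometry.
#' @param tier,tissue The region unit.
#' @return An object of class `region_stack`: list with `values`
#'   (n_voxels x n_frames matrix), `coords` (0-based row/col/slice with
#'   the originating sample index) and `tier`, `tissue`.
#' @export
extract_region_stack <- function(series, template, tier, tissue) {
  g <- series$geometry; gt <- template$geometry
  if (g$n_rows != gt$n_rows || g$n_cols != gt$n_cols ||
      g$n_slices != gt$n_slices)
    stop("template geometry does not match the series", call. = FALSE)
  vox <- unit_voxels(template, tier, tissue)
  nrnc <- g$n_rows * g$n_cols
  lin <- (vox[, "row"] + 1L) + g$n_rows * vox[, "col"] +
    nrnc * vox[, "slice"]
  vol <- nrnc * g$n_slices
  vals <- vapply(seq_len(g$n_frames),
                 function(f) series$data[lin + (f - 1L) * vol],
                 numeric(length(lin)))
  structure(list(values = matrix(vals, nrow = length(lin)),
                 coords = vox, tier = tier, tissue = tissue),
            class = "region_stack")
}

#' Write / read a sampling template as JSON
#'
#' The JSON round-trip is lossless: fields `tier`, `slice_index`,
#' `center_row`, `center_col`, `radius_mm`, `tissue` plus the geometry.
#'
#' @param template A `sampling_template`.
#' @param path File path.
#' @return `write_template` invisibly returns `path`;
#'   `read_template` returns the `sampling_template`.
#' @export
write_template <- function(template, path) {
  jsonlite::write_json(list(samples = template$samples,
                            geometry = unclass(template$geometry)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(acquisition_geometry, as.list(x$geometry))
  samples <- as.data.frame(x$samples, stringsAsFactors = FALSE)
  samples$slice_index <- as.integer(samples$slice_index)
  structure(list(samples = samples, geometry = g),
            class = "sampling_template")
}

#' Render a template as an integer mask
#'
#' For visual inspection: voxels of sample `i` get value `i`, others 0.
#'
#' @param template A `sampling_template`.
#' @return Integer 3D array matching the template geometry.
#' @export
template_mask <- function(template) {
  g <- template$geometry
  m <- array(0L, c(g$n_rows, g$n_cols, g$n_slices))
  s <- template$samples
  for (i in seq_len(nrow(s))) {
    v <- disc_voxels(s$center_row[i], s$center_col[i], s$radius_mm[i],
                     g$in_plane_spacing)
    m[cbind(v[, 1L] + 1L, v[, 2L] + 1L, s$slice_index[i] + 1L)] <- i
  }
  m
}
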