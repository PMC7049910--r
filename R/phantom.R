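#' Cohort covariate model
#'
#' Marginal distributions for the synthetic cohort generator.  The
#' defaults reproduce the published distribution of a 42-patient mild
#' stroke cohort with small vessel disease (SVD) features: age binned in
#' decades between 39 and 89 years, 71% male, 79% hypertensive, white
#' matter hyperintensity (WMH) volume between 0.07% and 8.73% of
#' intracranial volume, a total SVD score of 0-4, and 19/42 lacunar
#' (vs cortical) index strokes.  The total SVD score is coupled to WMH
#' burden through a Gaussian copula with configurable Spearman rank
#' correlation, since WMH burden is one of the features the score counts.
#'
#' @param age_breaks,age_probs Age bin edges (years) and bin
#'   probabilities.
#' @param male_prop Proportion of male subjects.
#' @param hypertension_prop Proportion of hypertensive subjects.
#' @param wmh_breaks,wmh_probs WMH volume fraction bin edges (% of
#'   intracranial volume) and bin probabilities.
#' @param svd_probs Probabilities of total SVD scores 0, 1, 2, 3, 4.
#' @param lacunar_prop Proportion of lacunar index strokes.
#' @param svd_wmh_rho Spearman rank correlation between WMH fraction and
#'   total SVD score.
#' @return A list of class `covariate_model`.
#' @export
covariate_model <- function(age_breaks = c(39, 49, 59, 69, 79, 89),
                            age_probs = c(2, 11, 15, 11, 3) / 42,
                            male_prop = 30 / 42,
                            hypertension_prop = 33 / 42,
                            wmh_breaks = c(0.07, 1.80, 3.53, 5.26, 6.99, 8.73),
                            wmh_probs = c(23, 6, 7, 2, 4) / 42,
                            svd_probs = c(8, 10, 12, 7, 5) / 42,
                            lacunar_prop = 19 / 42,
                            svd_wmh_rho = 0.6) {
  m <- list(age_breaks = age_breaks, age_probs = age_probs / sum(age_probs),
            male_prop = male_prop, hypertension_prop = hypertension_prop,
            wmh_breaks = wmh_breaks, wmh_probs = wmh_probs / sum(wmh_probs),
            svd_probs = svd_probs / sum(svd_probs),
            lacunar_prop = lacunar_prop, svd_wmh_rho = svd_wmh_rho)
  stopifnot(length(m$age_breaks) == length(m$age_probs) + 1L,
            length(m$wmh_breaks) == length(m$wmh_probs) + 1L,
            length(m$svd_probs) == 5L)
  class(m) <- "covariate_model"
  m
}

# inverse CDF of a piecewise-uniform distribution given bin edges and probs
q_piecewise <- function(u, breaks, probs) {
  cum <- c(0, cumsum(probs))
  cum[length(cum)] <- 1
  bin <- pmin(pmax(findInterval(u, cum, rightmost.closed = TRUE), 1L),
              length(probs))
  frac <- (u - cum[bin]) / probs[bin]
  breaks[bin] + frac * (breaks[bin + 1L] - breaks[bin])
}

#' Generate synthetic cohort covariates
#'
#' Draws a reproducible per-subject covariate table whose marginal
#' distributions follow the configured cohort model.  Continuous
#' variables (age, WMH fraction) are piecewise-uniform within the
#' configured bins; the total SVD score is drawn jointly with the WMH
#' fraction through a Gaussian copula so the two are rank-correlated.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param seed Integer seed; the same seed yields an identical table.
#' @param model A [covariate_model()].
#' @return A data.frame with columns `subject_id`, `age`, `sex`
#'   (`"male"`/`"female"`), `hypertensive` (logical), `wmh_fraction`
#'   (% of intracranial volume), `svd_score` (integer 0-4) and `lacunar`
#'   (logical; `FALSE` codes a cortical index stroke).
#' @export
generate_covariates <- function(n_subjects, seed = NULL,
                                model = covariate_model()) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      is.na(n_subjects) || n_subjects < 0)
    stop("`n_subjects` must be a non-negative integer", call. = FALSE)
  n <- as.integer(n_subjects)
  empty <- data.frame(subject_id = character(), age = numeric(),
                      sex = character(), hypertensive = logical(),
                      wmh_fraction = numeric(), svd_score = integer(),
                      lacunar = logical(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  with_seed(seed, {
    # Gaussian copula linking WMH burden and SVD score; the latent
    # normal correlation that realises a Spearman rho is 2*sin(pi*rho/6)
    r <- 2 * sin(pi * model$svd_wmh_rho / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    u_wmh <- stats::pnorm(z1)
    u_svd <- stats::pnorm(z2)
    wmh <- q_piecewise(u_wmh, model$wmh_breaks, model$wmh_probs)
    svd <- findInterval(u_svd, cumsum(model$svd_probs))
    svd <- pmin(svd, 4L)
    age <- q_piecewise(stats::runif(n), model$age_breaks, model$age_probs)
    sex <- ifelse(stats::runif(n) < model$male_prop, "male", "female")
    ht <- stats::runif(n) < model$hypertension_prop
    lac <- stats::runif(n) < model$lacunar_prop
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               age = age, sex = sex, hypertensive = ht,
               wmh_fraction = wmh, svd_score = as.integer(svd),
               lacunar = lac, stringsAsFactors = FALSE)
  })
}

#' Phantom kinetics model
#'
#' Parameters of the signal model that turns subject covariates into a
#' dynamic series.  Contrast arrival is modelled with a gamma-variate
#' vascular input function (VIF) normalised to unit peak; each tissue's
#' fractional enhancement is `tissue_gain * VIF(t) + leakage_rate *
#' integral of VIF` (the leakage term emulates extravascular accumulation
#' through a compromised blood-brain barrier).  The WMH burden of a
#' subject raises the white-matter leakage rate linearly
#' (`leakage_link`, 1/min per % WMH) and the CSF/WM texture
#' heterogeneity (`heterogeneity_link`, per % WMH).  Spatial texture is a
#' stationary Gaussian random field whose standard deviation, relative to
#' the tissue baseline, is the tissue's heterogeneity.
#'
#' @param vif Gamma-variate parameters: `amplitude` (peak fractional
#'   units), `onset_s` (bolus arrival, seconds), `shape` (dimensionless),
#'   `scale_s` (seconds; time-to-peak is `shape * scale_s`).
#' @param baseline Pre-contrast signal per tissue (arbitrary units).
#' @param tissue_gain Peak vascular enhancement fraction per tissue.
#' @param leakage_base Baseline leakage rate per tissue (1/min).
#' @param leakage_link Added WM leakage rate per % WMH (1/min/%).
#' @param heterogeneity_base Relative texture SD per tissue.
#' @param heterogeneity_link Added CSF/WM heterogeneity per % WMH.
#' @param gain_jitter Log-normal SD of per-subject tissue gain.
#' @param texture_corr_mm Correlation length of the texture field (mm).
#' @param noise_sd Voxelwise Gaussian noise SD as a fraction of the
#'   tissue baseline.
#' @return A list of class `kinetics_model`.
#' @export
kinetics_model <- function(vif = list(amplitude = 1, onset_s = 73,
                                      shape = 3, scale_s = 60),
                           baseline = c(BL = 300, CSF = 500, GMD = 600,
                                        GMC = 650, WM = 700),
                           tissue_gain = c(BL = 2.0, CSF = 0.05, GMD = 0.5,
                                           GMC = 0.6, WM = 0.3),
                           leakage_base = c(BL = 0.004, CSF = 0.001,
                                            GMD = 0.002, GMC = 0.002,
                                            WM = 0.002),
                           leakage_link = 0.004,
                           heterogeneity_base = c(BL = 0.05, CSF = 0.06,
                                                  GMD = 0.08, GMC = 0.08,
                                                  WM = 0.08),
                           heterogeneity_link = 0.01,
                           gain_jitter = 0.15,
                           texture_corr_mm = 3,
                           noise_sd = 0.02) {
  stopifnot(vif$amplitude >= 0, noise_sd >= 0,
            all(names(TISSUES) %in% names(baseline)),
            all(names(TISSUES) %in% names(tissue_gain)))
  structure(list(vif = vif, baseline = baseline, tissue_gain = tissue_gain,
                 leakage_base = leakage_base, leakage_link = leakage_link,
                 heterogeneity_base = heterogeneity_base,
                 heterogeneity_link = heterogeneity_link,
                 gain_jitter = gain_jitter,
                 texture_corr_mm = texture_corr_mm,
                 noise_sd = noise_sd),
            class = "kinetics_model")
}

#' Gamma-variate vascular input function
#'
#' `amplitude * x^shape * exp(shape * (1 - x))` with
#' `x = (t - onset) / (shape * scale)`, so the curve peaks at `amplitude`
#' when `t - onset = shape * scale`, and is exactly zero up to the bolus
#' onset.
#'
#' @param t_s Times in seconds.
#' @param vif Parameter list as in [kinetics_model()].
#' @return Numeric vector of VIF values (dimensionless).
#' @export
gamma_variate_vif <- function(t_s, vif) {
  tp <- vif$shape * vif$scale_s
  x <- (t_s - vif$onset_s) / tp
  out <- numeric(length(t_s))
  pos <- x > 0
  out[pos] <- vif$amplitude * x[pos]^vif$shape * exp(vif$shape * (1 - x[pos]))
  out
}

#' Per-subject ground truth for the phantom
#'
#' Combines one covariate row with the kinetics model to fix the
#' subject's per-tissue leakage rates, texture heterogeneities and
#' (jittered) vascular gains.  These are the quantities the recovery
#' tests compare against.
#'
#' @param covariates One-row data.frame as from [generate_covariates()].
#' @param kinetics A [kinetics_model()].
#' @param seed Optional seed for the gain jitter.
#' @return A list of class `subject_truth`.
#' @export
subject_truth <- function(covariates, kinetics = kinetics_model(),
                          seed = NULL) {
  stopifnot(nrow(covariates) == 1L)
  wmh <- covariates$wmh_fraction
  leak <- kinetics$leakage_base
  leak["WM"] <- leak["WM"] + kinetics$leakage_link * wmh
  het <- kinetics$heterogeneity_base
  het[c("CSF", "WM")] <- het[c("CSF", "WM")] +
    kinetics$heterogeneity_link * wmh
  gain <- with_seed(seed, {
    kinetics$tissue_gain *
      exp(stats::rnorm(length(kinetics$tissue_gain), 0, kinetics$gain_jitter))
  })
  structure(list(subject_id = covariates$subject_id,
                 age = covariates$age, sex = covariates$sex,
                 hypertensive = covariates$hypertensive,
                 wmh_fraction = wmh,
                 svd_score = covariates$svd_score,
                 lacunar = covariates$lacunar,
                 leakage_rate = leak,
                 texture_heterogeneity = het,
                 tissue_gain = gain),
            class = "subject_truth")
}

#' Geometric brain label map for the phantom
#'
#' A concentric-ring layout replicated on every slice: a central CSF
#' "ventricle", a deep grey matter ring, a broad white matter annulus, a
#' cortical grey matter rim, and three blood-vessel blobs placed outside
#' the cortical rim (stand-ins for the sagittal sinus and arteries).  The
#' rings are scaled to the in-plane matrix so every tissue offers enough
#' area for the sampling plan at any grid size.
#'
#' @param geometry An `acq_geometry`.
#' @return Integer 3D array (row, col, slice) with codes from [TISSUES]
#'   and 0 for background.
#' @export
build_label_map <- function(geometry) {
  nr <- geometry$n_rows; nc <- geometry$n_cols
  rmax <- min(nr, nc) / 2 - 2
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2   # 0-based grid centre
  d <- sqrt(outer(((0:(nr - 1)) - cr)^2, ((0:(nc - 1)) - cc)^2, "+"))
  sl <- matrix(0L, nr, nc)
  sl[d <= 0.9867 * rmax] <- TISSUES[["GMC"]]
  sl[d <= 0.8267 * rmax] <- TISSUES[["WM"]]
  sl[d <= 0.5667 * rmax] <- TISSUES[["GMD"]]
  sl[d <= 0.40 * rmax]   <- TISSUES[["CSF"]]
  blob_r <- max(0.1133 * rmax, 2.6)
  for (ang in c(45, 135, 225) * pi / 180) {
    br <- cr + 1.0167 * rmax * sin(ang)
    bc <- cc + 1.0167 * rmax * cos(ang)
    db <- sqrt(outer(((0:(nr - 1)) - br)^2, ((0:(nc - 1)) - bc)^2, "+"))
    sl[db <= blob_r] <- TISSUES[["BL"]]
  }
  array(sl, dim = c(nr, nc, geometry$n_slices))
}

# stationary Gaussian random field on an nr x nc torus, standardised to
# zero mean and unit SD; corr_len in voxels
gaussian_field <- function(nr, nc, corr_len) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 0) {
    dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    k <- exp(-outer(dr^2, dc^2, "+") / (2 * corr_len^2))
    w <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
      (nr * nc)
  }
  (w - mean(w)) / stats::sd(w)
}

#' Generate a synthetic dynamic series for one subject
#'
#' Builds the tissue label map, draws a per-slice correlated texture
#' field, and composes the signal
#' `baseline * (1 + heterogeneity * field) * (1 + E(t)) + noise`, where
#' the programmed fractional enhancement of each tissue is
#' `gain * VIF(t) + leakage_rate * cumulative-integral of VIF` (integral
#' in minutes, trapezoidal on the frame grid).  Frame 0 is the
#' pre-contrast baseline and carries no enhancement.
#'
#' @param truth A [subject_truth()].
#' @param geometry An `acq_geometry`; defaults to [phantom_geometry()].
#' @param kinetics A [kinetics_model()].
#' @param seed Integer seed for texture and noise.
#' @return A list with elements `series` (a `dce_series`), `labels`
#'   (integer 3D label map), `enhancement` (5 x n_frames matrix of the
#'   programmed per-tissue fractional enhancement) and `truth`.
#' @export
generate_series <- function(truth, geometry = phantom_geometry(),
                            kinetics = kinetics_model(), seed = NULL) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(geometry, "acq_geometry"))
  labels <- build_label_map(geometry)
  t_s <- frame_times(geometry, "s")
  vif <- gamma_variate_vif(t_s, kinetics$vif)
  t_min <- t_s / 60
  cum <- c(0, cumsum(diff(t_min) * (vif[-1] + vif[-length(vif)]) / 2))
  tn <- names(TISSUES)
  enh <- matrix(0, length(tn), length(t_s), dimnames = list(tn, NULL))
  for (ts in tn)
    enh[ts, ] <- truth$tissue_gain[[ts]] * vif + truth$leakage_rate[[ts]] * cum
  nr <- geometry$n_rows; nc <- geometry$n_cols; ns <- geometry$n_slices
  nt <- geometry$n_frames
  base3 <- array(0, c(nr, nc, ns))
  base3[] <- c(0, kinetics$baseline[tn])[labels + 1L]
  corr_len <- kinetics$texture_corr_mm / geometry$in_plane_spacing
  het_lut <- c(0, truth$texture_heterogeneity[tn])
  dat <- with_seed(seed, {
    tex <- array(0, c(nr, nc, ns))
    for (s in seq_len(ns)) {
      g <- gaussian_field(nr, nc, corr_len)
      tex[, , s] <- het_lut[labels[, , s] + 1L] * g
    }
    static <- base3 * (1 + tex)
    out <- array(0, c(nr, nc, ns, nt))
    for (f in seq_len(nt)) {
      efac <- c(0, enh[, f])[labels + 1L]
      frame <- static * (1 + array(efac, c(nr, nc, ns)))
      if (kinetics$noise_sd > 0)
        frame <- frame + stats::rnorm(length(frame)) * kinetics$noise_sd * base3
      out[, , , f] <- frame
    }
    out
  })
  list(series = dce_series(dat, geometry), labels = labels,
       enhancement = enh, truth = truth)
}

#' Generate a phantom cohort's covariates and ground truth
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param kinetics A [kinetics_model()].
#' @param model A [covariate_model()].
#' @return A list with `covariates` (data.frame) and `truths` (list of
#'   `subject_truth`).  Image series are generated per subject with
#'   [generate_series()] to keep memory bounded.
#' @export
phantom_cohort <- function(n_subjects, seed = NULL,
                           kinetics = kinetics_model(),
                           model = covariate_model()) {
  cov <- generate_covariates(n_subjects, seed = seed, model = model)
  truths <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    lapply(seq_len(nrow(cov)), function(i)
      subject_truth(cov[i, , drop = FALSE], kinetics))
  })
  list(covariates = cov, truths = truths)
}

#' Write a phantom subject to disk
#'
#' Writes the 4D series and the 3D label map as NIfTI-1 images, plus a
#' JSON sidecar echoing the seed and geometry.
#'
#' @param phantom Output of [generate_series()].
#' @param dir Output directory (created if needed).
#' @param id Subject identifier used as the filename stem.
#' @param seed Seed echoed into the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, id = phantom$truth$subject_id,
                          seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- phantom$series$geometry
  pix <- c(g$in_plane_spacing, g$in_plane_spacing, g$slice_thickness,
           g$frame_interval)
  img <- RNifti::asNifti(phantom$series$data, pixdim = pix)
  lab <- RNifti::asNifti(phantom$labels,
                         pixdim = pix[1:3], datatype = "int16")
  p1 <- file.path(dir, paste0(id, "_dce.nii.gz"))
  p2 <- file.path(dir, paste0(id, "_labels.nii.gz"))
  p3 <- file.path(dir, paste0(id, "_meta.json"))
  RNifti::writeNifti(img, p1)
  RNifti::writeNifti(lab, p2)
  jsonlite::write_json(list(subject_id = id, seed = seed,
                            geometry = unclass(g),
                            tissues = as.list(TISSUES)),
                       p3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(series = p1, labels = p2, meta = p3))
}

#' Read a phantom subject back from disk
#'
#' @param dir Directory written by [write_phantom()].
#' @param id Subject identifier.
#' @return A list with `series` (a `dce_series`) and `labels`.
#' @export
read_phantom <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  g <- do.call(acquisition_geometry, as.list(meta$geometry))
  dat <- array(as.numeric(RNifti::readNifti(
    file.path(dir, paste0(id, "_dce.nii.gz")))),
    dim = c(g$n_rows, g$n_cols, g$n_slices, g$n_frames))
  lab <- array(as.integer(RNifti::readNifti(
    file.path(dir, paste0(id, "_labels.nii.gz")))),
    dim = c(g$n_rows, g$n_cols, g$n_slices))
  list(series = dce_series(dat, g), labels = lab)
}
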