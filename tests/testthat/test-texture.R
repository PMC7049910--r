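test_that("grey-level quantisation bins linearly over the global range", {
  expect_error(quantize_levels(numeric(0)), "empty")
  expect_true(all(quantize_levels(rep(3.2, 10)) == 0L))
  expect_identical(as.integer(quantize_levels(0:15, L = 16L)), 0:15)
  set.seed(201)
  u <- stats::runif(16000)
  occ <- tabulate(quantize_levels(u, L = 16L) + 1L, nbins = 16L)
  # equal-width bins on uniform data: multinomial fluctuation only
  expect_lt(max(abs(occ - 1000)), 4 * sqrt(1000))
  # bounds global over the full time series, not per frame
  m <- matrix(c(0, 1, 10, 11), nrow = 2)   # frame 2 shifted upward
  q <- quantize_levels(m, L = 4L)
  expect_identical(as.integer(q), c(0L, 0L, 3L, 3L))
})

test_that("co-occurrence counting matches exhaustive pair enumeration", {
  set.seed(202)
  L <- 4L
  for (rep in 1:100) {
    mat <- matrix(sample(0:(L - 1), 25, replace = TRUE), 5, 5)
    co <- cbind(row = as.vector(row(mat)) - 1L,
                col = as.vector(col(mat)) - 1L,
                sample = 1L)
    C <- glcm(as.integer(mat), co, L = L)
    expect_equal(unclass(C), bf_glcm(mat, L), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(C), 1, tolerance = 1e-12)
    expect_equal(unclass(C), t(unclass(C)), tolerance = 1e-12)
  }
})

test_that("co-occurrence handles constant and two-voxel regions", {
  co2 <- cbind(row = c(0L, 0L), col = c(0L, 1L), sample = 1L)
  C <- glcm(c(3L, 5L), co2, L = 16L)
  expect_equal(C[4, 6], 0.5)
  expect_equal(C[6, 4], 0.5)
  const <- glcm(rep(2L, 4), cbind(row = c(0L, 0L, 1L, 1L),
                                  col = c(0L, 1L, 0L, 1L), sample = 1L),
                L = 16L)
  expect_equal(const[3, 3], 1)
  # pairs never cross disc boundaries
  co_split <- cbind(row = c(0L, 0L), col = c(0L, 1L), sample = c(1L, 2L))
  expect_error(glcm(c(1L, 2L), co_split, L = 16L), "degenerate")
})

test_that("Haralick features reproduce hand-computed values", {
  L <- 16L
  diagC <- matrix(0, L, L); diagC[5, 5] <- 1
  h <- haralick_features(structure(diagC, normalised = TRUE))
  expect_length(h, 9L)
  expect_equal(unname(h[c("contrast", "energy", "entropy")]), c(0, 1, 0))
  expect_equal(unname(h["correlation"]), 1)   # degenerate marginals
  # two-level checkerboard: all mass on (0,1) and (1,0)
  cb <- matrix(0, L, L); cb[1, 2] <- 0.5; cb[2, 1] <- 0.5
  h2 <- haralick_features(structure(cb, normalised = TRUE))
  expect_equal(unname(h2["contrast"]), 1)
  expect_equal(unname(h2["energy"]), 0.5)
  expect_equal(unname(h2["correlation"]), -1)
  expect_equal(unname(h2["sum_average"]), 1)  # all pairs sum to 1
  expect_equal(unname(h2["sum_variance"]), 0)
  expect_equal(unname(h2["entropy"]), log(2))
  # printed-form IDM flag changes only the IDM feature
  h3 <- haralick_features(structure(cb, normalised = TRUE),
                          idm_printed_form = TRUE)
  expect_equal(unname(h2["idm"]), 0.5)        # 1/(1+1)
  expect_equal(unname(h3["idm"]), 0.5)        # 1/(1+|0+1|^2)
  expect_equal(h2[-6], h3[-6])
  expect_error(haralick_features(cb), "normalised")
})

test_that("LBP codes follow the worked-example convention and match the oracle", {
  # centre 4 with neighbours 1..8 in order E,NE,N,NW,W,SW,S,SE
  img <- matrix(0, 3, 3)
  img[2, 2] <- 4
  img[2, 3] <- 1; img[1, 3] <- 2; img[1, 2] <- 3; img[1, 1] <- 4
  img[2, 1] <- 5; img[3, 1] <- 6; img[3, 2] <- 7; img[3, 3] <- 8
  code <- lbp_codes(patch_frame(img), cbind(row = 1L, col = 1L, slice = 0L))
  expect_identical(as.integer(code), 7L)       # bits 1,1,1,0,0,0,0,0
  expect_identical(as.integer(lbp_codes(patch_frame(matrix(2, 3, 3)),
                   cbind(row = 1L, col = 1L, slice = 0L))), 0L)
  set.seed(203)
  for (rep in 1:100) {
    m <- matrix(stats::rnorm(16), 4, 4)
    codes <- lbp_codes(patch_frame(m), interior_coords(m))
    oracle <- c(bf_lbp(m, 2, 2), bf_lbp(m, 3, 2),
                bf_lbp(m, 2, 3), bf_lbp(m, 3, 3))
    expect_identical(as.integer(codes), as.integer(oracle))
  }
  # border voxels are excluded with a warning
  expect_warning(
    out <- lbp_codes(patch_frame(matrix(1, 3, 3)),
                     cbind(row = 0L, col = 0L, slice = 0L)),
    "excluded")
  expect_length(out, 0L)
})

test_that("the uniform-pattern mapping has 58 own bins plus one pooled bin", {
  transitions <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }
  n_uniform <- sum(vapply(0:255, transitions, 0L) <= 2L)
  expect_identical(n_uniform, 58L)
  h <- ulbp_histogram(0:255)
  expect_length(h, 59L)
  expect_equal(sum(h), 1)
  expect_error(ulbp_histogram(integer(0)), "empty")
})

test_that("ULBP histograms are invariant to monotone intensity changes", {
  set.seed(204)
  m <- matrix(stats::rnorm(36), 6, 6)
  h0 <- ulbp_histogram(lbp_codes(patch_frame(m), interior_coords(m)))
  h1 <- ulbp_histogram(lbp_codes(patch_frame(3 * m + 10),
                                 interior_coords(m)))
  expect_equal(h0, h1)
})

test_that("LCP yields 81 features combining occurrences and configuration magnitudes", {
  set.seed(205)
  m <- matrix(stats::rnorm(64), 8, 8)
  f <- lcp_features(patch_frame(m), interior_coords(m))
  expect_length(f, 81L)
  expect_true(all(is.finite(f)))
  # occurrence entries (every 9th starting at 1) sum to at most 1
  occ <- f[seq(1, 81, by = 9)]
  expect_lte(sum(occ), 1 + 1e-12)
  # constant image: every code is 0 (class with zero set bits)
  fc <- lcp_features(patch_frame(matrix(5, 6, 6)),
                     interior_coords(matrix(0, 6, 6)))
  expect_equal(unname(fc[1]), 1)               # all mass in class 0
  expect_true(all(is.finite(fc)))
})

test_that("LCP least-squares weights recover a known configuration", {
  # 16 centres with disjoint neighbourhoods, each centre exactly the
  # mean of its 8 neighbours; the first four neighbours (E,NE,N,NW) sit
  # below the mean and the last four above, so every centre shares the
  # uniform code 00001111 (class: four set bits) and the pooled
  # least-squares system is consistent with weights 1/8 each
  set.seed(206)
  m <- matrix(stats::runif(256, 3, 4), 16, 16)
  centres <- as.matrix(expand.grid(row = c(2L, 5L, 8L, 11L),
                                   col = c(2L, 5L, 8L, 11L)))
  off <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
               dc = c(1, 1, 0, -1, -1, -1, 0, 1))
  X <- matrix(0, nrow(centres), 8); y <- numeric(nrow(centres))
  for (v in seq_len(nrow(centres))) {
    nbrs <- c(stats::runif(4, 0, 0.5), stats::runif(4, 1.5, 2))
    for (p in 1:8)
      m[centres[v, 1] + off[p, 1] + 1, centres[v, 2] + off[p, 2] + 1] <-
        nbrs[p]
    m[centres[v, 1] + 1, centres[v, 2] + 1] <- mean(nbrs)
    X[v, ] <- nbrs; y[v] <- mean(nbrs)
  }
  co <- cbind(centres, slice = 0L)
  f <- lcp_features(patch_frame(m), co)
  # normal-equations oracle on the same pooled system
  w_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(as.numeric(w_oracle), rep(1 / 8, 8), tolerance = 1e-8)
  block <- f[(9 * 4 + 1):(9 * 5)]          # class with four set bits
  expect_equal(unname(block[1]), 1)        # all centres in this class
  expect_equal(unname(block[-1]), Mod(stats::fft(as.numeric(w_oracle))),
               tolerance = 1e-8)
  expect_equal(unname(block[-1]), c(1, rep(0, 7)), tolerance = 1e-8)
})

test_that("LCP rotation-invariant occurrence block is unchanged by 90-degree rotation", {
  set.seed(207)
  m <- matrix(stats::rnorm(49), 7, 7)
  f0 <- lcp_features(patch_frame(m), interior_coords(m))
  mr <- t(m)[ncol(m):1, ]                      # 90 degree rotation
  f1 <- lcp_features(patch_frame(mr), interior_coords(mr))
  occ0 <- f0[seq(1, 81, by = 9)]
  occ1 <- f1[seq(1, 81, by = 9)]
  expect_equal(unname(occ0), unname(occ1), tolerance = 1e-12)
})

test_that("texture trajectories have the published dimensionalities", {
  g <- phantom_geometry(n_frames = 3L)
  cv <- generate_covariates(1, seed = 208)
  ph <- generate_series(subject_truth(cv, seed = 1), g, seed = 2)
  tpl <- build_template(ph$labels, g, seed = 3)
  tt <- texture_trajectories(ph$series, tpl, "middle-high", "WM")
  expect_identical(dim(tt$GLCM), c(9L, 3L))
  expect_identical(dim(tt$ULBP), c(59L, 3L))
  expect_identical(dim(tt$LCP), c(81L, 3L))
  expect_equal(colSums(tt$ULBP), rep(1, 3))
})
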