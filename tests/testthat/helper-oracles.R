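# Independent brute-force oracles used to cross-check the fast
# implementations.  These deliberately mirror the defining formulas by
# explicit loops and never share code with the package internals.

# O(N^6) triple-sum evaluation of the 3D DFT magnitude
bf_dft3_magnitude <- function(x) {
  N <- dim(x)[1]
  out <- array(0, dim(x))
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) for (w in 0:(N - 1)) {
    s <- 0 + 0i
    for (i in 0:(N - 1)) for (j in 0:(N - 1)) for (k in 0:(N - 1))
      s <- s + x[i + 1, j + 1, k + 1] *
        exp(-2i * pi * (u * i + v * j + w * k) / N)
    out[u + 1, v + 1, w + 1] <- Mod(s)
  }
  out
}

# explicit-loop ring average of a magnitude spectrum
bf_radial_average <- function(mag) {
  N <- dim(mag)[1]
  n_bins <- N %/% 2
  sums <- numeric(n_bins); counts <- numeric(n_bins)
  ctr <- function(k) if (k > N / 2) k - N else k
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) for (w in 0:(N - 1)) {
    r <- round(sqrt(ctr(u)^2 + ctr(v)^2 + ctr(w)^2))
    if (r <= n_bins - 1) {
      sums[r + 1] <- sums[r + 1] + mag[u + 1, v + 1, w + 1]
      counts[r + 1] <- counts[r + 1] + 1
    }
  }
  ifelse(counts > 0, sums / counts, 0)
}

# exhaustive double-loop pair enumeration for the co-occurrence matrix
# of a single rectangular patch (all voxels in one disc)
bf_glcm <- function(levels_mat, L) {
  nr <- nrow(levels_mat); nc <- ncol(levels_mat)
  C <- matrix(0, L, L)
  for (i in 1:nr) for (j in 1:nc) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      a <- levels_mat[i, j]; b <- levels_mat[ii, jj]
      C[a + 1, b + 1] <- C[a + 1, b + 1] + 1
    }
  }
  C / sum(C)
}

# per-voxel comparison oracle for LBP codes on a 2D patch
# (neighbour order E, NE, N, NW, W, SW, S, SE; bit p set when
# neighbour < centre)
bf_lbp <- function(img, i, j) {
  nb <- c(img[i, j + 1], img[i - 1, j + 1], img[i - 1, j],
          img[i - 1, j - 1], img[i, j - 1], img[i + 1, j - 1],
          img[i + 1, j], img[i + 1, j + 1])
  sum(2^(0:7) * (nb < img[i, j]))
}

# published rank formula for the Kruskal-Wallis statistic with tie
# correction: H = [12/(n(n+1)) * sum R_g^2/n_g - 3(n+1)] / (1 - sum(t^3-t)/(n^3-n))
bf_kruskal <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  groups <- split(r, g)
  H <- 12 / (n * (n + 1)) * sum(vapply(groups, function(rg)
    sum(rg)^2 / length(rg), 0)) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / corr
}

# small patch as a 3D single-slice frame plus interior coordinates
patch_frame <- function(mat) {
  array(mat, c(nrow(mat), ncol(mat), 1))
}
interior_coords <- function(mat, border = 1) {
  g <- expand.grid(row = (border):(nrow(mat) - 1 - border),
                   col = (border):(ncol(mat) - 1 - border))
  cbind(row = g$row, col = g$col, slice = 0L)
}

# shared small phantom objects (built once per test run)
test_geometry <- function() phantom_geometry()
test_labels <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_label_map(phantom_geometry())
    val
  }
})
test_template <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- build_template(test_labels(), phantom_geometry(), seed = 99)
    val
  }
})
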