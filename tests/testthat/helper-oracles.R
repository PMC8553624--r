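# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# exhaustive nearest-foreground distance, any dimension
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (r in seq_len(nrow(all_idx))) {
    diffs <- sweep(fg, 2L, all_idx[r, ])
    diffs <- sweep(diffs, 2L, spacing, "*")
    out[r] <- sqrt(min(rowSums(diffs^2)))
  }
  out
}

# angle-sum winding-number point-in-polygon (boundary counted inside)
winding_inside <- function(px, py, poly) {
  m <- nrow(poly)
  total <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ax <- poly[i, 1L] - px; ay <- poly[i, 2L] - py
    bx <- poly[j, 1L] - px; by <- poly[j, 2L] - py
    # on-vertex or on-edge => inside
    cross <- ax * by - ay * bx
    dot <- ax * bx + ay * by
    if (abs(cross) < 1e-9 && dot <= 1e-9) return(TRUE)
    total <- total + atan2(cross, dot)
  }
  abs(total) > pi
}

# group-by-rounded-distance mean intensity (the naive re-binning)
brute_force_profile <- function(image, dvals, max_distance) {
  keep <- dvals > 0
  b <- floor(dvals[keep] + 0.5)
  v <- image[keep]
  sel <- b <= max_distance
  b <- b[sel]; v <- v[sel]
  agg <- split(v, b)
  data.frame(bin_center_um = as.numeric(names(agg)),
             mean_intensity = vapply(agg, mean, 0),
             n_voxels = vapply(agg, length, 0L),
             row.names = NULL)
}

# small random binary mask guaranteed non-empty
random_mask <- function(dims, p = 0.08) {
  m <- array(runif(prod(dims)) < p, dim = dims)
  if (!any(m)) m[[sample(length(m), 1L)]] <- TRUE
  m
}

expect_profiles_equal <- function(a, b, tol = 1e-12) {
  o_a <- order(a$bin_center_um)
  o_b <- order(b$bin_center_um)
  expect_equal(a$bin_center_um[o_a], b$bin_center_um[o_b])
  expect_equal(a$mean_intensity[o_a], b$mean_intensity[o_b],
               tolerance = tol)
  expect_equal(as.integer(a$n_voxels[o_a]), as.integer(b$n_voxels[o_b]))
}

# circular difference on a 24-h wheel, result in [0, 12]
circ_diff_h <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}
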