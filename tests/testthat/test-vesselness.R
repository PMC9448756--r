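sp <- oct_default_spacing()

test_that("invert_and_normalize flips polarity onto [0, 1]", {
  arr <- array(80, dim = c(8, 8, 8))
  arr[4, 4, 4] <- 0                                 # one dark (vessel) voxel
  g <- voxel_grid(arr, sp, "uint8")
  n <- invert_and_normalize(g)
  expect_equal(n$data[4, 4, 4], 1)                  # dark voxel becomes max
  expect_equal(max(n$data), n$data[4, 4, 4])
  # involution with full-range percentiles
  back <- invert_and_normalize(voxel_grid(n$data, sp, "float"))
  expect_equal(back$data, (arr - 0) / 80, tolerance = 1e-12)
  # binary {0, max} volume: vessels (0) -> 1
  b <- array(c(0, 200), dim = c(4, 4, 2))
  nb <- invert_and_normalize(voxel_grid(b, sp, "uint8"))
  expect_setequal(unique(as.vector(nb$data)), c(0, 1))
  expect_equal(nb$data[1, 1, 1], 1)
  # degenerate constant input
  expect_warning(
    nc <- invert_and_normalize(voxel_grid(array(7, c(3, 3, 3)), sp)),
    "constant|degenerate")
  expect_true(all(nc$data == 0.5))
  expect_error(invert_and_normalize(g, 50, 50), "exceed")
})

test_that("constant volumes give an identically zero response", {
  g <- voxel_grid(array(0.4, dim = c(16, 16, 16)), sp, "float")
  r <- hessian_vesselness(g, vesselness_params(scales = c(0.024, 0.048)))
  expect_true(all(r$data == 0))
})

test_that("tube response: centerline dominance and scale selection match an
           independent smoothed-profile oracle", {
  # bright x-aligned tube of radius 4 dx on dark background, periodic in x
  n <- 96L
  spc <- voxel_spacing(0.012, 0.012, 0.012)
  r_mm <- 4 * spc$dx
  ctr <- (n / 2 + 0.5) * spc$dx
  yy <- ((1:n) - 0.5) * spc$dx
  d2 <- outer((yy - ctr)^2, (yy - ctr)^2, "+")
  slice <- 0.15 + 0.85 * (d2 <= r_mm^2)
  vol <- array(rep(slice, each = n), dim = c(n, n, n))
  g <- voxel_grid(vol, spc, "float")
  params <- vesselness_params()
  scales <- params$scales
  per_scale <- lapply(scales, function(s)
    hessian_vesselness(g, vesselness_params(scales = s)))
  at <- c(n / 2, n / 2 + 1, n / 2 + 1)              # centerline voxel
  center_resp <- vapply(per_scale, function(r) r$data[at[1], at[2], at[3]],
                        numeric(1))
  # oracle: FFT Gaussian smoothing + finite-difference Hessian + Frangi
  # formula, with the per-scale structureness constant estimated from a
  # coarse subsample of voxels
  spacing <- c(spc$dx, spc$dy, spc$dz)
  oracle_resp <- vapply(seq_along(scales), function(si) {
    s <- scales[si]
    sm <- gauss_smooth_3d_fft(vol, s, spacing)
    # Frobenius norm needs no eigendecomposition; subsample one x-slice
    # (the tube is x-invariant) to estimate the per-scale maximum
    sub <- as.matrix(expand.grid(x = n / 2,
                                 y = seq(6, n - 6, by = 1),
                                 z = seq(6, n - 6, by = 1)))
    svals <- apply(sub, 1, function(p) {
      sqrt(sum((fd_hessian_at(sm, p, spacing) * s^2)^2))
    })
    lam <- eigen(fd_hessian_at(sm, at, spacing) * s^2, symmetric = TRUE,
                 only.values = TRUE)$values
    frangi_formula_r(lam, c = 0.5 * max(svals))
  }, numeric(1))
  expect_equal(which.max(center_resp), which.max(oracle_resp))
  # the selected scale matches the tube's equivalent Gaussian width r/sqrt(2)
  # (the oracle-derived optimum for a top-hat profile under sigma^2
  # normalization)
  expect_equal(scales[which.max(center_resp)],
               scales[which.min(abs(scales - r_mm / sqrt(2)))])
  expect_equal(center_resp, oracle_resp, tolerance = 0.08)
  # centerline response strictly exceeds the response 2r off-axis
  combined <- hessian_vesselness(g, params)
  off <- combined$data[at[1], at[2] + 8, at[3]]
  expect_gt(combined$data[at[1], at[2], at[3]], off)
})

test_that("blob suppression: a sphere responds less than an equal tube", {
  n <- 72L
  spc <- voxel_spacing(0.012, 0.012, 0.012)
  r_mm <- 4 * spc$dx
  ctr <- (n / 2 + 0.5) * spc$dx
  ax <- ((1:n) - 0.5) * spc$dx
  tube <- array(0.15, dim = c(n, n, n))
  d2yz <- outer((ax - ctr)^2, (ax - ctr)^2, "+")
  tube <- tube + 0.85 * array(rep(d2yz <= r_mm^2, each = n), dim = dim(tube))
  sph <- array(0.15, dim = c(n, n, n))
  dd <- outer(outer((ax - ctr)^2, (ax - ctr)^2, "+"), (ax - ctr)^2, "+")
  sph[dd <= r_mm^2] <- 1
  prm <- vesselness_params(scales = c(0.024, 0.048, 0.096))
  rt <- hessian_vesselness(voxel_grid(tube, spc, "float"), prm)
  rs <- hessian_vesselness(voxel_grid(sph, spc, "float"), prm)
  expect_lt(max(rs$data), max(rt$data))
})

test_that("response is invariant to global intensity scaling", {
  set.seed(8)
  base <- array(runif(24^3), dim = c(24, 24, 24))
  g1 <- voxel_grid(base, sp, "float")
  g2 <- voxel_grid(base * 3.7, sp, "float")
  prm <- vesselness_params(scales = c(0.024, 0.048))
  r1 <- hessian_vesselness(g1, prm)
  r2 <- hessian_vesselness(g2, prm)
  expect_equal(r1$data, r2$data, tolerance = 1e-6)
})

test_that("x- and z-aligned tubes respond identically (dx = dz)", {
  n <- 64L
  spc <- voxel_spacing(0.012, 0.012, 0.012)
  r_mm <- 3 * spc$dx
  ctr <- (n / 2 + 0.5) * spc$dx
  ax <- ((1:n) - 0.5) * spc$dx
  d2 <- outer((ax - ctr)^2, (ax - ctr)^2, "+")
  xt <- array(0.15 + 0.85 * rep(d2 <= r_mm^2, each = n), dim = c(n, n, n))
  zt <- aperm(xt, c(3, 2, 1))
  prm <- vesselness_params(scales = c(0.024, 0.048))
  rx <- hessian_vesselness(voxel_grid(xt, spc, "float"), prm)
  rz <- hessian_vesselness(voxel_grid(zt, spc, "float"), prm)
  at_x <- rx$data[n / 2, n / 2 + 1, n / 2 + 1]
  at_z <- rz$data[n / 2 + 1, n / 2 + 1, n / 2]
  expect_lt(abs(at_x - at_z) / at_x, 0.05)
})

test_that("under-resolved scales trigger a warning", {
  g <- voxel_grid(array(runif(8^3), c(8, 8, 8)), sp, "float")
  expect_warning(hessian_vesselness(g, vesselness_params(scales = 0.001)),
                 "under-resolved")
})

test_that("binarize_vessels respects threshold bounds and the mask", {
  set.seed(3)
  shape <- c(20L, 20L, 20L)
  resp <- voxel_grid(array(runif(prod(shape), 0, 0.5), dim = shape), sp,
                     "float")
  resp$data[1:5, , ] <- 0
  resp$data[10, 10, 10] <- 1          # unique max, > one 8-bit quantum clear
  mask_arr <- array(FALSE, dim = shape)
  mask_arr[, 6:15, ] <- TRUE
  mask <- choroid_mask(mask_arr, sp)
  # threshold 0: all nonzero-response voxels inside the mask
  v0 <- binarize_vessels(resp, mask, 0)
  expect_identical(v0$data, (resp$data > 0) & mask_arr)
  # threshold 255: subset of the argmax voxels
  v255 <- binarize_vessels(resp, mask, 255)
  expect_true(all(resp$data[v255$data] == max(resp$data)))
  # vessel set is always inside the choroid mask
  v <- binarize_vessels(resp, mask, 40)
  expect_false(any(v$data & !mask_arr))
  expect_error(binarize_vessels(resp, mask, 300), "0..255")
  expect_error(binarize_vessels(resp, mask, -1), "0..255")
})

test_that("a 3-voxel-radius tube phantom binarizes near its true volume", {
  # radius 3 dx; depth kept large enough for the biggest default kernel
  ph <- default_phantom(shape = c(128L, 128L, 64L), noise_sigma = 0.05,
                        seed = 2)
  tube <- ph$tubes[[1]]
  norm <- invert_and_normalize(ph$volume$grid)
  resp <- hessian_vesselness(norm, vesselness_params())
  vol <- binarize_vessels(resp, ph$mask, 40)
  zb <- ph$z_bands[[1]]
  nv <- sum(vol$data[, , (zb[1] + 1):(zb[2] + 1)])
  err <- nv * voxel_volume(ph$mask$spacing) / tube$volume - 1
  expect_lt(abs(err), 0.25)
})
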