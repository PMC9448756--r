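sp <- oct_default_spacing()

test_that("surface model follows the 6-neighbour border-exclusion rule", {
  # single interior foreground voxel
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  expect_equal(sum(build_surface_model(v)), 1)
  # solid 3x3x3 cube in the interior: everything but the centre
  v <- array(FALSE, c(7, 7, 7)); v[3:5, 3:5, 3:5] <- TRUE
  s <- build_surface_model(v)
  expect_equal(sum(s), 26)
  expect_false(s[4, 4, 4])
  # fully foreground volume: only scan-border exposure, which does not count
  v <- array(TRUE, c(4, 5, 6))
  expect_equal(sum(build_surface_model(v)), 0)
  # empty input
  expect_equal(sum(build_surface_model(array(FALSE, c(3, 3, 3)))), 0)
})

test_that("surface model equals the brute-force oracle on random volumes", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- array(runif(20^3) > 0.6, dim = c(20, 20, 20))
    got <- build_surface_model(v)
    expect_identical(got, surface_oracle(v))
    expect_false(any(got & !v))                    # surface subset of volume
  }
})

test_that("find_slice_maxima matches its stated examples", {
  gauss2d <- function(n, cx, cy, h, s) {
    h * exp(-(outer((1:n - cx)^2, (1:n - cy)^2, "+")) / (2 * s^2))
  }
  # single blob, prominence below its height -> exactly one point at the peak
  img <- gauss2d(41, 13.2, 27.8, 1, 4)
  pts <- find_slice_maxima(img, 0.5)
  expect_equal(nrow(pts), 1)
  expect_equal(unname(pts[1, ]), c(13, 28))
  # two blobs (1.0 and 0.6) joined by a saddle near 0.2
  img2 <- pmax(gauss2d(61, 15, 31, 1, 5), gauss2d(61, 47, 31, 0.6, 5))
  saddle <- max(img2[31, ])
  expect_lt(saddle, 0.3)
  expect_equal(nrow(find_slice_maxima(img2, 0.3)), 2)
  expect_equal(nrow(find_slice_maxima(img2, 0.7)), 1)
  # constant image -> no maxima
  expect_equal(nrow(find_slice_maxima(matrix(5, 20, 20), 0)), 0)
  expect_error(find_slice_maxima(img, -1), "prominence")
})

test_that("plateau maxima report one centroid point, half rounded down", {
  img <- matrix(0, 11, 11)
  img[4:6, 5:7] <- 1                       # 3x3 plateau, centroid (5, 6)
  pts <- find_slice_maxima(img, 0.5)
  expect_equal(nrow(pts), 1)
  expect_equal(unname(pts[1, ]), c(5, 6))
  img2 <- matrix(0, 11, 11)
  img2[4:5, 7:8] <- 2                      # 2x2 plateau, centroid (4.5, 7.5)
  pts2 <- find_slice_maxima(img2, 0.5)
  expect_equal(nrow(pts2), 1)
  expect_equal(unname(pts2[1, ]), c(4, 7)) # ties round toward smaller index
})

test_that("find_slice_maxima equals the MST prominence oracle on random
           smoothed fields", {
  set.seed(123)
  smooth2d <- function(m, k = 3) {
    kern <- outer(dnorm(-4:4, sd = k), dnorm(-4:4, sd = k))
    kern <- kern / sum(kern)
    out <- matrix(0, nrow(m), ncol(m))
    padded <- m[c(rep(1, 4), 1:nrow(m), rep(nrow(m), 4)),
                c(rep(1, 4), 1:ncol(m), rep(ncol(m), 4))]
    for (i in 1:nrow(m)) for (j in 1:ncol(m)) {
      out[i, j] <- sum(padded[i:(i + 8), j:(j + 8)] * kern)
    }
    out
  }
  n_checked <- 0
  for (rep in 1:50) {
    img <- smooth2d(matrix(runif(32 * 32), 32, 32))
    img <- img + matrix(runif(32 * 32, 0, 1e-9), 32, 32)  # break exact ties
    stopifnot(!anyDuplicated(as.vector(img)))
    tol <- runif(1, 0.005, 0.05)
    got <- find_slice_maxima(img, tol)
    want <- mst_prominence_maxima(img, tol)
    got_keys <- sort(got[, 1] + 1000 * got[, 2])
    want_keys <- sort(want[, 1] + 1000 * want[, 2])
    expect_identical(as.integer(got_keys), as.integer(want_keys))
    n_checked <- n_checked + nrow(got)
  }
  expect_gt(n_checked, 50)          # the comparison was not vacuous
})

test_that("line model recovers an x-aligned tube and respects masking", {
  # synthetic response: infinite tube along x (no end caps), radial Gaussian
  nx <- 220L; ny <- 48L; nz <- 48L
  yc <- 24.5; zc <- 24.5
  r_vox <- 5
  prof <- exp(-(outer(((1:ny) - yc)^2, ((1:nz) - zc)^2, "+")) /
                (2 * (r_vox / sqrt(2))^2))
  resp_arr <- array(rep(255 * prof, each = nx), dim = c(nx, ny, nz))
  vol_arr <- array(rep(prof > 0.3, each = nx), dim = c(nx, ny, nz))
  response <- voxel_grid(resp_arr, sp, "float")
  volume_model <- voxel_grid(vol_arr, sp, "uint8")
  line <- build_line_model(response, volume_model, prominence = 10)
  # fixed-x pass: exactly one voxel per slice at the centre
  per_slice <- apply(line$data, 1, sum)
  expect_true(all(per_slice >= 1))
  n_line <- sum(line$data)
  # length recovery: x-pass contributes nx, the orthogonal pass ~2r extras
  expect_lt(abs(n_line - nx) / nx, 0.10)
  # line model is always inside the volume model
  expect_false(any(line$data & !vol_arr))
  # masking: empty volume model -> empty line model
  empty <- voxel_grid(array(FALSE, dim = dim(resp_arr)), sp, "uint8")
  expect_equal(sum(build_line_model(response, empty, 10)$data), 0)
  # determinism
  line2 <- build_line_model(response, volume_model, prominence = 10)
  expect_identical(line$data, line2$data)
})

test_that("oblique in-plane tubes yield a dilated-connected maxima chain", {
  # 45-degree tube in the en-face (x, z) plane at fixed depth
  nx <- 96L; ny <- 24L; nz <- 96L
  yc <- 12.5
  resp_arr <- array(0, dim = c(nx, ny, nz))
  for (x in 1:nx) {
    z0 <- x                                    # diagonal centreline
    dz2 <- outer(((1:ny) - yc)^2 / 2, ((1:nz) - z0)^2 / 2, "+")
    resp_arr[x, , ] <- pmax(resp_arr[x, , ], 255 * exp(-dz2 / (2 * 3^2)))
  }
  vol_arr <- resp_arr > 0.3 * 255
  response <- voxel_grid(resp_arr, sp, "float")
  volume_model <- voxel_grid(vol_arr, sp, "uint8")
  line <- build_line_model(response, volume_model, prominence = 10)
  pts <- which(line$data, arr.ind = TRUE)
  expect_gt(nrow(pts), nx / 2)
  ord <- order(pts[, 1] + pts[, 3])
  sorted <- pts[ord, , drop = FALSE]
  gaps <- pmax(abs(diff(sorted[, 1])), abs(diff(sorted[, 2])),
               abs(diff(sorted[, 3])))
  expect_lte(max(gaps), 3)                     # connected when dilated by 1
})

test_that("vessel_model_set enforces the subset invariants", {
  v <- array(FALSE, c(6, 6, 6)); v[2:5, 2:5, 2:5] <- TRUE
  vg <- voxel_grid(v, sp, "uint8")
  sg <- voxel_grid(build_surface_model(v), sp, "uint8")
  lg <- voxel_grid(array(FALSE, c(6, 6, 6)), sp, "uint8")
  expect_s3_class(vessel_model_set(vg, sg, lg), "vessel_model_set")
  bad <- lg; bad$data[1, 1, 1] <- TRUE         # outside the volume model
  expect_error(vessel_model_set(vg, sg, bad), "subset")
})
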