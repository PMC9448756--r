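# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package implementation.

# Brute-force 6-neighbour surface oracle: triple loop, border exposure
# excluded.
surface_oracle <- function(vol) {
  d <- dim(vol)
  out <- array(FALSE, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!vol[x, y, z]) next
    nb <- list(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
               c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    for (q in nb) {
      if (q[1] < 1 || q[1] > d[1] || q[2] < 1 || q[2] > d[2] ||
          q[3] < 1 || q[3] > d[3]) next               # scan border: no count
      if (!vol[q[1], q[2], q[3]]) { out[x, y, z] <- TRUE; break }
    }
  }
  out
}

# Vectorized shift-based variant of the surface oracle for large volumes
# (same rule, different mechanism than the compiled scan).
surface_oracle_shift <- function(v) {
  d <- dim(v)
  out <- array(FALSE, d)
  out[2:d[1], , ] <- out[2:d[1], , ] | !v[1:(d[1] - 1), , ]
  out[1:(d[1] - 1), , ] <- out[1:(d[1] - 1), , ] | !v[2:d[1], , ]
  out[, 2:d[2], ] <- out[, 2:d[2], ] | !v[, 1:(d[2] - 1), ]
  out[, 1:(d[2] - 1), ] <- out[, 1:(d[2] - 1), ] | !v[, 2:d[2], ]
  out[, , 2:d[3]] <- out[, , 2:d[3]] | !v[, , 1:(d[3] - 1)]
  out[, , 1:(d[3] - 1)] <- out[, , 1:(d[3] - 1)] | !v[, , 2:d[3]]
  out & v
}

# Maximum-spanning-tree prominence oracle for images with all-distinct
# values. The maximin path value between two pixels equals the minimum edge
# weight on their maximum-spanning-tree path (edge weight = min of endpoint
# values); prominence of a local maximum p is v_p minus the best such value
# to any higher pixel (global maximum: v_p - min(img)). Returns the 1-based
# (i, j) coordinates of maxima with prominence strictly above `tol`.
mst_prominence_maxima <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img); n <- nr * nc
  v <- as.vector(img)
  stopifnot(!anyDuplicated(v))
  idx <- function(i, j) (j - 1L) * nr + i
  ed_from <- integer(0); ed_to <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 >= 1 && i2 <= nr && j2 <= nc) {
        ed_from <- c(ed_from, idx(i, j)); ed_to <- c(ed_to, idx(i2, j2))
      }
    }
  }
  w <- pmin(v[ed_from], v[ed_to])
  g <- igraph::graph_from_edgelist(cbind(ed_from, ed_to), directed = FALSE)
  igraph::E(g)$weight <- -w
  tree <- igraph::mst(g)                  # maximum spanning tree
  tw <- -igraph::E(tree)$weight           # back to min-endpoint values
  adj <- lapply(seq_len(n), function(i) integer(0))
  tel <- igraph::as_edgelist(tree)
  for (e in seq_len(nrow(tel))) {
    a <- tel[e, 1]; b <- tel[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, tw[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, tw[e]))
  }
  # strict local maxima over 8-neighbourhood
  cand <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    p <- idx(i, j)
    ismax <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
          v[idx(i2, j2)] > v[p]) ismax <- FALSE
    }
    if (ismax) cand <- c(cand, p)
  }
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    p <- cand[ci]
    # BFS over the tree from p tracking the minimum edge weight en route
    best_to <- rep(NA_real_, n)
    best_to[p] <- Inf
    queue <- p
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      nbrs <- adj[[q]]
      if (is.null(dim(nbrs))) next
      for (k in seq_len(nrow(nbrs))) {
        u <- nbrs[k, 1]
        if (!is.na(best_to[u])) next
        best_to[u] <- min(best_to[q], nbrs[k, 2])
        queue <- c(queue, u)
      }
    }
    higher <- which(v > v[p])
    saddle <- if (length(higher)) max(best_to[higher]) else -Inf
    prom <- if (is.finite(saddle)) v[p] - saddle else v[p] - min(v)
    keep[ci] <- prom > tol
  }
  pts <- cand[keep]
  cbind(i = ((pts - 1L) %% nr) + 1L, j = ((pts - 1L) %/% nr) + 1L)
}

# FFT-based Gaussian smoothing of a 3D array with periodic wrap; kernels are
# built directly from the Gaussian, independent of the package's separable
# correlation path. Spacing may be anisotropic (physical units).
gauss_smooth_3d_fft <- function(vol, sigma_mm, spacing) {
  d <- dim(vol)
  kern1 <- function(n, dx) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * dx
    k <- exp(-x^2 / (2 * sigma_mm^2))
    k / sum(k)
  }
  kx <- kern1(d[1], spacing[1]); ky <- kern1(d[2], spacing[2])
  kz <- kern1(d[3], spacing[3])
  K <- outer(outer(kx, ky), kz)
  dim(K) <- d
  Re(fft(fft(vol) * fft(K), inverse = TRUE)) / prod(d)
}

# Frangi line-filter formula at one voxel given its Hessian eigenvalues
# (plain R transcription of the published formula).
frangi_formula_r <- function(lams, alpha = 0.5, beta = 0.5, c) {
  ord <- order(abs(lams))
  l1 <- lams[ord[1]]; l2 <- lams[ord[2]]; l3 <- lams[ord[3]]
  if (l2 > 0 || l3 > 0 || abs(l3) == 0) return(0)
  ra <- abs(l2) / abs(l3)
  rb <- abs(l1) / sqrt(abs(l2 * l3))
  s <- sqrt(sum(lams^2))
  (1 - exp(-ra^2 / (2 * alpha^2))) * exp(-rb^2 / (2 * beta^2)) *
    (1 - exp(-s^2 / (2 * c^2)))
}

# Central finite-difference Hessian (physical units) of a 3D array at a
# single 1-based voxel index.
fd_hessian_at <- function(vol, at, spacing) {
  x <- at[1]; y <- at[2]; z <- at[3]
  sp <- spacing
  g <- function(dx1, dy1, dz1) vol[x + dx1, y + dy1, z + dz1]
  hxx <- (g(1, 0, 0) - 2 * g(0, 0, 0) + g(-1, 0, 0)) / sp[1]^2
  hyy <- (g(0, 1, 0) - 2 * g(0, 0, 0) + g(0, -1, 0)) / sp[2]^2
  hzz <- (g(0, 0, 1) - 2 * g(0, 0, 0) + g(0, 0, -1)) / sp[3]^2
  hxy <- (g(1, 1, 0) - g(1, -1, 0) - g(-1, 1, 0) + g(-1, -1, 0)) /
    (4 * sp[1] * sp[2])
  hxz <- (g(1, 0, 1) - g(1, 0, -1) - g(-1, 0, 1) + g(-1, 0, -1)) /
    (4 * sp[1] * sp[3])
  hyz <- (g(0, 1, 1) - g(0, 1, -1) - g(0, -1, 1) + g(0, -1, -1)) /
    (4 * sp[2] * sp[3])
  matrix(c(hxx, hxy, hxz, hxy, hyy, hyz, hxz, hyz, hzz), 3, 3)
}
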