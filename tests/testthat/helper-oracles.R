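# Brute-force reference implementations and small fixture builders.
# The oracles deliberately use direct loops / all-pairs arithmetic and
# never touch the package's distance-transform path.

mk_mask <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    role = "OTHER") {
  structure_mask(array(as.logical(arr), dim(arr)), spacing, origin,
                 role = role)
}

# union of random spheres on a small grid; guaranteed non-empty
rand_mask <- function(dims = c(20, 20, 20), spacing = c(1, 1, 1),
                      n_spheres = 2, r_range = c(2, 7)) {
  ext <- (dims - 1) * spacing
  m <- array(FALSE, dims)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  for (i in seq_len(n_spheres)) {
    ctr <- runif(3, 0.15, 0.85) * ext
    r <- runif(1, r_range[1], r_range[2])
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                (ax[[3]] - ctr[3])^2, "+")
    m <- m | (d2 <= r^2)
  }
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  structure_mask(m, spacing, c(0, 0, 0))
}

# physical coordinates (mm) of the TRUE voxels of a logical array
coords_mm <- function(logical_arr, spacing, origin = c(0, 0, 0)) {
  idx <- which(logical_arr, arr.ind = TRUE)
  t((t(idx) - 1) * spacing + origin)
}

# surface voxels by explicit per-voxel neighbour check
oracle_surface <- function(mask) {
  m <- mask$data
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (p in nb) {
      if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# for each row of A (n x 3, mm) the distance to the nearest row of B
oracle_nn_dists <- function(A, B) {
  apply(A, 1, function(a) sqrt(min(colSums((t(B) - a)^2))))
}

oracle_hd95 <- function(source, target, percentile = 95) {
  A <- coords_mm(oracle_surface(source), source$spacing, source$origin)
  B <- coords_mm(oracle_surface(target), target$spacing, target$origin)
  dd <- oracle_nn_dists(A, B)
  stats::quantile(dd, percentile / 100, type = 7, names = FALSE)
}

oracle_svc <- function(gtv, btv) {
  svc <- btv$data & !gtv$data
  if (!any(svc)) return(c(max_mm = 0, mean_mm = 0))
  A <- coords_mm(svc, gtv$spacing, gtv$origin)
  B <- coords_mm(oracle_surface(gtv), gtv$spacing, gtv$origin)
  dd <- oracle_nn_dists(A, B)
  c(max_mm = max(dd), mean_mm = mean(dd))
}

# 26-connected flood fill, plain R
oracle_label26 <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        p <- ijk + c(di, dj, dk)
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (m[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# compact phantom variants used across tests: a 64^3 grid at 2 mm with
# the same anatomy as the package default, scaled to fit
small_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
         brain_semiaxes_mm = c(50, 55, 45),
         basal_ganglia = list(
           list(offset_mm = c(-16, 18, 0), radius_mm = 9, tn = 2.2),
           list(offset_mm = c(16, 18, 0), radius_mm = 9, tn = 2.2)),
         tumor = list(offset_mm = c(24, -14, 4),
                      enhancement_radius_mm = 9,
                      infiltration_radius_mm = 20,
                      peak_tn_ratio = 3.0,
                      profile = "radial_linear")),
    list(...))
  do.call(phantom_spec, args)
}

noiseless_args <- list(noise_sigma_fraction = 0, psf_fwhm_mm = 0)

small_noiseless_spec <- function(...) {
  do.call(small_spec, c(noiseless_args, list(...)))
}

# 1 mm isotropic single-tumor phantom for accuracy tests; the tumor
# center sits off the voxel lattice so no voxel lies exactly on an
# iso-contour
fine_spec <- function(...) {
  phantom_spec(shape = c(72, 72, 72), spacing_mm = c(1, 1, 1),
               brain_semiaxes_mm = c(34, 34, 34),
               basal_ganglia = list(),
               tumor = list(offset_mm = c(0.3, 0.2, 0.1),
                            enhancement_radius_mm = 9,
                            infiltration_radius_mm = 20,
                            peak_tn_ratio = 3.0,
                            profile = "radial_linear"),
               noise_sigma_fraction = 0, psf_fwhm_mm = 0,
               ...)
}
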