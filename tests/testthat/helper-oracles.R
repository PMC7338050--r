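# Independent oracles used across the suite. All are deliberately naive
# (loops, queues, direct sums) and share no code with the implementation.

# breadth-first-search connected-component labeling of a (z,y,x) logical array
bfs_label_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  s <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  keep <- s > 0 & s <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, ]
  labels <- array(0L, dim = d)
  lab <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || labels[z, y, x] > 0) next
    lab <- lab + 1L
    queue <- list(c(z, y, x))
    labels[z, y, x] <- lab
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0) {
          labels[q[1], q[2], q[3]] <- lab
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  labels
}

# two labelings agree up to renaming iff the label pairing is a bijection
same_partition <- function(a, b) {
  sel <- a > 0 | b > 0
  fa <- a[sel]; fb <- b[sel]
  if (any(fa == 0) || any(fb == 0)) return(FALSE)
  pairs <- unique(cbind(fa, fb))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# exhaustive-scan Renyi threshold oracle on raw bin counts (0-based bin out)
naive_renyi_bin <- function(counts) {
  p <- counts / sum(counts); P1 <- cumsum(p); n <- length(p)
  best <- function(rho) {
    bestv <- -Inf; bestt <- NA
    for (t in seq_len(n - 1)) {
      if (P1[t] <= 0 || P1[t] >= 1) next
      pb <- p[1:t] / P1[t]; pf <- p[(t + 1):n] / (1 - P1[t])
      h <- if (rho == 1)
        -sum(pb[pb > 0] * log(pb[pb > 0])) - sum(pf[pf > 0] * log(pf[pf > 0]))
      else log(sum(pb^rho)) / (1 - rho) + log(sum(pf^rho)) / (1 - rho)
      if (h > bestv) { bestv <- h; bestt <- t - 1 }
    }
    bestt
  }
  ts <- sort(c(best(0.5), best(1), best(2)))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  b <- if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  om <- P1[t3 + 1] - P1[t1 + 1]
  as.integer(floor(t1 * (P1[t1 + 1] + 0.25 * om * b[1]) +
                     0.25 * t2 * om * b[2] +
                     t3 * (1 - P1[t3 + 1] + 0.25 * om * b[3])))
}

# direct truncated-Gaussian kernel sum at an arbitrary voxel offset
gauss3d_at <- function(dz, dy, dx, sigma) {
  k1 <- function(offset, s) {
    r <- ceiling(4 * s)
    w <- exp(-0.5 * (-r:r)^2 / s^2)
    w <- w / sum(w)
    if (abs(offset) > r) 0 else w[offset + r + 1]
  }
  k1(dz, sigma[1]) * k1(dy, sigma[2]) * k1(dx, sigma[3])
}

# small utility: stack with given marker volume (z,y,x) plus optional cargo
make_stack <- function(marker, cal = calibration(0.2, dz = 0.4),
                       cargo = NULL) {
  d <- dim(marker)
  n_ch <- 1L + length(cargo)
  v <- array(0, dim = c(n_ch, d))
  v[1, , , ] <- marker
  for (i in seq_along(cargo)) v[i + 1, , , ] <- cargo[[i]]
  image_stack(v, cal, marker_channel = 1L)
}

# hand-rolled measured cilium for analysis tests
fake_cilium <- function(id, intensity, length_um = NA_real_,
                        centroid = c(0, 0, 0)) {
  structure(list(id = as.integer(id), voxel_indices = matrix(1, 1, 3),
                 n_voxels = 1L, volume_um3 = NA_real_,
                 centroid_um = c(z = centroid[1], y = centroid[2],
                                 x = centroid[3]),
                 mean_intensity = intensity, skeleton = NULL,
                 length_um = length_um, total_skeleton_um = NA_real_,
                 border_touching = FALSE, calibration = NULL),
            class = "cilium")
}
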