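# Independent brute-force oracles and small fixture builders.

# Local thickness by naive distance matrices: no distance transform, no
# bounding boxes.  mask: 3D {0,1} array; phase: "background"/"foreground";
# returns thickness in voxel units on the selected phase.
oracle_local_thickness <- function(mask, phase = "background") {
  sel <- if (phase == "background") mask == 0 else mask == 1
  d <- dim(mask)
  out <- array(0, d)
  idx <- which(sel, arr.ind = TRUE)
  comp <- which(!sel, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  if (nrow(comp) == 0) {
    out[sel] <- 2 * (sqrt(sum(d^2)) - 0.5)
    return(out)
  }
  # max admissible radius per center: distance to nearest complement
  # voxel center minus half a voxel
  D2 <- outer(rowSums(idx^2), rowSums(comp^2), "+") - 2 * idx %*% t(comp)
  R <- sqrt(pmax(apply(D2, 1, min), 0)) - 0.5
  DD <- outer(rowSums(idx^2), rowSums(idx^2), "+") - 2 * idx %*% t(idx)
  DD[DD < 0] <- 0
  for (ci in seq_len(nrow(idx))) {
    covered <- idx[DD[, ci] <= R[ci]^2, , drop = FALSE]
    tv <- 2 * R[ci]
    for (rr in seq_len(nrow(covered))) {
      cur <- out[covered[rr, 1], covered[rr, 2], covered[rr, 3]]
      if (cur < tv) {
        out[covered[rr, 1], covered[rr, 2], covered[rr, 3]] <- tv
      }
    }
  }
  out
}

# Exact conditional two-proportion p-value by explicit table
# enumeration: probabilities of every 2x2 table with the observed
# margins computed from binomial coefficients, minimum-likelihood
# two-sided tail.
oracle_fraction_test <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  xs <- max(0, k - n2):min(k, n1)
  w <- vapply(xs, function(x) choose(n1, x) * choose(n2, k - x), numeric(1))
  pr <- w / sum(w)
  obs <- pr[xs == k1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# toy 5-frame track with hand-enumerated msd_1 = 1, msd_2 = 2
toy_track_pos <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0), c(2, 1, 1))
}

# simple isotropic Gaussian random walk positions
random_walk_pos <- function(n, sd = 1) {
  apply(matrix(rnorm(3 * (n - 1), sd = sd), ncol = 3), 2,
        function(s) c(0, cumsum(s)))
}

# random 3D rotation matrix
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

make_track_df <- function(track_id, pos, dt = 1200, condition = "unknown",
                          phenotype = "unknown") {
  n <- nrow(pos)
  data.frame(track_id = track_id, frame = 0:(n - 1),
             time_s = (0:(n - 1)) * dt, x_um = pos[, 1], y_um = pos[, 2],
             z_um = pos[, 3], condition = condition, phenotype = phenotype)
}
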