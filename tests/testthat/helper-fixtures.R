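# shared fixtures and independent oracles

# helix with exact `bond`-length backbone bonds (genuinely chiral 3-D chain)
helix_chain <- function(n_atoms = 20, bond = 1.5, radius = 1.2, phi = 0.7) {
  rise <- sqrt(bond^2 - (2 * radius * sin(phi / 2))^2)
  t <- seq_len(n_atoms) - 1
  cbind(radius * cos(phi * t), radius * sin(phi * t), rise * t)
}

mirror_z <- function(m) {
  m <- as.matrix(m)
  m[, 3] <- -m[, 3]
  m
}

# RMSD up to rigid motion AND global mirror (reconstruction cannot know
# chirality)
rmsd_up_to_mirror <- function(a, b) min(rmsd(a, b), rmsd(mirror_z(a), b))

rotation_from_euler <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

random_rotation <- function() {
  rotation_from_euler(stats::runif(3, 0, 2 * pi))
}

# independent RMSD oracle: numeric search over Euler angles (multi-start
# Nelder-Mead), no SVD involved
rmsd_bruteforce <- function(a, b, n_starts = 40) {
  a <- sweep(as.matrix(a), 2, colMeans(a))
  b <- sweep(as.matrix(b), 2, colMeans(b))
  obj <- function(ang) {
    r <- rotation_from_euler(ang)
    sqrt(mean(rowSums((a %*% r - b)^2)))
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    start <- stats::runif(3, 0, 2 * pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# minimum-image distance oracle: explicit search over all 27 periodic images
min_dist_27_images <- function(point, solute, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  best <- Inf
  for (i in seq_len(nrow(solute))) {
    for (s in seq_len(nrow(shifts))) {
      img <- solute[i, ] + shifts[s, ] * box
      best <- min(best, sqrt(sum((point - img)^2)))
    }
  }
  best
}
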