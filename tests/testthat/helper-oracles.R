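# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: covariance by explicit double loop, RMSD minimization by
# grid search + simplex refinement over Euler angles, hydrogen bonds by
# triple enumeration with scalar geometry.

# population covariance of an M x d matrix by explicit double loop
bf_covariance <- function(flat) {
  m <- nrow(flat); d <- ncol(flat)
  mu <- numeric(d)
  for (j in seq_len(d)) mu[j] <- sum(flat[, j]) / m
  C <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    s <- 0
    for (f in seq_len(m)) s <- s + (flat[f, i] - mu[i]) * (flat[f, j] - mu[j])
    C[i, j] <- s / m
  }
  C
}

euler_rot <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

# minimum RMSD (Angstrom) over all rigid transforms, by numerical
# minimization: centroid alignment is optimal for any rotation, so only
# the rotation is searched (coarse grid, then Nelder-Mead refinement)
bf_rmsd_min <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  f <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((A %*% R - B)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); best_v <- f(best)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- f(c(a, b, c))
    if (v < best_v) { best_v <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
  opt$value * 10  # nm -> Angstrom
}

# hydrogen bonds by triple enumeration with scalar geometry
bf_hbonds <- function(coords, structure, donor_ids, acceptor_ids,
                      d_cut = 3.5, a_cut = 30) {
  a <- structure$atoms
  found <- list()
  for (d_id in donor_ids) {
    if (!(a$element[d_id + 1] %in% c("N", "O"))) next
    hs <- structure$bonded_hydrogens[[d_id + 1]]
    if (!length(hs)) next
    for (h_id in hs) for (acc in acceptor_ids) {
      if (!(a$element[acc + 1] %in% c("N", "O")) || acc == d_id) next
      dvec <- coords[acc + 1, ] - coords[d_id + 1, ]
      dda <- sqrt(sum(dvec^2)) * 10
      hvec <- coords[h_id + 1, ] - coords[d_id + 1, ]
      cosang <- sum(hvec * dvec) / sqrt(sum(hvec^2) * sum(dvec^2))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (dda <= d_cut && ang <= a_cut)
        found[[length(found) + 1]] <- c(d_id, h_id, acc)
    }
  }
  if (!length(found)) return(matrix(integer(0), 0, 3))
  do.call(rbind, found)
}

# random polar fixture: n atoms in a box, N/O/H elements, every N/O given
# 0-2 bonded hydrogens placed ~1 A away
random_polar_fixture <- function(n = 30, span_nm = 1.2) {
  heavy_n <- n
  el <- sample(c("N", "O", "C"), heavy_n, replace = TRUE, prob = c(.4, .4, .2))
  coords <- matrix(runif(heavy_n * 3, 0, span_nm), heavy_n, 3)
  hx <- list(); hparent <- integer(0)
  for (i in seq_len(heavy_n)) {
    if (el[i] %in% c("N", "O") && runif(1) < 0.7) {
      nh <- sample(1:2, 1)
      for (k in seq_len(nh)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        hx[[length(hx) + 1]] <- coords[i, ] + 0.1 * u
        hparent <- c(hparent, i)
      }
    }
  }
  nh_tot <- length(hx)
  all_coords <- rbind(coords, do.call(rbind, hx))
  bonded <- rep(list(integer(0)), heavy_n + nh_tot)
  for (k in seq_len(nh_tot))
    bonded[[hparent[k]]] <- c(bonded[[hparent[k]]], heavy_n + k - 1L)
  structure_model(
    atom_name = c(paste0(el, seq_len(heavy_n)), paste0("H", seq_len(nh_tot))),
    element = c(el, rep("H", nh_tot)),
    residue_seq = seq_len(heavy_n + nh_tot),
    residue_name = rep("UNK", heavy_n + nh_tot),
    chain_id = rep("A", heavy_n + nh_tot),
    coords = all_coords,
    bonded_hydrogens = bonded
  )
}

make_charged_cluster <- function(n, span = 0.8, seed = 1) {
  set.seed(seed)
  repeat {
    coords <- matrix(runif(n * 3, 0, span), n, 3)
    if (min(dist(coords)) > 0.08) break
  }
  structure_model(
    atom_name = paste0("X", seq_len(n)), element = rep("C", n),
    residue_seq = seq_len(n), residue_name = rep("UNK", n),
    chain_id = rep("A", n), coords = coords,
    charge = round(runif(n, -1, 1), 2),
    lj_sigma = runif(n, 0.25, 0.4), lj_epsilon = runif(n, 0.1, 1))
}

sel_ids <- function(ids) structure(list(indices = as.integer(ids),
                                        label = "ids"), class = "AtomSelection")

apply_transform_test <- function(x, fit)
  sweep(x %*% fit$rotation, 2, fit$translation, "+")

# PrincipalModes object directly from explicit mode vectors (3N x k)
modes_from_vectors <- function(vectors, values = NULL) {
  vectors <- as.matrix(vectors)
  if (is.null(values)) values <- rev(seq_len(ncol(vectors)))
  structure(list(values = values, vectors = vectors,
                 n_atoms = nrow(vectors) / 3, selection = NULL),
            class = "PrincipalModes")
}

random_orthonormal_cols <- function(d, k) {
  qr.Q(qr(matrix(rnorm(d * k), d, k)))
}

# quick planted spec over n atoms with k seeded random modes
quick_spec <- function(n_atoms, eigenvalues = c(1.0, 0.3),
                       residual = 0.01, n_frames = 2000, seed = 1,
                       mode_seed = seed) {
  d <- 3 * n_atoms
  V <- motioncons:::with_seed(mode_seed,
                              random_orthonormal_cols(d, length(eigenvalues)))
  mu <- motioncons:::with_seed(mode_seed + 1,
                               matrix(rnorm(n_atoms * 3), n_atoms, 3))
  planted_mode_spec(n_atoms, V, eigenvalues, residual, mu, n_frames, seed)
}

# minimal CHARMM-style DCD writer (frames in Angstrom), for exercising the
# binary trajectory path without shipping binary fixtures
write_test_dcd <- function(path, frames_A) {
  m <- dim(frames_A)[1]; n <- dim(frames_A)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20); icntrl[1] <- m; icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[20] <- 24L
  writeBin(84L, con, size = 4); writeChar("CORD", con, 4, eos = NULL)
  writeBin(icntrl, con, size = 4); writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4); writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "synthetic test trajectory"), con, 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(as.integer(n), con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- 4L * n
  for (f in seq_len(m)) for (ax in 1:3) {
    writeBin(nb, con, size = 4)
    writeBin(as.numeric(frames_A[f, , ax]), con, size = 4)
    writeBin(nb, con, size = 4)
  }
  invisible(path)
}
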