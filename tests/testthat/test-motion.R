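test_that("covariance matches hand-computable cases", {
  # one atom observed at x = +1 and -1 nm: mean 0, variance 1 on x only
  m1 <- structure_model(atom_name = "CA", element = "C", residue_seq = 1L,
                        residue_name = "GLY", chain_id = "A",
                        coords = matrix(0, 1, 3))
  fr <- array(0, dim = c(2, 1, 3)); fr[1, 1, 1] <- 1; fr[2, 1, 1] <- -1
  cov <- build_covariance(trajectory_ensemble(m1, fr),
                          structure(list(indices = 0L, label = "a"),
                                    class = "AtomSelection"),
                          superpose = FALSE)
  expect_equal(cov$mean_coords, matrix(0, 1, 3))
  expect_equal(cov$matrix, diag(c(1, 0, 0)))

  # static trajectory: zero matrix
  spec <- quick_spec(5, eigenvalues = c(.1, .05), n_frames = 4, seed = 6)
  traj <- generate_gaussian_ensemble(spec)
  traj$frames <- array(rep(traj$frames[1, , ], each = 4), dim = dim(traj$frames))
  sel <- select_atoms(traj$structure, "name CA")
  cov0 <- build_covariance(traj, sel, superpose = FALSE)
  expect_equal(max(abs(cov0$matrix)), 0)

  expect_error(build_covariance(traj, sel, window = c(2, 2)), "at least 2")
})

test_that("covariance equals the double-loop oracle to 1e-12", {
  set.seed(61)
  for (rep in 1:5) {
    spec <- quick_spec(6, eigenvalues = c(0.5, 0.1), residual = 0.02,
                       n_frames = 10, seed = 100 + rep)
    traj <- generate_gaussian_ensemble(spec)
    sel <- select_atoms(traj$structure, "name CA")
    cov <- build_covariance(traj, sel, superpose = FALSE)
    flat <- matrix(0, 10, 18)
    for (ax in 1:3) flat[, seq(ax, 18, 3)] <- traj$frames[, , ax]
    expect_lt(max(abs(cov$matrix - bf_covariance(flat))), 1e-12)
    expect_lt(max(abs(cov$matrix - t(cov$matrix))), 1e-15)
  }
})

test_that("superposed covariance is invariant under rigid-body motion of the frames", {
  spec <- quick_spec(8, eigenvalues = c(0.05, 0.02), residual = 1e-3,
                     n_frames = 30, seed = 62)
  traj <- generate_gaussian_ensemble(spec)
  sel <- select_atoms(traj$structure, "name CA")
  ref_coords <- spec$mean_structure
  cov1 <- build_covariance(traj, sel, superpose = TRUE,
                           fit_reference = ref_coords)

  set.seed(63)
  moved <- traj
  th <- runif(3, 0, 2 * pi); R <- euler_rot(th[1], th[2], th[3])
  for (i in seq_len(n_frames(traj)))
    moved$frames[i, , ] <- sweep(get_frame(traj, i) %*% R, 2, c(5, -3, 1), "+")
  cov2 <- build_covariance(moved, sel, superpose = TRUE,
                           fit_reference = ref_coords)
  expect_lt(max(abs(cov1$matrix - cov2$matrix)), 1e-8)

  # the iterative-mean fit preserves the covariance spectrum under the
  # same rigid motion (the matrix itself co-rotates with the frames)
  ev1 <- eigen(build_covariance(traj, sel)$matrix, TRUE, TRUE)$values
  ev2 <- eigen(build_covariance(moved, sel)$matrix, TRUE, TRUE)$values
  expect_equal(ev1, ev2, tolerance = 1e-8)
})

test_that("eigendecomposition sorts, canonicalizes and reconstructs", {
  pm <- principal_modes(diag(c(4, 1, 0)))
  expect_equal(pm$values, c(4, 1, 0))
  expect_equal(abs(pm$vectors), diag(3))

  set.seed(64)
  for (rep in 1:5) {
    B <- matrix(rnorm(144), 12, 12)
    C <- crossprod(B) / 12
    pm <- principal_modes(C)
    expect_equal(sum(pm$values), sum(diag(C)), tolerance = 1e-10)
    # A^T C A diagonal with the eigenvalues on the diagonal
    E <- t(pm$vectors) %*% C %*% pm$vectors
    expect_lt(max(abs(E - diag(pm$values))), 1e-8)
    expect_lt(max(abs(crossprod(pm$vectors) - diag(12))), 1e-8)
    # reported convention: largest-magnitude component positive
    for (k in 1:12) expect_gt(pm$vectors[which.max(abs(pm$vectors[, k])), k], 0)
  }
  expect_error(principal_modes(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  expect_error(principal_modes(diag(3), n_modes = 5), "exceeds")
})

test_that("planted modes are recovered from a sampled ensemble", {
  spec <- quick_spec(32, eigenvalues = c(1.0, 0.3), residual = 0.01,
                     n_frames = 3000, seed = 65)
  traj <- generate_gaussian_ensemble(spec)
  pm <- principal_modes(build_covariance(traj,
                                         select_atoms(traj$structure, "name CA"),
                                         superpose = FALSE), n_modes = 2)
  for (k in 1:2)
    expect_gt(abs(sum(pm$vectors[, k] * spec$modes[, k])), 0.99)
})

test_that("directional similarity hits its analytic anchor points", {
  set.seed(66)
  v <- random_orthonormal_cols(30, 1)
  mv <- modes_from_vectors(cbind(v, v))  # need >= 1 mode; self-compare uses m=n=1
  expect_equal(as.numeric(directional_similarity(mv, mv, 1, 1)), 1)

  neg <- modes_from_vectors(cbind(-v, v))
  expect_equal(as.numeric(directional_similarity(neg, mv, 1, 1,
                                                 sign_policy = "off")), 0)
  # sign policy rescues the flip and records it
  s <- directional_similarity(neg, mv, 1, 1, sign_policy = "maximize")
  expect_equal(as.numeric(s), 1)
  expect_true(attr(s, "flipped"))

  # everywhere-orthogonal per-atom slices: sigma = 0.5 exactly
  n <- 10
  vx <- rep(c(1, 0, 0) / sqrt(n), n); vy <- rep(c(0, 1, 0) / sqrt(n), n)
  expect_equal(as.numeric(directional_similarity(
    modes_from_vectors(cbind(vx, vx)), modes_from_vectors(cbind(vy, vy)),
    1, 1, sign_policy = "off")), 0.5)
})

test_that("sigma of random directions converges to 1/2 (Monte-Carlo oracle)", {
  set.seed(67)
  n <- 4000
  a <- matrix(rnorm(3 * n), n, 3); a <- a / sqrt(rowSums(a^2))
  b <- matrix(rnorm(3 * n), n, 3); b <- b / sqrt(rowSums(b^2))
  va <- as.vector(t(a)) / sqrt(n); vb <- as.vector(t(b)) / sqrt(n)
  s <- as.numeric(directional_similarity(modes_from_vectors(cbind(va, va)),
                                         modes_from_vectors(cbind(vb, vb)),
                                         1, 1, sign_policy = "off"))
  # sd of (1 - theta/pi) under uniform angles: sqrt(1/4 - 2/pi^2)
  se <- sqrt(1 / 4 - 2 / pi^2) / sqrt(n)
  expect_lt(abs(s - 0.5), 3 * se)
})

test_that("sigma properties: symmetry, bounds, negation complement", {
  set.seed(68)
  for (rep in 1:10) {
    V <- random_orthonormal_cols(24, 2)
    W <- random_orthonormal_cols(24, 2)
    mv <- modes_from_vectors(V); mw <- modes_from_vectors(W)
    s_ab <- as.numeric(directional_similarity(mv, mw, 1, 2,
                                              sign_policy = "off"))
    s_ba <- as.numeric(directional_similarity(mw, mv, 2, 1,
                                              sign_policy = "off"))
    expect_equal(s_ab, s_ba, tolerance = 1e-12)
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)
    neg <- modes_from_vectors(-V)
    s_neg <- as.numeric(directional_similarity(neg, mw, 1, 2,
                                               sign_policy = "off"))
    expect_equal(s_ab + s_neg, 1, tolerance = 1e-12)
  }
  expect_error(directional_similarity(modes_from_vectors(diag(6)[, 1:2]),
                                      modes_from_vectors(diag(9)[, 1:2])),
               "mismatch")
})

test_that("degenerate per-atom slices contribute the uninformative midpoint", {
  # atom 2's slice is zero in the test mode
  v_ref <- c(1, 0, 0, 0, 1, 0) / sqrt(2)
  v_test <- c(1, 0, 0, 0, 0, 0)
  s <- as.numeric(directional_similarity(
    modes_from_vectors(cbind(v_test, v_test)),
    modes_from_vectors(cbind(v_ref, v_ref)), 1, 1, sign_policy = "off"))
  expect_equal(s, (1 + 0.5) / 2)
})

test_that("conservation classification follows the Sigma_C/Sigma_U rule", {
  # single-atom system: PC1 = x, PC2 = y
  px <- c(1, 0, 0); py <- c(0, 1, 0)
  ref <- modes_from_vectors(cbind(px, py), values = c(2, 1))
  same <- conservation_classify(ref, ref)
  expect_equal(unname(same$sigma), matrix(c(1, .5, .5, 1), 2, 2))
  expect_equal(same$sigma_c, 2)
  expect_equal(same$sigma_u, 1)
  expect_equal(same$label, "conserved")

  swapped <- modes_from_vectors(cbind(py, px), values = c(2, 1))
  sw <- conservation_classify(swapped, ref)
  expect_equal(sw$sigma_c, 1)
  expect_equal(sw$sigma_u, 2)
  expect_equal(sw$label, "unconserved")

  expect_error(conservation_classify(modes_from_vectors(matrix(px)), ref),
               "at least 2")

  # tie: test modes at 45 degrees between the reference modes
  d45 <- (px + py) / sqrt(2); d45b <- (px - py) / sqrt(2)
  tie <- conservation_classify(modes_from_vectors(cbind(d45, d45b)), ref)
  expect_equal(tie$label, "ambiguous")
})

test_that("planted-perturbation pipeline classifies rotations correctly", {
  base <- quick_spec(24, eigenvalues = c(1.0, 0.3), residual = 0.01,
                     n_frames = 2000, seed = 69)
  get_modes <- function(spec) {
    traj <- generate_gaussian_ensemble(spec)
    principal_modes(build_covariance(traj,
                                     select_atoms(traj$structure, "name CA"),
                                     superpose = FALSE), n_modes = 2)
  }
  ref_modes <- get_modes(base)
  for (cs in list(list(perturbation_spec("rotate_in_plane", angle = 0),
                       "conserved"),
                  list(perturbation_spec("rotate_in_plane", angle = pi / 2),
                       "unconserved"))) {
    spec2 <- perturb_modes(base, cs[[1]])
    spec2$seed <- base$seed + 5L
    expect_equal(conservation_classify(get_modes(spec2), ref_modes)$label,
                 cs[[2]])
  }
})

test_that("per-residue decomposition averages back to Sigma_C and localizes damage", {
  set.seed(70)
  n <- 12
  V <- random_orthonormal_cols(3 * n, 2)
  ref <- modes_from_vectors(V)
  res <- conservation_classify(ref, ref)
  expect_equal(res$per_residue_sigma_c, rep(2, n))
  expect_equal(mean(res$per_residue_sigma_c), res$sigma_c, tolerance = 1e-10)

  # rotate one residue's slices by 90 degrees in both modes:
  # that residue's term drops to 1.0, everyone else stays at 2.0
  vx <- rep(0, 3 * n); vy <- rep(0, 3 * n)
  vx[seq(1, 3 * n, 3)] <- 1 / sqrt(n)       # all-x mode
  vy[seq(2, 3 * n, 3)] <- 1 / sqrt(n)       # all-y mode
  tx <- vx; ty <- vy
  j <- 5
  tx[3 * (j - 1) + 1] <- 0; tx[3 * (j - 1) + 3] <- 1 / sqrt(n)  # x -> z
  ty[3 * (j - 1) + 2] <- 0; ty[3 * (j - 1) + 1] <- 1 / sqrt(n)  # y -> x
  out <- conservation_classify(modes_from_vectors(cbind(tx, ty)),
                               modes_from_vectors(cbind(vx, vy)))
  expect_equal(out$per_residue_sigma_c[j], 1.0)
  expect_equal(out$per_residue_sigma_c[-j], rep(2, n - 1))
  expect_equal(mean(out$per_residue_sigma_c), out$sigma_c, tolerance = 1e-12)

  # mapping onto residue labels via a structure
  spec <- quick_spec(n, eigenvalues = c(.1, .05), n_frames = 50, seed = 71)
  traj <- generate_gaussian_ensemble(spec)
  sel <- select_atoms(traj$structure, "name CA")
  pm <- principal_modes(build_covariance(traj, sel, superpose = FALSE), 2)
  cc <- conservation_classify(pm, pm)
  tab <- per_residue_conservation(cc, traj$structure)
  expect_equal(nrow(tab), n)
  expect_equal(mean(tab$sigma_c), cc$sigma_c, tolerance = 1e-10)
  sub <- per_residue_conservation(cc, traj$structure, residue_range = 3:5)
  expect_equal(sub$residue_seq, 3:5)
})
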