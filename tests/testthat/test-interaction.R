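hb_groups <- function(m) list(a = select_atoms(m, "chain A"),
                              b = select_atoms(m, "chain B"))

test_that("geometric H-bond criterion honours both cutoffs inclusively", {
  cases <- list(list(3.4, 10, 1L),   # inside both
                list(3.6, 10, 0L),   # distance fails
                list(3.0, 35, 0L),   # angle fails
                list(3.5, 30, 1L))   # boundary inclusive
  for (cs in cases) {
    m <- make_hbond_fixture(cs[[1]], cs[[2]])
    g <- hb_groups(m)
    hb <- detect_hbonds(m$coords, m, g$a, g$b)
    expect_equal(nrow(hb), cs[[3]],
                 info = sprintf("d=%.1f A angle=%.0f deg", cs[[1]], cs[[2]]))
  }
  m <- make_hbond_fixture(3.4, 10)
  g <- hb_groups(m)
  hb <- detect_hbonds(m$coords, m, g$a, g$b)
  expect_equal(hb$donor, 0L)
  expect_equal(hb$hydrogen, 1L)
  expect_equal(hb$acceptor, 2L)
  expect_equal(hb$distance_DA, 3.4, tolerance = 1e-9)
  expect_equal(hb$angle_HDA, 10, tolerance = 1e-9)
})

test_that("candidate donors without bonded hydrogens are skipped with a warning", {
  m <- make_hbond_fixture(3.0, 5)
  m$bonded_hydrogens <- rep(list(integer(0)), 3)
  g <- hb_groups(m)
  expect_warning(hb <- detect_hbonds(m$coords, m, g$a, g$b),
                 "no bonded hydrogens")
  expect_equal(nrow(hb), 0L)
})

test_that("H-bond detection agrees with brute-force triple enumeration", {
  set.seed(51)
  for (rep in 1:20) {
    m <- random_polar_fixture(30)
    all_sel <- select_atoms(m, "all")
    got <- detect_hbonds(m$coords, m, all_sel, all_sel, warn = FALSE)
    want <- bf_hbonds(m$coords, m, all_sel$indices, all_sel$indices)
    got_keys <- sort(sprintf("%d_%d_%d", got$donor, got$hydrogen, got$acceptor))
    want_keys <- if (nrow(want)) sort(sprintf("%d_%d_%d", want[, 1],
                                              want[, 2], want[, 3])) else character(0)
    expect_identical(got_keys, want_keys)
  }
})

test_that("H-bond count series counts both donor directions over the window", {
  m <- make_hbond_fixture(3.4, 10)
  g <- hb_groups(m)
  frames <- array(rep(m$coords, each = 5), dim = c(5, 3, 3))
  traj <- trajectory_ensemble(m, frames)
  hc <- hbond_count_series(traj, g$a, g$b)
  expect_equal(hc$counts, rep(1, 5))
  expect_equal(hc$mean, 1)

  # one bonded frame + one broken frame -> mean 0.5
  far <- m$coords; far[3, 1] <- far[3, 1] + 1.0
  fr2 <- array(0, dim = c(2, 3, 3))
  fr2[1, , ] <- m$coords; fr2[2, , ] <- far
  expect_equal(hbond_count_series(trajectory_ensemble(m, fr2), g$a, g$b)$mean,
               0.5)

  # acceptor-free partner group -> zero
  m2 <- m
  m2$atoms$element[3] <- "C"
  expect_equal(hbond_count_series(trajectory_ensemble(m2, frames),
                                  g$a, g$b)$mean, 0)

  # reversed direction: donor in B, acceptor in A still counted
  mr <- structure_model(
    atom_name = c("O", "N", "H"), element = c("O", "N", "H"),
    residue_seq = c(1L, 2L, 2L), residue_name = c("ACC", "DON", "DON"),
    chain_id = c("A", "B", "B"),
    coords = rbind(c(0.34, 0, 0), c(0, 0, 0), c(0.1, 0, 0)),
    bonded_hydrogens = list(integer(0), 2L, integer(0)))
  gr <- hb_groups(mr)
  expect_equal(hbond_count_series(
    trajectory_ensemble(mr, array(rep(mr$coords, each = 1),
                                  dim = c(1, 3, 3))), gr$a, gr$b)$mean, 1)
})

test_that("Coulomb term matches the analytic expression", {
  m <- make_charge_pair_fixture(q1 = 1, q2 = 1, r = 0.5)
  g <- hb_groups(m)
  e <- pair_energy(m$coords, m, g$a, g$b)
  expect_equal(unname(e["e_coul"]), 277.870916, tolerance = 1e-9)
  expect_equal(unname(e["e_vdw"]), 0)

  # opposite charges attract (negative), like repel (positive)
  m2 <- make_charge_pair_fixture(q1 = 1, q2 = -1, r = 0.5)
  expect_lt(pair_energy(m2$coords, m2, g$a, g$b)["e_coul"], 0)
})

test_that("Lennard-Jones term hits its minimum, zero crossing, and cutoff", {
  sig <- 0.34; eps <- 0.7
  rmin <- 2^(1 / 6) * sig
  m <- make_charge_pair_fixture(sigma = sig, epsilon = eps, r = rmin)
  g <- hb_groups(m)
  e <- pair_energy(m$coords, m, g$a, g$b)
  expect_equal(unname(e["e_vdw"]), -eps, tolerance = 1e-12)
  expect_equal(unname(e["e_coul"]), 0)

  m0 <- make_charge_pair_fixture(sigma = sig, epsilon = eps, r = sig)
  expect_equal(unname(pair_energy(m0$coords, m0, g$a, g$b)["e_vdw"]), 0,
               tolerance = 1e-12)

  mfar <- make_charge_pair_fixture(q1 = 1, q2 = 1, sigma = sig,
                                   epsilon = eps, r = 1.1)
  expect_equal(unname(pair_energy(mfar$coords, mfar, g$a, g$b)),
               c(0, 0), ignore_attr = TRUE)

  mclash <- make_charge_pair_fixture(q1 = 1, q2 = 1, r = 0.01)
  expect_error(pair_energy(mclash$coords, mclash, g$a, g$b), "clash")
})

test_that("pair energy is symmetric, additive over groups, and linear in charge", {
  m <- make_charged_cluster(12, seed = 52)
  A <- sel_ids(0:3); B <- sel_ids(4:7); C <- sel_ids(8:11)
  eAB <- pair_energy(m$coords, m, A, B)
  eBA <- pair_energy(m$coords, m, B, A)
  expect_identical(eAB, eBA)

  eAC <- pair_energy(m$coords, m, A, C)
  eA_BC <- pair_energy(m$coords, m, A, sel_ids(4:11))
  expect_equal(eA_BC, eAB + eAC, tolerance = 1e-12)

  # zeroing one charge changes e_coul by exactly that atom's pair sum
  m0 <- m
  m0$atoms$charge[1] <- 0
  e0 <- pair_energy(m0$coords, m0, A, B)
  single <- pair_energy(m$coords, m, sel_ids(0), B)
  expect_equal(unname(eAB["e_coul"] - e0["e_coul"]),
               unname(single["e_coul"]), tolerance = 1e-12)

  expect_error(pair_energy(m$coords, m, A, sel_ids(2:5)), "overlap")
})

test_that("minimum-image convention folds pair distances into the box", {
  m <- make_charge_pair_fixture(q1 = 1, q2 = 1, r = 1.7)
  g <- hb_groups(m)
  # unwrapped distance 1.7 nm is beyond the cutoff...
  expect_equal(unname(pair_energy(m$coords, m, g$a, g$b)["e_coul"]), 0)
  # ...but wraps to 0.3 nm in a 2 nm box
  e <- pair_energy(m$coords, m, g$a, g$b, box = c(2, 2, 2))
  expect_equal(unname(e["e_coul"]), 138.935458 / 0.3, tolerance = 1e-9)
})

test_that("interaction profile aggregates per-frame series and obeys the decomposition identity", {
  m <- make_charge_pair_fixture(q1 = 1, q2 = -1, sigma = 0.3, epsilon = 0.4,
                                r = 0.5)
  g <- hb_groups(m)
  # frame 2 beyond the cutoff: energies 0
  fr <- array(0, dim = c(2, 2, 3))
  fr[1, , ] <- m$coords
  fr[2, , ] <- m$coords; fr[2, 2, 1] <- 1.5
  traj <- trajectory_ensemble(m, fr)
  prof <- interaction_profile(traj, g$a, g$b)
  e1 <- pair_energy(m$coords, m, g$a, g$b)
  expect_equal(prof$e_coul_series, c(e1[["e_coul"]], 0))
  expect_equal(prof$mean_e_coul, e1[["e_coul"]] / 2)
  expect_equal(prof$mean_e_total, prof$mean_e_coul + prof$mean_e_vdw)

  static <- trajectory_ensemble(m, fr[c(1, 1), , ])
  profs <- interaction_profile(static, g$a, g$b)
  expect_equal(profs$mean_e_vdw, e1[["e_vdw"]])
})

test_that("delta-vs-reference is componentwise with the additivity identity", {
  m <- make_charge_pair_fixture(q1 = 1, q2 = -1, sigma = 0.3, epsilon = 0.4,
                                r = 0.5)
  g <- hb_groups(m)
  traj <- trajectory_ensemble(m, array(rep(m$coords, each = 2),
                                       dim = c(2, 2, 3)))
  prof <- interaction_profile(traj, g$a, g$b)
  d0 <- delta_vs_reference(prof, prof)
  expect_equal(d0$delta_e_total, 0)
  expect_equal(d0$delta_hbonds, 0)

  ref <- prof; ref$mean_e_coul <- -100
  mod <- prof; mod$mean_e_coul <- -80
  d <- delta_vs_reference(mod, ref)
  expect_equal(d$delta_e_coul, 20)  # destabilized
  expect_equal(d$delta_e_total, d$delta_e_coul + d$delta_e_vdw,
               tolerance = 1e-12)
})

test_that("contact residues follow the cutoff and occupancy threshold", {
  # probe atom at origin; residue 10 at 4.9 A, residue 20 at 5.1 A
  m <- structure_model(
    atom_name = c("P", "CB", "CB"), element = c("P", "C", "C"),
    residue_seq = c(1L, 10L, 20L), residue_name = c("MPT", "ARG", "LYS"),
    chain_id = c("B", "A", "A"),
    coords = rbind(c(0, 0, 0), c(0.49, 0, 0), c(0.51, 0, 0)))
  probe <- select_atoms(m, "chain B")
  targ <- select_atoms(m, "chain A")
  traj <- trajectory_ensemble(m, array(rep(m$coords, each = 1),
                                       dim = c(1, 3, 3)))
  got <- contact_residues(traj, probe, targ, cutoff = 5.0)
  expect_equal(got$residue_seq, 10L)
  expect_equal(got$occupancy, 1.0)

  # contact in 1 of 2 frames: present at threshold 0.5, absent at 0.75
  fr <- array(rep(m$coords, each = 2), dim = c(2, 3, 3))
  fr[2, 2, 1] <- 0.8
  t2 <- trajectory_ensemble(m, fr)
  expect_equal(contact_residues(t2, probe, targ, 5, 0.5)$residue_seq, 10L)
  expect_equal(nrow(contact_residues(t2, probe, targ, 5, 0.75)), 0L)
  expect_error(contact_residues(t2, probe, targ, cutoff = -1), "cutoff")
})
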