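#' Geometric hydrogen-bond detection in one frame
#'
#' A hydrogen bond is defined geometrically: donor-acceptor distance
#' <= \code{d_cut} (3.5 Angstrom by default) and hydrogen-donor-acceptor
#' angle <= \code{a_cut} (30 degrees by default). Both cutoffs are
#' inclusive, so boundary fixtures are deterministic. Donors are N/O atoms
#' with at least one bonded hydrogen; acceptors are N/O atoms; sulfur is
#' excluded (no relevant polar contacts at this level of description).
#'
#' @param coords n_atoms x 3 coordinate matrix, nm.
#' @param structure a \code{StructureModel} with \code{bonded_hydrogens}
#'   populated for donor atoms.
#' @param donors_sel,acceptors_sel \code{AtomSelection}s to scan.
#' @param d_cut donor-acceptor distance cutoff, Angstrom.
#' @param a_cut hydrogen-donor-acceptor angle cutoff, degrees.
#' @param box optional box lengths (nm) for minimum-image distances.
#' @param warn warn about candidate donors with no bonded hydrogens
#'   (they are skipped either way).
#' @return data.frame with one row per (donor, hydrogen, acceptor) triple
#'   passing both cutoffs: 0-based atom ids, \code{distance_DA}
#'   (Angstrom), \code{angle_HDA} (degrees).
#' @export
detect_hbonds <- function(coords, structure, donors_sel, acceptors_sel,
                          d_cut = 3.5, a_cut = 30, box = NULL, warn = TRUE) {
  a <- structure$atoms
  don <- donors_sel$indices
  don <- don[a$element[don + 1L] %in% c("N", "O")]
  if (length(don)) {
    has_h <- lengths(structure$bonded_hydrogens[don + 1L]) > 0
    if (any(!has_h) && warn)
      warning(sum(!has_h),
              " candidate donor(s) have no bonded hydrogens; skipped")
    don <- don[has_h]
  }
  acc <- acceptors_sel$indices
  acc <- acc[a$element[acc + 1L] %in% c("N", "O")]
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance_DA = numeric(0),
                      angle_HDA = numeric(0))
  if (!length(don) || !length(acc)) return(empty)
  out <- vector("list", length(don))
  d_cut_nm <- d_cut / 10
  for (k in seq_along(don)) {
    d_id <- don[k]
    dv <- sweep(coords[acc + 1L, , drop = FALSE], 2, coords[d_id + 1L, ])
    if (!is.null(box)) dv <- t(apply(dv, 1, minimum_image, box = box))
    dd <- sqrt(rowSums(dv^2))
    ok <- which(dd <= d_cut_nm & acc != d_id)
    if (!length(ok)) next
    rows <- list()
    for (h_id in structure$bonded_hydrogens[[d_id + 1L]]) {
      hv <- coords[h_id + 1L, ] - coords[d_id + 1L, ]
      if (!is.null(box)) hv <- minimum_image(hv, box)
      nh <- sqrt(sum(hv^2))
      for (j in ok) {
        cosang <- sum(hv * dv[j, ]) / (nh * dd[j])
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= a_cut)
          rows[[length(rows) + 1L]] <- data.frame(
            donor = d_id, hydrogen = h_id, acceptor = acc[j],
            distance_DA = dd[j] * 10, angle_HDA = ang)
      }
    }
    if (length(rows)) out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Hydrogen-bond count per frame between two groups
#'
#' Counts bonds with donor in group A / acceptor in group B plus donor in
#' group B / acceptor in group A, per frame, and the window mean.
#'
#' @param traj a \code{TrajectoryEnsemble}.
#' @param group_a,group_b \code{AtomSelection}s (disjoint groups).
#' @param d_cut,a_cut cutoffs as in \code{\link{detect_hbonds}}.
#' @param window integer pair (first, last).
#' @return list with \code{counts} per frame and \code{mean}.
#' @export
hbond_count_series <- function(traj, group_a, group_b,
                               d_cut = 3.5, a_cut = 30, window = NULL) {
  window <- check_window(window, n_frames(traj))
  structure <- traj$structure
  idx <- seq(window[1], window[2])
  counts <- vapply(idx, function(i) {
    x <- get_frame(traj, i)
    box <- if (is.null(traj$box)) NULL else traj$box[i, ]
    nrow(detect_hbonds(x, structure, group_a, group_b, d_cut, a_cut, box,
                       warn = FALSE)) +
      nrow(detect_hbonds(x, structure, group_b, group_a, d_cut, a_cut, box,
                         warn = FALSE))
  }, numeric(1))
  list(counts = counts, mean = mean(counts))
}

# Coulomb conversion factor, kJ mol^-1 nm e^-2 (1 / 4 pi eps0)
COULOMB_KJ_NM_E2 <- 138.935458

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Short-range pairwise decomposition over all pairs (i in A, j in B) with
#' r_ij <= \code{r_cut} (inclusive), hard truncation without switch or
#' shift:
#' \deqn{E_{Coul} = \sum f q_i q_j / r_{ij}, \quad
#'       E_{vdW} = \sum 4\epsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} -
#'                 (\sigma_{ij}/r_{ij})^6]}
#' with f = 138.935458 kJ mol^-1 nm e^-2 and Lorentz-Berthelot combination
#' (arithmetic-mean sigma, geometric-mean epsilon — the AMBER-family
#' convention). Minimum-image distances are used when a box is supplied.
#' No reciprocal-space (Ewald) term is included: a per-group decomposition
#' of the long-range mesh contribution is not defined here, so group
#' energies carry a systematic short-range-only offset relative to a full
#' lattice-summed electrostatic energy.
#'
#' @param coords n_atoms x 3 coordinate matrix, nm.
#' @param structure a \code{StructureModel} with charges/LJ populated.
#' @param group_a,group_b disjoint \code{AtomSelection}s.
#' @param r_cut cutoff, nm (default 1.0).
#' @param box optional box lengths (nm).
#' @return named numeric vector \code{c(e_coul, e_vdw)} in kJ/mol.
#' @export
pair_energy <- function(coords, structure, group_a, group_b, r_cut = 1.0,
                        box = NULL) {
  ia <- group_a$indices; ib <- group_b$indices
  if (length(intersect(ia, ib)))
    stop("interaction groups overlap (", length(intersect(ia, ib)),
         " shared atoms)")
  # canonical group order so (A,B) and (B,A) run the identical computation
  if (min(ib) < min(ia)) { tmp <- ia; ia <- ib; ib <- tmp }
  a <- structure$atoms
  xa <- coords[ia + 1L, , drop = FALSE]; xb <- coords[ib + 1L, , drop = FALSE]
  # pair displacement tensor, minimum image per axis
  d2 <- matrix(0, length(ia), length(ib))
  for (ax in 1:3) {
    dx <- outer(xa[, ax], xb[, ax], "-")
    if (!is.null(box)) dx <- dx - box[ax] * round(dx / box[ax])
    d2 <- d2 + dx * dx
  }
  r <- sqrt(d2)
  if (any(r < 0.05))
    stop(sprintf("atomic clash: pair distance %.4f nm < 0.05 nm; energies meaningless",
                 min(r)))
  within <- r <= r_cut
  if (!any(within)) return(c(e_coul = 0, e_vdw = 0))
  qq <- outer(a$charge[ia + 1L], a$charge[ib + 1L])
  e_coul <- COULOMB_KJ_NM_E2 * sum((qq / r)[within])
  sig <- outer(a$lj_sigma[ia + 1L], a$lj_sigma[ib + 1L], "+") / 2
  eps <- sqrt(outer(a$lj_epsilon[ia + 1L], a$lj_epsilon[ib + 1L]))
  sr6 <- (sig / r)^6
  e_vdw <- sum((4 * eps * (sr6^2 - sr6))[within])
  c(e_coul = e_coul, e_vdw = e_vdw)
}

#' Per-frame interaction profile between two groups
#'
#' Evaluates \code{\link{pair_energy}} and the hydrogen-bond count for
#' every frame in the window and summarizes the means. The decomposition
#' identity mean_e_total = mean_e_coul + mean_e_vdw holds to float
#' precision by construction.
#'
#' @param traj a \code{TrajectoryEnsemble}.
#' @param group_a,group_b disjoint \code{AtomSelection}s.
#' @param r_cut energy cutoff, nm.
#' @param d_cut,a_cut hydrogen-bond cutoffs (Angstrom, degrees).
#' @param window integer pair (first, last).
#' @return object of class \code{InteractionProfile}.
#' @export
interaction_profile <- function(traj, group_a, group_b, r_cut = 1.0,
                                d_cut = 3.5, a_cut = 30, window = NULL) {
  window <- check_window(window, n_frames(traj))
  idx <- seq(window[1], window[2])
  e <- vapply(idx, function(i) {
    box <- if (is.null(traj$box)) NULL else traj$box[i, ]
    pair_energy(get_frame(traj, i), traj$structure, group_a, group_b,
                r_cut, box)
  }, numeric(2))
  hb <- hbond_count_series(traj, group_a, group_b, d_cut, a_cut, window)
  structure(list(
    e_coul_series = e[1, ], e_vdw_series = e[2, ],
    mean_e_coul = mean(e[1, ]), mean_e_vdw = mean(e[2, ]),
    mean_e_total = mean(e[1, ]) + mean(e[2, ]),
    hbond_count_series = hb$counts, mean_hbonds = hb$mean,
    window = window
  ), class = "InteractionProfile")
}

#' @export
print.InteractionProfile <- function(x, ...) {
  cat(sprintf(
    "InteractionProfile: E_coul %.2f, E_vdw %.2f, E_total %.2f kJ/mol; %.2f H-bonds\n",
    x$mean_e_coul, x$mean_e_vdw, x$mean_e_total, x$mean_hbonds))
  invisible(x)
}

#' Interaction differences of a modified system versus a reference
#'
#' Componentwise modified - reference. Positive energy differences mean
#' the modification destabilizes the interaction (the modified complex
#' binds less favourably than the reference).
#'
#' @param modified,reference \code{InteractionProfile}s.
#' @return object of class \code{DeltaProfile} with
#'   \code{delta_e_total}, \code{delta_e_coul}, \code{delta_e_vdw}
#'   (kJ/mol) and \code{delta_hbonds}.
#' @export
delta_vs_reference <- function(modified, reference) {
  structure(list(
    delta_e_coul = modified$mean_e_coul - reference$mean_e_coul,
    delta_e_vdw = modified$mean_e_vdw - reference$mean_e_vdw,
    delta_e_total = (modified$mean_e_coul + modified$mean_e_vdw) -
      (reference$mean_e_coul + reference$mean_e_vdw),
    delta_hbonds = modified$mean_hbonds - reference$mean_hbonds
  ), class = "DeltaProfile")
}

#' Contact-residue shell around a probe group
#'
#' A target residue is in contact in a frame if any of its atoms lies
#' within \code{cutoff} of any probe atom; residues are reported when
#' their frame occupancy reaches \code{occupancy_threshold}. The default
#' threshold of 0.5 asks for contact in at least half the frames.
#'
#' @param traj a \code{TrajectoryEnsemble}.
#' @param probe_sel probe atoms (e.g. a modified linkage or methyl group).
#' @param target_sel candidate contact atoms (e.g. all protein atoms).
#' @param cutoff contact distance, Angstrom (> 0).
#' @param occupancy_threshold minimum fraction of frames in contact.
#' @param window integer pair (first, last).
#' @return data.frame (chain_id, residue_seq, residue_name, occupancy),
#'   occupancy-descending, restricted to residues passing the threshold.
#' @export
contact_residues <- function(traj, probe_sel, target_sel, cutoff = 5.0,
                             occupancy_threshold = 0.5, window = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  window <- check_window(window, n_frames(traj))
  a <- traj$structure$atoms
  ti <- target_sel$indices + 1L; pi_ <- probe_sel$indices + 1L
  res_key <- paste(a$chain_id[ti], a$residue_seq[ti], a$residue_name[ti])
  keys <- unique(res_key)
  cut_nm <- cutoff / 10
  idx <- seq(window[1], window[2])
  hits <- matrix(0, length(keys), length(idx),
                 dimnames = list(keys, NULL))
  for (f in seq_along(idx)) {
    x <- traj$frames[idx[f], , ]
    d2 <- matrix(0, length(ti), length(pi_))
    for (ax in 1:3) {
      dx <- outer(x[ti, ax], x[pi_, ax], "-")
      if (!is.null(traj$box)) {
        b <- traj$box[idx[f], ax]
        dx <- dx - b * round(dx / b)
      }
      d2 <- d2 + dx * dx
    }
    close_atom <- apply(d2 <= cut_nm^2, 1, any)
    in_contact <- tapply(close_atom, res_key, any)
    hits[names(in_contact), f] <- as.numeric(in_contact)
  }
  occ <- rowMeans(hits)
  keep <- occ >= occupancy_threshold
  parts <- do.call(rbind, strsplit(keys[keep], " "))
  out <- if (any(keep)) data.frame(
    chain_id = parts[, 1], residue_seq = as.integer(parts[, 2]),
    residue_name = parts[, 3], occupancy = occ[keep],
    stringsAsFactors = FALSE
  ) else data.frame(chain_id = character(0), residue_seq = integer(0),
                    residue_name = character(0), occupancy = numeric(0))
  out[order(-out$occupancy, out$residue_seq), , drop = FALSE]
}
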