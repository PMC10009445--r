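#' Positional covariance matrix of a selection over a trajectory window
#'
#' Builds the 3N x 3N covariance matrix
#' C_ij = < (x_i - <x_i>)(x_j - <x_j>) > over the selected atoms, in
#' selection order, using the population estimator (divide by the number
#' of frames M, matching the ensemble-average definition). By default each
#' frame is first Kabsch-superposed onto the running mean of the selection
#' (two passes), because unfitted covariance conflates rigid-body and
#' internal motion; pass \code{superpose = FALSE} for ensembles known to
#' carry no rigid-body component, or a \code{fit_reference} coordinate
#' matrix to fit onto a fixed structure instead.
#'
#' @param traj a \code{TrajectoryEnsemble}.
#' @param selection \code{AtomSelection} of N atoms (Calpha, typically).
#' @param window integer pair (first, last); needs >= 2 frames.
#' @param superpose logical; fit frames before taking deviations.
#' @param fit_reference optional N x 3 matrix (nm); when given, frames are
#'   fitted onto it in a single pass.
#' @return object of class \code{CovarianceModel}: \code{selection},
#'   \code{mean_coords} (N x 3, nm), \code{matrix} (3N x 3N, nm^2),
#'   \code{n_frames_used}.
#' @export
build_covariance <- function(traj, selection, window = NULL,
                             superpose = TRUE, fit_reference = NULL) {
  window <- check_window(window, n_frames(traj))
  m <- window[2] - window[1] + 1L
  if (m < 2) stop("need at least 2 frames to estimate a covariance")
  rows <- sel_rows(selection)
  n <- length(rows)
  idx <- seq(window[1], window[2])
  # M x N x 3 working copy of the selected coordinates
  X <- traj$frames[idx, rows, , drop = FALSE]
  if (superpose) {
    fit_one_pass <- function(X, ref) {
      for (i in seq_len(dim(X)[1])) {
        fit <- kabsch_superpose(X[i, , ], ref)
        X[i, , ] <- apply_transform(X[i, , ], fit)
      }
      X
    }
    if (!is.null(fit_reference)) {
      stopifnot(nrow(fit_reference) == n)
      X <- fit_one_pass(X, as.matrix(fit_reference))
    } else {
      for (pass in 1:2) {
        ref <- apply(X, c(2, 3), mean)
        X <- fit_one_pass(X, ref)
      }
    }
  }
  # flatten to M x 3N in (x1,y1,z1,x2,...) order
  flat <- matrix(0, m, 3 * n)
  for (ax in 1:3) flat[, seq(ax, 3 * n, by = 3)] <- X[, , ax]
  mu <- colMeans(flat)
  dev <- sweep(flat, 2, mu)
  C <- crossprod(dev) / m
  mean_coords <- matrix(mu, n, 3, byrow = TRUE)
  structure(list(selection = selection, mean_coords = mean_coords,
                 matrix = C, n_frames_used = m),
            class = "CovarianceModel")
}

#' @export
print.CovarianceModel <- function(x, ...) {
  cat(sprintf("CovarianceModel: %d atoms (3N = %d), %d frames, trace %.4g nm^2\n",
              nrow(x$mean_coords), nrow(x$matrix), x$n_frames_used,
              sum(diag(x$matrix))))
  invisible(x)
}

#' Principal modes (essential dynamics) of a covariance model
#'
#' Symmetric eigendecomposition of the covariance matrix. Eigenvalues are
#' the mean-square fluctuations along each mode (nm^2), sorted descending,
#' so the first principal component is the collective motion with the
#' largest amplitude. Each eigenvector's sign is canonicalized (its
#' largest-magnitude component made positive) so repeated runs and
#' different LAPACK builds produce identical output; the directional
#' similarity machinery handles the remaining physical sign ambiguity
#' explicitly (see \code{\link{directional_similarity}}).
#'
#' @param cov a \code{CovarianceModel} (or a plain symmetric matrix).
#' @param n_modes how many leading modes to keep; default all.
#' @return object of class \code{PrincipalModes}: \code{values} (nm^2),
#'   \code{vectors} (3N x n_modes, orthonormal columns), \code{n_atoms},
#'   and the originating \code{selection} if available.
#' @export
principal_modes <- function(cov, n_modes = NULL) {
  C <- if (inherits(cov, "CovarianceModel")) cov$matrix else as.matrix(cov)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("covariance matrix is not symmetric")
  C <- (C + t(C)) / 2
  d <- nrow(C)
  if (is.null(n_modes)) n_modes <- d
  if (n_modes > d) stop("n_modes exceeds matrix dimension ", d)
  eig <- eigen(C, symmetric = TRUE)
  vals <- eig$values[seq_len(n_modes)]
  vecs <- eig$vectors[, seq_len(n_modes), drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(values = vals, vectors = vecs, n_atoms = d / 3,
                 selection = if (inherits(cov, "CovarianceModel"))
                   cov$selection else NULL),
            class = "PrincipalModes")
}

#' @export
print.PrincipalModes <- function(x, ...) {
  cat(sprintf("PrincipalModes: %d modes over %d atoms; leading eigenvalues %s nm^2\n",
              length(x$values), x$n_atoms,
              paste(signif(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Per-atom 3-vector slice of one mode
#'
#' @param modes a \code{PrincipalModes}.
#' @param mode mode index (1 = largest eigenvalue).
#' @return N x 3 matrix of per-atom mode components.
#' @export
mode_slices <- function(modes, mode) {
  v <- modes$vectors[, mode]
  matrix(v, ncol = 3, byrow = TRUE)
}

# per-atom (1 - theta_i/pi) terms between two N x 3 slice matrices;
# atoms where either slice has negligible norm contribute the
# uninformative midpoint 0.5 so N stays fixed. theta via
# atan2(|a x b|, a.b): exact at 0, pi/2 and pi, unlike acos of a
# rounded cosine
sigma_terms <- function(slice_test, slice_ref) {
  dot <- rowSums(slice_test * slice_ref)
  cx <- slice_test[, 2] * slice_ref[, 3] - slice_test[, 3] * slice_ref[, 2]
  cy <- slice_test[, 3] * slice_ref[, 1] - slice_test[, 1] * slice_ref[, 3]
  cz <- slice_test[, 1] * slice_ref[, 2] - slice_test[, 2] * slice_ref[, 1]
  cross <- sqrt(cx^2 + cy^2 + cz^2)
  na <- sqrt(rowSums(slice_test^2)); nb <- sqrt(rowSums(slice_ref^2))
  deg <- na < 1e-12 | nb < 1e-12
  theta <- atan2(cross, dot)
  theta[deg] <- pi / 2
  1 - theta / pi
}

#' Directional similarity between two principal modes
#'
#' For each atom i, the angle theta_i between the test mode's and the
#' reference mode's per-atom 3-vectors is computed; the similarity is
#' \deqn{\sigma_{mn} = \frac{1}{N}\sum_i (1 - \theta_i/\pi)}
#' which is 1 for identical motion, 0.5 for everywhere-orthogonal motion,
#' and 0 for exactly opposite motion.
#'
#' Eigenvectors are defined only up to a global sign and sigma is not
#' sign-invariant (negating one mode maps sigma to 1 - sigma). With
#' \code{sign_policy = "maximize"} (the default) the test mode is globally
#' negated iff that raises sigma, and the flip is recorded in the
#' \code{"flipped"} attribute; \code{"off"} evaluates the formula
#' literally on the vectors as given.
#'
#' @param modes_test,modes_ref \code{PrincipalModes} over the same N atoms
#'   in the same order.
#' @param m,n mode indices into test and reference respectively.
#' @param sign_policy "maximize" or "off".
#' @return sigma in [0, 1], with attribute \code{flipped} (logical).
#' @export
directional_similarity <- function(modes_test, modes_ref, m = 1, n = 1,
                                   sign_policy = c("maximize", "off")) {
  sign_policy <- match.arg(sign_policy)
  if (modes_test$n_atoms != modes_ref$n_atoms)
    stop(sprintf("atom-count mismatch: %d vs %d",
                 modes_test$n_atoms, modes_ref$n_atoms))
  st <- mode_slices(modes_test, m); sr <- mode_slices(modes_ref, n)
  terms <- sigma_terms(st, sr)
  sigma <- mean(terms)
  flipped <- FALSE
  if (sign_policy == "maximize") {
    sigma_neg <- mean(sigma_terms(-st, sr))
    if (sigma_neg > sigma) {
      sigma <- sigma_neg
      flipped <- TRUE
    }
  }
  structure(sigma, flipped = flipped)
}

#' Conservation classification of the two leading motions
#'
#' Computes the 2 x 2 directional-similarity matrix between the first two
#' principal components of a test system and of a reference system, sums
#' its diagonal (Sigma_C = sigma_11 + sigma_22) and off-diagonal
#' (Sigma_U = sigma_12 + sigma_21), and classifies: Sigma_C > Sigma_U
#' means the two leading motions of the test system correspond to the
#' reference's (conserved); Sigma_C < Sigma_U means they are swapped or
#' altered (unconserved); ties to 1e-12 are labelled ambiguous. Only the
#' first two modes enter the classification — they carry the dominant
#' collective motions; higher modes are computed by
#' \code{\link{principal_modes}} but unused here.
#'
#' The per-atom diagonal terms
#' (1 - theta_i^11/pi) + (1 - theta_i^22/pi), evaluated with the same sign
#' flips as sigma_11/sigma_22, form the per-residue decomposition: their
#' mean over atoms equals Sigma_C exactly.
#'
#' @param modes_test,modes_ref \code{PrincipalModes} with >= 2 modes over
#'   the same atoms.
#' @param sign_policy "maximize" (default) or "off"; see
#'   \code{\link{directional_similarity}}.
#' @return object of class \code{ConservationResult}: \code{sigma} (2 x 2),
#'   \code{sigma_c}, \code{sigma_u}, \code{label}, \code{per_residue_sigma_c}
#'   (per-atom, in [0, 2]), \code{sign_flips} (2 x 2 logical).
#' @export
conservation_classify <- function(modes_test, modes_ref,
                                  sign_policy = c("maximize", "off")) {
  sign_policy <- match.arg(sign_policy)
  if (length(modes_test$values) < 2 || length(modes_ref$values) < 2)
    stop("conservation classification needs at least 2 modes per system")
  if (modes_test$n_atoms != modes_ref$n_atoms)
    stop(sprintf("atom-count mismatch: %d vs %d",
                 modes_test$n_atoms, modes_ref$n_atoms))
  sigma <- matrix(0, 2, 2, dimnames = list(paste0("test_pc", 1:2),
                                           paste0("ref_pc", 1:2)))
  flips <- matrix(FALSE, 2, 2, dimnames = dimnames(sigma))
  diag_terms <- matrix(0, modes_test$n_atoms, 2)
  for (m in 1:2) for (n in 1:2) {
    st <- mode_slices(modes_test, m); sr <- mode_slices(modes_ref, n)
    terms <- sigma_terms(st, sr)
    if (sign_policy == "maximize") {
      terms_neg <- sigma_terms(-st, sr)
      if (mean(terms_neg) > mean(terms)) {
        terms <- terms_neg
        flips[m, n] <- TRUE
      }
    }
    sigma[m, n] <- mean(terms)
    if (m == n) diag_terms[, m] <- terms
  }
  sigma_c <- sigma[1, 1] + sigma[2, 2]
  sigma_u <- sigma[1, 2] + sigma[2, 1]
  label <- if (abs(sigma_c - sigma_u) <= 1e-12) "ambiguous"
           else if (sigma_c > sigma_u) "conserved" else "unconserved"
  structure(list(sigma = sigma, sigma_c = sigma_c, sigma_u = sigma_u,
                 label = label,
                 per_residue_sigma_c = diag_terms[, 1] + diag_terms[, 2],
                 sign_flips = flips,
                 selection = modes_test$selection),
            class = "ConservationResult")
}

#' @export
print.ConservationResult <- function(x, ...) {
  cat(sprintf("ConservationResult: Sigma_C = %.3f, Sigma_U = %.3f -> %s\n",
              x$sigma_c, x$sigma_u, x$label))
  invisible(x)
}

#' Per-residue decomposition of the conservation parameter
#'
#' Maps the per-atom Sigma_C terms (range [0, 2], one Calpha per residue)
#' onto residue labels from the structure, optionally restricted to a
#' residue range such as a loop of interest. The mean of the full table
#' equals Sigma_C by construction.
#'
#' @param result a \code{ConservationResult} carrying its selection.
#' @param structure the \code{StructureModel} the selection refers to.
#' @param residue_range optional integer vector of residue_seq values to
#'   keep (e.g. \code{500:520}).
#' @return data.frame (chain_id, residue_seq, residue_name, sigma_c).
#' @export
per_residue_conservation <- function(result, structure, residue_range = NULL) {
  if (is.null(result$selection))
    stop("result carries no atom selection; cannot map atoms to residues")
  rows <- sel_rows(result$selection)
  a <- structure$atoms
  out <- data.frame(
    chain_id = a$chain_id[rows],
    residue_seq = a$residue_seq[rows],
    residue_name = a$residue_name[rows],
    sigma_c = result$per_residue_sigma_c,
    stringsAsFactors = FALSE
  )
  if (!is.null(residue_range))
    out <- out[out$residue_seq %in% residue_range, , drop = FALSE]
  out
}

#' Write principal modes as an NMD-style plain-text file
#'
#' Emits a minimal NMD (normal-mode data) file — coordinates line plus one
#' mode line per principal component, each scaled by sqrt(eigenvalue) —
#' readable by common mode viewers.
#'
#' @param modes a \code{PrincipalModes}.
#' @param mean_coords N x 3 mean coordinates, nm (written in Angstrom).
#' @param path output path.
#' @param n_modes how many modes to write.
#' @export
write_nmd <- function(modes, mean_coords, path, n_modes = length(modes$values)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("nmd generated by motioncons", con)
  writeLines(paste("coordinates",
                   paste(sprintf("%.3f", t(mean_coords) * 10), collapse = " ")),
             con)
  for (k in seq_len(n_modes)) {
    writeLines(paste("mode", k, sprintf("%.6f", sqrt(max(modes$values[k], 0))),
                     paste(sprintf("%.5f", modes$vectors[, k]), collapse = " ")),
               con)
  }
  invisible(path)
}
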