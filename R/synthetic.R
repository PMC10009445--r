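#' Planted-mode specification for synthetic Gaussian ensembles
#'
#' Describes a multivariate-normal positional ensemble whose covariance is
#' built from a small set of prescribed ("planted") principal modes plus
#' isotropic residual noise in the orthogonal complement:
#' \deqn{\Sigma = \sum_k \lambda_k v_k v_k^T +
#'       \sigma^2_{res} (I - \sum_k v_k v_k^T).}
#' Planted ensembles are the ground-truth stand-in for equilibrium MD
#' trajectories: downstream PCA should recover the modes and their
#' variances.
#'
#' @param n_atoms number of (pseudo-)atoms N.
#' @param modes 3N x k matrix of mutually orthonormal mode vectors
#'   (orthonormal to 1e-10).
#' @param eigenvalues length-k variances along the modes, nm^2, strictly
#'   decreasing and all > residual_variance.
#' @param residual_variance isotropic variance of the orthogonal
#'   complement, nm^2.
#' @param mean_structure N x 3 mean coordinates, nm.
#' @param n_frames number of frames to draw (>= 2).
#' @param seed integer seed; generation never touches global RNG state.
#' @return object of class \code{PlantedModeSpec}.
#' @export
planted_mode_spec <- function(n_atoms, modes, eigenvalues, residual_variance,
                              mean_structure, n_frames, seed) {
  modes <- as.matrix(modes)
  stopifnot(nrow(modes) == 3 * n_atoms)
  G <- crossprod(modes)
  off <- max(abs(G - diag(ncol(modes))))
  if (off > 1e-10)
    stop(sprintf("modes are not orthonormal (max gram deviation %.3g)", off))
  if (length(eigenvalues) != ncol(modes))
    stop("one eigenvalue per mode required")
  if (any(diff(eigenvalues) >= 0))
    stop("eigenvalues must be strictly decreasing")
  if (any(eigenvalues <= residual_variance))
    stop("eigenvalues must all exceed residual_variance")
  mean_structure <- as.matrix(mean_structure)
  stopifnot(nrow(mean_structure) == n_atoms, ncol(mean_structure) == 3)
  if (n_frames < 2) stop("n_frames must be >= 2")
  structure(list(n_atoms = n_atoms, modes = modes,
                 eigenvalues = as.numeric(eigenvalues),
                 residual_variance = residual_variance,
                 mean_structure = mean_structure,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "PlantedModeSpec")
}

# run expr with a local RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a synthetic Gaussian ensemble with planted principal modes
#'
#' Frames are drawn i.i.d. from a zero-mean multivariate normal with the
#' spec's covariance and added to the mean structure. There is no temporal
#' correlation between frames: every statistic in this package is a
#' single-time-point functional of the ensemble, so autocorrelation is
#' irrelevant to correctness (it would only change effective sample sizes
#' on real data).
#'
#' @param spec a \code{PlantedModeSpec}.
#' @return a \code{TrajectoryEnsemble} over a pseudo-Calpha
#'   \code{StructureModel} (one CA atom per residue, chain A).
#' @export
generate_gaussian_ensemble <- function(spec) {
  stopifnot(inherits(spec, "PlantedModeSpec"))
  structure_mod <- ca_pseudo_structure(spec$mean_structure)
  traj <- with_seed(spec$seed, {
    M <- spec$n_frames
    d <- 3 * spec$n_atoms
    V <- spec$modes
    k <- ncol(V)
    Z <- matrix(stats::rnorm(M * k), M, k)            # mode amplitudes
    W <- matrix(stats::rnorm(M * d), M, d)            # complement noise
    W <- W - (W %*% V) %*% t(V)                       # project out modes
    X <- Z %*% (t(V) * sqrt(spec$eigenvalues)) +
      sqrt(spec$residual_variance) * W                # M x 3N deviations
    frames <- array(0, dim = c(M, spec$n_atoms, 3))
    for (ax in 1:3) {
      cols <- seq(ax, d, by = 3)
      frames[, , ax] <- sweep(X[, cols, drop = FALSE], 2,
                              spec$mean_structure[, ax], "+")
    }
    frames
  })
  trajectory_ensemble(structure_mod, traj)
}

# one CA pseudo-atom per residue on chain A
ca_pseudo_structure <- function(mean_coords) {
  n <- nrow(mean_coords)
  structure_model(
    atom_name = rep("CA", n), element = rep("C", n),
    residue_seq = seq_len(n), residue_name = rep("GLY", n),
    chain_id = rep("A", n), coords = mean_coords
  )
}

#' Perturbation of planted modes
#'
#' Builds the "modified system" ground truth for the conservation
#' classifier: \code{identity} leaves the leading motions untouched
#' (classifier should call conserved), \code{swap_first_two} exchanges the
#' first two modes (unconserved by construction), \code{rotate_in_plane}
#' mixes modes 1 and 2 by a given angle, and \code{randomize} replaces all
#' modes by a seeded random orthonormal set.
#'
#' @param kind one of "identity", "swap_first_two", "rotate_in_plane",
#'   "randomize".
#' @param angle rotation angle in radians, in [0, pi]; only used by
#'   \code{rotate_in_plane}.
#' @param seed integer seed for \code{randomize}.
#' @return object of class \code{PerturbationSpec}.
#' @export
perturbation_spec <- function(kind = c("identity", "swap_first_two",
                                       "rotate_in_plane", "randomize"),
                              angle = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "rotate_in_plane" && (angle < 0 || angle > pi))
    stop("angle must be in [0, pi]")
  structure(list(kind = kind, angle = angle, seed = as.integer(seed)),
            class = "PerturbationSpec")
}

#' Apply a perturbation to a planted-mode spec
#'
#' @param spec a \code{PlantedModeSpec}.
#' @param pert a \code{PerturbationSpec}.
#' @return a new \code{PlantedModeSpec} with perturbed modes (eigenvalues
#'   unchanged).
#' @export
perturb_modes <- function(spec, pert) {
  stopifnot(inherits(spec, "PlantedModeSpec"),
            inherits(pert, "PerturbationSpec"))
  V <- spec$modes
  if (pert$kind %in% c("swap_first_two", "rotate_in_plane") && ncol(V) < 2)
    stop("perturbation '", pert$kind, "' requires at least 2 modes")
  V2 <- switch(pert$kind,
    identity = V,
    swap_first_two = {
      W <- V; W[, 1] <- V[, 2]; W[, 2] <- V[, 1]; W
    },
    rotate_in_plane = {
      W <- V
      a <- pert$angle
      W[, 1] <- cos(a) * V[, 1] + sin(a) * V[, 2]
      W[, 2] <- -sin(a) * V[, 1] + cos(a) * V[, 2]
      W
    },
    randomize = with_seed(pert$seed,
                          random_orthonormal(nrow(V), ncol(V)))
  )
  out <- spec
  out$modes <- V2
  out
}

# k orthonormal columns in d dimensions via QR of a Gaussian matrix
random_orthonormal <- function(d, k) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  # fix QR sign convention so the draw is uniform over orientations
  s <- sign(stats::rnorm(k)); s[s == 0] <- 1
  sweep(Q, 2, s, "*")
}

#' Three-atom hydrogen-bond geometry fixture
#'
#' Builds a donor (N) + hydrogen + acceptor (O) structure with exactly the
#' requested donor-acceptor distance and hydrogen-donor-acceptor angle.
#' Donor and hydrogen sit on chain A, the acceptor on chain B, so the pair
#' spans the two interaction groups used in the H-bond census. The N-H
#' bond length is 1.0 Angstrom.
#'
#' @param d_DA donor-acceptor distance, Angstrom (> 0.9).
#' @param angle_HDA hydrogen-donor-acceptor angle, degrees, in [0, 180].
#' @return a \code{StructureModel} with \code{bonded_hydrogens} set.
#' @export
make_hbond_fixture <- function(d_DA, angle_HDA) {
  if (d_DA <= 0.9) stop("d_DA must exceed 0.9 Angstrom")
  if (angle_HDA < 0 || angle_HDA > 180) stop("angle_HDA must be in [0, 180]")
  a <- angle_HDA * pi / 180
  d_nm <- d_DA / 10
  coords <- rbind(
    c(0, 0, 0),                              # donor N at origin
    c(0.1 * cos(a), 0.1 * sin(a), 0),        # H: 1.0 A from donor
    c(d_nm, 0, 0)                            # acceptor O on +x
  )
  m <- structure_model(
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_seq = c(1L, 1L, 2L), residue_name = c("DON", "DON", "ACC"),
    chain_id = c("A", "A", "B"), coords = coords,
    bonded_hydrogens = list(1L, integer(0), integer(0))
  )
  m
}

#' Two-atom charge/LJ pair fixture
#'
#' Two atoms on the x-axis at separation \code{r} (nm), tagged as distinct
#' chains so they fall in different interaction groups for
#' \code{\link{pair_energy}}.
#'
#' @param q1,q2 partial charges, elementary units.
#' @param sigma,epsilon per-atom LJ parameters (nm, kJ/mol), applied to
#'   both atoms.
#' @param r separation, nm.
#' @return a \code{StructureModel}.
#' @export
make_charge_pair_fixture <- function(q1 = 0, q2 = 0, sigma = 0, epsilon = 0,
                                     r = 0.5) {
  structure_model(
    atom_name = c("Q1", "Q2"), element = c("N", "N"),
    residue_seq = c(1L, 2L), residue_name = c("ION", "ION"),
    chain_id = c("A", "B"), coords = rbind(c(0, 0, 0), c(r, 0, 0)),
    charge = c(q1, q2), lj_sigma = c(sigma, sigma),
    lj_epsilon = c(epsilon, epsilon)
  )
}
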