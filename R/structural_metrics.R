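#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation + translation mapping \code{mobile} onto
#' \code{reference}, via SVD of the weighted cross-covariance with the
#' proper-rotation (det = +1) correction. Superposition is unweighted by
#' default; with Calpha-only selections mass weighting is immaterial.
#'
#' @param mobile,reference N x 3 coordinate matrices (nm), N >= 3 and not
#'   collinear.
#' @param weights optional non-negative per-atom weights.
#' @return list with \code{rotation} (3 x 3, applied on the right:
#'   \code{x \%*\% rotation}), \code{translation} (length-3, nm), and
#'   \code{rmsd} after fitting, in Angstrom.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 atoms for a unique superposition")
  stopifnot(nrow(reference) == n, ncol(mobile) == 3, ncol(reference) == 3)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  # collinear point sets leave the rotation about the axis undetermined
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) coordinates: rotation not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R
  msd <- sum(w * rowSums((fitted - B)^2))
  list(rotation = R,
       translation = cr - as.numeric(cm %*% R),
       rmsd = sqrt(msd) * 10)  # nm -> Angstrom
}

apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

rmsd_A <- function(x, y) sqrt(mean(rowSums((x - y)^2))) * 10

#' RMSD time series against a reference structure
#'
#' Each frame is rigid-body superposed onto the reference over the fit
#' selection; the RMSD is then evaluated over the measure selection. The
#' reported mean covers the window only — equilibration frames are
#' excluded by windowing explicitly, never discarded automatically (see
#' \code{\link{find_equilibration}} for a helper that merely flags a
#' candidate frame).
#'
#' @param traj a \code{TrajectoryEnsemble}.
#' @param reference a \code{StructureModel} with matching atoms.
#' @param fit_sel selection used for superposition; defaults to
#'   \code{measure_sel}.
#' @param measure_sel selection over which RMSD is computed.
#' @param window integer pair (first, last), 1-based inclusive; default
#'   whole trajectory.
#' @return object of class \code{RmsdSeries}: per-frame RMSD (Angstrom),
#'   window, mean, and both selections.
#' @export
rmsd_series <- function(traj, reference, measure_sel, fit_sel = measure_sel,
                        window = NULL) {
  window <- check_window(window, n_frames(traj))
  fr <- sel_rows(fit_sel); mr <- sel_rows(measure_sel)
  ref_fit <- reference$coords[fr, , drop = FALSE]
  ref_meas <- reference$coords[mr, , drop = FALSE]
  idx <- seq(window[1], window[2])
  vals <- vapply(idx, function(i) {
    x <- get_frame(traj, i)
    fit <- kabsch_superpose(x[fr, , drop = FALSE], ref_fit)
    rmsd_A(apply_transform(x[mr, , drop = FALSE], fit), ref_meas)
  }, numeric(1))
  structure(list(per_frame_rmsd = vals, window = window, mean = mean(vals),
                 fit_selection = fit_sel, measure_selection = measure_sel),
            class = "RmsdSeries")
}

#' @export
print.RmsdSeries <- function(x, ...) {
  cat(sprintf("RmsdSeries: frames %d..%d, mean %.3f A\n",
              x$window[1], x$window[2], x$mean))
  invisible(x)
}

check_window <- function(window, m) {
  if (is.null(window)) window <- c(1L, m)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 1 || window[2] > m ||
      window[1] > window[2])
    stop(sprintf("window [%d,%d] outside trajectory (1..%d)",
                 window[1], window[2], m))
  window
}

#' Flag a candidate equilibration frame
#'
#' Returns the earliest frame after which the sliding-window mean of a
#' per-frame series changes by less than \code{tol} for the rest of the
#' series. Advisory only; windows are always passed explicitly to the
#' analyses.
#'
#' @param values numeric per-frame series (e.g. RMSD, Angstrom).
#' @param width sliding-window width in frames.
#' @param tol maximum allowed change of the window mean.
#' @return frame index (1-based), or \code{NA} if the series never settles.
#' @export
find_equilibration <- function(values, width = 10L, tol = 0.1) {
  m <- length(values)
  if (m < 2 * width) return(NA_integer_)
  cums <- cumsum(c(0, values))
  wm <- (cums[(width + 1):(m + 1)] - cums[1:(m - width + 1)]) / width
  # the settled stretch must span at least `width` windows, otherwise the
  # tail end would trivially qualify
  for (s in seq_len(length(wm) - width)) {
    if (max(wm[s:length(wm)]) - min(wm[s:length(wm)]) < tol)
      return(as.integer(s))
  }
  NA_integer_
}

#' Mean distance between two single atoms over a trajectory window
#'
#' Minimum-image convention is applied per frame when the trajectory
#' carries a periodic box.
#'
#' @param traj a \code{TrajectoryEnsemble}.
#' @param atom_a,atom_b single-atom \code{AtomSelection}s.
#' @param window integer pair (first, last); default whole trajectory.
#' @return list with \code{mean} (Angstrom) and \code{per_frame}
#'   (Angstrom).
#' @export
active_site_distance <- function(traj, atom_a, atom_b, window = NULL) {
  if (length(atom_a$indices) != 1 || length(atom_b$indices) != 1)
    stop("active_site_distance requires single-atom selections (got ",
         length(atom_a$indices), " and ", length(atom_b$indices), ")")
  window <- check_window(window, n_frames(traj))
  ia <- atom_a$indices + 1L; ib <- atom_b$indices + 1L
  idx <- seq(window[1], window[2])
  d <- vapply(idx, function(i) {
    dx <- traj$frames[i, ia, ] - traj$frames[i, ib, ]
    if (!is.null(traj$box)) dx <- minimum_image(dx, traj$box[i, ])
    sqrt(sum(dx^2))
  }, numeric(1)) * 10
  list(mean = mean(d), per_frame = d)
}

minimum_image <- function(dx, box) {
  dx - box * round(dx / box)
}

#' Average a quantity over S and R stereoisomers
#'
#' Chemically modified backbone linkages exist as two stereoisomers; the
#' headline per-site quantities (RMSD, interaction-energy differences,
#' hydrogen-bond count differences) are reported as the arithmetic mean of
#' the two isomer values.
#'
#' @param s_value,r_value scalar values for the S and R isomers.
#' @return object of class \code{IsomerPair} with fields \code{s_value},
#'   \code{r_value}, \code{mean}.
#' @export
isomer_average <- function(s_value, r_value) {
  structure(list(s_value = s_value, r_value = r_value,
                 mean = (s_value + r_value) / 2),
            class = "IsomerPair")
}
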