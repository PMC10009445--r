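#' Generate the packaged synthetic demo dataset
#'
#' Writes a file tree of synthetic systems exercising the full comparison
#' workflow through the on-disk I/O path: a reference ensemble ("wt") plus
#' four perturbed systems, each as an S/R stereoisomer pair, whose leading
#' motions are respectively identical, swapped, rotated by 45 degrees, and
#' randomized relative to the reference. Every system is emitted as a
#' structure PDB, a nonbonded-parameter CSV, and a multi-model PDB
#' trajectory, together with a pipeline config (\code{config.yaml}).
#'
#' Each synthetic complex has a 128-residue pseudo-Calpha "protein" chain A
#' carrying the planted collective motions (plus one carbonyl-like oxygen
#' acceptor), and a 6-atom pseudo-nucleotide chain B donating an N-H
#' hydrogen bond to it, so the energy/H-bond analyses produce non-trivial
#' numbers. Fluctuation scales (mode variances 0.04 and 0.012 nm^2,
#' residual 0.0004 nm^2) give Angstrom-scale positional noise and
#' sub-2-Angstrom complex RMSD, the regime typical of a stable
#' protein/DNA complex.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; all per-system seeds derive from it.
#' @param n_frames frames per trajectory.
#' @return invisibly, the path to the written config file.
#' @export
make_demo_dataset <- function(out_dir, seed = 1L, n_frames = 400L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- demo_base_structure()
  n_tot <- n_atoms(base)
  d <- 3 * n_tot
  # planted modes live in the chain-A Calpha subspace
  ca_rows <- which(base$atoms$atom_name == "CA")
  ca_coord_idx <- as.vector(t(outer(ca_rows - 1L, 1:3, function(r, ax) 3 * r + ax)))
  V <- matrix(0, d, 2)
  Vsub <- with_seed(seed, random_orthonormal(length(ca_coord_idx), 2))
  V[ca_coord_idx, ] <- Vsub
  eigenvalues <- c(0.04, 0.012)
  residual <- 4e-4
  base_spec <- planted_mode_spec(
    n_atoms = n_tot, modes = V, eigenvalues = eigenvalues,
    residual_variance = residual, mean_structure = base$coords,
    n_frames = n_frames, seed = seed
  )
  perts <- list(
    wt = perturbation_spec("identity"),
    `mod-ident` = perturbation_spec("identity"),
    `mod-swap` = perturbation_spec("swap_first_two"),
    `mod-rot45` = perturbation_spec("rotate_in_plane", angle = pi / 4),
    `mod-rand` = perturbation_spec("randomize", seed = seed + 900L)
  )
  systems <- list()
  sys_i <- 0L
  for (pname in names(perts)) {
    isomers <- if (pname == "wt") list(NULL) else list("S", "R")
    for (iso in isomers) {
      sys_i <- sys_i + 1L
      spec_i <- perturb_modes(base_spec, perts[[pname]])
      spec_i$seed <- seed + 17L * sys_i
      traj <- generate_gaussian_ensemble_over(spec_i, base)
      tag <- if (is.null(iso)) pname else paste0(pname, "_", iso)
      spath <- file.path(out_dir, paste0(tag, ".pdb"))
      ppath <- file.path(out_dir, paste0(tag, "_params.csv"))
      tpath <- file.path(out_dir, paste0(tag, "_traj.pdb"))
      write_structure_pdb(base, spath)
      write_params_csv(base, ppath)
      write_structure_pdb(base, tpath, traj = traj)
      systems[[sys_i]] <- list(
        name = pname, isomer = iso,
        structure = basename(spath), params = basename(ppath),
        trajectory = basename(tpath)
      )
    }
  }
  config <- list(
    reference = "wt",
    window = c(1L, n_frames),
    cutoffs = list(d_cut_A = 3.5, a_cut_deg = 30.0, r_cut_nm = 1.0,
                   contact_A = 5.0),
    n_modes = 2L,
    sign_policy = "maximize",
    superpose = TRUE,
    selections = list(
      complex_rmsd = "name CA",
      thumb_ca = "chain A and name CA",
      protein_group = "chain A",
      dna_group = "chain B",
      active_site_a = "resid 129 and name O",
      active_site_b = "resid 201 and name N"
    ),
    systems = systems
  )
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

# sample from a PlantedModeSpec but keep a full structure model (the
# default generator builds a bare pseudo-Calpha chain)
generate_gaussian_ensemble_over <- function(spec, structure) {
  traj <- generate_gaussian_ensemble(spec)
  trajectory_ensemble(structure, traj$frames)
}

demo_base_structure <- function() {
  n_res <- 128L
  t <- seq_len(n_res) - 1
  helix <- cbind(1.2 * cos(0.6 * t), 1.2 * sin(0.6 * t), 0.05 * t)
  anchor <- helix[64, ]
  inward <- -c(anchor[1], anchor[2], 0) / sqrt(sum(anchor[1:2]^2))
  o_pos <- anchor + 0.30 * inward
  n_pos <- o_pos + 0.29 * inward   # donor-acceptor 2.9 A
  h_pos <- n_pos - 0.10 * inward   # H on the N->O axis, 1.0 A bond
  perp <- c(-inward[2], inward[1], 0)
  chainb <- rbind(
    n_pos, h_pos,
    n_pos + 0.15 * perp,                       # C1'
    n_pos + 0.05 * inward + 0.20 * perp,       # P (3.9 A from the acceptor O)
    n_pos + 0.15 * inward + 0.28 * perp,       # O1P
    n_pos - 0.03 * inward + 0.34 * perp        # O2P
  )
  coords <- rbind(helix, o_pos, chainb)
  qa <- rep(c(0.1, -0.1), length.out = n_res)
  structure_model(
    atom_name = c(rep("CA", n_res), "O", "N", "H1", "C1'", "P", "O1P", "O2P"),
    element = c(rep("C", n_res), "O", "N", "H", "C", "P", "O", "O"),
    residue_seq = c(seq_len(n_res), 129L, rep(201L, 6)),
    residue_name = c(rep("GLY", n_res), "HOH"[0:0], "ACC", rep("DN", 6)),
    chain_id = c(rep("A", n_res + 1L), rep("B", 6)),
    coords = coords,
    charge = c(qa, -0.5, -0.3, 0.3, 0.1, 1.1, -0.8, -0.8),
    lj_sigma = c(rep(0.34, n_res), 0.30, 0.325, 0.107, 0.34, 0.374, 0.30, 0.30),
    lj_epsilon = c(rep(0.36, n_res), 0.88, 0.71, 0.066, 0.36, 0.84, 0.88, 0.88),
    bonded_hydrogens = c(rep(list(integer(0)), n_res + 1L),
                         list(130L), rep(list(integer(0)), 5))
  )
}

#' Run the full multi-system comparison pipeline
#'
#' Executes the structural, energetic and motion analyses for every system
#' in a config file against one reference system: RMSD series,
#' protein/DNA interaction profile (Coulomb + van der Waals + H-bonds),
#' active-site distance, essential-dynamics PCA of the thumb-domain
#' Calphas, conservation classification versus the reference's modes, and
#' all delta-vs-reference quantities, plus isomer-pair averages. Failure
#' of one system aborts only that system; the report marks it failed.
#'
#' Per-system TSVs, an NMD mode file, a \code{summary.tsv}, an
#' \code{isomer_summary.tsv} and a run log (with a banner listing every
#' cutoff and window in force) are written under \code{out_dir}. The
#' numeric outputs are deterministic given the inputs; timestamps go only
#' to the log.
#'
#' @param config path to a YAML config (see \code{\link{make_demo_dataset}}
#'   for the schema) or an equivalent list.
#' @param out_dir output directory for tables; default
#'   \code{<config dir>/results}.
#' @return a \code{ComparisonReport}: list with \code{per_system} and
#'   \code{per_pair} data.frames, \code{conservation} (per-system
#'   \code{ConservationResult}s), and \code{provenance}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(cfg_path)) stop("config file not found: ", cfg_path)
    cfg <- yaml::read_yaml(cfg_path)
    cfg_dir <- dirname(cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
  } else {
    cfg <- config; cfg_dir <- "."; cfg_hash <- NA_character_
  }
  validate_config(cfg)
  if (is.null(out_dir)) out_dir <- file.path(cfg_dir, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("motioncons pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("defaults in force: d_cut = %.2f A, a_cut = %.1f deg, r_cut = %.2f nm, n_modes = %d, window = [%d, %d], sign_policy = %s, superpose = %s",
       cfg$cutoffs$d_cut_A, cfg$cutoffs$a_cut_deg, cfg$cutoffs$r_cut_nm,
       cfg$n_modes, cfg$window[1], cfg$window[2], cfg$sign_policy,
       cfg$superpose)

  sys_tag <- function(s) if (is.null(s$isomer)) s$name else
    paste0(s$name, "_", s$isomer)
  tags <- vapply(cfg$systems, sys_tag, character(1))
  if (anyDuplicated(tags)) stop("system name/isomer combinations not unique")
  ref_i <- which(vapply(cfg$systems, function(s)
    s$name == cfg$reference && is.null(s$isomer), logical(1)))
  if (length(ref_i) != 1)
    stop("reference system '", cfg$reference, "' not found in config")

  analyze_one <- function(s) {
    path_of <- function(p) if (file.exists(p)) p else file.path(cfg_dir, p)
    for (f in c(s$structure, s$params, s$trajectory))
      if (!file.exists(path_of(f)))
        stop("system '", sys_tag(s), "': missing file ", f)
    str <- read_structure(path_of(s$structure))
    str <- read_nonbonded_params(str, path_of(s$params))
    traj <- read_trajectory(path_of(s$trajectory), str)
    window <- check_window(if (!is.null(s$window)) s$window else cfg$window,
                           n_frames(traj))
    sel <- lapply(cfg$selections, function(q) select_atoms(str, q))
    rs <- rmsd_series(traj, str, measure_sel = sel$complex_rmsd,
                      window = window)
    prof <- interaction_profile(traj, sel$protein_group, sel$dna_group,
                                r_cut = cfg$cutoffs$r_cut_nm,
                                d_cut = cfg$cutoffs$d_cut_A,
                                a_cut = cfg$cutoffs$a_cut_deg, window = window)
    asd <- active_site_distance(traj, sel$active_site_a, sel$active_site_b,
                                window = window)
    cov <- build_covariance(traj, sel$thumb_ca, window = window,
                            superpose = isTRUE(cfg$superpose))
    modes <- principal_modes(cov, n_modes = max(cfg$n_modes, 2L))
    list(spec = s, tag = sys_tag(s), structure = str, rmsd = rs,
         profile = prof, active_site = asd, cov = cov, modes = modes)
  }

  results <- vector("list", length(cfg$systems))
  names(results) <- tags
  ref_res <- analyze_one(cfg$systems[[ref_i]])  # reference must succeed
  results[[ref_i]] <- ref_res
  for (i in seq_along(cfg$systems)) {
    if (i == ref_i) next
    results[[i]] <- tryCatch(analyze_one(cfg$systems[[i]]),
      error = function(e) {
        logf("system %s FAILED: %s", tags[i], conditionMessage(e))
        list(failed = conditionMessage(e), tag = tags[i])
      })
  }

  rows <- list(); cons_list <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!is.null(r$failed)) {
      rows[[i]] <- data.frame(system = r$tag, name = cfg$systems[[i]]$name,
                              isomer = tag_or_na(cfg$systems[[i]]$isomer),
                              status = "failed", mean_rmsd_A = NA,
                              mean_e_coul = NA, mean_e_vdw = NA,
                              mean_e_total = NA, mean_hbonds = NA,
                              active_site_A = NA, delta_e_coul = NA,
                              delta_e_vdw = NA, delta_e_total = NA,
                              delta_hbonds = NA, sigma_c = NA, sigma_u = NA,
                              label = NA, stringsAsFactors = FALSE)
      next
    }
    delta <- delta_vs_reference(r$profile, ref_res$profile)
    cons <- conservation_classify(r$modes, ref_res$modes,
                                  sign_policy = cfg$sign_policy)
    cons_list[[r$tag]] <- cons
    rows[[i]] <- data.frame(
      system = r$tag, name = r$spec$name, isomer = tag_or_na(r$spec$isomer),
      status = "ok",
      mean_rmsd_A = r$rmsd$mean,
      mean_e_coul = r$profile$mean_e_coul,
      mean_e_vdw = r$profile$mean_e_vdw,
      mean_e_total = r$profile$mean_e_total,
      mean_hbonds = r$profile$mean_hbonds,
      active_site_A = r$active_site$mean,
      delta_e_coul = delta$delta_e_coul,
      delta_e_vdw = delta$delta_e_vdw,
      delta_e_total = delta$delta_e_total,
      delta_hbonds = delta$delta_hbonds,
      sigma_c = cons$sigma_c, sigma_u = cons$sigma_u, label = cons$label,
      stringsAsFactors = FALSE
    )
    # per-system artifacts
    utils::write.table(
      data.frame(frame = seq(r$rmsd$window[1], r$rmsd$window[2]),
                 rmsd_A = r$rmsd$per_frame_rmsd),
      file.path(out_dir, paste0(r$tag, "_rmsd.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(frame = seq(r$profile$window[1], r$profile$window[2]),
                 e_coul = r$profile$e_coul_series,
                 e_vdw = r$profile$e_vdw_series,
                 n_hbonds = r$profile$hbond_count_series),
      file.path(out_dir, paste0(r$tag, "_interactions.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      per_residue_conservation(cons, r$structure),
      file.path(out_dir, paste0(r$tag, "_perres_sigma.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    write_nmd(r$modes, r$cov$mean_coords,
              file.path(out_dir, paste0(r$tag, "_modes.nmd")),
              n_modes = min(2L, length(r$modes$values)))
    logf("system %s: rmsd %.3f A, E %.2f kJ/mol, %.2f H-bonds, Sigma_C %.3f, Sigma_U %.3f -> %s",
         r$tag, r$rmsd$mean, r$profile$mean_e_total, r$profile$mean_hbonds,
         cons$sigma_c, cons$sigma_u, cons$label)
  }
  per_system <- do.call(rbind, rows)

  # isomer-pair averages
  pair_rows <- list()
  for (nm in unique(per_system$name[!is.na(per_system$isomer)])) {
    sub <- per_system[per_system$name == nm & per_system$status == "ok", ]
    if (!all(c("S", "R") %in% sub$isomer)) next
    s <- sub[sub$isomer == "S", ]; r <- sub[sub$isomer == "R", ]
    avg <- function(col) isomer_average(s[[col]], r[[col]])$mean
    pair_rows[[nm]] <- data.frame(
      name = nm,
      mean_rmsd_A = avg("mean_rmsd_A"),
      delta_e_total = avg("delta_e_total"),
      delta_e_coul = avg("delta_e_coul"),
      delta_e_vdw = avg("delta_e_vdw"),
      delta_hbonds = avg("delta_hbonds"),
      active_site_A = avg("active_site_A"),
      sigma_c = avg("sigma_c"), sigma_u = avg("sigma_u"),
      stringsAsFactors = FALSE
    )
  }
  per_pair <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL

  write_num_tsv(per_system, file.path(out_dir, "summary.tsv"))
  if (!is.null(per_pair))
    write_num_tsv(per_pair, file.path(out_dir, "isomer_summary.tsv"))

  structure(list(per_system = per_system, per_pair = per_pair,
                 conservation = cons_list,
                 provenance = list(config_hash = cfg_hash,
                                   package_version =
                                     as.character(utils::packageVersion("motioncons")),
                                   r_version = R.version.string)),
            class = "ComparisonReport")
}

tag_or_na <- function(x) if (is.null(x)) NA_character_ else x

# fixed-precision numeric formatting so reruns are byte-identical
write_num_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

validate_config <- function(cfg) {
  need <- c("reference", "window", "cutoffs", "n_modes", "sign_policy",
            "superpose", "selections", "systems")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing field(s): ", paste(miss, collapse = ", "))
  need_sel <- c("complex_rmsd", "thumb_ca", "protein_group", "dna_group",
                "active_site_a", "active_site_b")
  miss <- setdiff(need_sel, names(cfg$selections))
  if (length(miss))
    stop("config selections missing: ", paste(miss, collapse = ", "))
  for (k in seq_along(cfg$systems)) {
    s <- cfg$systems[[k]]
    miss <- setdiff(c("name", "structure", "params", "trajectory"), names(s))
    if (length(miss))
      stop("config system #", k, " missing field(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport\n")
  print(x$per_system[, c("system", "status", "mean_rmsd_A", "delta_e_total",
                         "delta_hbonds", "sigma_c", "sigma_u", "label")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
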