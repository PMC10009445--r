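#' Construct a StructureModel
#'
#' A \code{StructureModel} is the static topology every analysis selects
#' from: atom names, residue assignments, coordinates (nm) and, optionally,
#' nonbonded parameters (partial charge in elementary-charge units,
#' Lennard-Jones sigma in nm and epsilon in kJ/mol) plus the list of
#' hydrogens covalently bound to each atom.
#'
#' Internal units follow the MD ecosystem: nm for lengths, elementary
#' charge, kJ/mol for energies. Angstrom values are accepted and emitted
#' only at PDB boundaries. Atom ids are 0-based and contiguous;
#' \code{residue_seq} is kept as authored (1-based in PDB files).
#'
#' @param atom_name character vector of atom names (e.g. "CA", "O3'").
#' @param element character vector of element symbols.
#' @param residue_seq integer vector of residue sequence numbers.
#' @param residue_name character vector of residue names.
#' @param chain_id character vector of chain identifiers.
#' @param coords N x 3 numeric matrix of coordinates, nm.
#' @param charge numeric vector, elementary charges (default 0).
#' @param lj_sigma,lj_epsilon numeric vectors of LJ parameters
#'   (nm, kJ/mol); default 0.
#' @param bonded_hydrogens list (length N) of integer vectors of 0-based
#'   atom ids of hydrogens bound to each atom.
#' @return object of class \code{StructureModel}.
#' @export
structure_model <- function(atom_name, element, residue_seq, residue_name,
                            chain_id, coords,
                            charge = NULL, lj_sigma = NULL, lj_epsilon = NULL,
                            bonded_hydrogens = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3)
  if (length(atom_name) != n) stop("atom_name length must match coords rows")
  if (is.null(charge)) charge <- rep(0, n)
  if (is.null(lj_sigma)) lj_sigma <- rep(0, n)
  if (is.null(lj_epsilon)) lj_epsilon <- rep(0, n)
  if (is.null(bonded_hydrogens)) bonded_hydrogens <- rep(list(integer(0)), n)
  m <- structure(list(
    atoms = data.frame(
      atom_id = 0:(n - 1L),
      atom_name = as.character(atom_name),
      element = as.character(element),
      residue_seq = as.integer(residue_seq),
      residue_name = as.character(residue_name),
      chain_id = as.character(chain_id),
      charge = as.numeric(charge),
      lj_sigma = as.numeric(lj_sigma),
      lj_epsilon = as.numeric(lj_epsilon),
      stringsAsFactors = FALSE
    ),
    coords = unname(coords),
    bonded_hydrogens = bonded_hydrogens
  ), class = "StructureModel")
  validate_structure_model(m)
  m
}

validate_structure_model <- function(m) {
  a <- m$atoms
  n <- nrow(a)
  if (!identical(a$atom_id, 0:(n - 1L)))
    stop("atom_ids must be unique and contiguous from 0")
  if (!all(is.finite(m$coords))) stop("coords must be finite")
  if (any(a$lj_sigma < 0) || any(a$lj_epsilon < 0))
    stop("lj_sigma and lj_epsilon must be >= 0")
  hs <- unlist(m$bonded_hydrogens)
  if (length(hs)) {
    if (any(hs < 0 | hs >= n)) stop("bonded_hydrogens ids out of range")
    bad <- hs[a$element[hs + 1L] != "H"]
    if (length(bad))
      stop("bonded_hydrogens must refer to atoms with element H (atom ids: ",
           paste(bad, collapse = ", "), ")")
  }
  invisible(m)
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel: %d atoms, %d residues, chains [%s]\n",
              nrow(a), length(unique(paste(a$chain_id, a$residue_seq))),
              paste(unique(a$chain_id), collapse = ",")))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

#' Construct a TrajectoryEnsemble
#'
#' An ordered set of coordinate frames over one \code{StructureModel},
#' optionally carrying per-frame orthorhombic box lengths and timestamps.
#'
#' @param structure a \code{StructureModel}.
#' @param frames numeric array (n_frames x n_atoms x 3, nm) or a list of
#'   n_atoms x 3 matrices.
#' @param box optional n_frames x 3 matrix of box lengths (nm), all > 0.
#' @param times optional numeric vector of frame timestamps (ps).
#' @return object of class \code{TrajectoryEnsemble}.
#' @export
trajectory_ensemble <- function(structure, frames, box = NULL, times = NULL) {
  if (is.list(frames)) {
    arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3)
  if (dim(frames)[2] != n_atoms(structure))
    stop(sprintf("frame atom count (%d) does not match structure atom count (%d)",
                 dim(frames)[2], n_atoms(structure)))
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (nrow(box) == 1) box <- box[rep(1, dim(frames)[1]), , drop = FALSE]
    stopifnot(nrow(box) == dim(frames)[1], ncol(box) == 3)
    if (any(box <= 0)) stop("box lengths must be > 0")
  }
  structure(list(structure = structure, frames = frames, box = box,
                 times = times),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms%s\n",
              n_frames(x), dim(x$frames)[2],
              if (is.null(x$box)) "" else ", periodic box"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{TrajectoryEnsemble}.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as an n_atoms x 3 coordinate matrix (nm)
#' @param traj a \code{TrajectoryEnsemble}.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  traj$frames[i, , , drop = TRUE]
}

element_from_name <- function(atom_name) {
  # PDB convention: strip digits/primes, first alphabetic character is a
  # reasonable element guess for organic/biomolecular atoms
  s <- gsub("[0-9']", "", atom_name)
  toupper(substr(s, 1, 1))
}

#' Read a molecular structure from PDB or GRO
#'
#' Coordinates are converted to nm (PDB Angstrom / 10; GRO is already nm).
#' Residue and atom metadata are preserved verbatim. Charges and LJ fields
#' are left unset (zero) until \code{\link{read_nonbonded_params}} is
#' applied.
#'
#' @param path file path.
#' @param format "pdb" or "gro"; default guessed from the file extension.
#' @return a \code{StructureModel}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot guess structure format from extension '",
                          ext, "'; pass format="))
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_gro(path)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("parse error: no ATOM/HETATM records in ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("parse error reading PDB ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  elem <- a$elesy
  miss <- is.na(elem) | elem == ""
  elem[miss] <- element_from_name(a$elety[miss])
  coords <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  structure_model(
    atom_name = a$elety, element = elem,
    residue_seq = a$resno, residue_name = a$resid,
    chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    coords = coords
  )
}

# GRO fixed-format: resnum(1-5) resname(6-10) atomname(11-15) atomnum(16-20)
# then x, y, z in nm (8.3 fields)
read_structure_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("parse error: GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("parse error at line 2: expected atom count in ", path)
  if (length(lines) < 2 + n) stop("parse error: GRO file truncated: ", path)
  al <- lines[3:(2 + n)]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("parse error at GRO line ", which(is.na(v))[1] + 2,
           ": bad coordinate field")
    v
  }
  resno <- as.integer(trimws(substr(al, 1, 5)))
  resid <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  x <- num(substr(al, 21, 28)); y <- num(substr(al, 29, 36)); z <- num(substr(al, 37, 44))
  structure_model(
    atom_name = aname, element = element_from_name(aname),
    residue_seq = resno, residue_name = resid,
    chain_id = rep("A", n), coords = cbind(x, y, z)
  )
}

#' Apply a nonbonded-parameter table onto a StructureModel
#'
#' The table is a CSV/TSV sidecar with header
#' \code{key,charge,sigma_nm,epsilon_kjmol} and an optional
#' \code{hydrogens} column. \code{key} matches atoms by \code{atom_name},
#' or by \code{residue_seq/atom_name} when it contains a "/" (the qualified
#' form wins over a bare name). \code{hydrogens} is a semicolon-separated
#' list of atom names resolved within the same residue, populating
#' \code{bonded_hydrogens}. This is a deliberately simple sidecar, not a
#' force-field parser: parameterization is upstream of this package.
#'
#' @param structure a \code{StructureModel}.
#' @param path path to the parameter table.
#' @return the structure with charge/lj/bonded-hydrogen fields filled.
#'   Atoms with no matching row get zero parameters with a warning.
#' @export
read_nonbonded_params <- function(structure, path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  # na.strings empty: "NA" is a legitimate atom key (sodium)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = character(0))
  need <- c("key", "charge", "sigma_nm", "epsilon_kjmol")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(tab$key))
    stop("duplicate match keys in parameter table: ",
         paste(unique(tab$key[duplicated(tab$key)]), collapse = ", "))
  a <- structure$atoms
  bare <- a$atom_name
  qual <- paste0(a$residue_seq, "/", a$atom_name)
  i_qual <- match(qual, tab$key)
  i_bare <- match(bare, tab$key)
  idx <- ifelse(is.na(i_qual), i_bare, i_qual)
  unmatched <- which(is.na(idx))
  if (length(unmatched))
    warning(length(unmatched), " atom(s) had no parameter entry (zeroed): ",
            paste(utils::head(a$atom_name[unmatched], 5), collapse = ", "))
  ok <- !is.na(idx)
  a$charge[ok] <- tab$charge[idx[ok]]
  a$lj_sigma[ok] <- tab$sigma_nm[idx[ok]]
  a$lj_epsilon[ok] <- tab$epsilon_kjmol[idx[ok]]
  structure$atoms <- a
  if ("hydrogens" %in% names(tab)) {
    bh <- structure$bonded_hydrogens
    for (k in which(ok)) {
      hspec <- tab$hydrogens[idx[k]]
      if (is.na(hspec) || !nzchar(hspec)) next
      hnames <- strsplit(hspec, ";", fixed = TRUE)[[1]]
      same_res <- a$residue_seq == a$residue_seq[k] &
        a$chain_id == a$chain_id[k]
      hids <- a$atom_id[same_res & a$atom_name %in% hnames]
      bh[[k]] <- as.integer(hids)
    }
    structure$bonded_hydrogens <- bh
  }
  validate_structure_model(structure)
  structure
}

#' Read a trajectory into a TrajectoryEnsemble
#'
#' Supported formats: multi-model PDB and DCD (binary, CHARMM/NAMD style).
#' Frames are kept in file order; a frame window (first/last/stride) may be
#' applied at read time.
#'
#' @param path trajectory file.
#' @param structure the matching \code{StructureModel}.
#' @param format "pdb", "dcd" or "auto" (from extension). "xtc" is
#'   recognized but not supported and raises an error.
#' @param first,last,stride frame-window slicing (1-based, inclusive;
#'   \code{last = NA} means end of file).
#' @return a \code{TrajectoryEnsemble}.
#' @export
read_trajectory <- function(path, structure,
                            format = c("auto", "pdb", "dcd", "xtc"),
                            first = 1L, last = NA, stride = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", xtc = "xtc",
                     stop("cannot guess trajectory format from extension '",
                          ext, "'"))
  }
  if (format == "xtc")
    stop("XTC reading is not supported; convert to DCD or multi-model PDB")
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("parse error reading PDB ",
                                             path, ": ", conditionMessage(e)))
    xyz <- pdb$xyz  # models x 3N, Angstrom
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  }
  natom_file <- ncol(xyz) / 3
  if (natom_file != n_atoms(structure))
    stop(sprintf("trajectory atom count (%d) does not match structure atom count (%d)",
                 natom_file, n_atoms(structure)))
  m <- nrow(xyz)
  if (is.na(last)) last <- m
  if (first < 1 || last > m || first > last)
    stop(sprintf("frame window [%d,%d] outside trajectory (1..%d)",
                 first, last, m))
  keep <- seq(first, last, by = stride)
  xyz <- xyz[keep, , drop = FALSE] / 10  # Angstrom -> nm
  frames <- array(0, dim = c(length(keep), natom_file, 3))
  frames[, , 1] <- xyz[, seq(1, ncol(xyz), 3)]
  frames[, , 2] <- xyz[, seq(2, ncol(xyz), 3)]
  frames[, , 3] <- xyz[, seq(3, ncol(xyz), 3)]
  trajectory_ensemble(structure, frames)
}

#' Resolve an atom-selection expression
#'
#' The selection language is a conjunction of simple predicates joined by
#' \code{and}:
#' \itemize{
#'   \item \code{name CA} — atom name;
#'   \item \code{resid 480:640} (also \code{480..640} or a single number,
#'     comma lists allowed) — residue_seq range;
#'   \item \code{chain A} — chain id;
#'   \item \code{element O} — element symbol;
#'   \item \code{resname ASP} — residue name;
#'   \item \code{all} — every atom.
#' }
#' The result is deterministic: atoms ordered by residue_seq then atom_id,
#' so Calpha selections come out in residue order.
#'
#' @param structure a \code{StructureModel}.
#' @param query selection expression string.
#' @param label optional label; defaults to the query text.
#' @return an \code{AtomSelection}: list with \code{indices} (0-based atom
#'   ids) and \code{label}.
#' @export
select_atoms <- function(structure, query, label = query) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- toks[1]
    if (key == "all") next
    if (length(toks) < 2)
      stop("cannot parse selection clause: '", cl, "'")
    val <- paste(toks[-1], collapse = " ")
    keep <- keep & switch(key,
      name = a$atom_name %in% strsplit(val, ",")[[1]],
      chain = a$chain_id %in% strsplit(val, ",")[[1]],
      element = a$element %in% strsplit(val, ",")[[1]],
      resname = a$residue_name %in% strsplit(val, ",")[[1]],
      resid = a$residue_seq %in% parse_resid_range(val),
      stop("unsupported selection predicate: '", key, "'")
    )
  }
  idx <- a$atom_id[keep]
  ord <- order(a$residue_seq[keep], idx)
  idx <- idx[ord]
  if (length(idx) == 0)
    stop("selection '", query, "' matched no atoms")
  structure(list(indices = as.integer(idx), label = label),
            class = "AtomSelection")
}

parse_resid_range <- function(val) {
  parts <- strsplit(val, ",")[[1]]
  out <- integer(0)
  for (p in parts) {
    p <- trimws(p)
    if (grepl("\\.\\.|:", p)) {
      ends <- as.integer(strsplit(p, "\\.\\.|:")[[1]])
      if (length(ends) != 2 || any(is.na(ends)))
        stop("cannot parse residue range: '", p, "'")
      out <- c(out, seq(ends[1], ends[2]))
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) stop("cannot parse residue id: '", p, "'")
      out <- c(out, v)
    }
  }
  out
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

# 1-based row indices into coords for a selection
sel_rows <- function(selection) selection$indices + 1L

#' Write a StructureModel (and optionally trajectory frames) as PDB
#'
#' Coordinates are emitted in Angstrom. If \code{traj} is given, a
#' multi-model PDB is written with one MODEL per frame.
#'
#' @param structure a \code{StructureModel}.
#' @param path output path.
#' @param traj optional \code{TrajectoryEnsemble} over the same structure.
#' @export
write_structure_pdb <- function(structure, path, traj = NULL) {
  a <- structure$atoms
  fmt_atom <- function(coords_nm) {
    xyz <- coords_nm * 10
    sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$atom_id + 1L,
            ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
            a$residue_name, a$chain_id, a$residue_seq,
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(traj)) {
    writeLines(fmt_atom(structure$coords), con)
    writeLines("END", con)
  } else {
    for (i in seq_len(n_frames(traj))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(fmt_atom(get_frame(traj, i)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Write the nonbonded-parameter sidecar for a StructureModel
#'
#' Emits one residue-qualified row per atom
#' (\code{residue_seq/atom_name}) so the round trip through
#' \code{\link{read_nonbonded_params}} is exact, including the
#' bonded-hydrogen lists.
#'
#' @param structure a \code{StructureModel}.
#' @param path output CSV path.
#' @export
write_params_csv <- function(structure, path) {
  a <- structure$atoms
  hyd <- vapply(seq_len(nrow(a)), function(i) {
    ids <- structure$bonded_hydrogens[[i]]
    if (!length(ids)) return("")
    paste(a$atom_name[ids + 1L], collapse = ";")
  }, character(1))
  tab <- data.frame(key = paste0(a$residue_seq, "/", a$atom_name),
                    charge = a$charge, sigma_nm = a$lj_sigma,
                    epsilon_kjmol = a$lj_epsilon, hydrogens = hyd,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$key))
    stop("structure has duplicate residue_seq/atom_name keys; cannot emit table")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
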