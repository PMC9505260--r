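#' Trajectory container
#'
#' A `pg_trajectory` couples a topology (`pg_structure`, atom order fixed)
#' with an n_frames x (3 * n_atoms) coordinate matrix in the usual
#' xyzxyz... layout, plus optional timestep metadata. Frames are assumed
#' already imaged/unwrapped; no periodic-boundary treatment is applied.
#'
#' @param topology `pg_structure`.
#' @param xyz numeric matrix, one row per frame, 3 * n_atoms columns.
#' @param dt_ps optional picoseconds per frame.
#' @return object of class `pg_trajectory`.
#' @export
new_trajectory <- function(topology, xyz, dt_ps = NULL) {
  stopifnot(is_structure(topology))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("frame width (", ncol(xyz), ") does not match 3 x topology atoms")
  if (nrow(xyz) < 1L) stop("trajectory needs at least one frame")
  structure(list(topology = topology, xyz = xyz, dt_ps = dt_ps),
            class = "pg_trajectory")
}

#' @export
print.pg_trajectory <- function(x, ...) {
  cat(sprintf("<pg_trajectory> %d frames x %d atoms\n", nrow(x$xyz),
              ncol(x$xyz) / 3L))
  invisible(x)
}

#' @rdname new_trajectory
#' @param traj `pg_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

# n_atoms x 3 coordinates of one frame
frame_xyz <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Materialize one frame as a structure
#' @param traj `pg_trajectory`; @param frame 1-based frame index.
#' @return `pg_structure` with the topology's atom table and the frame's
#'   coordinates.
#' @export
frame_structure <- function(traj, frame) {
  set_xyz(traj$topology, frame_xyz(traj, frame))
}

#' Read a trajectory from disk
#'
#' Supports a multi-MODEL PDB (topology and frames in one file) or a DCD
#' coordinate file alongside a PDB topology. Frames must match the
#' topology's atom count.
#'
#' @param path multi-model PDB, or DCD file.
#' @param topology required for DCD input: path of the topology PDB.
#' @param dt_ps optional picoseconds per frame.
#' @return `pg_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL, dt_ps = NULL) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topology))
      stop("DCD input needs a PDB topology via `topology=`")
    topo <- if (is_structure(topology)) topology else
      read_structure(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    return(new_trajectory(topo, xyz, dt_ps))
  }
  raw <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  topo <- read_structure(path)  # altloc policy applied to topology
  xyz <- raw$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(topo$atoms))
    stop("multi-model PDB has altloc records; trajectories must not")
  new_trajectory(topo, xyz, dt_ps)
}

#' Atom selection on a structure
#'
#' Named selections: `"protein-ca"` (CA atoms of polymer residues),
#' `"protein-heavy"`, `"ligand-heavy"` (non-hydrogen atoms of non-water
#' HETATM residues), `"all"`. A numeric vector selects polymer residues
#' by author number (heavy atoms). An integer vector wrapped in [I()] is
#' taken as raw atom-row indices.
#'
#' @param s `pg_structure`.
#' @param selection see above.
#' @return integer atom-row indices.
#' @export
select_atoms <- function(s, selection) {
  a <- s$atoms
  if (inherits(selection, "AsIs")) return(as.integer(selection))
  if (is.numeric(selection))
    return(which(a$type == "ATOM" & a$resno %in% selection &
                   !is_hydrogen(a)))
  idx <- switch(selection,
    "protein-ca" = which(a$type == "ATOM" & a$elety == "CA"),
    "protein-heavy" = which(a$type == "ATOM" & !is_hydrogen(a)),
    "ligand-heavy" = which(a$type == "HETATM" &
                             !a$resid %in% c("HOH", "WAT", "TIP3") &
                             !is_hydrogen(a)),
    "all" = seq_len(nrow(a)),
    stop("unknown selection: ", selection))
  idx
}

#' RMSD-versus-first-frame time series
#'
#' For every frame, the `fit_selection` atoms are superposed (Kabsch) onto
#' their positions in frame 1, the fitted transform is applied to the
#' `measure_selection` atoms, and the RMSD against frame 1 is recorded.
#' The conventional choice — fitting on protein CA even when measuring a
#' ligand — exposes ligand drift within the protein frame of reference;
#' fitting on the measured selection itself yields the minimized series.
#'
#' @param traj `pg_trajectory`.
#' @param fit_selection,measure_selection selections for [select_atoms];
#'   defaults fit and measure protein CA.
#' @return data.frame with columns frame, rmsd; attributes `fit`,
#'   `measure`.
#' @export
rmsd_series <- function(traj, fit_selection = "protein-ca",
                        measure_selection = "protein-ca") {
  topo <- traj$topology
  fit_idx <- select_atoms(topo, fit_selection)
  mea_idx <- select_atoms(topo, measure_selection)
  if (length(fit_idx) < 3L) stop("fit selection has fewer than 3 atoms")
  if (length(mea_idx) == 0L) stop("empty measure selection")
  nf <- n_frames(traj)
  ref <- frame_xyz(traj, 1L)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    cur <- frame_xyz(traj, f)
    fit <- kabsch(cur[fit_idx, , drop = FALSE],
                  ref[fit_idx, , drop = FALSE])
    moved <- apply_transform(fit, cur[mea_idx, , drop = FALSE])
    out[f] <- raw_rmsd(moved, ref[mea_idx, , drop = FALSE])
  }
  res <- data.frame(frame = seq_len(nf), rmsd = out)
  attr(res, "fit") <- fit_selection
  attr(res, "measure") <- measure_selection
  res
}

#' Per-frame CA distance between two residues
#'
#' Tracks the binding-pocket indicator distance (e.g. A228-R578) along a
#' trajectory and summarizes its first, last and mean values.
#'
#' @param traj `pg_trajectory`; @param chain chain id.
#' @param res_i,res_j author residue numbers.
#' @return list with `series` (numeric, one value per frame), `first`,
#'   `last`, `mean`.
#' @export
indicator_series <- function(traj, chain, res_i, res_j) {
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f)
    ca_distance(frame_structure(traj, f), chain, res_i, res_j),
    numeric(1))
  list(series = vals, first = vals[1L], last = vals[nf],
       mean = mean(vals))
}
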