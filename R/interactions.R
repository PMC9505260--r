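# side-chain nitrogen/oxygen role atoms for charged residues
CATION_RES <- c("ARG", "LYS")
CATION_HIS <- c("HIP", "HSP")          # protonated histidine naming variants
ANION_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Detect salt bridges
#'
#' A salt bridge is reported when any side-chain nitrogen of an
#' arginine/lysine (and, optionally, protonated histidine) lies within
#' `cutoff` of any side-chain carboxylate oxygen of a glutamate/aspartate.
#' Results are deduplicated to one record per residue pair, reporting the
#' minimum-distance atom pair (set `all_pairs = TRUE` for every qualifying
#' atom pair). The 4.0 Angstrom nitrogen-oxygen default is a stated,
#' configurable convention. Neutral histidine is excluded unless
#' `include_his = TRUE`; residues named HIP/HSP always count as cations.
#'
#' @param s `pg_structure`.
#' @param chains optional chain filter (default: all chains).
#' @param cutoff N-O distance cutoff, Angstrom.
#' @param include_his treat every histidine as a potential cation.
#' @param all_pairs report every atom pair instead of one per residue
#'   pair.
#' @return data.frame of contact records: kind, chain_i, resno_i, resid_i,
#'   atom_i, chain_j, resno_j, resid_j, atom_j, distance. Zero rows when
#'   nothing is found.
#' @export
detect_salt_bridges <- function(s, chains = NULL, cutoff = 4.0,
                                include_his = FALSE, all_pairs = FALSE) {
  a <- s$atoms
  sel <- a$type == "ATOM" & !is_hydrogen(a)
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  cat_res <- c(CATION_RES, CATION_HIS, if (include_his) "HIS")
  is_cat <- sel & a$resid %in% cat_res & a$elesy == "N" &
    !a$elety %in% BACKBONE_ATOMS
  is_an <- sel & ((a$resid %in% c("GLU", "GLH") &
                     a$elety %in% ANION_ATOMS$GLU) |
                    (a$resid %in% c("ASP", "ASH") &
                       a$elety %in% ANION_ATOMS$ASP))
  ci <- which(is_cat); ai <- which(is_an)
  empty <- data.frame(kind = character(), chain_i = character(),
                      resno_i = integer(), resid_i = character(),
                      atom_i = character(), chain_j = character(),
                      resno_j = integer(), resid_j = character(),
                      atom_j = character(), distance = numeric())
  if (length(ci) == 0L || length(ai) == 0L) return(empty)
  pc <- atom_xyz(s, ci); pa <- atom_xyz(s, ai)
  dm <- sqrt(pmax(outer(rowSums(pc^2), rowSums(pa^2), `+`) -
                    2 * pc %*% t(pa), 0))
  hit <- which(dm <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  i <- ci[hit[, 1]]; j <- ai[hit[, 2]]
  out <- data.frame(kind = "salt-bridge",
                    chain_i = a$chain[i], resno_i = a$resno[i],
                    resid_i = a$resid[i], atom_i = a$elety[i],
                    chain_j = a$chain[j], resno_j = a$resno[j],
                    resid_j = a$resid[j], atom_j = a$elety[j],
                    distance = dm[hit], stringsAsFactors = FALSE)
  if (!all_pairs) {
    key <- paste(out$chain_i, out$resno_i, out$chain_j, out$resno_j)
    out <- do.call(rbind, lapply(split(out, key),
                                 function(g) g[which.min(g$distance), ]))
  }
  out <- out[order(out$resno_i, out$resno_j, out$distance), ]
  rownames(out) <- NULL
  out
}

# hydrogens covalently bonded to a heavy atom: same residue, within 1.25 A
bonded_hydrogens <- function(s, idx) {
  a <- s$atoms
  h <- which(is_hydrogen(a) & a$chain == a$chain[idx] &
               a$resno == a$resno[idx] & a$insert == a$insert[idx] &
               a$type == a$type[idx])
  if (length(h) == 0L) return(integer())
  p0 <- atom_xyz(s, idx)
  d <- sqrt(rowSums(sweep(atom_xyz(s, h), 2, p0)^2))
  h[d <= 1.25]
}

#' Detect hydrogen bonds in a structure or single frame
#'
#' Donor/acceptor roles are derived from elements: nitrogen and oxygen
#' heavy atoms act as acceptors; those with at least one covalently bonded
#' hydrogen (same residue, within 1.25 Angstrom) also act as donors. A
#' bond is reported when the donor-acceptor heavy-atom distance is at most
#' `d_cut` and — whenever the structure carries hydrogens — the best
#' D-H...A angle is at least `angle_cut`. Structures without hydrogens are
#' evaluated in distance-only mode: every N/O pair across different
#' residues is a candidate. HETATM ligand atoms (water excluded)
#' participate when `include_ligand = TRUE`.
#'
#' @param s `pg_structure` (one frame).
#' @param chains optional chain filter.
#' @param d_cut donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cut minimum D-H...A angle, degrees; used only when
#'   hydrogens are present.
#' @param include_ligand include non-water HETATM atoms.
#' @return data.frame of contact records as in [detect_salt_bridges],
#'   with an `angle` column (NA in distance-only mode).
#' @export
detect_hbonds <- function(s, chains = NULL, d_cut = 3.5, angle_cut = 135,
                          include_ligand = FALSE) {
  a <- s$atoms
  sel <- !is_hydrogen(a) & a$elesy %in% c("N", "O")
  sel <- sel & (a$type == "ATOM" |
                  (include_ligand & a$type == "HETATM" &
                     !a$resid %in% c("HOH", "WAT", "TIP3")))
  if (!is.null(chains)) sel <- sel & a$chain %in% chains
  cand <- which(sel)
  empty <- data.frame(kind = character(), chain_i = character(),
                      resno_i = integer(), resid_i = character(),
                      atom_i = character(), chain_j = character(),
                      resno_j = integer(), resid_j = character(),
                      atom_j = character(), distance = numeric(),
                      angle = numeric())
  if (length(cand) < 2L) {
    warning("no donor/acceptor candidates found")
    return(empty)
  }
  have_h <- any(is_hydrogen(a))
  hyd <- if (have_h) lapply(cand, function(i) bonded_hydrogens(s, i))
  else vector("list", length(cand))
  # donors: with hydrogens present, require a bonded H; otherwise any N/O
  donor_ok <- if (have_h) lengths(hyd) > 0L else rep(TRUE, length(cand))
  p <- atom_xyz(s, cand)
  dm <- sqrt(pmax(outer(rowSums(p^2), rowSums(p^2), `+`) - 2 * p %*% t(p),
                  0))
  rkey <- res_key(a$chain[cand], a$resno[cand], a$insert[cand])
  same_res <- outer(rkey, rkey, `==`)
  hit <- which(dm <= d_cut & !same_res & donor_ok, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  if (!have_h) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  rows <- vector("list", nrow(hit))
  for (k in seq_len(nrow(hit))) {
    di <- hit[k, 1]; ai_ <- hit[k, 2]
    ang <- NA_real_
    if (have_h) {
      hs <- hyd[[di]]
      ang <- max(vapply(hs, function(h)
        three_point_angle(atom_xyz(s, cand[di]), atom_xyz(s, h),
                          atom_xyz(s, cand[ai_])), numeric(1)))
      if (ang < angle_cut) next
    }
    i <- cand[di]; j <- cand[ai_]
    rows[[k]] <- data.frame(kind = "hbond",
                            chain_i = a$chain[i], resno_i = a$resno[i],
                            resid_i = a$resid[i], atom_i = a$elety[i],
                            chain_j = a$chain[j], resno_j = a$resno[j],
                            resid_j = a$resid[j], atom_j = a$elety[j],
                            distance = dm[di, ai_], angle = ang,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$resno_i, out$resno_j, out$distance), ]
  rownames(out) <- NULL
  out
}

# angle at vertex b of points a-b-c, degrees
three_point_angle <- function(a, b, c_) {
  u <- as.numeric(a - b); v <- as.numeric(c_ - b)
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# stable identity of a contact across frames
contact_key <- function(df) {
  paste0(df$chain_i, df$resno_i, ":", df$atom_i, "--",
         df$chain_j, df$resno_j, ":", df$atom_j)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Runs [detect_hbonds] on every frame and reports, for each contact
#' observed in at least one frame, the fraction of frames in which it
#' satisfies the geometric criteria — the standard persistence summary of
#' an MD simulation's hydrogen-bond analysis.
#'
#' @param traj `pg_trajectory` (see [make_toy_trajectory],
#'   [read_trajectory]).
#' @param ... passed to [detect_hbonds] (cutoffs, chain filter,
#'   `include_ligand`).
#' @return data.frame with columns contact, chain_i, resno_i, atom_i,
#'   chain_j, resno_j, atom_j, n_present, occupancy; attribute
#'   `n_frames`.
#' @export
hbond_occupancy <- function(traj, ...) {
  stopifnot(inherits(traj, "pg_trajectory"))
  nf <- n_frames(traj)
  if (nf == 0L) stop("empty trajectory")
  tally <- list()
  meta <- list()
  for (f in seq_len(nf)) {
    hb <- suppressWarnings(detect_hbonds(frame_structure(traj, f), ...))
    if (nrow(hb) == 0L) next
    keys <- contact_key(hb)
    for (k in seq_along(keys)) {
      key <- keys[k]
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
      if (is.null(meta[[key]])) meta[[key]] <- hb[k, , drop = FALSE]
    }
  }
  if (length(tally) == 0L)
    return(structure(data.frame(contact = character(),
                                n_present = integer(),
                                occupancy = numeric()),
                     n_frames = nf))
  keys <- names(tally)
  md <- do.call(rbind, meta[keys])
  out <- data.frame(contact = keys,
                    chain_i = md$chain_i, resno_i = md$resno_i,
                    atom_i = md$atom_i, chain_j = md$chain_j,
                    resno_j = md$resno_j, atom_j = md$atom_j,
                    n_present = unlist(tally[keys], use.names = FALSE),
                    stringsAsFactors = FALSE)
  out$occupancy <- out$n_present / nf
  out <- out[order(-out$occupancy, out$contact), ]
  rownames(out) <- NULL
  attr(out, "n_frames") <- nf
  out
}
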