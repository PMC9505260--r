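# backbone heavy atoms; everything else heavy is "side chain" (CB included)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# atom rows of one residue (polymer atoms of one chain)
residue_atoms <- function(s, chain, resno, insert = "") {
  a <- s$atoms
  which(a$type == "ATOM" & a$chain == chain & a$resno == resno &
          a$insert == insert)
}

#' Distance between the alpha-carbons of two residues
#'
#' The CA-CA distance between residues at the opposite rims of an
#' inter-domain cleft is the package's binding-pocket formation indicator
#' (for NLRP3/MCC950: A228 in the Walker A motif versus R578 in HD2).
#'
#' @param s `pg_structure`; @param chain chain id.
#' @param res_i,res_j author residue numbers.
#' @return distance in Angstrom.
#' @export
ca_distance <- function(s, chain, res_i, res_j) {
  ca_of <- function(r) {
    idx <- residue_atoms(s, chain, r)
    ca <- idx[s$atoms$elety[idx] == "CA"]
    if (length(ca) == 0L)
      stop("residue ", r, " in chain ", chain, " is missing or has no CA")
    atom_xyz(s, ca[1])
  }
  if (res_i == res_j) return(0)
  sqrt(sum((ca_of(res_i) - ca_of(res_j))^2))
}

# side-chain heavy-atom rows of a residue; integer(0) if none
sidechain_idx <- function(s, chain, resno, insert = "") {
  idx <- residue_atoms(s, chain, resno, insert)
  idx[!s$atoms$elety[idx] %in% BACKBONE_ATOMS &
        !is_hydrogen(s$atoms[idx, , drop = FALSE])]
}

#' Side-chain distance between two residues
#'
#' `definition = "min-heavy"` (default, the common contact convention) is
#' the minimum pairwise distance between the side-chain heavy atoms of the
#' two residues; `"centroid"` is the distance between their side-chain
#' heavy-atom centroids. Side chain means heavy atoms beyond the backbone
#' (N, CA, C, O, OXT), CB included. A residue without side-chain atoms
#' (glycine, or truncated side-chain density) falls back to its CA with a
#' warning.
#'
#' @inheritParams ca_distance
#' @param definition "min-heavy" or "centroid".
#' @return distance in Angstrom.
#' @export
sidechain_distance <- function(s, chain, res_i, res_j,
                               definition = c("min-heavy", "centroid")) {
  definition <- match.arg(definition)
  pts <- function(r) {
    idx <- sidechain_idx(s, chain, r)
    if (length(idx) == 0L) {
      idx <- residue_atoms(s, chain, r)
      idx <- idx[s$atoms$elety[idx] == "CA"]
      if (length(idx) == 0L)
        stop("residue ", r, " in chain ", chain,
             " has neither side-chain atoms nor CA")
      warning("residue ", r, " has no side-chain heavy atoms; using CA")
    }
    atom_xyz(s, idx)
  }
  pi_ <- pts(res_i); pj <- pts(res_j)
  if (definition == "centroid")
    return(sqrt(sum((colMeans(pi_) - colMeans(pj))^2)))
  min(sqrt(pmax(outer(rowSums(pi_^2), rowSums(pj^2), `+`) -
                  2 * pi_ %*% t(pj), 0)))
}

#' Pairwise distance matrix over a key-residue set
#'
#' Symmetric, zero-diagonal matrix of CA or side-chain distances among an
#' ordered set of key residues, the raw material for pocket-geometry
#' heatmaps. Residues missing from the structure yield NA rows/columns
#' with a warning (masked, never imputed).
#'
#' @param s `pg_structure`; @param chain chain id.
#' @param residues data.frame with columns `resno` and `resid` (3-letter,
#'   used for labels), or an integer vector of residue numbers.
#' @param metric "calpha" or "sidechain" (min-heavy).
#' @return object of class `pg_distance_matrix`: a labeled symmetric
#'   numeric matrix with attribute `metric`.
#' @export
pocket_matrix <- function(s, chain, residues,
                          metric = c("calpha", "sidechain")) {
  metric <- match.arg(metric)
  if (is.numeric(residues)) {
    rt <- residue_table(s, chain = chain)
    residues <- data.frame(
      resno = as.integer(residues),
      resid = rt$resid[match(residues, rt$resno)],
      stringsAsFactors = FALSE)
    residues$resid[is.na(residues$resid)] <- "UNK"
  }
  n <- nrow(residues)
  if (n < 2L) stop("need at least 2 key residues")
  labels <- residue_label(residues$resid, residues$resno)
  ok <- vapply(residues$resno, function(r) {
    idx <- residue_atoms(s, chain, r)
    length(idx) > 0L && any(s$atoms$elety[idx] == "CA")
  }, logical(1))
  if (sum(ok) < 2L) stop("fewer than 2 key residues resolvable in chain ",
                         chain)
  if (any(!ok))
    warning("unresolvable key residue(s) masked: ",
            paste(labels[!ok], collapse = ", "))
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  dg <- diag(m); dg[ok] <- 0; diag(m) <- dg
  fun <- if (metric == "calpha") ca_distance else sidechain_distance
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (ok[i] && ok[j])
      m[i, j] <- m[j, i] <- fun(s, chain, residues$resno[i],
                                residues$resno[j])
  }
  attr(m, "metric") <- metric
  class(m) <- c("pg_distance_matrix", class(m))
  m
}

#' Signed deviation matrix (model minus reference)
#'
#' Elementwise difference of two key-residue distance matrices with
#' identical labels; positive entries mean the model's pair is farther
#' apart than in the reference, negative closer. Masked (NA) entries
#' propagate. Swapping the arguments negates the matrix.
#'
#' @param model_m,ref_m matrices from [pocket_matrix] with identical
#'   labels.
#' @return labeled antisymmetrically-signed matrix of class
#'   `pg_deviation_matrix`.
#' @export
deviation_matrix <- function(model_m, ref_m) {
  if (!identical(dimnames(model_m), dimnames(ref_m)))
    stop("label mismatch between model and reference matrices")
  d <- unclass(model_m) - unclass(ref_m)
  class(d) <- c("pg_deviation_matrix", "matrix", "array")
  d
}

#' Binding-pocket formation verdict from the indicator distance
#'
#' Categorizes pocket formation by the CA distance between the two
#' indicator residues (default A228-R578 for NLRP3): `formed` when the
#' distance is at most `t_formed`, `unformed` when above `t_loose`,
#' `loose` in between; both bounds inclusive toward the tighter category.
#' The default thresholds (14 and 18 Angstrom) are heuristics anchored to
#' exemplar geometries — an experimentally formed pocket near 12.7 A, a
#' partially closed one at 14.5 A, and an open solvent-exposed arrangement
#' near 20 A — and are configurable.
#'
#' @param s `pg_structure`; @param chain chain id.
#' @param res_i,res_j indicator residue numbers (defaults 228 and 578).
#' @param thresholds numeric `c(formed, loose)` upper bounds in Angstrom.
#' @return list with `indicator_distance`, `category`, `thresholds`,
#'   `residues`.
#' @export
pocket_verdict <- function(s, chain, res_i = 228, res_j = 578,
                           thresholds = c(formed = 14, loose = 18)) {
  if (length(thresholds) != 2L || thresholds[1] > thresholds[2])
    stop("thresholds must be c(formed, loose) with formed <= loose")
  d <- ca_distance(s, chain, res_i, res_j)
  cat_ <- if (d <= thresholds[1]) "formed"
  else if (d <= thresholds[2]) "loose" else "unformed"
  list(indicator_distance = d, category = cat_,
       thresholds = thresholds, residues = c(res_i, res_j))
}
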