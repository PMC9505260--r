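#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Closed-form SVD solution for the proper rotation `R` and translation
#' `t` minimizing the (optionally weighted) RMSD of `R a + t` against `b`.
#' Reflections are corrected by flipping the sign of the smallest singular
#' value so that `det(R) = +1`: biological coordinates are chiral and an
#' improper "superposition" would silently mirror the molecule.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (Angstrom), row i of
#'   `a` paired with row i of `b`.
#' @param weights optional non-negative per-atom weights (sum > 0);
#'   uniform weights reproduce the unweighted solution.
#' @return object of class `pg_superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length-3), `rmsd` (Angstrom), `n_atoms`.
#' @export
kabsch <- function(coords_a, coords_b, weights = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("coordinate arrays must be n x 3 and the same shape")
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 paired atoms, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  ca <- colSums(a * w); cb <- colSums(b * w)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  # degenerate (collinear or coincident) sets leave the rotation
  # under-determined about the point axis; reject rather than regularize
  if (svd(ac, nu = 0, nv = 0)$d[2] < 1e-8 ||
      svd(bc, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate (collinear) point set: superposition undefined")
  h <- t(ac * w) %*% bc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cb - as.numeric(rot %*% ca)
  dev2 <- rowSums((ac %*% t(rot) - bc)^2)
  structure(list(rotation = rot, translation = trans,
                 rmsd = sqrt(sum(w * dev2)), n_atoms = n),
            class = "pg_superposition")
}

#' @export
print.pg_superposition <- function(x, ...) {
  cat(sprintf("<pg_superposition> rmsd %.3f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition's rigid transform to coordinates
#' @param fit `pg_superposition`; @param xyz n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(fit, xyz) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, `+`)
}

# plain (already superposed) coordinate RMSD
raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD between model and reference over a residue mapping
#'
#' @param model,reference `pg_structure` objects.
#' @param mapping a [map_residues] result.
#' @param selection "heavy" (all non-hydrogen atoms) or "calpha".
#' @param superpose TRUE (default) for the Kabsch-minimized RMSD; FALSE
#'   for the raw RMSD in the structures' current frames.
#' @return `pg_superposition` (with identity transform when
#'   `superpose = FALSE`).
#' @export
rmsd_between <- function(model, reference, mapping,
                         selection = c("heavy", "calpha"),
                         superpose = TRUE) {
  selection <- match.arg(selection)
  pr <- pair_atoms(model, reference, mapping, selection)
  a <- atom_xyz(model, pr$model_idx)
  b <- atom_xyz(reference, pr$ref_idx)
  if (superpose) return(kabsch(a, b))
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 rmsd = raw_rmsd(a, b), n_atoms = nrow(a)),
            class = "pg_superposition")
}

#' Domain-partitioned RMSD table
#'
#' The assessment protocol for multi-subdomain models: each named domain is
#' superposed onto the reference *independently*, so a domain whose internal
#' fold is correct scores low RMSD even when inter-domain packing is wrong;
#' the "Full-length" row is a single global superposition over all mapped
#' atoms (including residues outside every named domain) and therefore
#' reflects domain assembly. Both heavy-atom and CA RMSDs are reported per
#' row with their atom counts. Domains with fewer than 3 paired atoms in a
#' selection get NA for that selection.
#'
#' @param model,reference `pg_structure` objects.
#' @param mapping a [map_residues] result.
#' @param scheme a [domain_scheme]; domain membership is decided by the
#'   model-side author residue number.
#' @return data.frame with columns domain, rmsd_heavy, rmsd_ca, n_heavy,
#'   n_ca; one row per scheme domain present plus "Full-length".
#' @export
domain_rmsd_table <- function(model, reference, mapping, scheme) {
  heavy <- pair_atoms(model, reference, mapping, "heavy")
  calpha <- pair_atoms(model, reference, mapping, "calpha")
  am_h <- atom_xyz(model, heavy$model_idx)
  ar_h <- atom_xyz(reference, heavy$ref_idx)
  am_c <- atom_xyz(model, calpha$model_idx)
  ar_c <- atom_xyz(reference, calpha$ref_idx)
  dom_h <- domain_of(heavy$resno, scheme)
  dom_c <- domain_of(calpha$resno, scheme)

  one <- function(sel_h, sel_c) {
    nh <- sum(sel_h); nc <- sum(sel_c)
    rh <- if (nh >= 3L)
      tryCatch(kabsch(am_h[sel_h, , drop = FALSE],
                      ar_h[sel_h, , drop = FALSE])$rmsd,
               error = function(e) NA_real_) else NA_real_
    rc <- if (nc >= 3L)
      tryCatch(kabsch(am_c[sel_c, , drop = FALSE],
                      ar_c[sel_c, , drop = FALSE])$rmsd,
               error = function(e) NA_real_) else NA_real_
    c(rh, rc, nh, nc)
  }

  doms <- rownames(scheme$ranges)
  rows <- lapply(doms, function(d) one(dom_h == d, dom_c == d))
  rows <- c(rows, list(one(rep(TRUE, length(dom_h)),
                           rep(TRUE, length(dom_c)))))
  m <- do.call(rbind, rows)
  out <- data.frame(domain = c(doms, "Full-length"),
                    rmsd_heavy = m[, 1], rmsd_ca = m[, 2],
                    n_heavy = as.integer(m[, 3]),
                    n_ca = as.integer(m[, 4]),
                    stringsAsFactors = FALSE)
  # domains with no paired atoms at all are absent rows, not NA rows
  out <- out[out$n_heavy > 0L | out$n_ca > 0L | out$domain == "Full-length",
             , drop = FALSE]
  rownames(out) <- NULL
  out
}
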