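# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# rotation matrix from axis (3-vector) and angle in degrees
rotation_about <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(diag(3))
  k <- axis / n
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# fixed local offsets giving each residue a minimal ALA-like body
BACKBONE_OFFSETS <- list(
  N  = c(-1.20, 0.50, -0.70),
  C  = c(1.20, 0.60, 0.60),
  O  = c(1.30, 1.80, 0.80),
  CB = c(-0.50, -1.30, 0.60))

#' Specification for a synthetic multi-domain toy protein
#'
#' Describes the ground truth [make_toy_protein] realizes: a helical
#' poly-alanine chain partitioned into equal-size named domains, an
#' idealized stand-in for a multi-subdomain protein. Per-domain rigid
#' transforms and Gaussian coordinate noise perturb the *model* copy
#' (emulating mispacked but internally correct subdomains); per-domain
#' missing fractions delete residues from the *reference* copy (emulating
#' unresolved experimental density); per-domain confidence means plant
#' pLDDT-style B-factors in the model.
#'
#' @param n_domains number of domains (>= 1).
#' @param residues_per_domain residues per domain (>= 3).
#' @param transforms NULL (identity) or a list, one per domain, each NULL
#'   or `list(angle = degrees, axis = 3-vector, translation = 3-vector)`;
#'   rotations act about the domain's CA centroid.
#' @param noise_sd Gaussian coordinate noise sd applied to the model,
#'   Angstrom.
#' @param missing per-domain fraction of residues deleted from the
#'   reference, in `[0, 1]` (recycled). The deleted count is
#'   `floor(fraction * n + 0.5)`.
#' @param confidence per-domain mean planted pLDDT (recycled, default
#'   80); per-residue scores are drawn around the mean with sd 2 and
#'   clamped to `[0, 100]`.
#' @param seed mandatory RNG seed; identical seeds give byte-identical
#'   structures.
#' @return object of class `pg_toy_spec`.
#' @export
toy_spec <- function(n_domains = 3, residues_per_domain = 30,
                     transforms = NULL, noise_sd = 0, missing = 0,
                     confidence = 80, seed) {
  if (n_domains < 1L) stop("need at least one domain")
  if (residues_per_domain < 3L) stop("need at least 3 residues per domain")
  missing <- rep_len(missing, n_domains)
  if (any(missing < 0 | missing > 1)) stop("missing fractions must be in [0,1]")
  confidence <- rep_len(confidence, n_domains)
  if (!is.null(transforms) && length(transforms) != n_domains)
    stop("transforms must have one entry per domain (or be NULL)")
  structure(list(n_domains = as.integer(n_domains),
                 residues_per_domain = as.integer(residues_per_domain),
                 transforms = transforms, noise_sd = noise_sd,
                 missing = missing, confidence = confidence, seed = seed),
            class = "pg_toy_spec")
}

# helical CA trace + fixed backbone offsets for residues 1..n (chain A, ALA)
ideal_chain_atoms <- function(n, b = 30) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- c(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
            1.5 * i)
    nm <- c("N", "CA", "C", "O", "CB")
    xyz <- rbind(ca + BACKBONE_OFFSETS$N, ca, ca + BACKBONE_OFFSETS$C,
                 ca + BACKBONE_OFFSETS$O, ca + BACKBONE_OFFSETS$CB)
    rows[[i]] <- data.frame(
      type = "ATOM", eleno = 0L, elety = nm, alt = "", resid = "ALA",
      chain = "A", resno = i, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = b,
      elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$eleno <- seq_len(nrow(out))
  out
}

#' Generate a synthetic model/reference structure pair with ground truth
#'
#' @param spec a [toy_spec].
#' @return list with `model` and `reference` (`pg_structure`), `scheme`
#'   (a [domain_scheme] with domains D1..Dk), and `truth`: planted
#'   per-residue pLDDT (named by residue number), per-domain deleted
#'   residue numbers, the transforms and noise level.
#' @export
make_toy_protein <- function(spec) {
  stopifnot(inherits(spec, "pg_toy_spec"))
  k <- spec$n_domains; m <- spec$residues_per_domain
  n <- k * m
  ranges <- lapply(seq_len(k), function(d) c((d - 1L) * m + 1L, d * m))
  names(ranges) <- paste0("D", seq_len(k))
  scheme <- domain_scheme(ranges)
  base <- ideal_chain_atoms(n)
  dom <- domain_of(base$resno, scheme)

  with_seed(spec$seed, {
    # RNG draws in fixed order: confidence, deletions, coordinate noise
    plddt <- numeric(n)
    for (d in seq_len(k)) {
      in_d <- which(seq_len(n) >= ranges[[d]][1] & seq_len(n) <= ranges[[d]][2])
      plddt[in_d] <- pmin(100, pmax(0, rnorm(length(in_d),
                                             spec$confidence[d], 2)))
    }
    plddt <- round(plddt, 2)  # PDB B-factor precision

    deleted <- vector("list", k)
    names(deleted) <- names(ranges)
    for (d in seq_len(k)) {
      res_d <- ranges[[d]][1]:ranges[[d]][2]
      n_del <- floor(spec$missing[d] * length(res_d) + 0.5)
      deleted[[d]] <- if (n_del > 0L) sort(sample(res_d, n_del))
      else integer()
    }

    model <- base
    for (d in seq_len(k)) {
      tr <- if (is.null(spec$transforms)) NULL else spec$transforms[[d]]
      if (is.null(tr)) next
      sel <- dom == names(ranges)[d]
      xyz <- as.matrix(model[sel, c("x", "y", "z")])
      cen <- colMeans(xyz[model$elety[sel] == "CA", , drop = FALSE])
      R <- rotation_about(tr$axis %||% c(0, 0, 1), tr$angle %||% 0)
      shifted <- sweep(sweep(xyz, 2, cen) %*% t(R), 2,
                       cen + (tr$translation %||% c(0, 0, 0)), `+`)
      model[sel, c("x", "y", "z")] <- shifted
    }
    if (spec$noise_sd > 0) {
      model$x <- model$x + rnorm(n * 5L, 0, spec$noise_sd)
      model$y <- model$y + rnorm(n * 5L, 0, spec$noise_sd)
      model$z <- model$z + rnorm(n * 5L, 0, spec$noise_sd)
    }
    model$b <- plddt[model$resno]

    reference <- base[!base$resno %in% unlist(deleted), , drop = FALSE]
    reference$eleno <- seq_len(nrow(reference))

    list(model = new_structure(model, id = "toy_model"),
         reference = new_structure(reference, id = "toy_reference"),
         scheme = scheme,
         truth = list(plddt = setNames(plddt, seq_len(n)),
                      deleted = deleted,
                      transforms = spec$transforms,
                      noise_sd = spec$noise_sd,
                      spec = spec))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# side-chain templates: atom name, distance along the outward axis,
# lateral offset (Angstrom)
SIDECHAIN_TEMPLATES <- list(
  ALA = cbind(along = 1.5, lateral = 0),
  ILE = cbind(along = c(1.5, 2.8, 2.6, 4.0), lateral = c(0, 0.5, -0.9, 0.4)),
  TYR = cbind(along = c(1.5, 2.9, 4.1, 4.1, 5.4, 5.4, 6.0, 7.3),
              lateral = c(0, 0, 0.7, -0.7, 0.7, -0.7, 0, 0)),
  PHE = cbind(along = c(1.5, 2.9, 4.1, 4.1, 5.4, 5.4, 6.0),
              lateral = c(0, 0, 0.7, -0.7, 0.7, -0.7, 0)),
  ARG = cbind(along = c(1.5, 2.9, 4.2, 5.5, 6.2, 7.4, 7.4),
              lateral = c(0, 0.2, 0, 0.2, 0, 0.5, -0.5)),
  GLU = cbind(along = c(1.5, 2.9, 4.2, 5.3, 5.3),
              lateral = c(0, 0.2, 0, 0.5, -0.5)),
  ASP = cbind(along = c(1.5, 2.9, 4.0, 4.0),
              lateral = c(0, 0.2, 0.5, -0.5)))
SIDECHAIN_NAMES <- list(
  ALA = "CB", ILE = c("CB", "CG1", "CG2", "CD1"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  ASP = c("CB", "CG", "OD1", "OD2"))

# a unit vector perpendicular to u
perp_of <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- v - sum(v * u) * u
  p / sqrt(sum(p^2))
}

#' Generate a synthetic binding-pocket structure with planted geometry
#'
#' Places a set of key residues (default: the NLRP3 pocket set A228,
#' I411, Y443, F575, R578, E629 as ALA/ILE/TYR/PHE/ARG/GLU) so that their
#' CA-CA distances match `ca_targets` to machine precision, then attaches
#' template side chains pointing outward from the pocket centroid.
#' Optionally a salt bridge is planted by directing the side chains of an
#' ARG/GLU (or ASP) pair toward each other so that their closest
#' nitrogen-oxygen distance equals `salt_bridge$distance` exactly.
#'
#' `ca_targets = NULL` draws random, well-separated CA positions (seeded)
#' and records the realized matrix in the truth; a supplied full symmetric
#' matrix is embedded in 3-D by classical multidimensional scaling and
#' rejected as infeasible if it cannot be realized within 1e-6 Angstrom.
#'
#' @param residues data.frame with columns `resno`, `resid`.
#' @param ca_targets NULL or full symmetric target CA distance matrix
#'   (Angstrom, zero diagonal) in `residues` order.
#' @param salt_bridge NULL or `list(i = resno, j = resno, distance = A)`
#'   with `i` an ARG and `j` a GLU/ASP of the set.
#' @param seed mandatory RNG seed.
#' @return list with `structure` (`pg_structure`, chain "A") and `truth`
#'   (realized CA distance matrix, salt-bridge plant).
#' @export
make_toy_pocket <- function(residues = data.frame(
                              resno = c(228L, 411L, 443L, 575L, 578L, 629L),
                              resid = c("ALA", "ILE", "TYR", "PHE", "ARG",
                                        "GLU"),
                              stringsAsFactors = FALSE),
                            ca_targets = NULL, salt_bridge = NULL, seed) {
  n <- nrow(residues)
  if (n < 2L) stop("need at least two residues")
  if (!all(residues$resid %in% names(SIDECHAIN_TEMPLATES)))
    stop("unsupported residue type(s): ",
         paste(setdiff(residues$resid, names(SIDECHAIN_TEMPLATES)),
               collapse = ", "))
  with_seed(seed, {
    if (is.null(ca_targets)) {
      repeat {
        ca <- matrix(runif(3L * n, 0, 8 + 4 * n), n, 3L)
        if (n < 2L || min(dist(ca)) > 9) break
      }
    } else {
      ca_targets <- as.matrix(ca_targets)
      if (!isTRUE(all.equal(ca_targets, t(ca_targets))) ||
          any(diag(ca_targets) != 0))
        stop("ca_targets must be symmetric with zero diagonal")
      if (any(ca_targets[upper.tri(ca_targets)] <= 0))
        stop("degenerate target: off-diagonal distances must be positive")
      # negative eigenvalues here just mean "not 3-D embeddable"; that case
      # is caught below by the realized-distance check
      ca <- suppressWarnings(cmdscale(as.dist(ca_targets),
                                      k = min(3L, n - 1L)))
      if (ncol(ca) < 3L)
        ca <- cbind(ca, matrix(0, n, 3L - ncol(ca)))
      err <- max(abs(as.matrix(dist(ca)) - ca_targets))
      if (is.na(err) || err > 1e-6)
        stop("infeasible geometry: targets not realizable in 3-D (max ",
             "error ", format(err), " A)")
    }
    centroid <- colMeans(ca)

    sb_dir <- NULL
    if (!is.null(salt_bridge)) {
      ii <- match(salt_bridge$i, residues$resno)
      jj <- match(salt_bridge$j, residues$resno)
      if (is.na(ii) || is.na(jj)) stop("salt-bridge residues not in the set")
      D <- sqrt(sum((ca[ii, ] - ca[jj, ])^2))
      if (D <= salt_bridge$distance + 2)
        stop("salt-bridge residues too close for the requested N-O distance")
      sb_dir <- list(ii = ii, jj = jj, d = salt_bridge$distance, D = D)
    }

    rows <- vector("list", n)
    ord <- order(residues$resno)
    for (q in seq_len(n)) {
      i <- ord[q]
      resid <- residues$resid[i]; resno <- residues$resno[i]
      cai <- ca[i, ]
      u <- cai - centroid
      if (sqrt(sum(u^2)) < 1e-9) u <- c(1, 0, 0)
      u <- u / sqrt(sum(u^2))
      tmpl <- SIDECHAIN_TEMPLATES[[resid]]
      nms <- SIDECHAIN_NAMES[[resid]]
      if (!is.null(sb_dir) && i %in% c(sb_dir$ii, sb_dir$jj)) {
        other <- if (i == sb_dir$ii) sb_dir$jj else sb_dir$ii
        u <- (ca[other, ] - cai) / sb_dir$D
        reach <- (sb_dir$D - sb_dir$d) / 2
        # rescale the template so the terminal polar atom sits exactly at
        # `reach` along the axis toward the partner
        tip <- if (i == sb_dir$ii) match("NH1", nms) else
          match(if (resid == "GLU") "OE1" else "OD1", nms)
        tmpl <- tmpl * cbind(rep(reach / tmpl[tip, "along"], nrow(tmpl)),
                             rep(1, nrow(tmpl)))
      }
      p <- perp_of(u)
      sc <- t(vapply(seq_len(nrow(tmpl)), function(r)
        cai + tmpl[r, "along"] * u + tmpl[r, "lateral"] * p, numeric(3)))
      nm <- c("N", "CA", "C", "O", nms)
      xyz <- rbind(cai + BACKBONE_OFFSETS$N, cai, cai + BACKBONE_OFFSETS$C,
                   cai + BACKBONE_OFFSETS$O, sc)
      rows[[q]] <- data.frame(
        type = "ATOM", eleno = 0L, elety = nm, alt = "", resid = resid,
        chain = "A", resno = resno, insert = "",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 60,
        elesy = guess_element(nm), stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    atoms$eleno <- seq_len(nrow(atoms))
    realized <- as.matrix(dist(ca))
    dimnames(realized) <- list(residue_label(residues$resid, residues$resno),
                               residue_label(residues$resid, residues$resno))
    list(structure = new_structure(atoms, id = "toy_pocket"),
         truth = list(ca_matrix = realized, salt_bridge = salt_bridge))
  })
}

#' Generate a synthetic trajectory with planted motions and contacts
#'
#' Frames start from `base` and realize a motion program exactly: each
#' motion drifts a selection linearly by `drift` Angstrom per frame (and
#' optionally oscillates along `oscillate$axis` with the given amplitude
#' and period, in frames). Each planted contact is made to hold in exactly
#' `round(fraction * n_frames)` frames (chosen at random under the seed):
#' in "on" frames the acceptor residue is translated along the
#' donor-acceptor axis so the contact distance equals `on_distance`
#' exactly; in "off" frames, `off_distance`.
#'
#' @param base `pg_structure` (becomes the topology; frame 1 is the base
#'   after frame-1 motion, i.e. zero drift).
#' @param n_frames number of frames (>= 1).
#' @param motions list of `list(selection, drift = c(dx, dy, dz),
#'   oscillate = NULL or list(axis, amplitude, period))`; selections as in
#'   [select_atoms].
#' @param contacts list of `list(donor = c(resno, atom), acceptor =
#'   c(resno, atom), fraction, on_distance = 2.9, off_distance = 6.5)`;
#'   donor/acceptor atoms must exist in chain "A" of `base`. Contact
#'   residues should not also be motion targets.
#' @param seed mandatory RNG seed.
#' @param dt_ps optional picoseconds per frame.
#' @return list with `trajectory` (`pg_trajectory`) and `truth`
#'   (per-contact on-frame indices and realized occupancy).
#' @export
make_toy_trajectory <- function(base, n_frames, motions = list(),
                                contacts = list(), seed, dt_ps = NULL) {
  stopifnot(is_structure(base), n_frames >= 1L)
  atoms <- base$atoms
  na <- nrow(atoms)
  find_atom <- function(resno, elety) {
    i <- which(atoms$resno == resno & atoms$elety == elety)
    if (length(i) != 1L)
      stop("contact atom ", elety, " of residue ", resno,
           " not found uniquely in base structure")
    i
  }
  with_seed(seed, {
    truth <- list()
    on_frames <- lapply(contacts, function(ct) {
      m <- round(ct$fraction * n_frames)
      sort(sample(n_frames, m))
    })
    xyz <- matrix(0, n_frames, 3L * na)
    for (f in seq_len(n_frames)) {
      co <- atom_xyz(base)
      for (mo in motions) {
        idx <- select_atoms(base, mo$selection)
        shift <- (f - 1) * (mo$drift %||% c(0, 0, 0))
        if (!is.null(mo$oscillate))
          shift <- shift + mo$oscillate$amplitude *
            sin(2 * pi * (f - 1) / mo$oscillate$period) *
            (mo$oscillate$axis / sqrt(sum(mo$oscillate$axis^2)))
        co[idx, ] <- sweep(co[idx, , drop = FALSE], 2, shift, `+`)
      }
      for (ci in seq_along(contacts)) {
        ct <- contacts[[ci]]
        d_i <- find_atom(ct$donor[[1]], ct$donor[[2]])
        a_i <- find_atom(ct$acceptor[[1]], ct$acceptor[[2]])
        target <- if (f %in% on_frames[[ci]]) ct$on_distance %||% 2.9
        else ct$off_distance %||% 6.5
        v <- co[a_i, ] - co[d_i, ]
        cur <- sqrt(sum(v^2))
        if (cur < 1e-9) stop("contact atoms coincide")
        move <- (target / cur - 1) * v
        res_sel <- which(atoms$resno == ct$acceptor[[1]] &
                           atoms$chain == atoms$chain[a_i])
        co[res_sel, ] <- sweep(co[res_sel, , drop = FALSE], 2, move, `+`)
      }
      xyz[f, ] <- as.numeric(t(co))
    }
    for (ci in seq_along(contacts))
      truth[[ci]] <- list(on_frames = on_frames[[ci]],
                          occupancy = length(on_frames[[ci]]) / n_frames)
    list(trajectory = new_trajectory(base, xyz, dt_ps), truth = truth)
  })
}
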