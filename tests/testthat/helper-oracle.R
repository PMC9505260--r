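# rotation matrix from a rotation vector (axis * angle, radians)
rotvec_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# independent oracle for the minimal superposed RMSD: direct numerical
# minimization over rotation-vector parameters (translation optimal at the
# centroids), multi-start Nelder-Mead
oracle_min_rmsd <- function(a, b) {
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  obj <- function(p) {
    R <- rotvec_matrix(p)
    sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
  }
  starts <- list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi),
                 c(1, 1, 1), c(-1, 2, 0.5), c(2, -2, 1))
  min(vapply(starts, function(s)
    optim(s, obj, method = "Nelder-Mead",
          control = list(maxit = 50000, reltol = 1e-15))$value,
    numeric(1)))
}

# quick hand-built structure: df needs elety, resid, resno, x, y, z;
# chain/type/elesy filled with defaults
mini_structure <- function(df, id = "mini") {
  n <- nrow(df)
  atoms <- data.frame(
    type = if (is.null(df$type)) rep("ATOM", n) else df$type,
    eleno = seq_len(n),
    elety = df$elety,
    alt = "",
    resid = df$resid,
    chain = if (is.null(df$chain)) rep("A", n) else df$chain,
    resno = df$resno,
    insert = "",
    x = df$x, y = df$y, z = df$z,
    o = if (is.null(df$o)) rep(1, n) else df$o,
    b = if (is.null(df$b)) rep(50, n) else df$b,
    elesy = if (is.null(df$elesy))
      toupper(substr(sub("^[0-9]+", "", df$elety), 1, 1)) else df$elesy,
    stringsAsFactors = FALSE)
  new_structure(atoms, id = id)
}

# apply a global rigid transform (random under seed) to a structure
rigid_copy <- function(s, seed = 1) {
  set.seed(seed)
  R <- rotvec_matrix(runif(3, -pi, pi))
  t0 <- runif(3, -20, 20)
  set_xyz_pub(s, sweep(coords_of(s) %*% t(R), 2, t0, `+`))
}

coords_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_xyz_pub <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# append a rigid HETATM ligand to a structure
add_ligand <- function(s, offset = c(15, 0, 0), resno = 900L,
                       resid = "LIG") {
  local <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0), c(1.0, 2.3, 0.8),
                 c(-0.6, 1.9, 1.1))
  nm <- c("C1", "C2", "N1", "O1", "C3")
  lig <- data.frame(
    type = "HETATM", eleno = max(s$atoms$eleno) + seq_len(nrow(local)),
    elety = nm, alt = "", resid = resid, chain = "A", resno = resno,
    insert = "",
    x = local[, 1] + offset[1], y = local[, 2] + offset[2],
    z = local[, 3] + offset[3],
    o = 1, b = 40,
    elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
  new_structure(rbind(s$atoms, lig), id = s$id)
}

# default three-residue pocket used across tests: A228/R578/E629 with a
# planted 3.0 A salt bridge and a formed-pocket indicator distance
pocket_fixture <- function(seed = 7, d_no = 3.0, ca_228_578 = 12.7) {
  tgt <- matrix(0, 3, 3)
  tgt[1, 2] <- tgt[2, 1] <- ca_228_578
  # companion distances scale with the indicator so every requested
  # indicator value stays triangle-feasible
  tgt[1, 3] <- tgt[3, 1] <- 0.8 * ca_228_578 + 4
  tgt[2, 3] <- tgt[3, 2] <- 0.9 * ca_228_578 + 6
  make_toy_pocket(
    residues = data.frame(resno = c(228L, 578L, 629L),
                          resid = c("ALA", "ARG", "GLU"),
                          stringsAsFactors = FALSE),
    ca_targets = tgt,
    salt_bridge = list(i = 578, j = 629, distance = d_no),
    seed = seed)
}
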