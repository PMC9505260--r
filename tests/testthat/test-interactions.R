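test_that("a planted ARG-GLU nitrogen-oxygen contact is one salt bridge", {
  pk <- pocket_fixture(seed = 7, d_no = 3.1)
  sb <- detect_salt_bridges(pk$structure)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$resno_i, 578L)
  expect_equal(sb$resno_j, 629L)
  expect_equal(sb$distance, 3.1, tolerance = 1e-9)
  expect_true(sb$atom_i %in% c("NH1", "NH2", "NE"))
  expect_true(sb$atom_j %in% c("OE1", "OE2"))
  # every reported distance respects the criterion cutoff
  expect_true(all(sb$distance <= 4.0))
})

test_that("pairs beyond the cutoff are not salt bridges", {
  pk <- pocket_fixture(seed = 7, d_no = 5.5)
  expect_equal(nrow(detect_salt_bridges(pk$structure)), 0L)
  # but a larger cutoff recovers it: monotonicity in the cutoff
  expect_equal(nrow(detect_salt_bridges(pk$structure, cutoff = 6.0)), 1L)
})

test_that("salt-bridge detection is monotone in the cutoff", {
  pk <- pocket_fixture(seed = 5, d_no = 3.5)
  prev <- 0L
  for (cut in c(2, 3, 3.5, 4, 6, 10)) {
    n <- nrow(detect_salt_bridges(pk$structure, cutoff = cut,
                                  all_pairs = TRUE))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("salt-bridge lists are invariant under global rigid transforms", {
  pk <- pocket_fixture(seed = 7, d_no = 3.0)
  a <- detect_salt_bridges(pk$structure)
  b <- detect_salt_bridges(rigid_copy(pk$structure, seed = 99))
  expect_equal(b[, c("resno_i", "resno_j")], a[, c("resno_i", "resno_j")])
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
})

test_that("residue-pair deduplication reports the minimum-distance atom pair", {
  pk <- pocket_fixture(seed = 7, d_no = 3.0)
  all_p <- detect_salt_bridges(pk$structure, all_pairs = TRUE)
  one <- detect_salt_bridges(pk$structure)
  expect_gte(nrow(all_p), nrow(one))
  expect_equal(one$distance, min(all_p$distance))
})

test_that("neutral histidine is excluded unless opted in", {
  df <- data.frame(
    elety = c("N", "CA", "CB", "ND1", "NE2", "N", "CA", "CB", "OD1", "OD2"),
    resid = rep(c("HIS", "ASP"), each = 5),
    resno = rep(1:2, each = 5),
    x = c(0, 1, 2, 3, 3.5, 9, 8, 7, 6.4, 6.9),
    y = 0, z = 0)
  s <- mini_structure(df)   # NE2-OD1 at 2.9 A
  expect_equal(nrow(detect_salt_bridges(s)), 0L)
  sb <- detect_salt_bridges(s, include_his = TRUE)
  expect_equal(nrow(sb), 1L)
  # protonated naming counts without the flag
  df$resid[df$resid == "HIS"] <- "HIP"
  expect_equal(nrow(detect_salt_bridges(mini_structure(df))), 1L)
})

hb_geometry <- function(angle_deg, d_na = NULL) {
  # donor N at origin with H along +x; acceptor O placed so the
  # N-H...O angle at H equals angle_deg
  h <- c(1, 0, 0)
  dir <- c(cos(pi * (180 - angle_deg) / 180),
           sin(pi * (180 - angle_deg) / 180), 0)
  o <- h + 1.9 * dir
  if (!is.null(d_na)) o <- o * d_na / sqrt(sum(o^2))
  df <- data.frame(
    elety = c("N", "H", "CA", "O", "C", "CA"),
    resid = c("ALA", "ALA", "ALA", "ALA", "ALA", "ALA"),
    resno = c(1, 1, 1, 2, 2, 2),
    x = c(0, h[1], -1.2, o[1], o[1] + 1.2, o[1] + 2.2),
    y = c(0, h[2], 0.3, o[2], o[2] + 0.4, o[2] + 1.1),
    z = c(0, 0, 0, o[3], o[3], 0.4),
    elesy = c("N", "H", "C", "O", "C", "C"))
  mini_structure(df)
}

test_that("hydrogen bonds require both distance and angle when H present", {
  good <- hb_geometry(165)
  hb <- detect_hbonds(good)
  expect_gte(nrow(hb), 1L)
  expect_equal(hb$atom_i[1], "N")
  expect_equal(hb$atom_j[1], "O")
  expect_gte(hb$angle[1], 135)

  bent <- hb_geometry(100)
  expect_equal(nrow(detect_hbonds(bent)), 0L)
  # relaxing the angle criterion recovers it (monotonicity)
  expect_gte(nrow(detect_hbonds(bent, angle_cut = 90)), 1L)
})

test_that("distance-only mode applies the heavy-atom cutoff", {
  near <- hb_geometry(180, d_na = 2.9)
  near$atoms <- near$atoms[near$atoms$elety != "H", ]  # strip hydrogens
  near <- new_structure(near$atoms)
  hb <- detect_hbonds(near)
  expect_equal(nrow(hb), 1L)
  expect_true(is.na(hb$angle))

  far <- hb_geometry(180, d_na = 3.6)
  far$atoms <- far$atoms[far$atoms$elety != "H", ]
  far <- new_structure(far$atoms)
  expect_equal(nrow(detect_hbonds(far)), 0L)
  expect_equal(nrow(detect_hbonds(far, d_cut = 3.7)), 1L)
})

test_that("ligand atoms participate only when include_ligand is set", {
  pk <- pocket_fixture(seed = 7, d_no = 3.0)
  s <- add_ligand(pk$structure, offset = c(0, 0, 0))
  # place ligand O1 2.9 A from ARG NH1
  a <- s$atoms
  nh1 <- which(a$resno == 578 & a$elety == "NH1")
  o1 <- which(a$elety == "O1")
  a[o1, c("x", "y", "z")] <- a[nh1, c("x", "y", "z")] + c(2.9, 0, 0) / sqrt(1)
  a[which(a$elety == "N1"), c("x", "y", "z")] <-
    a[nh1, c("x", "y", "z")] + c(50, 50, 50)
  s <- new_structure(a)
  without <- detect_hbonds(s)
  with_lig <- detect_hbonds(s, include_ligand = TRUE)
  expect_false(any(without$resid_j == "LIG" | without$resid_i == "LIG"))
  expect_true(any(with_lig$resid_j == "LIG" | with_lig$resid_i == "LIG"))
})

test_that("occupancy recovery on planted trajectories is exact", {
  pk <- pocket_fixture(seed = 7, d_no = 3.0)
  tj <- make_toy_trajectory(
    pk$structure, n_frames = 100,
    contacts = list(list(donor = list(578, "NH1"),
                         acceptor = list(629, "OE1"), fraction = 0.60)),
    seed = 13)
  occ <- hbond_occupancy(tj$trajectory)
  key <- "A578:NH1--A629:OE1"
  expect_equal(occ$occupancy[occ$contact == key], 0.60)
  expect_equal(occ$n_present[occ$contact == key], 60L)
  expect_equal(attr(occ, "n_frames"), 100L)
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
})

test_that("always-on contacts score 1 and absent contacts never appear", {
  pk <- pocket_fixture(seed = 3, d_no = 3.0)
  tj <- make_toy_trajectory(
    pk$structure, n_frames = 20,
    contacts = list(list(donor = list(578, "NH1"),
                         acceptor = list(629, "OE1"), fraction = 1)),
    seed = 17)
  occ <- hbond_occupancy(tj$trajectory)
  expect_equal(occ$occupancy[occ$contact == "A578:NH1--A629:OE1"], 1.0)

  tj0 <- make_toy_trajectory(
    pk$structure, n_frames = 20,
    contacts = list(list(donor = list(578, "NH1"),
                         acceptor = list(629, "OE1"), fraction = 0)),
    seed = 17)
  occ0 <- hbond_occupancy(tj0$trajectory)
  expect_false("A578:NH1--A629:OE1" %in% occ0$contact)
})
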