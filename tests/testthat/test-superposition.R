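random_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(n * 3, sd = 5), n, 3)
}

test_that("identical point sets superpose with zero rmsd and identity", {
  a <- random_points(10, 1)
  fit <- kabsch(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(fit$n_atoms, 10L)
})

test_that("a planted rigid transform is recovered exactly", {
  a <- random_points(12, 2)
  R <- rotvec_matrix(c(0.3, -1.1, 0.7))
  t0 <- c(4, -2, 9)
  b <- sweep(a %*% t(R), 2, t0, `+`)
  fit <- kabsch(a, b)
  expect_lte(fit$rmsd, 1e-8)
  expect_lte(norm(fit$rotation - R, "F"), 1e-6)
  expect_equal(as.numeric(fit$translation), t0, tolerance = 1e-6)
  # returned transform actually maps a onto b
  expect_lte(max(abs(apply_transform(fit, a) - b)), 1e-6)
})

test_that("rotation output is orthonormal with determinant +1", {
  for (seed in 1:5) {
    a <- random_points(8, seed)
    b <- a + matrix(rnorm(24, sd = 1), 8, 3)
    fit <- kabsch(a, b)
    expect_lte(norm(t(fit$rotation) %*% fit$rotation - diag(3), "F"), 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
})

test_that("kabsch equals brute-force rotational minimization on small sets", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:10, 1)
    a <- matrix(rnorm(n * 3, sd = 4), n, 3)
    b <- sweep(a %*% t(rotvec_matrix(rnorm(3))), 2, rnorm(3, sd = 5), `+`) +
      matrix(rnorm(n * 3, sd = 0.5), n, 3)
    expect_equal(kabsch(a, b)$rmsd, oracle_min_rmsd(a, b),
                 tolerance = 1e-4)
  }
})

test_that("kabsch agrees with bio3d's fitting on the same coordinates", {
  a <- random_points(30, 3)
  b <- a + matrix(rnorm(90, sd = 0.8), 30, 3)
  ours <- kabsch(a, b)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("superposed rmsd is invariant under rigid transforms of either side", {
  a <- random_points(15, 4)
  b <- a + matrix(rnorm(45, sd = 0.7), 15, 3)
  base <- kabsch(a, b)$rmsd
  R <- rotvec_matrix(c(2, 0.5, -1)); t0 <- c(-30, 12, 5)
  expect_equal(kabsch(sweep(a %*% t(R), 2, t0, `+`), b)$rmsd, base,
               tolerance = 1e-8)
  expect_equal(kabsch(a, sweep(b %*% t(R), 2, t0, `+`))$rmsd, base,
               tolerance = 1e-8)
})

test_that("uniform weights reproduce the unweighted fit; weights validated", {
  a <- random_points(9, 5)
  b <- a + matrix(rnorm(27, sd = 0.4), 9, 3)
  expect_equal(kabsch(a, b, weights = rep(2, 9))$rmsd, kabsch(a, b)$rmsd,
               tolerance = 1e-12)
  expect_error(kabsch(a, b, weights = rep(-1, 9)), "non-negative")
  expect_error(kabsch(a, b, weights = rep(0, 9)), "non-negative")
})

test_that("degenerate inputs are rejected", {
  a <- random_points(5, 6)
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))   # collinear
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(a, a[1:4, ]), "same shape")
})

test_that("structure-level rmsd is zero against itself and honors superpose flag", {
  tp <- make_toy_protein(toy_spec(n_domains = 2, residues_per_domain = 15,
                                  seed = 8))
  mp <- map_residues(tp$model, tp$model, "A", "A")
  expect_equal(rmsd_between(tp$model, tp$model, mp, "heavy")$rmsd, 0,
               tolerance = 1e-10)
  moved <- set_xyz_pub(tp$model, coords_of(tp$model) + 5)
  raw <- rmsd_between(moved, tp$model, mp, "calpha", superpose = FALSE)
  expect_equal(raw$rmsd, sqrt(75), tolerance = 1e-8)  # uniform (5,5,5) shift
  fit <- rmsd_between(moved, tp$model, mp, "calpha", superpose = TRUE)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
})

test_that("separate domain superposition absorbs rigid domain displacement", {
  tr <- list(NULL,
             list(angle = 30, axis = c(0, 1, 1), translation = c(8, 0, 0)),
             NULL)
  tp <- make_toy_protein(toy_spec(n_domains = 3, residues_per_domain = 20,
                                  transforms = tr, seed = 10))
  mp <- map_residues(tp$model, tp$reference, "A", "A")
  tab <- domain_rmsd_table(tp$model, tp$reference, mp, tp$scheme)
  r <- setNames(tab$rmsd_ca, tab$domain)
  expect_lte(r[["D1"]], 1e-6)
  expect_lte(r[["D2"]], 1e-6)     # own superposition absorbs the transform
  expect_lte(r[["D3"]], 1e-6)
  expect_gt(r[["Full-length"]], 1)
  expect_true(all(tab$rmsd_heavy[1:3] <= 1e-6))
})

test_that("self comparison yields all-zero rows with full atom counts", {
  tp <- make_toy_protein(toy_spec(n_domains = 3, residues_per_domain = 10,
                                  seed = 12))
  mp <- map_residues(tp$model, tp$model, "A", "A")
  tab <- domain_rmsd_table(tp$model, tp$model, mp, tp$scheme)
  expect_true(all(tab$rmsd_heavy < 1e-9 & tab$rmsd_ca < 1e-9))
  expect_equal(tab$n_heavy[tab$domain == "Full-length"], 150L)
  expect_equal(tab$n_ca[tab$domain == "Full-length"], 30L)
  expect_true(all(tab$n_heavy[tab$domain != "Full-length"] == 50L))
})

test_that("per-domain separate rmsd never exceeds the global-fit domain rmsd", {
  for (seed in c(21, 22, 23)) {
    tr <- list(list(angle = 15, axis = c(1, 0, 0), translation = c(2, 1, 0)),
               list(angle = -25, axis = c(0, 0, 1), translation = c(0, 4, 2)),
               NULL)
    tp <- make_toy_protein(toy_spec(n_domains = 3, residues_per_domain = 15,
                                    transforms = tr, noise_sd = 0.3,
                                    seed = seed))
    mp <- map_residues(tp$model, tp$reference, "A", "A")
    pr <- pair_atoms(tp$model, tp$reference, mp, "calpha")
    a <- coords_of(tp$model)[pr$model_idx, ]
    b <- coords_of(tp$reference)[pr$ref_idx, ]
    global <- kabsch(a, b)
    a_fit <- apply_transform(global, a)
    dom <- tp$scheme
    tab <- domain_rmsd_table(tp$model, tp$reference, mp, dom)
    for (d in paste0("D", 1:3)) {
      sel <- pr$resno %in% (dom$ranges[d, 1]:dom$ranges[d, 2])
      under_global <- sqrt(mean(rowSums((a_fit[sel, ] - b[sel, ])^2)))
      separate <- tab$rmsd_ca[tab$domain == d]
      expect_lte(separate, under_global + 1e-9)
    }
  }
})
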