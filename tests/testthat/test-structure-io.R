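test_that("PDB write/read round trip preserves coordinates and residues", {
  pk <- pocket_fixture(seed = 7)
  s <- pk$structure
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_true(max(abs(coords_of(s2) - coords_of(s))) <= 1e-3)
  expect_identical(residue_table(s2), residue_table(s))
  expect_identical(s2$atoms$elety, s$atoms$elety)
})

test_that("two-chain synthetic file reads back with expected chain census", {
  tp <- make_toy_protein(toy_spec(n_domains = 2, residues_per_domain = 10,
                                  seed = 11))
  atoms <- tp$model$atoms
  atoms$chain[atoms$resno > 10] <- "B"
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(new_structure(atoms), f)
  s <- read_structure(f)
  expect_setequal(unique(s$atoms$chain), c("A", "B"))
  expect_equal(nrow(residue_table(s, chain = "A")), 10L)
  expect_equal(nrow(residue_table(s, chain = "B")), 10L)
})

test_that("highest-occupancy altloc wins, ties broken by file order", {
  hdr <- "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(hdr, "ATOM", 1, " CA", "A", "ALA", "A", 1, 1, 0, 0, 0.6, 10, "C"),
    sprintf(hdr, "ATOM", 2, " CA", "B", "ALA", "A", 1, 9, 9, 9, 0.4, 11, "C"),
    sprintf(hdr, "ATOM", 3, " CB", "A", "ALA", "A", 1, 2, 0, 0, 0.5, 10, "C"),
    sprintf(hdr, "ATOM", 4, " CB", "B", "ALA", "A", 1, 8, 8, 8, 0.5, 11, "C"),
    sprintf(hdr, "ATOM", 5, " N",  "",  "ALA", "A", 1, 3, 0, 0, 1.0, 10, "N"),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 3L)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(ca$x, 1)          # occupancy 0.6 beats 0.4
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(cb$x, 2)          # tie: first record in the file
})

test_that("mmCIF input parses with author numbering regardless of column order", {
  s <- read_structure(test_path("fixtures", "toy_pocket.cif"))
  pk <- pocket_fixture(seed = 7)   # same geometry the fixture was built from
  expect_equal(nrow(s$atoms), nrow(pk$structure$atoms))
  expect_equal(sort(unique(s$atoms$resno)), c(228L, 578L, 629L))
  expect_equal(ca_distance(s, "A", 228, 578), 12.7, tolerance = 1e-3)
  expect_equal(coords_of(s), coords_of(pk$structure), tolerance = 1e-3)
})

test_that("unreadable or empty inputs raise parse errors", {
  expect_error(read_structure(withr::local_tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f))
})

test_that("pLDDT extraction follows CA B-factors, mean fallback, auto rescale", {
  df <- data.frame(elety = c("N", "CA", "CB", "N", "CB"),
                   resid = "ALA", resno = c(1, 1, 1, 2, 2),
                   x = 1:5, y = 0, z = 0,
                   b = c(70, 83.3, 90, 60, 80))
  s <- mini_structure(df)
  p <- extract_plddt(s, scale = "0-100")
  expect_equal(p$plddt[p$resno == 1], 83.3)  # CA wins
  expect_equal(p$plddt[p$resno == 2], 70)    # mean fallback (no CA)

  df$b <- c(0.7, 0.793, 0.9, 0.6, 0.8)
  expect_equal(extract_plddt(mini_structure(df))$plddt[1], 79.3)
  # scale=0-100 is the identity on CA B-factors
  expect_equal(extract_plddt(mini_structure(df), scale = "0-100")$plddt[1],
               0.793)
})

test_that("planted per-residue confidence survives a file round trip exactly", {
  tp <- make_toy_protein(toy_spec(n_domains = 3, residues_per_domain = 15,
                                  confidence = c(62, 78, 93), seed = 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tp$model, f)
  p <- extract_plddt(read_structure(f))
  expect_equal(setNames(p$plddt, p$resno), tp$truth$plddt)
})

test_that("NLRP3 domain assignment follows the published subdomain ranges", {
  sch <- nlrp3_scheme()
  resnos <- c(1, 3, 95, 96, 228, 373, 435, 578, 651, 652, 700, 1036, 1040)
  df <- data.frame(elety = "CA", resid = "ALA", resno = resnos,
                   x = seq_along(resnos), y = 0, z = 0)
  asg <- assign_domains(mini_structure(df), sch, "A")
  got <- setNames(asg$domain, asg$resno)
  expect_equal(got[["228"]], "NBD")
  expect_equal(got[["578"]], "HD2")
  expect_equal(got[["700"]], "LRR")
  expect_equal(got[["1"]], "other")     # below PYD start
  expect_equal(got[["1040"]], "other")  # beyond LRR end
  expect_equal(got[["3"]], "PYD")
  expect_equal(got[["95"]], "PYD")
  expect_equal(got[["96"]], "FISNA")
})

test_that("domain assignment partitions the chain", {
  tp <- make_toy_protein(toy_spec(n_domains = 4, residues_per_domain = 12,
                                  seed = 2))
  asg <- assign_domains(tp$model, tp$scheme, "A")
  expect_equal(nrow(asg), nrow(residue_table(tp$model, "A")))
  sizes <- table(asg$domain)
  expect_true(all(sizes[paste0("D", 1:4)] == 12L))
  expect_equal(sum(sizes), 48L)
})

test_that("missing fraction counts deleted residues exactly", {
  spec <- toy_spec(n_domains = 1, residues_per_domain = 110,
                   missing = 0.318, seed = 9)
  tp <- make_toy_protein(spec)
  mf <- missing_fraction(tp$reference, tp$scheme, "D1", "A")
  expect_equal(length(mf$absent), 35L)           # floor(0.318*110 + 0.5)
  expect_equal(mf$fraction, 35 / 110)
  expect_equal(sort(mf$absent), tp$truth$deleted$D1)

  complete <- missing_fraction(tp$model, tp$scheme, "D1", "A")
  expect_equal(complete$fraction, 0)
  expect_length(complete$absent, 0)
  expect_error(missing_fraction(tp$model, tp$scheme, "nope", "A"),
               "unknown domain")
})

test_that("missing fraction stays in [0,1] and is 0 iff range complete", {
  for (f in c(0, 0.1, 0.5, 1)) {
    tp <- make_toy_protein(toy_spec(n_domains = 2, residues_per_domain = 20,
                                    missing = c(f, 0), seed = 3))
    mf <- missing_fraction(tp$reference, tp$scheme, "D1", "A")
    expect_gte(mf$fraction, 0)
    expect_lte(mf$fraction, 1)
    expect_identical(mf$fraction == 0, length(tp$truth$deleted$D1) == 0L)
  }
})

test_that("domain scheme rejects overlapping ranges", {
  expect_error(domain_scheme(list(A = c(1, 10), B = c(10, 20))), "overlap")
  expect_silent(domain_scheme(list(A = c(1, 10), B = c(11, 20))))
})
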