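# PDB I/O: parsing, chain selection, altlocs, round-trips.

fixture <- test_path("fixtures", "altloc.pdb")

test_that("chain selection partitions residues and rejects bad selectors", {
  conf <- read_configuration(fixture, ref_chains = "A", paired_chains = "B")
  expect_identical(unit_residue_keys(conf$reference), c("A:1", "A:2"))
  expect_identical(unit_residue_keys(conf$paired), c("B:10"))
  # every selected residue in exactly one unit
  expect_length(intersect(unit_residue_keys(conf$reference),
                          unit_residue_keys(conf$paired)), 0)
  expect_error(read_configuration(fixture, "A", "A"),
               class = "dz_validation_error")
  expect_error(read_configuration(fixture, "A", "Z"),
               class = "dz_selector_error")
  expect_error(read_configuration("no/such/file.pdb", "A", "B"),
               class = "dz_io_error")
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties by
           altloc order (verified against an independent parser)", {
  conf <- read_configuration(fixture, "A", "B")
  at <- conf$reference$atoms
  # expectations frozen from Biopython's parse of the same file
  met_ca <- at[at$key == "A:1" & at$name == "CA", ]
  expect_equal(nrow(met_ca), 1L)
  expect_equal(met_ca$altloc, "A")
  expect_equal(met_ca$x, 1.458)
  ser_ca <- at[at$key == "A:2" & at$name == "CA", ]
  expect_equal(nrow(ser_ca), 1L)
  expect_equal(ser_ca$altloc, "A")     # 0.50/0.50 tie -> altloc order
  expect_equal(ser_ca$x, 4.0)
  # hydrogens stored but flagged
  expect_true(any(at$is_hydrogen & at$name == "HB1"))
})

test_that("HETATM and waters are excluded by default, HETATM on demand", {
  conf <- read_configuration(fixture, "A", "B")
  expect_false("ZN" %in% conf$paired$atoms$resname)
  expect_false("HOH" %in% conf$paired$atoms$resname)
  het <- read_configuration(fixture, "A", "B", include_het = TRUE)
  expect_true("ZN" %in% het$paired$atoms$resname)
  expect_false("HOH" %in% het$paired$atoms$resname)
})

test_that("write/read round-trip preserves keys, names, atoms and
           coordinates within 1e-3 A", {
  gen <- tiny_ensemble(1, 6, seed = 11)
  conf <- gen$ensemble$configurations[[1]]
  p <- withr::local_tempfile(fileext = ".pdb")
  write_configuration(conf, p)
  back <- read_configuration(p, "A", "B", id = conf$id)
  for (side in c("reference", "paired")) {
    a0 <- conf[[side]]$atoms; a1 <- back[[side]]$atoms
    expect_identical(a1$key, a0$key)
    expect_identical(a1$name, a0$name)
    expect_identical(a1$resname, a0$resname)
    expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                        as.matrix(a0[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("per-unit transforms are applied on write", {
  gen <- tiny_ensemble(1, 5, seed = 12)
  conf <- gen$ensemble$configurations[[1]]
  p <- withr::local_tempfile(fileext = ".pdb")
  write_configuration(conf, p, transforms = list(
    paired = rigid_transform(diag(3), c(10, 0, 0))))
  back <- read_configuration(p, "A", "B")
  shift <- colMeans(back$paired$atoms[, c("x", "y", "z")]) -
    colMeans(conf$paired$atoms[, c("x", "y", "z")])
  expect_equal(unname(shift), c(10, 0, 0), tolerance = 1e-3)
  # reference untouched
  expect_equal(back$reference$atoms$x, conf$reference$atoms$x,
               tolerance = 1e-3)
})

test_that("random proper rotation preserves intra-unit distances through a
           file round-trip within 2e-3 A", {
  set.seed(42)
  gen <- tiny_ensemble(1, 6, seed = 13)
  conf <- gen$ensemble$configurations[[1]]
  tf <- random_rigid()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_configuration(conf, p, transforms = list(reference = tf, paired = tf))
  back <- read_configuration(p, "A", "B")
  for (side in c("reference", "paired")) {
    expect_lt(max(abs(unit_distmat(back[[side]]) -
                        unit_distmat(conf[[side]]))), 2e-3)
  }
})

test_that("multi-MODEL and per-file loading yield identical configurations", {
  gen <- tiny_ensemble(3, 6, seed = 14)
  dir <- withr::local_tempdir()
  files <- vapply(names(gen$ensemble$configurations), function(id) {
    p <- file.path(dir, paste0(id, ".pdb"))
    write_configuration(gen$ensemble$configurations[[id]], p)
    p
  }, "")
  # build one multi-MODEL file from the same poses
  multi <- file.path(dir, "multi.pdb")
  blocks <- unlist(lapply(seq_along(files), function(i) {
    body <- readLines(files[i])
    body <- body[!grepl("^(REMARK|END$)", body)]
    c(sprintf("MODEL     %4d", i), body, "ENDMDL")
  }))
  writeLines(c(blocks, "END"), multi)
  e_files <- read_ensemble(files, "A", "B")
  e_multi <- read_ensemble(multi, "A", "B")
  expect_length(e_multi$configurations, 3L)
  expect_identical(names(e_multi$configurations), c("1", "2", "3"))
  for (i in 1:3) {
    a <- e_files$configurations[[i]]; b <- e_multi$configurations[[i]]
    expect_identical(a$reference$atoms[, c("key", "name", "x", "y", "z")],
                     b$reference$atoms[, c("key", "name", "x", "y", "z")])
    expect_identical(a$paired$atoms[, c("key", "name", "x", "y", "z")],
                     b$paired$atoms[, c("key", "name", "x", "y", "z")])
  }
})

test_that("read_ensemble marks a member primary and loads external ones", {
  gen <- tiny_ensemble(2, 5, seed = 15)
  dir <- withr::local_tempdir()
  files <- vapply(names(gen$ensemble$configurations), function(id) {
    p <- file.path(dir, paste0(id, ".pdb"))
    write_configuration(gen$ensemble$configurations[[id]], p)
    p
  }, "")
  e1 <- read_ensemble(files, "A", "B", primary = files[1])
  expect_identical(e1$primary_id, "conf_001")
  expect_identical(get_primary(e1)$id, "conf_001")
  # external primary stays out of the member list
  ext <- file.path(dir, "crystal.pdb")
  file.copy(files[1], ext)
  e2 <- read_ensemble(files[2], "A", "B", primary = ext)
  expect_length(e2$configurations, 1L)
  expect_identical(get_primary(e2)$id, "crystal")
})
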