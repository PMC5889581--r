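# List-view models: repetition rule, sort keys, comparison modes.

test_that("right entries repeat one instance per contact pair, grouped
           under their left residue", {
  # pairs {A1-B1, A1-B2, A2-B1} -> left [A1, A2], right B1,B2,B1
  z <- make_zone(c(1, 1, 2), c(1, 2, 1), c(4, 4.5, 3.5),
                 ref_names = c("ALA", "ALA", "ALA"),
                 paired_names = c("GLY", "GLY", "GLY"))
  m <- build_listview(z, sort_key = "distance")
  expect_equal(nrow(m$right), 3L)
  expect_equal(nrow(m$connections), 3L)
  expect_identical(m$left$key, c("A:2", "A:1"))  # distance sort: 3.5 first
  grouped <- split(m$right$key, m$right$left_index)
  expect_identical(grouped[[which(m$left$key == "A:1")]], c("B:1", "B:2"))
  # connections drawn in listed order never cross: left_index must be
  # non-decreasing down the right column
  expect_true(all(diff(m$connections$left_index) >= 0))
})

test_that("hydrophobicity sort puts ILE before ASP and warns on unknown
           residues", {
  z <- make_zone(c(1, 2), c(1, 2), c(4, 4),
                 ref_names = c("ASP", "ILE"),
                 paired_names = c("GLY", "GLY"))
  m <- build_listview(z, sort_key = "hydrophobicity")
  expect_identical(m$left$name, c("ILE", "ASP"))
  expect_equal(m$left$sort_value, c(4.5, -3.5))
  expect_warning(kyte_doolittle("XXX"), "unknown residue")
  expect_equal(suppressWarnings(kyte_doolittle("XXX")), 0)
})

test_that("distance sort matches a per-residue min-connection oracle and
           frequency sort requires (and uses) the matrix", {
  set.seed(11)
  for (i in 1:10) {
    z <- random_zone(sample(2:12, 1))
    if (nrow(z$pairs) == 0L) next
    m <- build_listview(z, sort_key = "distance")
    oracle <- vapply(unique(z$pairs$ref_key), function(k) {
      min(z$pairs$distance[z$pairs$ref_key == k])
    }, 0)
    expect_identical(m$left$key,
                     names(oracle)[order(oracle,
                                         parse_res_key(names(oracle))$number)])
    expect_equal(nrow(m$right), nrow(z$pairs))
  }
  z <- make_zone(1:2, 1:2, c(4, 4))
  expect_error(build_listview(z, sort_key = "frequency"),
               class = "dz_validation_error")
  gen <- tiny_ensemble(3, 6, plants = data.frame(
    config = c(1, 2, 3, 1), ref_resnum = c(1, 1, 1, 3),
    paired_resnum = c(2, 2, 2, 4), distance = 4))
  mat <- build_frequency_matrix(gen$ensemble)
  zf <- compute_contact_zone(gen$ensemble$configurations[[1]])
  mf <- build_listview(zf, sort_key = "frequency", matrix = mat)
  expect_identical(mf$left$key[1], "A:1")   # count 3 beats count 1
  expect_equal(mf$left$sort_value, c(3, 1))
})

test_that("paired-side list view swaps the anchoring", {
  z <- make_zone(c(1, 1, 2), c(1, 2, 1), c(4, 4.5, 3.5))
  m <- build_listview(z, sort_key = "distance", side = "paired")
  expect_true(all(grepl("^B:", m$left$key)))
  expect_equal(nrow(m$right), 3L)
})

test_that("comparison against the primary: matched pairs, missing
           residues, compare vs compact", {
  primary <- make_zone(c(1, 2, 3), c(1, 2, 3), c(4, 4, 4),
                       config_id = "p")
  same <- make_zone(c(1, 2, 3), c(1, 2, 3), c(4, 4, 4), config_id = "s")
  other <- make_zone(c(7, 8), c(7, 8), c(4, 4), config_id = "o")
  cmp <- compare_listviews(primary, list(same, other), mode = "compare")
  expect_length(cmp$panels[[1]]$matched_pairs, 3L)
  expect_length(cmp$panels[[1]]$missing_left, 0L)
  expect_length(cmp$panels[[2]]$matched_pairs, 0L)
  expect_identical(sort(cmp$panels[[2]]$missing_left),
                   sort(cmp$primary$left$key))
  expect_identical(cmp$panels[[2]]$placeholders,
                   cmp$panels[[2]]$missing_left)
  compact <- compare_listviews(primary, list(same, other), mode = "compact")
  expect_length(compact$panels[[2]]$placeholders, 0L)
  # matched pairs agree exactly between modes
  expect_identical(compact$panels[[2]]$matched_pairs,
                   cmp$panels[[2]]$matched_pairs)
})

test_that("matched/missing sets equal a set-algebra oracle on random
           zones, and left ordering is shared across panels", {
  set.seed(12)
  for (i in 1:10) {
    primary <- random_zone(sample(2:10, 1), config_id = "p")
    panels <- lapply(1:3, function(j) random_zone(sample(1:10, 1),
                                                  config_id = paste0("c", j)))
    cmp <- compare_listviews(primary, panels)
    pset <- paste(primary$pairs$ref_key, primary$pairs$paired_key,
                  sep = "\r")
    for (k in seq_along(panels)) {
      cset <- paste(panels[[k]]$pairs$ref_key,
                    panels[[k]]$pairs$paired_key, sep = "\r")
      expect_setequal(cmp$panels[[k]]$matched_pairs, intersect(pset, cset))
      expect_setequal(cmp$panels[[k]]$missing_left,
                      setdiff(cmp$primary$left$key,
                              unique(panels[[k]]$pairs$ref_key)))
      # shared left residues keep the primary's relative order
      shared <- cmp$panels[[k]]$model$left$key
      shared <- shared[shared %in% cmp$primary$left$key]
      expect_identical(shared,
                       cmp$primary$left$key[cmp$primary$left$key %in%
                                              shared])
      # |right| == |pairs| under every sort
      expect_equal(nrow(cmp$panels[[k]]$model$right),
                   nrow(panels[[k]]$pairs))
    }
  }
})
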