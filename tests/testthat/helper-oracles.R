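# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately use naive scalar loops / set algebra, never the
# package's vectorized code paths.

# brute-force minimum heavy-atom distance (scalar loops)
bf_min_distance <- function(res_a, res_b) {
  A <- res_a[!res_a$is_hydrogen, , drop = FALSE]
  B <- res_b[!res_b$is_hydrogen, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# brute-force contact zone: enumerate all cross-unit residue pairs
bf_contact_zone <- function(conf, params = contact_params()) {
  ra <- split(conf$reference$atoms,
              factor(conf$reference$atoms$key,
                     levels = unique(conf$reference$atoms$key)))
  pa <- split(conf$paired$atoms,
              factor(conf$paired$atoms$key,
                     levels = unique(conf$paired$atoms$key)))
  pairs <- list(); coll <- list()
  for (rk in names(ra)) {
    for (pk in names(pa)) {
      d <- bf_min_distance(ra[[rk]], pa[[pk]])
      if (d >= params$d_min && d <= params$d_max) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          ref_key = rk, paired_key = pk, distance = d)
      } else if (d < params$d_min) {
        coll[[length(coll) + 1L]] <- data.frame(
          ref_key = rk, paired_key = pk, distance = d)
      }
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(ref_key = character(), paired_key = character(),
               distance = double())
  list(pairs = bind(pairs), collisions = bind(coll))
}

pair_str <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$ref_key, df$paired_key, sep = "|"))
}

expect_same_pairs <- function(zone, oracle) {
  expect_identical(pair_str(zone$pairs), pair_str(oracle$pairs))
  expect_identical(pair_str(zone$collisions), pair_str(oracle$collisions))
  m <- match(paste(zone$pairs$ref_key, zone$pairs$paired_key, sep = "|"),
             paste(oracle$pairs$ref_key, oracle$pairs$paired_key,
                   sep = "|"))
  expect_equal(zone$pairs$distance, oracle$pairs$distance[m],
               tolerance = 1e-12)
}

# hand-built contact zone (for scoring/listview tests without structures)
make_zone <- function(ref_numbers, paired_numbers, distances,
                      config_id = "z", ref_names = NULL,
                      paired_names = NULL) {
  n <- length(ref_numbers)
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  ref_names <- ref_names %||% aa[(ref_numbers - 1L) %% 20L + 1L]
  paired_names <- paired_names %||% aa[(paired_numbers - 1L) %% 20L + 1L]
  pairs <- data.frame(
    ref_key = if (n) res_key("A", ref_numbers) else character(0),
    ref_chain = rep("A", n),
    ref_number = as.integer(ref_numbers), ref_ins = rep("", n),
    ref_name = ref_names,
    paired_key = if (n) res_key("B", paired_numbers) else character(0),
    paired_chain = rep("B", n),
    paired_number = as.integer(paired_numbers), paired_ins = rep("", n),
    paired_name = paired_names,
    distance = distances, stringsAsFactors = FALSE
  )
  ord <- order(pairs$ref_chain, pairs$ref_number, pairs$paired_chain,
               pairs$paired_number)
  structure(list(config_id = config_id, pairs = pairs[ord, ],
                 collisions = pairs[0, ], params = contact_params(),
                 ref_side = "reference"),
            class = "contact_zone")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_zone <- function(n_pairs, config_id = "rz") {
  ref <- sample(1:30, n_pairs, replace = TRUE)
  paired <- sample(1:30, n_pairs, replace = TRUE)
  dup <- duplicated(paste(ref, paired))
  ref <- ref[!dup]; paired <- paired[!dup]
  make_zone(ref, paired, round(runif(length(ref), 3, 5), 3),
            config_id = config_id)
}

random_rotation <- function() {
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  angle <- runif(1, 0, pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rigid <- function(max_shift = 20) {
  rigid_transform(random_rotation(), runif(3, -max_shift, max_shift))
}

# all pairwise distances within a unit (rigidity checks)
unit_distmat <- function(unit) {
  as.matrix(dist(unit$atoms[, c("x", "y", "z")]))
}

# do two 2D segments (p1-p2, q1-q2) properly intersect?
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

count_svg_rects <- function(path) {
  lines <- readLines(path)
  hits <- gregexpr("<rect ", lines, fixed = TRUE)
  sum(vapply(hits, function(h) sum(h > 0), 0L))
}

tiny_ensemble <- function(n_configs = 3, residues = 8, seed = 1,
                          plants = NULL) {
  sp <- if (is.null(plants)) {
    random_ensemble_spec(n_configs, residues, seed = seed)
  } else {
    ensemble_spec(n_configs, residues, plants, seed = seed)
  }
  generate_ensemble(sp)
}
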