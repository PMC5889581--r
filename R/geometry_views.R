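# Rigid-body machinery for the exploded and open-book layouts.
#
# All motions are emitted as explicit proper rigid transforms
# (x' = R x + t, R orthonormal, det +1); nothing is rendered here.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1 within
#'   1e-9).
#' @param translation length-3 translation vector (Angstrom).
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  tf <- structure(list(rotation = rotation,
                       translation = as.numeric(translation)),
                  class = "rigid_transform")
  check_rigid(tf)
  tf
}

check_rigid <- function(tf, tol = 1e-9) {
  R <- tf$rotation
  if (!is.matrix(R) || any(dim(R) != 3L) ||
      max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop_dz("dz_validation_error",
      "not a proper rigid transform (R'R != I or det != +1)")
  }
  invisible(tf)
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param xyz n x 3 coordinate matrix (or a length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
apply_rigid <- function(tf, xyz) {
  if (is.null(dim(xyz))) {
    return(as.numeric(tf$rotation %*% xyz + tf$translation))
  }
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, "+")
}

compose_rigid <- function(a, b) {
  # returns transform equivalent to applying b first, then a
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

invert_rigid <- function(tf) {
  rigid_transform(t(tf$rotation),
                  as.numeric(-t(tf$rotation) %*% tf$translation))
}

rigid_to_matrix <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- tf$rotation
  m[1:3, 4] <- tf$translation
  m
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Rodrigues rotation about unit axis by angle (radians)
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- skew(axis)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal rotation taking unit vector a onto unit vector b;
# `flip_axis` resolves the antiparallel case deterministically
minimal_rotation <- function(a, b, flip_axis) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s2 <- sum(v^2)
  cth <- sum(a * b)
  if (s2 < 1e-24) {
    if (cth > 0) return(diag(3))
    return(rotation_about_axis(flip_axis, pi))
  }
  K <- skew(v)
  diag(3) + K + K %*% K * ((1 - cth) / s2)
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rigid transform mapping `moving` onto
#' `fixed` (SVD of the cross-covariance; reflections suppressed by
#' determinant correction).
#'
#' @param moving,fixed n x 3 matrices of corresponding points, n >= 3,
#'   not all collinear.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom, root-mean-square residual after superposition).
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 3L || ncol(fixed) != 3L) {
    stop_dz("dz_validation_error", "point sets must be equal-length n x 3")
  }
  if (nrow(moving) < 3L) {
    stop_dz("dz_degenerate_error", "need >= 3 correspondences, got ",
      nrow(moving))
  }
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  sv_p <- svd(P)$d
  if (sv_p[2] < 1e-9 * max(sv_p[1], 1)) {
    stop_dz("dz_degenerate_error", "moving points are (near) collinear")
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cf - R %*% cm)
  tf <- rigid_transform(R, tr)
  res <- apply_rigid(tf, moving) - fixed
  list(transform = tf, rmsd = sqrt(mean(rowSums(res^2))))
}

#' Superpose every configuration's reference protein onto an anchor
#'
#' The correspondence is the intersection of reference-unit residue keys
#' bearing C-alpha atoms (docking ensembles repose identical sequences, so
#' this correspondence is exact and no structural-alignment search is
#' needed). Each configuration is moved rigidly as a whole (both units), so
#' contact zones are unchanged.
#'
#' @param ensemble an `ensemble`.
#' @param anchor configuration id to align to; default the primary if it is
#'   a member, else the first configuration.
#' @return list with `ensemble` (aligned copy; the external primary, when
#'   present, is aligned too) and `results`, a data.frame
#'   (config_id, rmsd, n_matched).
#' @export
align_ensemble <- function(ensemble, anchor = NULL) {
  confs <- ensemble$configurations
  if (is.null(anchor)) {
    anchor <- if (!is.na(ensemble$primary_id)) ensemble$primary_id
              else confs[[1]]$id
  }
  if (!anchor %in% names(confs)) {
    stop_dz("dz_validation_error", "anchor '", anchor,
      "' is not a member of the ensemble")
  }
  anchor_ca <- unit_ca_coords(confs[[anchor]]$reference)
  align_one <- function(conf) {
    ca <- unit_ca_coords(conf$reference)
    common <- intersect(rownames(anchor_ca), rownames(ca))
    if (length(common) < 3L) {
      stop_dz("dz_alignment_error", "configuration '", conf$id,
        "': only ", length(common), " common C-alpha residues with anchor")
    }
    fit <- kabsch_superpose(ca[common, , drop = FALSE],
                            anchor_ca[common, , drop = FALSE])
    list(conf = transform_configuration(conf, fit$transform),
         transform = fit$transform, rmsd = fit$rmsd,
         n_matched = length(common))
  }
  fits <- lapply(confs, align_one)
  ensemble$configurations <- lapply(fits, `[[`, "conf")
  if (!is.null(ensemble$primary)) {
    pfit <- align_one(ensemble$primary)
    ensemble$primary <- pfit$conf
    fits <- c(fits, list(primary = pfit))
  }
  results <- data.frame(
    config_id = vapply(fits, function(f) f$conf$id, ""),
    rmsd = vapply(fits, `[[`, 0, "rmsd"),
    n_matched = vapply(fits, `[[`, 0L, "n_matched"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(ensemble = ensemble, results = results,
       transforms = lapply(fits, `[[`, "transform"))
}

# contact-zone geometry ---------------------------------------------------

zone_side_keys <- function(zone, side) {
  side <- match.arg(side, c("reference", "paired"))
  if (side == "reference") unique(zone$pairs$ref_key)
  else unique(zone$pairs$paired_key)
}

side_zone_coords <- function(conf, zone, side) {
  keys <- zone_side_keys(zone, side)
  if (length(keys) == 0L) {
    stop_dz("dz_empty_zone_error", "contact zone has no ", side,
      "-side residues")
  }
  unit <- conf[[side]]
  ca <- unit_ca_coords(unit)
  have <- intersect(keys, rownames(ca))
  if (length(have) == length(keys)) {
    return(ca[have, , drop = FALSE])
  }
  # fall back to all heavy atoms of the zone residues when C-alphas are
  # missing (e.g. pruned models)
  at <- unit$atoms
  at <- at[!at$is_hydrogen & at$key %in% keys, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Centroid of one side of a contact zone
#'
#' Mean of the C-alpha positions of the side's contact residues (all heavy
#' atoms when C-alphas are absent).
#'
#' @param conf the `configuration` the zone was computed from.
#' @param zone a `contact_zone`.
#' @param side `"reference"` or `"paired"`.
#' @return length-3 numeric vector (Angstrom).
#' @export
contact_zone_centroid <- function(conf, zone, side) {
  unname(colMeans(side_zone_coords(conf, zone, side)))
}

#' Outward normal of one side of a contact zone
#'
#' Unit normal of the least-squares plane through the side's contact-zone
#' C-alpha positions (smallest principal direction of their covariance),
#' sign-flipped to point toward the partner side's centroid. With fewer
#' than 3 residues the direction toward the partner centroid is returned.
#'
#' @inheritParams contact_zone_centroid
#' @return unit length-3 vector.
#' @export
contact_zone_normal <- function(conf, zone, side) {
  side <- match.arg(side, c("reference", "paired"))
  other <- if (side == "reference") "paired" else "reference"
  xyz <- side_zone_coords(conf, zone, side)
  partner <- contact_zone_centroid(conf, zone, other)
  ctr <- colMeans(xyz)
  towards <- partner - ctr
  if (nrow(xyz) < 3L) {
    len <- sqrt(sum(towards^2))
    if (len < 1e-12) stop_dz("dz_degenerate_error", "degenerate contact zone")
    return(towards / len)
  }
  X <- sweep(xyz, 2, ctr)
  s <- svd(X, nu = 0)
  if (s$d[1] < 1e-12) {
    stop_dz("dz_degenerate_error", "contact-zone points are coincident")
  }
  n <- s$v[, 3]
  if (sum(n * towards) < 0) n <- -n
  n / sqrt(sum(n^2))
}

bounding_sphere <- function(unit) {
  xyz <- unit_coords(unit)
  ctr <- colMeans(xyz)
  r <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  list(center = ctr, radius = r)
}

orthonormal_basis_for <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  h <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- h - sum(h * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2, axis = axis)
}

#' Exploded-view layout of an aligned ensemble
#'
#' Keeps the superposed reference proteins in place and translates each
#' configuration's paired protein to a slot on a parabolic regular grid
#' along the mean reference-side contact-zone normal, guaranteeing that
#' paired-unit bounding spheres never overlap. Paired units are translated
#' only, never re-oriented, so each pose's orientation is preserved for
#' comparison. Per-configuration tube endpoints (reference contact-zone
#' centroid, translated paired contact-zone centroid) record the pairing.
#'
#' @param ensemble an aligned `ensemble` (see [align_ensemble()]), in the
#'   display order (e.g. rank order).
#' @param zones named list of `contact_zone`s, one per configuration.
#' @param spacing_margin extra clearance between neighbouring bounding
#'   spheres (Angstrom, default 10).
#' @param focal paraboloid focal length f in w = (u^2+v^2)/(4 f); default
#'   2 x the largest paired-unit bounding-sphere radius.
#' @return a `layout_plan`: list with `slots` (data.frame of per-config
#'   translations, slot centres and tube endpoints), `grid` parameters and
#'   per-configuration `transforms` (pure translations for the paired
#'   unit).
#' @export
exploded_layout <- function(ensemble, zones, spacing_margin = 10,
                            focal = NULL) {
  confs <- ensemble$configurations
  ids <- names(confs)
  zones <- zones[ids]
  if (any(vapply(zones, is.null, TRUE))) {
    stop_dz("dz_validation_error", "missing contact zone for some members")
  }
  empty <- vapply(zones, function(z) nrow(z$pairs) == 0L, TRUE)
  if (all(empty)) {
    stop_dz("dz_layout_error", "all contact zones are empty")
  }
  use <- ids[!empty]
  spheres <- lapply(confs[use], function(cf) bounding_sphere(cf$paired))
  rmax <- max(vapply(spheres, `[[`, 0, "radius"))
  step <- 2 * rmax + spacing_margin
  f <- focal %||% (2 * rmax)
  if (f <= 0) f <- 1
  normals <- vapply(use, function(id) {
    contact_zone_normal(confs[[id]], zones[[id]], "reference")
  }, numeric(3))
  axis <- rowMeans(matrix(normals, nrow = 3))
  if (sqrt(sum(axis^2)) < 1e-9) axis <- c(0, 0, 1)
  basis <- orthonormal_basis_for(axis)
  ref_centroids <- vapply(use, function(id) {
    contact_zone_centroid(confs[[id]], zones[[id]], "reference")
  }, numeric(3))
  origin <- rowMeans(matrix(ref_centroids, nrow = 3))
  ref_reach <- max(vapply(confs[use], function(cf) {
    sqrt(max(rowSums(sweep(unit_coords(cf$reference), 2, origin)^2)))
  }, 0))
  offset <- ref_reach + rmax + spacing_margin

  k <- length(use)
  ncols <- ceiling(sqrt(k))
  nrows <- ceiling(k / ncols)
  rows <- data.frame()
  transforms <- list()
  for (i in seq_len(k)) {
    id <- use[i]
    r <- (i - 1L) %/% ncols
    c <- (i - 1L) %% ncols
    u <- (c - (ncols - 1) / 2) * step
    v <- (r - (nrows - 1) / 2) * step
    w <- offset + (u^2 + v^2) / (4 * f)
    slot <- origin + u * basis$e1 + v * basis$e2 + w * basis$axis
    tr <- slot - spheres[[id]]$center
    transforms[[id]] <- rigid_transform(diag(3), tr)
    tube_ref <- contact_zone_centroid(confs[[id]], zones[[id]], "reference")
    tube_pair <- contact_zone_centroid(confs[[id]], zones[[id]], "paired") + tr
    rows <- rbind(rows, data.frame(
      config_id = id, slot_u = u, slot_v = v,
      slot_x = slot[1], slot_y = slot[2], slot_z = slot[3],
      tx = tr[1], ty = tr[2], tz = tr[3],
      radius = spheres[[id]]$radius,
      tube_ref_x = tube_ref[1], tube_ref_y = tube_ref[2],
      tube_ref_z = tube_ref[3],
      tube_paired_x = tube_pair[1], tube_paired_y = tube_pair[2],
      tube_paired_z = tube_pair[3],
      stringsAsFactors = FALSE
    ))
  }
  structure(list(
    slots = rows,
    transforms = transforms,
    grid = list(step = step, focal = f, margin = spacing_margin,
                axis = basis$axis, e1 = basis$e1, e2 = basis$e2,
                origin = origin, offset = offset,
                skipped_empty = ids[empty])
  ), class = "layout_plan")
}

unit_aabb <- function(unit, tf = NULL) {
  xyz <- unit_coords(unit)
  if (!is.null(tf)) xyz <- apply_rigid(tf, xyz)
  list(min = apply(xyz, 2, min), max = apply(xyz, 2, max))
}

#' Open-book transforms for one configuration
#'
#' Rotates each protein unit about its contact-zone centroid by the minimal
#' rotation taking its outward zone normal onto the view direction, then
#' translates the units side by side along an in-plane axis so both contact
#' surfaces face the observer with at least `gap` between their bounding
#' boxes. A normal antiparallel to the view direction is resolved by a
#' fixed 180-degree rotation about the separation axis.
#'
#' @param conf a `configuration`.
#' @param zone its `contact_zone` (both sides non-empty).
#' @param view_dir unit vector toward the observer, default `c(0, 0, 1)`.
#' @param gap minimum bounding-box clearance between the opened units
#'   (Angstrom, default 10).
#' @return an `open_book_result`: rigid transforms for both units, normals
#'   before/after, and the realized gap.
#' @export
open_book_transforms <- function(conf, zone, view_dir = c(0, 0, 1),
                                 gap = 10) {
  if (nrow(zone$pairs) == 0L) {
    stop_dz("dz_empty_zone_error", "contact zone is empty")
  }
  view_dir <- view_dir / sqrt(sum(view_dir^2))
  basis <- orthonormal_basis_for(view_dir)
  sep <- basis$e1
  make_open <- function(side) {
    n <- contact_zone_normal(conf, zone, side)
    ctr <- contact_zone_centroid(conf, zone, side)
    R <- minimal_rotation(n, view_dir, flip_axis = sep)
    list(normal = n, centroid = ctr, R = R,
         tf = rigid_transform(R, ctr - as.numeric(R %*% ctr)))
  }
  ref <- make_open("reference")
  par <- make_open("paired")
  # shift along the separation axis: reference left, paired right
  box_r <- unit_aabb(conf$reference, ref$tf)
  box_p <- unit_aabb(conf$paired, par$tf)
  shift_r <- -(gap / 2) - proj_corners(box_r, sep)
  shift_p <- (gap / 2) - proj_corners(box_p, sep, lower = TRUE)
  tf_ref <- rigid_transform(ref$tf$rotation,
                            ref$tf$translation + shift_r * sep)
  tf_par <- rigid_transform(par$tf$rotation,
                            par$tf$translation + shift_p * sep)
  n_ref_after <- as.numeric(tf_ref$rotation %*% ref$normal)
  n_par_after <- as.numeric(tf_par$rotation %*% par$normal)
  structure(list(
    transform_ref = tf_ref, transform_paired = tf_par,
    normal_ref_before = ref$normal, normal_paired_before = par$normal,
    normal_ref_after = n_ref_after, normal_paired_after = n_par_after,
    view_dir = view_dir, separation_axis = sep, gap = gap
  ), class = "open_book_result")
}

# extreme projection of an axis-aligned box onto a direction
proj_corners <- function(box, dir, lower = FALSE) {
  corners <- as.matrix(expand.grid(
    c(box$min[1], box$max[1]), c(box$min[2], box$max[2]),
    c(box$min[3], box$max[3])))
  p <- corners %*% dir
  if (lower) min(p) else max(p)
}
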