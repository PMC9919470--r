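# Fixture builders shared by the test files. Everything is generated in code;
# no stored data.

# A flat leaf trace lying in the y = const plane band: rows evenly spaced
# along +x, constant width along y. Area of the traced polygon is
# length * width (rectangle) up to the tip triangle.
flat_leaf_trace <- function(n_rows = 5, length = 10, width = 2, z = 0) {
  xs <- seq(0, length * n_rows / (n_rows + 1), length.out = n_rows)
  vein <- cbind(xs, 0, z)
  left <- cbind(xs, width / 2, z)
  right <- cbind(xs, -width / 2, z)
  leaf_surface_trace(left, vein, right, tip = c(length, 0, z))
}

# A straight-leaf phytomer already in (or near) canonical pose: internode
# from `base` along `axis`, leaf vein leaving the internode top toward
# `leaf_dir`. Returns a `phytomer`.
toy_phytomer <- function(rank = 1, n_stem = 1, L_int = 10, leaf_len = 8,
                         base = c(0, 0, 0), axis = c(0, 0, 1),
                         leaf_dir = c(1, 0, 0.2), ear = FALSE, ear_len = 5,
                         widths = c(0.8, 1.2, 0.8)) {
  axis <- axis / sqrt(sum(axis^2))
  top <- base + L_int * axis
  ld <- leaf_dir / sqrt(sum(leaf_dir^2))
  vein <- rbind(top, top + leaf_len / 2 * ld, top + leaf_len * ld)
  # small two-row blade mesh around the vein
  perp <- c(-ld[2], ld[1], 0)
  if (sqrt(sum(perp^2)) < 1e-9) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  tr <- leaf_surface_trace(
    left = rbind(vein[1, ] + 0.4 * perp, vein[2, ] + 0.6 * perp),
    vein = vein[1:2, ],
    right = rbind(vein[1, ] - 0.4 * perp, vein[2, ] - 0.6 * perp),
    tip = vein[3, ])
  app <- if (ear) {
    phytomer3d:::organ_component(
      skeleton = skeleton_model(rbind(top, top + ear_len * axis)),
      params = appendage_params(L_ear = ear_len, D_ear_max = 1))
  } else NULL
  phytomer(
    phytomer_id(1, 1, rank),
    internode = phytomer3d:::organ_component(
      skeleton = skeleton_model(rbind(base, top)),
      params = internode_params(H_base = base[3], L_internode = L_int, D_max = 0.5, D_min = 0.4)),
    leaf = phytomer3d:::organ_component(
      mesh = leaf_mesh_from_trace(tr), skeleton = skeleton_model(vein),
      params = leaf_params(H_base = top[3], L_leaf = leaf_len),
      widths = tr$widths),
    appendage = app,
    n_stem = n_stem)
}

# Random rigid transform (uniform rotation via QR, bounded translation).
random_transform <- function(max_shift = 20) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, runif(3, -max_shift, max_shift))
}

# Random vertical-axis rotation + XY translation (the invariance group of
# the architecture traits).
random_vertical_motion <- function(max_shift = 30) {
  compose_transforms(
    rigid_transform(diag(3), c(runif(2, -max_shift, max_shift), 0)),
    rotation_about_vertical(runif(1, 0, 360)))
}

random_mesh <- function(n = 12) {
  v <- matrix(rnorm(3 * n, sd = 5), n, 3)
  f <- t(replicate(2 * n, sample(n, 3)))
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  mesh_model(v, f[ok, , drop = FALSE])
}

# Uniformly scale every mesh/skeleton point of a shoot (tests of scaling laws).
scale_shoot <- function(shoot, s) {
  shoot$stems <- lapply(shoot$stems, function(stem) {
    stem$components <- lapply(stem$components, function(comp) {
      if (!is.null(comp$mesh)) comp$mesh <- mesh_model(comp$mesh$vertices * s, comp$mesh$faces)
      if (!is.null(comp$skeleton))
        comp$skeleton <- skeleton_model(comp$skeleton$polyline * s)
      if (!is.null(comp$widths)) comp$widths <- comp$widths * s
      comp
    })
    stem
  })
  shoot
}

# Azimuth of a bare vein polyline (first non-degenerate XY segment, CCW
# from +x) -- used to check assembled leaf azimuths without re-wrapping the
# component in a phytomer.
polyline_azimuth <- function(poly) {
  base <- poly[1, ]
  for (i in 2:nrow(poly)) {
    d <- poly[i, 1:2] - base[1:2]
    if (sqrt(sum(d^2)) > 1e-9) return((atan2(d[2], d[1]) * 180 / pi) %% 360)
  }
  stop("vertical polyline")
}

# Small template set for assembly tests: normalized straight-leaf phytomers
# with the given internode lengths (leaf along +x so azimuth 0).
template_set <- function(L = c(10, 8), ear_on_top = TRUE) {
  n <- length(L)
  tpl <- lapply(seq_len(n), function(k)
    normalize_phytomer(toy_phytomer(rank = k, n_stem = n, L_int = L[k],
                                    ear = ear_on_top && k == n)))
  names(tpl) <- sprintf("tpl%d", seq_len(n))
  tpl
}

expect_points_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
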