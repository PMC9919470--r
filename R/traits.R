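# Multi-scale phenotypic parameters extracted from shoot geometry.
#
#   organ     : L_bend (blade curvature, chord/arc), theta_l (stem-leaf angle)
#   phytomer  : S_phy (envelope: internode [+ spike] length x tip-to-axis
#               distance x max blade width, cm^3)
#   stem      : N_length (mean internode length), theta_s (stem vs vertical)
#   plant     : h (height to spike top), S_area (spike-layer projected area)

#' Blade curvature
#'
#' Ratio of the base-to-tip chord to the vein arc length. 1 means a straight
#' blade; smaller values mean stronger drooping.
#'
#' @param vein a `skeleton_model` / `vein_trace`, or an n x 3 polyline matrix.
#' @return L_bend in (0, 1].
#' @export
blade_curvature <- function(vein) {
  poly <- if (inherits(vein, "skeleton_model") || is.list(vein)) vein$polyline else as_points(vein)
  arc <- polyline_length(poly)
  if (arc <= .EPS) stop("vein arc length is zero; curvature undefined", call. = FALSE)
  chord <- vnorm(poly[nrow(poly), ] - poly[1, ])
  min(chord / arc, 1)
}

#' Stem-leaf angle
#'
#' Angle between the stem vector and the leaf vector (the base-to-tip chord
#' of the blade), in degrees.
#'
#' @param stem_vector,leaf_vector numeric length-3 vectors.
#' @return angle in [0, 180] degrees.
#' @export
stem_leaf_angle <- function(stem_vector, leaf_vector) angle_between(stem_vector, leaf_vector)

#' Phytomer envelope
#'
#' Product of three lengths: internode length (plus spike length on the
#' spike-bearing unit), the perpendicular distance from the leaf tip to the
#' internode axis line, and the maximum blade width.
#'
#' @param internode component with an internode skeleton (>= 2 points).
#' @param leaf component with a vein skeleton (tip = last point) and row
#'   `widths`.
#' @param spike_length cm; 0 for phytomers without a spike.
#' @return S_phy in cm^3.
#' @export
phytomer_envelope <- function(internode, leaf, spike_length = 0) {
  if (is.null(leaf) || is.null(leaf$skeleton))
    stop("phytomer envelope undefined without a leaf", call. = FALSE)
  if (is.null(internode) || is.null(internode$skeleton))
    stop("phytomer envelope undefined without an internode", call. = FALSE)
  ipoly <- internode$skeleton$polyline
  L <- polyline_length(ipoly) + spike_length
  tip <- leaf$skeleton$polyline[nrow(leaf$skeleton$polyline), ]
  axis <- ipoly[nrow(ipoly), ] - ipoly[1, ]
  d <- point_line_distance(tip, ipoly[1, ], axis)
  if (d < 1e-9) warning("leaf tip lies on the internode axis; envelope is 0", call. = FALSE)
  w <- if (!is.null(leaf$widths)) max(leaf$widths) else max_mesh_width(leaf$mesh)
  L * d * w
}

# Fallback max blade width from a 3n+1 leaf mesh (left = 3i-2, right = 3i).
max_mesh_width <- function(mesh) {
  if (is.null(mesh)) stop("no widths and no mesh; blade width unavailable", call. = FALSE)
  n <- (nrow(mesh$vertices) - 1) / 3
  max(vapply(seq_len(n), function(i)
    vnorm(mesh$vertices[3 * i - 2, ] - mesh$vertices[3 * i, ]), numeric(1)))
}

#' Average internode length
#'
#' @param s a `stem_trace`, `assembled_stem`, or numeric vector of internode
#'   lengths.
#' @return N_length in cm.
#' @export
average_internode_length <- function(s) {
  lens <- if (is.numeric(s)) s else internode_lengths(s)
  if (length(lens) < 1) stop("need at least one internode", call. = FALSE)
  mean(lens)
}

# Base and top node of a stem's internode chain.
stem_endpoints <- function(s) {
  if (inherits(s, "stem_trace")) {
    return(list(base = s$nodes[1, ], top = s$nodes[nrow(s$nodes), ]))
  }
  ints <- Filter(function(c) c$organ == "internode", s$components)
  ks <- vapply(ints, `[[`, integer(1), "rank")
  bot <- ints[[which.min(ks)]]$skeleton$polyline
  top <- ints[[which.max(ks)]]$skeleton$polyline
  list(base = bot[1, ], top = top[nrow(top), ])
}

#' Stem inclination from vertical
#'
#' Angle between the base-to-top stem vector and the vertical (+z), degrees.
#'
#' @param s a `stem_trace` or `assembled_stem`.
#' @return theta_s in [0, 180] degrees.
#' @export
stem_vertical_angle <- function(s) {
  ep <- stem_endpoints(s)
  v <- ep$top - ep$base
  if (vnorm(v) < .EPS) stop("stem base and top coincide", call. = FALSE)
  angle_between(v, c(0, 0, 1))
}

#' Plant height
#'
#' Vertical height from the ground plane (z = 0) to the top of the spike:
#' the maximum z over spike (appendage) vertices. When the shoot has no
#' spike, falls back to the maximum z over all vertices, with a warning.
#'
#' @param shoot an `assembled_shoot` (or `assembled_stem`).
#' @return h in cm.
#' @export
plant_height <- function(shoot) {
  pts <- shoot_points(shoot, organ = "appendage")
  if (nrow(pts) == 0) {
    warning("no spike in shoot; plant height taken over all vertices", call. = FALSE)
    pts <- shoot_points(shoot)
  }
  if (nrow(pts) == 0) stop("shoot has no geometry", call. = FALSE)
  max(pts[, 3])
}

#' Spike-layer projected area
#'
#' Area of the 2D convex hull of the XY projection of all spike (appendage)
#' vertices across tillers. Shoots without spikes use the top height band of
#' all vertices as the layer (fraction configurable), with a warning.
#' Degenerate layers (< 3 points or collinear) return 0 with a warning.
#'
#' @param shoot an `assembled_shoot`.
#' @param fallback_fraction height fraction (from the top) defining the spike
#'   layer when no spike exists; default 0.2.
#' @return S_area in cm^2.
#' @export
spike_layer_projected_area <- function(shoot, fallback_fraction = 0.2) {
  pts <- shoot_points(shoot, organ = "appendage")
  if (nrow(pts) == 0) {
    warning(sprintf("no spike in shoot; using the top %.0f%% height band as the spike layer",
                    100 * fallback_fraction), call. = FALSE)
    all_pts <- shoot_points(shoot)
    if (nrow(all_pts) == 0) stop("shoot has no geometry", call. = FALSE)
    zr <- range(all_pts[, 3])
    zcut <- zr[2] - fallback_fraction * (zr[2] - zr[1])
    pts <- all_pts[all_pts[, 3] >= zcut, , drop = FALSE]
  }
  a <- convex_hull_area(pts[, 1:2, drop = FALSE])
  if (a <= 0) warning("degenerate spike layer (collinear or < 3 points); S_area = 0",
                      call. = FALSE)
  a
}

## ---- whole-table extraction ------------------------------------------------

stem_vector_of <- function(stem) {
  ep <- stem_endpoints(stem)
  ep$top - ep$base
}

rank_components <- function(stem, k, organ) {
  hit <- Filter(function(c) c$organ == organ && c$rank == k, stem$components)
  if (length(hit)) hit[[1]] else NULL
}

#' Extract the full multi-scale trait table from a shoot
#'
#' One row per (plant, tiller, rank, organ, trait): per leaf L_bend and
#' theta_l, per phytomer S_phy, per stem N_length and theta_s, per plant h
#' and S_area.
#'
#' @param shoot an `assembled_shoot`.
#' @param fallback_fraction passed to [spike_layer_projected_area()].
#' @return a `data.frame` with columns plant, tiller, rank, organ, trait,
#'   value, units.
#' @export
extract_traits <- function(shoot, fallback_fraction = 0.2) {
  stopifnot(inherits(shoot, "assembled_shoot"))
  rows <- list()
  add <- function(tiller, rank, organ, trait, value, units) {
    rows[[length(rows) + 1]] <<- data.frame(
      plant = shoot$plant, tiller = tiller, rank = rank, organ = organ,
      trait = trait, value = value, units = units)
  }
  for (stem in shoot$stems) {
    sv <- stem_vector_of(stem)
    for (k in seq_len(stem$n)) {
      leaf <- rank_components(stem, k, "leaf")
      internode <- rank_components(stem, k, "internode")
      app <- rank_components(stem, k, "appendage")
      spike_len <- if (!is.null(app)) polyline_length(app$skeleton$polyline) else 0
      if (!is.null(leaf) && !is.null(leaf$skeleton)) {
        poly <- leaf$skeleton$polyline
        add(stem$tiller, k, "leaf", "L_bend", blade_curvature(leaf$skeleton), "1")
        add(stem$tiller, k, "leaf", "theta_l",
            stem_leaf_angle(sv, poly[nrow(poly), ] - poly[1, ]), "deg")
        add(stem$tiller, k, "phytomer", "S_phy",
            phytomer_envelope(internode, leaf, spike_len), "cm3")
      }
    }
    add(stem$tiller, NA, "stem", "N_length", average_internode_length(stem), "cm")
    add(stem$tiller, NA, "stem", "theta_s", stem_vertical_angle(stem), "deg")
  }
  add(NA, NA, "plant", "h", plant_height(shoot), "cm")
  add(NA, NA, "plant", "S_area",
      spike_layer_projected_area(shoot, fallback_fraction), "cm2")
  do.call(rbind, rows)
}
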