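# Domain types for 3D phytomers and their canonical (template) form.
#
# A phytomer — the repeating unit of a grass shoot — is represented as up to
# four organ components (leaf blade, leaf sheath, internode, nodal appendage
# i.e. the ear on the top unit), each a triple of
#   mesh      : triangle mesh (surface geometry),
#   skeleton  : polyline (leaf vein, sheath mid-axis, internode mid-axis),
#   params    : named morphological parameters (lengths cm, angles degrees).
# The internode component is mandatory; the others are optional.

#' Construct a triangle mesh model
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (cm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return an object of class `mesh_model`.
#' @export
mesh_model <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) < 1) stop("mesh must have at least one vertex", call. = FALSE)
  if (ncol(faces) != 3) stop("faces must be vertex-index triples", call. = FALSE)
  if (nrow(faces) > 0) {
    if (any(faces < 1) || any(faces > nrow(vertices)))
      stop("face index out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]))
      stop("face repeats a vertex index", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "mesh_model")
}

#' Total surface area of a mesh
#' @param m a `mesh_model`.
#' @return area in cm^2.
#' @export
mesh_area <- function(m) {
  stopifnot(inherits(m, "mesh_model"))
  if (nrow(m$faces) == 0) return(0)
  sum(apply(m$faces, 1, function(f)
    triangle_area3(m$vertices[f[1], ], m$vertices[f[2], ], m$vertices[f[3], ])))
}

#' Construct a skeleton (polyline) model
#'
#' Skeletons carry the simplified axis of an organ: the leaf vein, the sheath
#' mid-axis, or the internode mid-axis.
#'
#' @param polyline numeric n x 3 matrix, n >= 2, ordered base to tip.
#' @return an object of class `skeleton_model`.
#' @export
skeleton_model <- function(polyline) {
  polyline <- as_points(polyline)
  if (nrow(polyline) < 2) stop("skeleton needs at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                         polyline[-nrow(polyline), , drop = FALSE])^2))
  if (any(seg < .EPS)) stop("skeleton has coincident consecutive points", call. = FALSE)
  structure(list(polyline = polyline), class = "skeleton_model")
}

skeleton_length <- function(s) polyline_length(s$polyline)

#' @export
print.mesh_model <- function(x, ...) {
  cat(sprintf("<mesh_model: %d vertices, %d faces, area %.3f cm^2>\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model: %d points, length %.3f cm>\n",
              nrow(x$polyline), skeleton_length(x)))
  invisible(x)
}

## ---- morphological parameter sets -----------------------------------------

#' Morphological parameter sets per organ
#'
#' Named, extensible parameter vectors for each organ of a phytomer. Lengths
#' in cm, angles in degrees, azimuth counter-clockwise from +x in [0, 360).
#'
#' @param H_base attachment height above the ground plane (cm).
#' @param L_leaf,L_sheath,L_internode,L_ear organ lengths (cm).
#' @param theta_leaf,theta_sheath,theta_internode inclination angles (degrees).
#' @param alpha_leaf leaf azimuth (degrees, [0, 360)).
#' @param D_max,D_min maximum / minimum diameter (cm).
#' @param D_node_max maximum node diameter (cm).
#' @param D_ear_max maximum ear diameter (cm); `L_ear > 0` only on the
#'   spike-bearing phytomer.
#' @param ... extra named entries (the parameter sets are extensible).
#' @return a named list with class `"<organ>_params"`.
#' @name organ_params
NULL

#' @rdname organ_params
#' @export
leaf_params <- function(H_base = 0, L_leaf, theta_leaf = 0, alpha_leaf = 0, ...) {
  if (L_leaf <= 0) stop("L_leaf must be positive", call. = FALSE)
  if (theta_leaf < 0 || theta_leaf > 180) stop("theta_leaf must be in [0, 180]", call. = FALSE)
  alpha_leaf <- alpha_leaf %% 360
  structure(list(H_base = H_base, L_leaf = L_leaf, theta_leaf = theta_leaf,
                 alpha_leaf = alpha_leaf, ...), class = "leaf_params")
}

#' @rdname organ_params
#' @export
sheath_params <- function(H_base = 0, L_sheath, theta_sheath = 0, D_max = 0, D_min = 0, ...) {
  if (L_sheath < 0 || D_max < 0 || D_min < 0) stop("sheath lengths must be >= 0", call. = FALSE)
  if (D_min > D_max) stop("D_min must not exceed D_max", call. = FALSE)
  structure(list(H_base = H_base, L_sheath = L_sheath, theta_sheath = theta_sheath,
                 D_max = D_max, D_min = D_min, ...), class = "sheath_params")
}

#' @rdname organ_params
#' @export
internode_params <- function(H_base = 0, L_internode, theta_internode = 0,
                             D_max = 0, D_min = 0, ...) {
  if (L_internode <= 0) stop("L_internode must be positive", call. = FALSE)
  if (D_min > D_max) stop("D_min must not exceed D_max", call. = FALSE)
  structure(list(H_base = H_base, L_internode = L_internode,
                 theta_internode = theta_internode,
                 D_max = D_max, D_min = D_min, ...), class = "internode_params")
}

#' @rdname organ_params
#' @export
appendage_params <- function(D_node_max = 0, L_ear = 0, D_ear_max = 0, ...) {
  if (D_node_max < 0 || L_ear < 0 || D_ear_max < 0)
    stop("appendage parameters must be >= 0", call. = FALSE)
  structure(list(D_node_max = D_node_max, L_ear = L_ear, D_ear_max = D_ear_max, ...),
            class = "appendage_params")
}

## ---- identity and naming ---------------------------------------------------

#' Phytomer identifier
#'
#' Identifies phytomer k on tiller j of plant i. Ranks count k = 1 at the base
#' and k = n at the top (spike-bearing) unit; naming enumerates top-down.
#'
#' @param plant,tiller,rank positive integers.
#' @return an object of class `phytomer_id`.
#' @export
phytomer_id <- function(plant, tiller, rank) {
  v <- c(plant = plant, tiller = tiller, rank = rank)
  if (any(v != round(v)) || any(v < 1)) stop("plant, tiller, rank must be positive integers", call. = FALSE)
  structure(list(plant = as.integer(plant), tiller = as.integer(tiller),
                 rank = as.integer(rank)), class = "phytomer_id")
}

#' @export
format.phytomer_id <- function(x, ...) sprintf("Phytomer%d,%d,%d", x$plant, x$tiller, x$rank)

#' @export
print.phytomer_id <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Name the phytomers of one stem, top to bottom
#'
#' Phytomers of a single stem are named from top to bottom: a stem of n
#' phytomers on tiller j of plant i yields ids with ranks n, n-1, ..., 1.
#'
#' @param plant_i,tiller_j positive integers identifying the stem.
#' @param n number of phytomers on the stem (>= 1).
#' @return list of `phytomer_id`, ordered top-down.
#' @export
#' @examples
#' sapply(name_phytomers(1, 1, 4), format)
name_phytomers <- function(plant_i, tiller_j, n) {
  if (length(n) != 1 || n != round(n) || n < 1)
    stop("invalid phytomer count: n must be a positive integer", call. = FALSE)
  lapply(seq(n, 1), function(k) phytomer_id(plant_i, tiller_j, k))
}

#' Classify a phytomer by its position on the stem
#'
#' The three kinds are spike-bearing (top unit carrying the ear), basal
#' (rank 1, which sets the growth direction of the stem), and middle.
#' A top unit without an ear (vegetative tiller) is legal and classified
#' `"middle"` with a warning.
#'
#' @param rank_k rank of the phytomer, 1 = basal.
#' @param n total phytomers on the stem.
#' @param has_ear does the top unit carry an ear?
#' @return one of `"spike-bearing"`, `"middle"`, `"basal"`.
#' @export
classify_phytomer <- function(rank_k, n, has_ear) {
  if (rank_k < 1 || rank_k > n) stop("rank out of range 1..n", call. = FALSE)
  if (rank_k == n) {
    if (has_ear) return("spike-bearing")
    if (n > 1) {
      warning("top phytomer without an ear; classified as middle", call. = FALSE)
      return("middle")
    }
    return("basal")  # one-phytomer vegetative stem: the basal rule wins
  }
  if (rank_k == 1) return("basal")
  "middle"
}

## ---- the phytomer ----------------------------------------------------------

# One organ component of a phytomer. `widths` (leaf only) stores the
# left-to-right blade width at each digitized row; widths are rigid-motion
# invariant so they survive assembly untouched.
organ_component <- function(mesh = NULL, skeleton = NULL, params = NULL, widths = NULL) {
  if (!is.null(mesh)) stopifnot(inherits(mesh, "mesh_model"))
  if (!is.null(skeleton)) stopifnot(inherits(skeleton, "skeleton_model"))
  structure(list(mesh = mesh, skeleton = skeleton, params = params, widths = widths),
            class = "organ_component")
}

#' Construct a phytomer
#'
#' Bundles the per-organ (mesh, skeleton, params) triples of one phytomer.
#' The internode component is mandatory and must carry a skeleton with at
#' least two points (its mid-axis); leaf, sheath and appendage are optional.
#'
#' @param id a [phytomer_id()].
#' @param n_stem total number of phytomers on the parent stem (used to derive
#'   the kind); defaults to the id's rank.
#' @param internode,leaf,sheath,appendage organ components created with
#'   `organ_component()` (internal) or assembled by the I/O layer.
#' @param kind override the derived kind; normally left `NULL`.
#' @return an object of class `phytomer`.
#' @export
phytomer <- function(id, internode, leaf = NULL, sheath = NULL, appendage = NULL,
                     n_stem = id$rank, kind = NULL) {
  stopifnot(inherits(id, "phytomer_id"))
  if (is.null(internode) || is.null(internode$skeleton))
    stop("internode component with a skeleton is mandatory", call. = FALSE)
  has_ear <- !is.null(appendage) && !is.null(appendage$params) &&
    isTRUE(appendage$params$L_ear > 0)
  if (is.null(kind)) kind <- classify_phytomer(id$rank, n_stem, has_ear)
  if (identical(kind, "spike-bearing") && !has_ear)
    stop("spike-bearing phytomer requires an appendage with L_ear > 0", call. = FALSE)
  structure(list(id = id, kind = kind, n_stem = as.integer(n_stem),
                 internode = internode, leaf = leaf, sheath = sheath,
                 appendage = appendage),
            class = "phytomer")
}

#' @export
print.phytomer <- function(x, ...) {
  organs <- c("internode", "leaf", "sheath", "appendage")
  have <- organs[!vapply(x[organs], is.null, logical(1))]
  cat(sprintf("<%s [%s]: %s>\n", format(x$id), x$kind, paste(have, collapse = ", ")))
  invisible(x)
}

.phytomer_organs <- c("leaf", "sheath", "internode", "appendage")

#' Leaf azimuth of a phytomer
#'
#' The azimuth is the direction, in the horizontal plane, in which the leaf
#' initially points: the angle in [0, 360) of the XY projection of the first
#' non-degenerate vein segment, measured counter-clockwise from +x.
#'
#' @param p a `phytomer` whose leaf carries a vein skeleton.
#' @return azimuth in degrees, [0, 360).
#' @export
azimuth_of <- function(p) {
  stopifnot(inherits(p, "phytomer"))
  if (is.null(p$leaf) || is.null(p$leaf$skeleton))
    stop("phytomer has no leaf vein; azimuth undefined", call. = FALSE)
  poly <- p$leaf$skeleton$polyline
  base <- poly[1, ]
  for (i in 2:nrow(poly)) {
    dxy <- poly[i, 1:2] - base[1:2]
    if (vnorm(c(dxy, 0)) > 1e-9)
      return((rad2deg(atan2(dxy[2], dxy[1]))) %% 360)
  }
  stop("vein is vertical everywhere; azimuth undefined", call. = FALSE)
}

# Apply f(points_matrix) -> points_matrix to every mesh and skeleton of p.
map_phytomer_points <- function(p, f) {
  for (org in .phytomer_organs) {
    comp <- p[[org]]
    if (is.null(comp)) next
    if (!is.null(comp$mesh))
      comp$mesh <- mesh_model(f(comp$mesh$vertices), comp$mesh$faces)
    if (!is.null(comp$skeleton))
      comp$skeleton <- skeleton_model(f(comp$skeleton$polyline))
    p[[org]] <- comp
  }
  p
}

#' Normalize a phytomer into its canonical template pose
#'
#' Rigidly moves the phytomer so that the internode base sits at the origin,
#' the internode axis points along +z, and the leaf azimuth is zero; all
#' meshes and skeletons are carried by the same rigid motion and the stored
#' parameters are updated (`H_base = 0`, `alpha_leaf = 0`). The operation is
#' idempotent. Alignment order: translate base to origin, minimal rotation of
#' the internode axis onto +z, then rotation about z to zero azimuth.
#'
#' @param p a `phytomer` with an internode skeleton of >= 2 points.
#' @return the normalized `phytomer`.
#' @export
normalize_phytomer <- function(p) {
  stopifnot(inherits(p, "phytomer"))
  poly <- p$internode$skeleton$polyline
  base <- poly[1, ]
  axis <- poly[nrow(poly), ] - base
  if (vnorm(axis) < 1e-9) stop("degenerate internode axis", call. = FALSE)
  R1 <- rotation_between(axis, c(0, 0, 1))
  p <- map_phytomer_points(p, function(v) t(R1 %*% (t(v) - base)))
  if (!is.null(p$leaf) && !is.null(p$leaf$skeleton)) {
    az <- azimuth_of(p)
    R2 <- rotation_z_matrix(-az)
    p <- map_phytomer_points(p, function(v) t(R2 %*% t(v)))
  }
  if (!is.null(p$internode$params)) p$internode$params$H_base <- 0
  if (!is.null(p$leaf) && !is.null(p$leaf$params)) {
    p$leaf$params$alpha_leaf <- 0
    p$leaf$params$H_base <- p$leaf$skeleton$polyline[1, 3]
  }
  if (!is.null(p$sheath) && !is.null(p$sheath$params)) p$sheath$params$H_base <- 0
  p
}
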