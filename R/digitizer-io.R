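# Contact-digitizer point convention and its on-disk dialect.
#
# A digitized leaf is a sequence of rows, each row three probe touches
# (left edge, vein, right edge), closed by a single tip point: 3n + 1 points
# for n rows. The vein skeleton is a separate polyline ending at the leaf
# tip apex. Stem thickness comes from three girth points wrapped around each
# node; internode lengths come from consecutive node points.
#
# File dialect (this package's own; the acquisition convention prescribes the
# gestures, not a format): one CSV per plant, UTF-8, mandatory header,
# columns tiller, phytomer_rank, organ in {leaf, vein, stem, ear},
# row_index, point_role in {left, vein, right, tip, node, girth1..girth3, ear},
# x, y, z (cm). Stem rows use phytomer_rank 0 and row_index = node number.
# A JSON sidecar (<file>.json) carries plant id and units.

#' Digitized leaf surface trace (3n + 1 convention)
#'
#' @param left,vein,right numeric n x 3 matrices, one row per digitized row,
#'   ordered base to tip.
#' @param tip numeric length-3 vector, the leaf tip apex.
#' @return object of class `leaf_surface_trace`. `$widths` holds the
#'   left-to-right distance of each row.
#' @export
leaf_surface_trace <- function(left, vein, right, tip) {
  left <- as_points(left); vein <- as_points(vein); right <- as_points(right)
  tip <- as.numeric(tip)
  if (nrow(left) < 1 || nrow(left) != nrow(vein) || nrow(vein) != nrow(right))
    stop("left/vein/right must have the same (>=1) number of rows", call. = FALSE)
  if (length(tip) != 3 || !all(is.finite(tip))) stop("tip must be a finite 3-vector", call. = FALSE)
  widths <- sqrt(rowSums((left - right)^2))
  structure(list(left = left, vein = vein, right = right, tip = tip,
                 n_rows = nrow(left), widths = widths),
            class = "leaf_surface_trace")
}

#' Digitized vein skeleton trace
#'
#' @param polyline numeric matrix (>= 2 points), base to tip apex.
#' @param surface optional matching [leaf_surface_trace()]; when given, the
#'   polyline end must coincide with the surface tip within `tip_tol` cm
#'   (warning above).
#' @param tip_tol coincidence tolerance, cm.
#' @return object of class `vein_trace`.
#' @export
vein_trace <- function(polyline, surface = NULL, tip_tol = 0.2) {
  s <- skeleton_model(polyline)
  if (!is.null(surface)) {
    gap <- vnorm(s$polyline[nrow(s$polyline), ] - surface$tip)
    if (gap > tip_tol)
      warning(sprintf("vein end is %.2f cm from the surface tip (tolerance %.2f cm)",
                      gap, tip_tol), call. = FALSE)
  }
  structure(list(polyline = s$polyline), class = c("vein_trace", "skeleton_model"))
}

#' Digitized stem trace: node points plus girth triples
#'
#' @param nodes numeric matrix of node points, base to top (>= 2 nodes).
#' @param girths list of 3 x 3 matrices (three girth points per node); may be
#'   `NULL` entries where girth was not digitized.
#' @return object of class `stem_trace`.
#' @export
stem_trace <- function(nodes, girths = NULL) {
  nodes <- as_points(nodes)
  if (nrow(nodes) < 2) stop("stem needs at least 2 nodes (1 internode)", call. = FALSE)
  if (is.null(girths)) girths <- vector("list", nrow(nodes))
  stopifnot(length(girths) == nrow(nodes))
  for (g in girths) if (!is.null(g) && (nrow(as_points(g)) != 3))
    stop("each girth must be a triple of points", call. = FALSE)
  structure(list(nodes = nodes, girths = girths), class = "stem_trace")
}

#' A fully digitized plant
#'
#' @param plant integer plant id.
#' @param tillers list; each tiller is a list with `stem` (a [stem_trace()]),
#'   `leaves` (list of `list(surface =, vein =)`, one per phytomer, base to
#'   top) and optional `ear` (`list(polyline =, girth =)`).
#' @return object of class `digitized_plant`.
#' @export
digitized_plant <- function(plant, tillers) {
  if (length(tillers) < 1) stop("plant needs at least one tiller", call. = FALSE)
  for (ti in seq_along(tillers)) {
    tl <- tillers[[ti]]
    stopifnot(inherits(tl$stem, "stem_trace"))
    n_int <- nrow(tl$stem$nodes) - 1
    if (length(tl$leaves) != n_int)
      stop(sprintf("tiller %d: %d leaves but %d internodes", ti, length(tl$leaves), n_int),
           call. = FALSE)
  }
  structure(list(plant = as.integer(plant), tillers = tillers), class = "digitized_plant")
}

#' @export
print.digitized_plant <- function(x, ...) {
  cat(sprintf("<digitized_plant %d: %d tillers, %s phytomers/tiller>\n", x$plant,
              length(x$tillers),
              paste(vapply(x$tillers, function(t) nrow(t$stem$nodes) - 1L, integer(1)),
                    collapse = ",")))
  invisible(x)
}

## ---- derived stem geometry -------------------------------------------------

#' Circumcircle diameter of a girth triple
#'
#' Stem thickness at a node is digitized as three probe touches around the
#' stem; the node diameter is the diameter of the circle through them
#' (computed in the plane of the triple: d = abc / (2 * area)).
#'
#' @param girth 3 x 3 matrix of points.
#' @return diameter in cm.
#' @export
node_diameter <- function(girth) {
  g <- as_points(girth)
  if (nrow(g) != 3) stop("girth must be exactly three points", call. = FALSE)
  a <- vnorm(g[2, ] - g[3, ]); b <- vnorm(g[1, ] - g[3, ]); c_ <- vnorm(g[1, ] - g[2, ])
  area <- triangle_area3(g[1, ], g[2, ], g[3, ])
  if (area < 1e-10 * max(a, b, c_)^2 || area == 0)
    stop("girth points are collinear; circumcircle undefined", call. = FALSE)
  a * b * c_ / (2 * area)
}

#' Internode lengths of a stem
#'
#' Euclidean distances between consecutive node points, base to top.
#'
#' @param s a [stem_trace()] or an `assembled_stem`.
#' @return numeric vector of length (number of nodes - 1).
#' @export
internode_lengths <- function(s) UseMethod("internode_lengths")

#' @export
internode_lengths.stem_trace <- function(s) {
  n <- s$nodes
  sqrt(rowSums((n[-1, , drop = FALSE] - n[-nrow(n), , drop = FALSE])^2))
}

#' @export
internode_lengths.assembled_stem <- function(s) {
  ks <- sort(unique(vapply(Filter(function(c) c$organ == "internode", s$components),
                           `[[`, integer(1), "rank")))
  vapply(ks, function(k) {
    comp <- Filter(function(c) c$organ == "internode" && c$rank == k, s$components)[[1]]
    skeleton_length(comp$skeleton)
  }, numeric(1))
}

## ---- leaf meshing ----------------------------------------------------------

#' Triangulate a digitized leaf surface
#'
#' Builds the blade mesh from the 3n + 1 trace: vertices are the rows' left,
#' vein and right points (in that order, base to top) followed by the tip.
#' Between consecutive rows the left-vein and vein-right quads are split into
#' two triangles each (diagonal toward the tip); a two-triangle fan closes
#' the tip. Hence 3n + 1 vertices and 4(n - 1) + 2 faces, all referenced.
#'
#' @param t a [leaf_surface_trace()].
#' @return a `mesh_model`.
#' @export
leaf_mesh_from_trace <- function(t) {
  stopifnot(inherits(t, "leaf_surface_trace"))
  n <- t$n_rows
  verts <- matrix(0, 3 * n + 1, 3)
  for (i in seq_len(n)) {
    verts[3 * i - 2, ] <- t$left[i, ]
    verts[3 * i - 1, ] <- t$vein[i, ]
    verts[3 * i, ]     <- t$right[i, ]
  }
  verts[3 * n + 1, ] <- t$tip
  L <- function(i) 3L * i - 2L; V <- function(i) 3L * i - 1L; R <- function(i) 3L * i
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n - 1)) {
    faces <- rbind(faces,
                   c(L(i), V(i), V(i + 1)), c(L(i), V(i + 1), L(i + 1)),
                   c(V(i), R(i), R(i + 1)), c(V(i), R(i + 1), V(i + 1)))
  }
  tip <- 3L * n + 1L
  faces <- rbind(faces, c(L(n), V(n), tip), c(V(n), R(n), tip))
  m <- mesh_model(verts, faces)
  areas <- apply(m$faces, 1, function(f)
    triangle_area3(m$vertices[f[1], ], m$vertices[f[2], ], m$vertices[f[3], ]))
  if (any(areas < 1e-10))
    stop("degenerate leaf geometry: coincident row points give zero-area triangles",
         call. = FALSE)
  m
}

## ---- CSV dialect -----------------------------------------------------------

.dig_header <- c("tiller", "phytomer_rank", "organ", "row_index", "point_role",
                 "x", "y", "z")

dig_rows <- function(tiller, rank, organ, row_index, role, pts) {
  pts <- as_points(pts)
  data.frame(tiller = tiller, phytomer_rank = rank, organ = organ,
             row_index = row_index, point_role = role,
             x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Write a digitized plant to the CSV dialect
#'
#' Emits one CSV (see the header of this file for the column dialect) plus a
#' JSON sidecar `<path>.json` with plant id and units.
#'
#' @param dp a [digitized_plant()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_digitized_plant <- function(dp, path) {
  stopifnot(inherits(dp, "digitized_plant"))
  out <- list()
  for (j in seq_along(dp$tillers)) {
    tl <- dp$tillers[[j]]
    nd <- tl$stem$nodes
    out[[length(out) + 1]] <- dig_rows(j, 0L, "stem", seq_len(nrow(nd)), "node", nd)
    for (ni in seq_len(nrow(nd))) {
      g <- tl$stem$girths[[ni]]
      if (!is.null(g))
        out[[length(out) + 1]] <- dig_rows(j, 0L, "stem", ni, paste0("girth", 1:3), g)
    }
    for (k in seq_along(tl$leaves)) {
      lf <- tl$leaves[[k]]
      s <- lf$surface
      for (ri in seq_len(s$n_rows))
        out[[length(out) + 1]] <- dig_rows(j, k, "leaf", ri, c("left", "vein", "right"),
                                           rbind(s$left[ri, ], s$vein[ri, ], s$right[ri, ]))
      out[[length(out) + 1]] <- dig_rows(j, k, "leaf", s$n_rows + 1L, "tip",
                                         matrix(s$tip, 1))
      out[[length(out) + 1]] <- dig_rows(j, k, "vein", seq_len(nrow(lf$vein$polyline)),
                                         "vein", lf$vein$polyline)
    }
    if (!is.null(tl$ear)) {
      out[[length(out) + 1]] <- dig_rows(j, length(tl$leaves), "ear",
                                         seq_len(nrow(as_points(tl$ear$polyline))),
                                         "ear", tl$ear$polyline)
      if (!is.null(tl$ear$girth))
        out[[length(out) + 1]] <- dig_rows(j, length(tl$leaves), "ear", 0L,
                                           paste0("girth", 1:3), tl$ear$girth)
    }
  }
  df <- do.call(rbind, out)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(plant = dp$plant, units = "cm", dialect = "phytomer3d-digitizer-1"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a digitized plant from the CSV dialect
#'
#' Validates the 3n + 1 leaf convention (point count, tip presence), row
#' monotonicity along the vein arc, and stem/leaf count consistency.
#'
#' @param path CSV path written by [write_digitized_plant()] (or produced by
#'   the synthetic generator).
#' @return a [digitized_plant()].
#' @export
read_digitized_plant <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.dig_header %in% names(df)))
    stop(sprintf("format error: missing columns %s",
                 paste(setdiff(.dig_header, names(df)), collapse = ", ")), call. = FALSE)
  side <- paste0(path, ".json")
  plant_id <- 1L
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$plant)) plant_id <- as.integer(meta$plant)
  }
  tillers <- list()
  for (j in sort(unique(df$tiller))) {
    dj <- df[df$tiller == j, , drop = FALSE]
    stem <- dj[dj$organ == "stem", , drop = FALSE]
    node_rows <- stem[stem$point_role == "node", , drop = FALSE]
    node_rows <- node_rows[order(node_rows$row_index), , drop = FALSE]
    if (nrow(node_rows) < 2)
      stop(sprintf("format error: tiller %d has fewer than 2 stem nodes", j), call. = FALSE)
    girths <- vector("list", nrow(node_rows))
    for (ni in seq_len(nrow(node_rows))) {
      g <- stem[stem$row_index == node_rows$row_index[ni] &
                  grepl("^girth", stem$point_role), , drop = FALSE]
      if (nrow(g) == 3) girths[[ni]] <- as.matrix(g[order(g$point_role), c("x", "y", "z")])
    }
    st <- stem_trace(as.matrix(node_rows[, c("x", "y", "z")]), girths)
    ranks <- sort(unique(dj$phytomer_rank[dj$organ %in% c("leaf", "vein")]))
    leaves <- list()
    for (k in ranks) {
      lf <- dj[dj$organ == "leaf" & dj$phytomer_rank == k, , drop = FALSE]
      if (nrow(lf) %% 3 != 1)
        stop(sprintf("format error: leaf (tiller %d, rank %d) has %d points; expected 3n+1",
                     j, k, nrow(lf)), call. = FALSE)
      tip_row <- lf[lf$point_role == "tip", , drop = FALSE]
      if (nrow(tip_row) != 1)
        stop(sprintf("format error: leaf (tiller %d, rank %d) is missing its tip point",
                     j, k), call. = FALSE)
      body <- lf[lf$point_role != "tip", , drop = FALSE]
      body <- body[order(body$row_index), , drop = FALSE]
      pick <- function(role) as.matrix(body[body$point_role == role, c("x", "y", "z")])
      surf <- leaf_surface_trace(pick("left"), pick("vein"), pick("right"),
                                 as.numeric(tip_row[1, c("x", "y", "z")]))
      vn <- dj[dj$organ == "vein" & dj$phytomer_rank == k, , drop = FALSE]
      vn <- vn[order(vn$row_index), , drop = FALSE]
      vt <- vein_trace(as.matrix(vn[, c("x", "y", "z")]), surface = surf)
      spos <- vapply(seq_len(surf$n_rows),
                     function(i) arc_position(surf$vein[i, ], vt$polyline), numeric(1))
      if (any(diff(spos) <= 0))
        stop(sprintf("format error: leaf rows (tiller %d, rank %d) do not advance along the vein",
                     j, k), call. = FALSE)
      leaves[[length(leaves) + 1]] <- list(surface = surf, vein = vt)
    }
    ear <- NULL
    er <- dj[dj$organ == "ear", , drop = FALSE]
    if (nrow(er) > 0) {
      poly <- er[er$point_role == "ear", , drop = FALSE]
      poly <- poly[order(poly$row_index), , drop = FALSE]
      g <- er[grepl("^girth", er$point_role), , drop = FALSE]
      ear <- list(polyline = as.matrix(poly[, c("x", "y", "z")]),
                  girth = if (nrow(g) == 3) as.matrix(g[order(g$point_role), c("x", "y", "z")]) else NULL)
    }
    tillers[[length(tillers) + 1]] <- list(stem = st, leaves = leaves, ear = ear)
  }
  digitized_plant(plant_id, tillers)
}

## ---- digitized plant -> measurable geometry --------------------------------

#' Build measurable shoot geometry from a digitized plant
#'
#' Converts raw digitizer traces into the same labeled-component structure
#' that template assembly produces, so that every trait extractor runs
#' unchanged on digitized and assembled plants: per phytomer an internode
#' skeleton (the node-to-node segment), a leaf mesh + vein skeleton with row
#' widths, and on the top unit the ear polyline as the appendage.
#'
#' @param dp a [digitized_plant()].
#' @return an `assembled_shoot`.
#' @export
shoot_from_digitized <- function(dp) {
  stopifnot(inherits(dp, "digitized_plant"))
  stems <- list()
  for (j in seq_along(dp$tillers)) {
    tl <- dp$tillers[[j]]
    nd <- tl$stem$nodes
    n <- nrow(nd) - 1
    comps <- list()
    for (k in seq_len(n)) {
      dmax <- NA_real_
      g1 <- tl$stem$girths[[k]]; g2 <- tl$stem$girths[[k + 1]]
      ds <- c(if (!is.null(g1)) node_diameter(g1), if (!is.null(g2)) node_diameter(g2))
      ip <- internode_params(H_base = nd[k, 3], L_internode = vnorm(nd[k + 1, ] - nd[k, ]),
                             D_max = if (length(ds)) max(ds) else 0,
                             D_min = if (length(ds)) min(ds) else 0)
      comps[[length(comps) + 1]] <- assembled_component(
        dp$plant, j, k, "internode",
        organ_component(skeleton = skeleton_model(nd[k:(k + 1), , drop = FALSE]),
                        params = ip))
      lf <- tl$leaves[[k]]
      comps[[length(comps) + 1]] <- assembled_component(
        dp$plant, j, k, "leaf",
        organ_component(mesh = leaf_mesh_from_trace(lf$surface),
                        skeleton = skeleton_model(lf$vein$polyline),
                        params = leaf_params(H_base = lf$vein$polyline[1, 3],
                                             L_leaf = polyline_length(lf$vein$polyline)),
                        widths = lf$surface$widths))
    }
    if (!is.null(tl$ear)) {
      ap <- appendage_params(L_ear = polyline_length(tl$ear$polyline),
                             D_ear_max = if (!is.null(tl$ear$girth)) node_diameter(tl$ear$girth) else 0)
      comps[[length(comps) + 1]] <- assembled_component(
        dp$plant, j, n, "appendage",
        organ_component(mesh = ear_mesh(tl$ear$polyline, tl$ear$girth),
                        skeleton = skeleton_model(tl$ear$polyline), params = ap))
    }
    stems[[length(stems) + 1]] <- structure(
      list(plant = dp$plant, tiller = j, n = n, components = comps),
      class = "assembled_stem")
  }
  structure(list(plant = dp$plant, stems = stems), class = "assembled_shoot")
}

# Bipyramid proxy mesh for a digitized ear: the girth triple as the waist,
# apexes at the ear base and tip. Gives the spike layer a real footprint.
ear_mesh <- function(polyline, girth) {
  if (is.null(girth)) return(NULL)
  poly <- as_points(polyline)
  g <- as_points(girth)
  v <- rbind(g, poly[1, ], poly[nrow(poly), ])
  f <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 1, 5),
             c(1, 2, 4), c(2, 3, 4), c(3, 1, 4))
  mesh_model(v, f)
}

#' Build normalized phytomer templates from a digitized plant
#'
#' Splits each tiller into its phytomers and normalizes each into canonical
#' template pose, ready for database ingestion or re-assembly.
#'
#' @param dp a [digitized_plant()].
#' @return list of normalized `phytomer` objects, named by their formatted id.
#' @export
phytomers_from_digitized <- function(dp) {
  shoot <- shoot_from_digitized(dp)
  out <- list()
  for (stem in shoot$stems) {
    n <- stem$n
    for (k in seq_len(n)) {
      comps <- Filter(function(c) c$rank == k, stem$components)
      get_org <- function(org) {
        hit <- Filter(function(c) c$organ == org, comps)
        if (length(hit) == 0) return(NULL)
        c0 <- hit[[1]]
        organ_component(mesh = c0$mesh, skeleton = c0$skeleton,
                        params = c0$params, widths = c0$widths)
      }
      ph <- phytomer(phytomer_id(dp$plant, stem$tiller, k),
                     internode = get_org("internode"), leaf = get_org("leaf"),
                     appendage = get_org("appendage"), n_stem = n)
      ph <- normalize_phytomer(ph)
      out[[format(ph$id)]] <- ph
    }
  }
  out
}
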