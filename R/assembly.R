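# Assembly algebra: compose normalized phytomer templates into tillers
# (vertical-axis rotation + vertical translation per phytomer) and tillers
# into whole shoots (general rigid motion per tiller). Every vertex of an
# assembled model keeps (tiller, rank, organ) provenance.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det = +1).
#' @param translation numeric length-3 vector (cm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with det = +1", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n"); print(x$rotation)
  cat("t =", format(x$translation), "\n"); invisible(x)
}

#' Rotation about the vertical axis
#'
#' @param alpha azimuth in degrees, counter-clockwise about +z.
#' @return a `rigid_transform` with zero translation.
#' @export
rotation_about_vertical <- function(alpha) {
  if (!is.finite(alpha)) stop("alpha must be finite", call. = FALSE)
  rigid_transform(rotation_z_matrix(alpha), c(0, 0, 0))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`:
#' x -> Ra (Rb x + tb) + ta.
#'
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation))
}

#' Apply a rigid transform to geometry
#'
#' Maps every point v to `R v + t`. Methods exist for point matrices, meshes,
#' skeletons, phytomers, and assembled stems/shoots; faces, widths and
#' provenance labels are untouched.
#'
#' @param x geometry to transform.
#' @param t a `rigid_transform`.
#' @return the transformed object, same class as `x`.
#' @export
apply_transform <- function(x, t) UseMethod("apply_transform")

transform_points <- function(v, t) t(t$rotation %*% t(as_points(v))) +
  matrix(t$translation, nrow(as_points(v)), 3, byrow = TRUE)

#' @export
apply_transform.matrix <- function(x, t) transform_points(x, t)

#' @export
apply_transform.mesh_model <- function(x, t) mesh_model(transform_points(x$vertices, t), x$faces)

#' @export
apply_transform.skeleton_model <- function(x, t) skeleton_model(transform_points(x$polyline, t))

#' @export
apply_transform.phytomer <- function(x, t) map_phytomer_points(x, function(v) transform_points(v, t))

#' @export
apply_transform.assembled_stem <- function(x, t) {
  x$components <- lapply(x$components, transform_component, t = t)
  x
}

#' @export
apply_transform.assembled_shoot <- function(x, t) {
  x$stems <- lapply(x$stems, apply_transform, t = t)
  x
}

transform_component <- function(comp, t) {
  if (!is.null(comp$mesh)) comp$mesh <- apply_transform(comp$mesh, t)
  if (!is.null(comp$skeleton)) comp$skeleton <- apply_transform(comp$skeleton, t)
  comp
}

## ---- specs -----------------------------------------------------------------

#' Tiller assembly specification
#'
#' Orders phytomer templates base to top. Each entry names a template, the
#' azimuth at which its leaf should point, and the base height of its
#' internode: a number (cm) or `NA` for "stacked" (base of unit k sits on the
#' top node of unit k-1).
#'
#' @param plant,tiller identifiers (positive integers).
#' @param templates character vector of template references, base to top.
#' @param azimuths numeric vector of leaf azimuths (degrees), recycled.
#' @param heights numeric vector of base heights (cm) or `NA` for stacked
#'   (the default).
#' @return an object of class `tiller_spec`.
#' @export
tiller_spec <- function(plant, tiller, templates, azimuths = 0, heights = NA_real_) {
  if (length(templates) < 1) stop("tiller needs at least one phytomer", call. = FALSE)
  n <- length(templates)
  azimuths <- rep_len(azimuths, n)
  heights <- rep_len(as.numeric(heights), n)
  hx <- heights[!is.na(heights)]
  if (length(hx) > 1 && any(diff(hx) < 0))
    stop("explicit base heights must be non-decreasing", call. = FALSE)
  structure(list(plant = as.integer(plant), tiller = as.integer(tiller),
                 templates = as.character(templates),
                 azimuths = azimuths, heights = heights),
            class = "tiller_spec")
}

#' Shoot assembly specification
#'
#' @param plant plant identifier.
#' @param tillers list of `tiller_spec`.
#' @param transforms list of `rigid_transform`, one per tiller (defaults to
#'   identities).
#' @return an object of class `shoot_spec`.
#' @export
shoot_spec <- function(plant, tillers, transforms = NULL) {
  if (length(tillers) < 1) stop("shoot needs at least one tiller", call. = FALSE)
  stopifnot(all(vapply(tillers, inherits, logical(1), "tiller_spec")))
  if (is.null(transforms)) transforms <- replicate(length(tillers), rigid_transform(), simplify = FALSE)
  stopifnot(length(transforms) == length(tillers),
            all(vapply(transforms, inherits, logical(1), "rigid_transform")))
  structure(list(plant = as.integer(plant), tillers = tillers, transforms = transforms),
            class = "shoot_spec")
}

# Resolve a template reference against a database (template_db) or a plain
# named list of phytomer objects.
resolve_template <- function(db, ref) {
  if (inherits(db, "template_db")) return(load_template(db, ref))
  if (is.list(db) && !is.null(db[[ref]])) return(db[[ref]])
  stop(sprintf("template '%s' not found in database", ref), call. = FALSE)
}

## ---- assembly --------------------------------------------------------------

# Labeled component of an assembled model.
assembled_component <- function(plant, tiller, rank, organ, comp) {
  structure(list(plant = as.integer(plant), tiller = as.integer(tiller),
                 rank = as.integer(rank), organ = organ,
                 mesh = comp$mesh, skeleton = comp$skeleton,
                 params = comp$params, widths = comp$widths),
            class = "assembled_component")
}

#' Assemble one tiller from normalized phytomer templates
#'
#' Each template is rotated about the vertical axis by its azimuth and raised
#' to its base height. In stacked mode (height `NA`) the base height of unit k
#' is the sum of the internode lengths of the units below, so consecutive
#' phytomers join node to node.
#'
#' @param spec a [tiller_spec()].
#' @param db a `template_db` or a named list of normalized `phytomer` objects.
#' @return an object of class `assembled_stem`, whose `components` carry
#'   (tiller, rank, organ) provenance.
#' @export
assemble_tiller <- function(spec, db) {
  stopifnot(inherits(spec, "tiller_spec"))
  n <- length(spec$templates)
  comps <- list()
  z <- 0
  for (k in seq_len(n)) {
    tpl <- resolve_template(db, spec$templates[k])
    stopifnot(inherits(tpl, "phytomer"))
    H <- if (is.na(spec$heights[k])) z else spec$heights[k]
    tf <- compose_transforms(
      rigid_transform(diag(3), c(0, 0, H)),
      rotation_about_vertical(spec$azimuths[k]))
    L_int <- skeleton_length(tpl$internode$skeleton)
    for (org in .phytomer_organs) {
      comp <- tpl[[org]]
      if (is.null(comp)) next
      comps[[length(comps) + 1]] <-
        assembled_component(spec$plant, spec$tiller, k, org, transform_component(comp, tf))
    }
    z <- H + L_int
  }
  structure(list(plant = spec$plant, tiller = spec$tiller, n = n, components = comps),
            class = "assembled_stem")
}

#' Assemble a whole shoot from tillers
#'
#' Unions the per-tiller assemblies, each mapped by its own rigid transform
#' (tillers may lean; the per-tiller transform is a general rigid motion).
#'
#' @param spec a [shoot_spec()].
#' @param db template database or named list of `phytomer` templates.
#' @return an object of class `assembled_shoot`.
#' @export
assemble_shoot <- function(spec, db) {
  stopifnot(inherits(spec, "shoot_spec"))
  stems <- mapply(function(ts, tf) apply_transform(assemble_tiller(ts, db), tf),
                  spec$tillers, spec$transforms, SIMPLIFY = FALSE)
  structure(list(plant = spec$plant, stems = stems), class = "assembled_shoot")
}

#' @export
print.assembled_stem <- function(x, ...) {
  cat(sprintf("<assembled_stem plant %d tiller %d: %d phytomers, %d components>\n",
              x$plant, x$tiller, x$n, length(x$components)))
  invisible(x)
}

#' @export
print.assembled_shoot <- function(x, ...) {
  cat(sprintf("<assembled_shoot plant %d: %d tillers>\n", x$plant, length(x$stems)))
  invisible(x)
}

# All vertices of a stem/shoot (mesh vertices + skeleton points), optionally
# restricted to one organ; returns an n x 3 matrix (possibly 0-row).
component_points <- function(comp) {
  pts <- NULL
  if (!is.null(comp$mesh)) pts <- comp$mesh$vertices
  if (!is.null(comp$skeleton)) pts <- rbind(pts, comp$skeleton$polyline)
  pts
}

shoot_points <- function(x, organ = NULL) {
  comps <- if (inherits(x, "assembled_shoot")) {
    unlist(lapply(x$stems, `[[`, "components"), recursive = FALSE)
  } else x$components
  out <- matrix(numeric(0), 0, 3)
  for (comp in comps) {
    if (!is.null(organ) && comp$organ != organ) next
    pts <- component_points(comp)
    if (!is.null(pts)) out <- rbind(out, pts)
  }
  out
}

## ---- template selection ----------------------------------------------------

#' Select the most similar template
#'
#' Nearest-neighbour search over the morphological parameters shared by the
#' query and every template, using Euclidean distance on z-scored values
#' (mean/sd taken over the templates). Zero-variance parameters are dropped
#' from scoring with a warning; exact ties resolve to the earliest database
#' entry.
#'
#' @param query named numeric vector of morphological parameters.
#' @param db a `template_db`, or a list whose entries have a `$params` named
#'   numeric vector.
#' @return the selected template reference (name / id).
#' @export
select_template_by_similarity <- function(query, db) {
  query <- unlist(query)
  recs <- template_param_table(db)
  if (length(recs$ids) == 0) stop("template database is empty", call. = FALSE)
  shared <- Reduce(intersect, c(list(names(query)), lapply(recs$params, names)))
  if (length(shared) == 0) stop("query and templates share no parameters", call. = FALSE)
  X <- t(vapply(recs$params, function(p) unlist(p[shared]), numeric(length(shared))))
  colnames(X) <- shared
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (nrow(X) == 1) sdv[] <- 1          # single template: scaling is moot
  keep <- sdv > .EPS
  if (!all(keep)) {
    warning(sprintf("zero-variance parameter(s) dropped from similarity scoring: %s",
                    paste(shared[!keep], collapse = ", ")), call. = FALSE)
    if (!any(keep)) keep[] <- TRUE      # all constant: distances all equal, first wins
  }
  sdv[sdv <= .EPS] <- 1
  q <- (unlist(query[shared]) - mu) / sdv
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  d2 <- rowSums(sweep(Z[, keep, drop = FALSE], 2, q[keep])^2)
  recs$ids[which.min(d2)]
}

# Uniform view of the parameter vectors of a template source.
template_param_table <- function(db) {
  if (inherits(db, "template_db")) {
    ids <- vapply(db$records, `[[`, character(1), "id")
    params <- lapply(db$records, function(r) unlist(r$params))
  } else {
    ids <- names(db)
    params <- lapply(db, function(e) {
      p <- if (inherits(e, "phytomer")) phytomer_param_vector(e) else unlist(e$params)
      p
    })
  }
  list(ids = ids, params = params)
}

# Flatten the numeric morphological parameters of a phytomer into one named
# vector (used for similarity search and database records).
phytomer_param_vector <- function(p) {
  out <- c()
  for (org in .phytomer_organs) {
    comp <- p[[org]]
    if (is.null(comp)) next
    if (!is.null(comp$params)) {
      q <- unlist(Filter(function(v) is.numeric(v) && length(v) == 1, comp$params))
      if (length(q)) names(q) <- paste(org, names(q), sep = ".")
      out <- c(out, q)
    }
    if (!is.null(comp$skeleton))
      out[paste0(org, ".skeleton_length")] <- skeleton_length(comp$skeleton)
  }
  out
}
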