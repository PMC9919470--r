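# Minimal ASCII Wavefront OBJ I/O (v/f records, 1-based indices, `o` groups).
# Only the subset this package emits is supported on read.

#' Write meshes to an ASCII OBJ file
#'
#' @param meshes a single `mesh_model` or a named list of them; names become
#'   `o` object-group names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(meshes, path) {
  if (inherits(meshes, "mesh_model")) meshes <- list(mesh = meshes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# phytomer3d OBJ export", con)
  offset <- 0L
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    writeLines(sprintf("o %s", nm), con)
    writeLines(sprintf("v %.9g %.9g %.9g",
                       m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
    if (nrow(m$faces) > 0)
      writeLines(sprintf("f %d %d %d",
                         m$faces[, 1] + offset, m$faces[, 2] + offset, m$faces[, 3] + offset), con)
    offset <- offset + nrow(m$vertices)
  }
  invisible(path)
}

#' Read meshes from an ASCII OBJ file
#'
#' @param path OBJ file with v/f records and optional `o` groups.
#' @return named list of `mesh_model` (single unnamed group reads as
#'   `$mesh`).
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  verts <- matrix(numeric(0), 0, 3)
  groups <- list()
  cur_name <- "mesh"
  cur_faces <- matrix(integer(0), 0, 3)
  cur_start <- 0L
  flush_group <- function() {
    if (nrow(cur_faces) > 0 || nrow(verts) > cur_start) {
      vidx <- (cur_start + 1L):nrow(verts)
      f <- cur_faces - cur_start
      groups[[cur_name]] <<- mesh_model(verts[vidx, , drop = FALSE], f)
    }
  }
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "o") {
      flush_group()
      cur_name <- paste(tok[-1], collapse = "_")
      cur_faces <- matrix(integer(0), 0, 3)
      cur_start <- nrow(verts)
    } else if (tok[1] == "v") {
      verts <- rbind(verts, as.numeric(tok[2:4]))
    } else if (tok[1] == "f") {
      idx <- as.integer(sub("/.*", "", tok[2:4]))
      cur_faces <- rbind(cur_faces, idx)
    }
  }
  flush_group()
  groups
}

#' Export an assembled shoot as OBJ
#'
#' One object group per mesh-bearing component, named
#' `<plant>_<tiller>_<rank>_<organ>`; components without meshes contribute
#' their skeleton polylines as degenerate-free `l`-less vertex runs and are
#' skipped from face output.
#'
#' @param shoot an `assembled_shoot`.
#' @param path output OBJ path.
#' @return `path`, invisibly.
#' @export
write_shoot_obj <- function(shoot, path) {
  stopifnot(inherits(shoot, "assembled_shoot"))
  meshes <- list()
  for (stem in shoot$stems) {
    for (comp in stem$components) {
      nm <- sprintf("%d_%d_%d_%s", comp$plant, comp$tiller, comp$rank, comp$organ)
      if (!is.null(comp$mesh)) {
        meshes[[nm]] <- comp$mesh
      } else if (!is.null(comp$skeleton)) {
        # represent a bare skeleton as a zero-width triangle strip so the
        # component is still visible in mesh viewers
        poly <- comp$skeleton$polyline
        if (nrow(poly) >= 2) {
          eps <- 1e-4
          verts <- rbind(poly, poly + matrix(c(eps, 0, 0), nrow(poly), 3, byrow = TRUE))
          np <- nrow(poly)
          faces <- do.call(rbind, lapply(seq_len(np - 1), function(i)
            rbind(c(i, i + 1, np + i), c(i + 1, np + i + 1, np + i))))
          meshes[[nm]] <- mesh_model(verts, faces)
        }
      }
    }
  }
  write_obj(meshes, path)
}
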