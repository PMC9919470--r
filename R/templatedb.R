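# Phytomer template database: a directory holding index.json plus one OBJ
# (meshes) and one JSON (skeletons + parameters) file per template. All
# geometry is stored normalized (base at origin, axis vertical, azimuth 0);
# assembly re-applies transforms from specs.
#
# Each record carries four keyword groups mirroring the database schema:
#   agronomic keywords : phytomer type, variety, growth period, density,
#                        row spacing, stem order, free-text extras
#   model info         : file paths, model names, vertex and mesh counts
#                        (recomputed at ingest, never trusted from input)
#   morphological      : flattened numeric parameter vector (used by
#                        similarity search)
#   provenance         : record number, access time, entry person

.known_keywords <- c("phytomer_type", "variety", "growth_period", "ecological_point",
                     "density", "row_spacing", "water_fertilizer", "stem_order")

#' Open (or create) a phytomer template database
#'
#' @param dir database directory; created with an empty `index.json` if
#'   missing.
#' @return object of class `template_db`.
#' @export
template_db <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- file.path(dir, "index.json")
  records <- if (file.exists(idx)) {
    jsonlite::read_json(idx, simplifyVector = FALSE)
  } else list()
  structure(list(dir = dir, records = records), class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat(sprintf("<template_db at %s: %d records>\n", x$dir, length(x$records)))
  invisible(x)
}

save_index <- function(db) {
  jsonlite::write_json(db$records, file.path(db$dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  db
}

#' Ingest a phytomer into the template database
#'
#' Normalizes the phytomer, writes its meshes (one OBJ, one group per organ)
#' and skeletons/parameters (JSON), and appends an index record with
#' recomputed vertex/mesh counts. Ingesting the same phytomer twice yields
#' two records with distinct ids.
#'
#' @param db a [template_db()].
#' @param p a `phytomer` (normalized or not; normalization failure rejects
#'   the ingest).
#' @param keywords named list of agronomic keywords (see
#'   `phytomer3d:::.known_keywords`); unknown names are stored as free text.
#' @param entry_person provenance string.
#' @return the updated `template_db` (with `attr(,"last_id")` set).
#' @export
ingest_template <- function(db, p, keywords = list(), entry_person = "phytomer3d") {
  stopifnot(inherits(db, "template_db"), inherits(p, "phytomer"))
  p <- tryCatch(normalize_phytomer(p),
                error = function(e) stop(sprintf("ingest rejected: %s", conditionMessage(e)),
                                         call. = FALSE))
  id <- sprintf("T%04d", length(db$records) + 1L)
  meshes <- list(); skels <- list()
  for (org in .phytomer_organs) {
    comp <- p[[org]]
    if (is.null(comp)) next
    if (!is.null(comp$mesh)) meshes[[org]] <- comp$mesh
    if (!is.null(comp$skeleton)) skels[[org]] <- comp$skeleton$polyline
  }
  obj_path <- file.path(db$dir, paste0(id, ".obj"))
  json_path <- file.path(db$dir, paste0(id, ".json"))
  if (length(meshes)) write_obj(meshes, obj_path)
  payload <- list(
    id = id, kind = p$kind,
    plant = p$id$plant, tiller = p$id$tiller, rank = p$id$rank, n_stem = p$n_stem,
    skeletons = skels,
    params = lapply(Filter(Negate(is.null), p[.phytomer_organs]),
                    function(comp) if (is.null(comp$params)) NULL else unclass(comp$params)),
    widths = if (!is.null(p$leaf)) p$leaf$widths else NULL)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  kw <- keywords
  if (is.null(kw$phytomer_type))
    kw$phytomer_type <- switch(p$kind, "spike-bearing" = "phytomers with spike",
                               "middle" = "middle phytomers", "basal" = "first phytomer")
  rec <- list(
    id = id,
    keywords = kw,
    model_info = list(
      obj_path = basename(obj_path), json_path = basename(json_path),
      model_names = names(meshes),
      n_vertices = sum(vapply(meshes, function(m) nrow(m$vertices), integer(1))),
      n_meshes = length(meshes)),
    params = as.list(phytomer_param_vector(p)),
    provenance = list(number = length(db$records) + 1L,
                      access_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      entry_person = entry_person))
  db$records[[length(db$records) + 1]] <- rec
  db <- save_index(db)
  attr(db, "last_id") <- id
  db
}

#' Query templates by keyword filters
#'
#' @param db a [template_db()].
#' @param filters named list of keyword = value predicates; records must
#'   match every filter. An empty filter returns all records; contradictory
#'   filters return an empty list. Unknown keyword names raise an error
#'   listing the valid keys.
#' @return list of index records, ordered by id.
#' @export
query_templates <- function(db, filters = list()) {
  stopifnot(inherits(db, "template_db"))
  bad <- setdiff(names(filters), .known_keywords)
  if (length(bad))
    stop(sprintf("unknown keyword(s) %s; valid keys: %s",
                 paste(bad, collapse = ", "), paste(.known_keywords, collapse = ", ")),
         call. = FALSE)
  hits <- Filter(function(r) {
    all(vapply(names(filters), function(k)
      !is.null(r$keywords[[k]]) && identical(as.character(r$keywords[[k]]),
                                             as.character(filters[[k]])),
      logical(1)))
  }, db$records)
  hits[order(vapply(hits, `[[`, character(1), "id"))]
}

#' Load a template back as a phytomer
#'
#' Round-trips the stored normalized geometry: meshes from the OBJ, skeletons
#' and parameters from the JSON.
#'
#' @param db a [template_db()].
#' @param id template id (e.g. `"T0001"`).
#' @return a normalized `phytomer`.
#' @export
load_template <- function(db, id) {
  stopifnot(inherits(db, "template_db"))
  ids <- vapply(db$records, `[[`, character(1), "id")
  if (!id %in% ids) stop(sprintf("template '%s' not found in database", id), call. = FALSE)
  rec <- db$records[[match(id, ids)]]
  json_path <- file.path(db$dir, rec$model_info$json_path)
  if (!file.exists(json_path)) stop(sprintf("missing template file: %s", json_path), call. = FALSE)
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  meshes <- list()
  obj_path <- file.path(db$dir, rec$model_info$obj_path)
  if (length(rec$model_info$model_names) > 0) {
    if (!file.exists(obj_path)) stop(sprintf("missing template file: %s", obj_path), call. = FALSE)
    meshes <- read_obj(obj_path)
  }
  comp_of <- function(org) {
    mesh <- meshes[[org]]
    skel <- payload$skeletons[[org]]
    if (is.null(mesh) && is.null(skel)) return(NULL)
    prm <- payload$params[[org]]
    organ_component(mesh = mesh,
                    skeleton = if (!is.null(skel)) skeleton_model(as.matrix(skel)) else NULL,
                    params = if (!is.null(prm)) as.list(prm) else NULL,
                    widths = if (org == "leaf" && !is.null(payload$widths))
                      as.numeric(payload$widths) else NULL)
  }
  phytomer(phytomer_id(payload$plant, payload$tiller, payload$rank),
           internode = comp_of("internode"), leaf = comp_of("leaf"),
           sheath = comp_of("sheath"), appendage = comp_of("appendage"),
           n_stem = payload$n_stem, kind = payload$kind)
}
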