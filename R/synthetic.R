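# Synthetic digitizer-format wheat plants with analytically known ground
# truth.
#
# The generator emulates the contact-digitizer acquisition convention:
# leaf rows as (left, vein, right) triples plus a tip (3n + 1 points), a vein
# polyline, stem node and girth points, and an ear polyline on each tiller's
# top phytomer. Leaf droop is modeled as a circular arc of arc length L and
# subtended angle phi in a vertical plane, chosen because the blade
# curvature then has the closed form L_bend = sin(phi/2) / (phi/2) and the
# stem-leaf angle equals base_angle + phi/2 exactly. Tillers fan uniformly
# in azimuth, leaves alternate 180 degrees up the stem (distichous), and each
# tiller leans rigidly by the stem lean angle, so theta_s equals the lean and
# h = cos(lean) * (total stem length + ear length) by construction.

#' Configuration for the synthetic plant generator
#'
#' Defaults describe a mid-size winter wheat plant at the filling stage
#' (total stem 66 cm + 10 cm ear; height about 75 cm at an 8 degree lean,
#' inside the 72.6-100 cm span of field cultivars).
#'
#' @param m tillers per plant (>= 1).
#' @param n phytomers per tiller (>= 1).
#' @param internode_lengths cm, per rank base to top (recycled to length n).
#' @param leaf_arc_length vein arc length (cm).
#' @param leaf_arc_angle subtended arc angle phi in radians, (0, 2*pi);
#'   controls droop: L_bend = sin(phi/2)/(phi/2).
#' @param leaf_base_angle angle of the vein's initial tangent from the stem
#'   axis (degrees).
#' @param leaf_max_width maximum blade width (cm); the width profile is
#'   parabolic, maximal at mid-length and zero at the tip.
#' @param stem_lean tiller inclination from vertical (degrees).
#' @param tiller_azimuths degrees; `NULL` fans the m tillers uniformly over
#'   [0, 360).
#' @param ear_length,ear_diameter spike dimensions (cm); the ear sits on the
#'   top phytomer, along the stem axis.
#' @param stem_diameter cm, used for the girth triples.
#' @param n_leaf_rows digitized rows per leaf.
#' @param n_vein_points points per vein polyline.
#' @param noise_sd Gaussian point noise SD (cm), applied to every digitized
#'   point; 0 = exact geometry.
#' @param seed optional RNG seed; identical seeds give identical output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(m = 3, n = 4,
                             internode_lengths = c(10, 14, 18, 24),
                             leaf_arc_length = 25,
                             leaf_arc_angle = 0.8,
                             leaf_base_angle = 20,
                             leaf_max_width = 1.8,
                             stem_lean = 8,
                             tiller_azimuths = NULL,
                             ear_length = 10,
                             ear_diameter = 1.2,
                             stem_diameter = 0.5,
                             n_leaf_rows = 6,
                             n_vein_points = 25,
                             noise_sd = 0,
                             seed = NULL) {
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  if (leaf_arc_angle <= 0 || leaf_arc_angle >= 2 * pi)
    stop("leaf_arc_angle must lie in (0, 2*pi)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cfg <- list(m = as.integer(m), n = as.integer(n),
              internode_lengths = rep_len(internode_lengths, n),
              leaf_arc_length = leaf_arc_length, leaf_arc_angle = leaf_arc_angle,
              leaf_base_angle = leaf_base_angle, leaf_max_width = leaf_max_width,
              stem_lean = stem_lean,
              tiller_azimuths = if (is.null(tiller_azimuths)) 360 * (seq_len(m) - 1) / m
                                else rep_len(tiller_azimuths, m),
              ear_length = ear_length, ear_diameter = ear_diameter,
              stem_diameter = stem_diameter,
              n_leaf_rows = as.integer(n_leaf_rows),
              n_vein_points = as.integer(n_vein_points),
              noise_sd = noise_sd, seed = seed)
  structure(cfg, class = "synthetic_config")
}

# Point on the leaf arc at arc parameter s in [0, phi], local frame:
# base at `base`, leaf pointing toward azimuth az (degrees), stem along +z.
leaf_arc_point <- function(s, base, az, r, theta0) {
  d <- c(cos(deg2rad(az)), sin(deg2rad(az)), 0)
  base + r * (cos(theta0) - cos(theta0 + s)) * d +
    r * (sin(theta0 + s) - sin(theta0)) * c(0, 0, 1)
}

#' Generate one synthetic leaf trace with ground truth
#'
#' The vein is a circular arc of length `leaf_arc_length` subtending
#' `leaf_arc_angle` radians in the vertical plane at `azimuth`; the blade
#' width profile is parabolic in arc position (zero at base and tip, maximum
#' at mid-length). Emits the surface rows (at arc positions (i - 1/2)/n_rows)
#' plus tip, and the vein polyline. Truth: L_bend = sin(phi/2)/(phi/2),
#' theta_l = base angle + phi/2, the tip's perpendicular offset from the stem
#' axis, and the maximum emitted row width.
#'
#' @param config a [synthetic_config()].
#' @param rank phytomer rank (chooses the distichous side).
#' @param base leaf attachment point (cm).
#' @param azimuth tiller azimuth (degrees); the leaf points at
#'   `azimuth + 180 * (rank %% 2)`.
#' @return list with `surface` ([leaf_surface_trace()]), `vein`
#'   ([vein_trace()]) and `truth` (named list).
#' @export
generate_leaf_trace <- function(config, rank, base = c(0, 0, 0), azimuth = 0) {
  phi <- config$leaf_arc_angle
  Larc <- config$leaf_arc_length
  r <- Larc / phi
  theta0 <- deg2rad(config$leaf_base_angle)
  az <- azimuth + 180 * (rank %% 2)
  nr <- config$n_leaf_rows
  t_rows <- (seq_len(nr) - 0.5) / nr
  w <- config$leaf_max_width * 4 * t_rows * (1 - t_rows)
  nperp <- c(-sin(deg2rad(az)), cos(deg2rad(az)), 0)
  vein_pts <- t(vapply(t_rows, function(t) leaf_arc_point(phi * t, base, az, r, theta0),
                       numeric(3)))
  left <- vein_pts + outer(w / 2, nperp)
  right <- vein_pts - outer(w / 2, nperp)
  tip <- leaf_arc_point(phi, base, az, r, theta0)
  surf <- leaf_surface_trace(left, vein_pts, right, tip)
  s_vein <- phi * (seq_len(config$n_vein_points) - 1) / (config$n_vein_points - 1)
  vpoly <- t(vapply(s_vein, function(s) leaf_arc_point(s, base, az, r, theta0), numeric(3)))
  vt <- vein_trace(vpoly, surface = surf)
  truth <- list(
    L_bend = sin(phi / 2) / (phi / 2),
    theta_l = config$leaf_base_angle + rad2deg(phi) / 2,
    tip_offset = r * (cos(theta0) - cos(theta0 + phi)),
    max_width = max(surf$widths))
  list(surface = surf, vein = vt, truth = truth)
}

# Girth triple: three points on a horizontal circle of the given diameter.
girth_triple <- function(center, diameter) {
  ang <- deg2rad(c(0, 120, 240))
  t(vapply(ang, function(a) center + diameter / 2 * c(cos(a), sin(a), 0), numeric(3)))
}

#' Generate a synthetic digitized plant with ground truth
#'
#' Builds m tillers of n phytomers each in digitizer format. Every tiller is
#' built upright (nodes on the z axis, leaves attached at the upper node of
#' their internode, the ear on the top unit) and then rigidly leaned by
#' `stem_lean` degrees toward its azimuth, so all relative angles are exact.
#' With `noise_sd > 0`, iid Gaussian noise is added to every emitted point;
#' the returned truth always refers to the noise-free geometry.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed`.
#' @return list with `plant` (a [digitized_plant()]) and `truth` (a
#'   data.frame in the layout of [extract_traits()]).
#' @export
generate_shoot <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  lean <- deg2rad(config$stem_lean)
  z_nodes <- cumsum(c(0, config$internode_lengths))
  total_len <- sum(config$internode_lengths) + config$ear_length
  tillers <- list()
  truth_rows <- list()
  tadd <- function(tiller, rank, organ, trait, value, units) {
    truth_rows[[length(truth_rows) + 1]] <<- data.frame(
      plant = 1L, tiller = tiller, rank = rank, organ = organ,
      trait = trait, value = value, units = units)
  }
  for (j in seq_len(config$m)) {
    azim <- config$tiller_azimuths[j]
    dir <- c(sin(lean) * cos(deg2rad(azim)), sin(lean) * sin(deg2rad(azim)), cos(lean))
    Rlean <- rotation_between(c(0, 0, 1), dir)
    bend <- function(pts) t(Rlean %*% t(as_points(pts)))
    nodes <- cbind(0, 0, z_nodes)
    girths <- lapply(seq_len(nrow(nodes)), function(ni)
      girth_triple(nodes[ni, ], config$stem_diameter))
    leaves <- list()
    for (k in seq_len(config$n)) {
      lf <- generate_leaf_trace(config, k, base = nodes[k + 1, ], azimuth = azim)
      leaves[[k]] <- lf
      tadd(j, k, "leaf", "L_bend", lf$truth$L_bend, "1")
      tadd(j, k, "leaf", "theta_l", lf$truth$theta_l, "deg")
      L_env <- config$internode_lengths[k] + if (k == config$n) config$ear_length else 0
      tadd(j, k, "phytomer", "S_phy",
           L_env * lf$truth$tip_offset * lf$truth$max_width, "cm3")
    }
    ear_z <- seq(z_nodes[length(z_nodes)], z_nodes[length(z_nodes)] + config$ear_length,
                 length.out = 5)
    ear_poly <- cbind(0, 0, ear_z)
    ear_girth <- girth_triple(c(0, 0, mean(ear_z)), config$ear_diameter)
    tl <- list(
      stem = stem_trace(bend(nodes), lapply(girths, bend)),
      leaves = lapply(leaves, function(lf) {
        s <- lf$surface
        list(surface = leaf_surface_trace(bend(s$left), bend(s$vein), bend(s$right),
                                          as.numeric(bend(matrix(s$tip, 1)))),
             vein = vein_trace(bend(lf$vein$polyline)))
      }),
      ear = list(polyline = bend(ear_poly), girth = bend(ear_girth)))
    tillers[[j]] <- tl
    tadd(j, NA, "stem", "N_length", mean(config$internode_lengths), "cm")
    tadd(j, NA, "stem", "theta_s", config$stem_lean, "deg")
  }
  tadd(NA, NA, "plant", "h", cos(lean) * total_len, "cm")
  if (config$noise_sd > 0) {
    jiggle <- function(pts) {
      pts <- as_points(pts)
      pts + matrix(stats::rnorm(length(pts), 0, config$noise_sd), nrow(pts), 3)
    }
    tillers <- lapply(tillers, function(tl) {
      tl$stem <- stem_trace(jiggle(tl$stem$nodes), lapply(tl$stem$girths, jiggle))
      tl$leaves <- lapply(tl$leaves, function(lf) {
        s <- lf$surface
        surf <- leaf_surface_trace(jiggle(s$left), jiggle(s$vein), jiggle(s$right),
                                   as.numeric(jiggle(matrix(s$tip, 1))))
        list(surface = surf, vein = vein_trace(jiggle(lf$vein$polyline)))
      })
      tl$ear <- list(polyline = jiggle(tl$ear$polyline), girth = jiggle(tl$ear$girth))
      tl
    })
  }
  list(plant = digitized_plant(1L, tillers), truth = do.call(rbind, truth_rows))
}

#' Generate a cultivar panel of digitizer files
#'
#' Writes one digitizer CSV per (config, replicate), with multiplicative
#' Gaussian jitter (default 5% CV) applied to the morphological parameters
#' between replicates, plus a combined `truth.csv`. Deterministic under
#' `seed`.
#'
#' @param configs list of [synthetic_config()] (one per cultivar), or a
#'   single config.
#' @param replicates replicates per cultivar.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @param jitter_cv coefficient of variation of the between-replicate jitter;
#'   0 makes replicates identical.
#' @return invisibly, a list with `files` (character vector of CSV paths) and
#'   `truth` (data.frame with cultivar and replicate columns).
#' @export
generate_panel <- function(configs, replicates = 3, seed = 1, dir = tempdir(),
                           jitter_cv = 0.05) {
  if (inherits(configs, "synthetic_config")) configs <- list(configs)
  if (length(configs) < 1) stop("need at least one config", call. = FALSE)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth_all <- list()
  jit <- function(x, lo = -Inf, hi = Inf) {
    f <- pmax(1 + stats::rnorm(length(x), 0, jitter_cv), 0.1)
    pmin(pmax(x * f, lo), hi)
  }
  for (ci in seq_along(configs)) {
    for (r in seq_len(replicates)) {
      cfg <- configs[[ci]]
      if (jitter_cv > 0) {
        cfg$internode_lengths <- jit(cfg$internode_lengths)
        cfg$leaf_arc_length <- jit(cfg$leaf_arc_length)
        cfg$leaf_max_width <- jit(cfg$leaf_max_width)
        cfg$leaf_arc_angle <- jit(cfg$leaf_arc_angle, 1e-3, 2 * pi - 1e-3)
        cfg$ear_length <- jit(cfg$ear_length)
        cfg$stem_lean <- jit(cfg$stem_lean, 0, 90)
      }
      sh <- generate_shoot(cfg, seed = NULL)   # RNG stream continues from `seed`
      path <- file.path(dir, sprintf("plant_c%02d_r%d.csv", ci, r))
      dp <- sh$plant
      dp$plant <- as.integer((ci - 1) * replicates + r)
      write_digitized_plant(dp, path)
      files <- c(files, path)
      tr <- sh$truth
      tr$plant <- dp$plant
      tr$cultivar <- ci
      tr$replicate <- r
      truth_all[[length(truth_all) + 1]] <- tr
    }
  }
  truth <- do.call(rbind, truth_all)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(files = files, truth = truth))
}
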