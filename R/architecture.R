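# The plant architecture vector PA = (C, L, PHY, S) and its classification.
#
#   C   = h * 10 / S_area    convergence index (vertical vs horizontal extent;
#                            the x10 scaling puts field-scale wheat in a
#                            convenient 1-10 band for classification)
#   L   = L_bend * theta_l   leaf structure index (degrees, curvature-weighted)
#   PHY = S_phy / N_length   phytomer structure index (cm^2)
#   S   = theta_s            stem structure index (degrees)
#
# Classification by C alone: loose / semi-compact / compact, with decision
# boundaries at the midpoints of the gaps between the published class ranges
# (1.95 | 2.87-5.72 | 6.36-9.56): 2.41 and 6.04.

#' Convergence index
#'
#' C = h * 10 / S_area. The factor of ten is part of the index definition.
#'
#' @param h plant height (cm, >= 0).
#' @param S_area spike-layer projected area (cm^2, > 0).
#' @return C (dimensionless).
#' @export
convergence_index <- function(h, S_area) {
  if (any(S_area <= 0)) stop("S_area must be positive", call. = FALSE)
  if (any(h < 0)) stop("h must be >= 0", call. = FALSE)
  h * 10 / S_area
}

#' Leaf structure index
#' @param L_bend blade curvature in (0, 1].
#' @param theta_l stem-leaf angle (degrees).
#' @return L = L_bend * theta_l (degrees).
#' @export
leaf_structure_index <- function(L_bend, theta_l) L_bend * theta_l

#' Phytomer structure index
#' @param S_phy phytomer envelope (cm^3).
#' @param N_length average internode length (cm, > 0).
#' @return PHY = S_phy / N_length (cm^2).
#' @export
phytomer_structure_index <- function(S_phy, N_length) {
  if (any(N_length <= 0)) stop("N_length must be positive", call. = FALSE)
  S_phy / N_length
}

#' Stem structure index
#' @param theta_s stem inclination from vertical (degrees, [0, 180]).
#' @return S = theta_s.
#' @export
stem_structure_index <- function(theta_s) {
  if (any(theta_s < 0 | theta_s > 180)) stop("theta_s must be in [0, 180]", call. = FALSE)
  theta_s
}

#' Default architecture class boundaries
#'
#' Midpoints of the gaps between the published class ranges for C:
#' loose | semi-compact at (1.95 + 2.87)/2 = 2.41 and semi-compact | compact
#' at (5.72 + 6.36)/2 = 6.04.
#' @export
pa_class_thresholds <- c(loose_max = 2.41, compact_min = 6.04)

#' Classify plant architecture from the convergence index
#'
#' @param C convergence index (> 0).
#' @param thresholds named vector `c(loose_max =, compact_min =)`.
#' @return `"loose"`, `"semi-compact"` or `"compact"` (vectorized over C).
#' @export
classify_architecture <- function(C, thresholds = pa_class_thresholds) {
  if (any(!is.finite(C)) || any(C <= 0)) stop("C must be positive and finite", call. = FALSE)
  if (thresholds[["loose_max"]] >= thresholds[["compact_min"]])
    stop("thresholds must be ordered", call. = FALSE)
  ifelse(C < thresholds[["loose_max"]], "loose",
         ifelse(C >= thresholds[["compact_min"]], "compact", "semi-compact"))
}

#' Plant architecture vector of a shoot
#'
#' Computes PA = (C, L, PHY, S) from the extracted trait table. Aggregation
#' to plant scale: L averages the per-leaf index, PHY the per-phytomer index
#' and S the per-tiller stem angle (`aggregate = "mean"`, default);
#' `"flag_leaf"` / `"top_phytomer"` restrict L and PHY to the top unit of
#' each tiller.
#'
#' @param shoot an `assembled_shoot`.
#' @param aggregate one of `"mean"`, `"flag_leaf"`, `"top_phytomer"`.
#' @param fallback_fraction passed to [spike_layer_projected_area()].
#' @return an object of class `pa_vector`: list with C, L, PHY, S, class.
#' @export
plant_architecture_vector <- function(shoot,
                                      aggregate = c("mean", "flag_leaf", "top_phytomer"),
                                      fallback_fraction = 0.2) {
  aggregate <- match.arg(aggregate)
  tr <- extract_traits(shoot, fallback_fraction)
  top_only <- aggregate %in% c("flag_leaf", "top_phytomer")
  pick <- function(trait, organ) {
    d <- tr[tr$trait == trait & tr$organ == organ, , drop = FALSE]
    if (top_only && nrow(d) > 0) {
      keep <- unlist(lapply(split(seq_len(nrow(d)), d$tiller),
                            function(i) i[which.max(d$rank[i])]))
      d <- d[keep, , drop = FALSE]
    }
    d
  }
  lb <- pick("L_bend", "leaf"); tl <- pick("theta_l", "leaf")
  sp <- pick("S_phy", "phytomer")
  nl <- tr[tr$trait == "N_length", , drop = FALSE]
  th <- tr[tr$trait == "theta_s", , drop = FALSE]
  h <- tr$value[tr$trait == "h"]
  S_area <- tr$value[tr$trait == "S_area"]
  # per-phytomer PHY uses its own stem's N_length
  nmap <- stats::setNames(nl$value, nl$tiller)
  PHY <- mean(phytomer_structure_index(sp$value, nmap[as.character(sp$tiller)]))
  pa <- structure(list(
    C = convergence_index(h, S_area),
    L = mean(leaf_structure_index(lb$value, tl$value)),
    PHY = unname(PHY),
    S = mean(stem_structure_index(th$value))), class = "pa_vector")
  pa$class <- classify_architecture(pa$C)
  pa
}

#' @export
print.pa_vector <- function(x, ...) {
  cat(sprintf("PA = (C = %.3f, L = %.2f deg, PHY = %.2f cm^2, S = %.2f deg)  [%s]\n",
              x$C, x$L, x$PHY, x$S, x$class))
  invisible(x)
}

#' @export
as.data.frame.pa_vector <- function(x, ...) {
  data.frame(C = x$C, L = x$L, PHY = x$PHY, S = x$S, class = x$class)
}

#' Summarize a cultivar panel of PA vectors
#'
#' Per cultivar: replicate mean, sample standard deviation and range of each
#' index; across all rows: the 4 x 4 Pearson correlation matrix of
#' (C, L, PHY, S). Zero-variance indices yield undefined (NA) correlations
#' and are reported in `$degenerate`.
#'
#' @param rows data.frame with columns cultivar, replicate, C, L, PHY, S
#'   (e.g. rbind of `as.data.frame(pa_vector)` plus ids).
#' @return list with `$summary` (per-cultivar data.frame), `$correlations`
#'   (4 x 4 matrix), `$degenerate` (character vector of constant indices).
#' @export
panel_summary <- function(rows) {
  idx <- c("C", "L", "PHY", "S")
  if (!is.data.frame(rows) || nrow(rows) == 0) stop("empty panel", call. = FALSE)
  if (!all(c("cultivar", idx) %in% names(rows)))
    stop("panel rows need columns cultivar, C, L, PHY, S", call. = FALSE)
  summ <- do.call(rbind, lapply(split(rows, rows$cultivar), function(d) {
    out <- data.frame(cultivar = d$cultivar[1], n = nrow(d))
    for (v in idx) {
      out[[paste0(v, "_mean")]] <- mean(d[[v]])
      out[[paste0(v, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[v]]) else NA_real_
      out[[paste0(v, "_range")]] <- diff(range(d[[v]]))
    }
    out
  }))
  rownames(summ) <- NULL
  X <- as.matrix(rows[, idx])
  sds <- apply(X, 2, stats::sd)
  degenerate <- idx[sds <= .EPS | !is.finite(sds)]
  cm <- suppressWarnings(stats::cor(X))
  diag(cm) <- 1
  list(summary = summ, correlations = cm, degenerate = degenerate)
}
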