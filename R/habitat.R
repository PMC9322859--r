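# InVEST-style habitat quality: threat sources with distance-decay impact
# kernels, sensitivity-weighted degradation, the half-saturation quality
# transform, grading, and zonal summaries.

#' Threat-source parameter table
#'
#' The five threat sources with their maximum stress distance (km), weight,
#' and spatial decay type: cultivated land (3 km, 0.7, linear),
#' construction land (10 km, 1, exponential), national roads, provincial
#' roads and main railways (each 2 km, 0.8, linear).
#'
#' @return Data frame with columns `threat`, `d_max_km`, `weight`, `decay`.
#' @export
threat_params <- function() {
  data.frame(
    threat = c("cultivated", "construction", "national_road",
               "provincial_road", "railway"),
    d_max_km = c(3, 10, 2, 2, 2),
    weight = c(0.7, 1, 0.8, 0.8, 0.8),
    decay = c("linear", "exponential", "linear", "linear", "linear"),
    stringsAsFactors = FALSE)
}

#' Habitat suitability and threat sensitivity table
#'
#' Per-class habitat suitability `H` and the relative sensitivity of each
#' class to each threat source. Construction and unused land are
#' non-habitat (all zeros).
#'
#' @return List with `H` (named vector, length 6) and `S` (6 x 5 matrix,
#'   rows classes, columns threats).
#' @export
sensitivity_table <- function() {
  H <- stats::setNames(c(0.6, 1, 1, 0.8, 0, 0), land_classes())
  S <- rbind(
    cultivated   = c(0.3, 1.0, 0.4, 0.4, 0.3),
    woodland     = c(0.8, 0.8, 0.6, 0.6, 0.5),
    grassland    = c(0.7, 0.7, 0.4, 0.3, 0.2),
    waters       = c(0.5, 0.9, 0.5, 0.4, 0.4),
    construction = c(0, 0, 0, 0, 0),
    unused       = c(0, 0, 0, 0, 0))
  colnames(S) <- threat_params()$threat
  list(H = H, S = S)
}

#' Build the threat-source set for a land-use map
#'
#' Cultivated-land and construction-land masks are derived from the map;
#' road/railway masks are passed through. Each source is paired with its
#' parameters; sources with an empty mask are skipped.
#'
#' @param lu A `cat_raster`.
#' @param roads Named list of logical masks (`national_road`,
#'   `provincial_road`, `railway`); missing entries drop those threats.
#' @param params Threat parameter table (default [threat_params]).
#' @return List of `threat_source` objects (name, mask, d_max_km, weight,
#'   decay).
#' @export
build_threat_masks <- function(lu, roads = list(), params = threat_params()) {
  masks <- list(
    cultivated = !is.na(lu) & values_of(lu) == 1L,
    construction = !is.na(lu) & values_of(lu) == 5L)
  for (nm in c("national_road", "provincial_road", "railway")) {
    if (!is.null(roads[[nm]])) {
      m <- as.matrix(roads[[nm]])
      if (!identical(dim(m), dim(lu)))
        stop("road mask '", nm, "' does not match the map's shape")
      masks[[nm]] <- m & TRUE
    }
  }
  configured <- intersect(params$threat, names(masks))
  out <- list()
  for (nm in configured) {
    if (!any(masks[[nm]])) next                  # empty source: skip
    p <- params[params$threat == nm, ]
    out[[nm]] <- structure(list(name = nm, mask = masks[[nm]],
                                d_max_km = p$d_max_km, weight = p$weight,
                                decay = p$decay),
                           class = "threat_source")
  }
  out
}

#' Distance-decay impact surface of one threat source
#'
#' Linear decay: `i = max(0, 1 - d/d_max)`. Exponential decay:
#' `i = exp(-2.99 d/d_max)` inside `d_max` and 0 beyond (the constant 2.99
#' puts the kernel at about 0.05 at the maximum stress distance, the InVEST
#' convention). Source cells have `i = 1` under both decays.
#'
#' @param threat A `threat_source`.
#' @param cell_size Cell edge in metres.
#' @return A `cont_raster` of impacts in `[0,1]`.
#' @export
threat_impact <- function(threat, cell_size) {
  if (!any(threat$mask)) stop("threat '", threat$name, "' has an empty mask")
  d_km <- values_of(distance_transform(threat$mask, cell_size)) / 1000
  rel <- d_km / threat$d_max_km
  i <- if (threat$decay == "linear") pmax(1 - rel, 0)
       else ifelse(rel < 1, exp(-2.99 * rel), 0)
  cont_raster(i, cell_size)
}

#' Habitat degradation surface
#'
#' `D_x = sum_r (w_r / sum w_r) * i_r(x) * beta_x * S[class(x), r]`,
#' clipped to `[0,1]`. Threat intensity is binary presence on source cells
#' (absorbed into the impact kernel); `beta` is the per-cell accessibility
#' (anti-interference) level, default 1 everywhere.
#'
#' @param lu A `cat_raster`.
#' @param threats List of `threat_source` (see [build_threat_masks]).
#' @param sens Sensitivity table (default [sensitivity_table]).
#' @param beta Scalar or matrix accessibility in `[0,1]`.
#' @return A `cont_raster` of degradation in `[0,1]` (NA off the map).
#' @export
habitat_degradation <- function(lu, threats, sens = sensitivity_table(),
                                beta = 1) {
  cs <- cell_size_of(lu)
  D <- matrix(0, nrow(lu), ncol(lu))
  if (length(threats) > 0L) {
    wsum <- sum(vapply(threats, `[[`, 0, "weight"))
    cls <- values_of(lu)
    for (th in threats) {
      if (!th$name %in% colnames(sens$S))
        stop("no sensitivity column for threat '", th$name, "'")
      i_r <- values_of(threat_impact(th, cs))
      S_map <- matrix(0, nrow(lu), ncol(lu))
      ok <- !is.na(cls)
      S_map[ok] <- sens$S[cls[ok], th$name]
      D <- D + (th$weight / wsum) * i_r * S_map
    }
  }
  D <- D * beta
  D <- pmin(pmax(D, 0), 1)
  D[is.na(values_of(lu))] <- NA_real_
  cont_raster(D, cs)
}

#' Habitat quality from degradation
#'
#' `Q = H * (1 - D^2 / (D^2 + k^2))` per cell, with `H` the class's habitat
#' suitability and `k` the half-saturation constant: at `D = k`, quality is
#' half the suitability.
#'
#' @param D Degradation `cont_raster` (values in `[0,1]`).
#' @param lu The `cat_raster` the degradation was computed for.
#' @param sens Sensitivity table (supplies `H`).
#' @param k Half-saturation constant (> 0, default 0.5).
#' @return A `cont_raster` of quality in `[0,1]`.
#' @export
habitat_quality <- function(D, lu, sens = sensitivity_table(), k = 0.5) {
  if (!is.numeric(k) || k <= 0) stop("half-saturation k must be > 0")
  check_aligned(D, lu, "degradation and map")
  cls <- values_of(lu)
  H <- matrix(NA_real_, nrow(lu), ncol(lu))
  ok <- !is.na(cls)
  H[ok] <- sens$H[cls[ok]]
  d <- values_of(D)
  Q <- H * (1 - d^2 / (d^2 + k^2))
  Q[!ok] <- NA_real_
  cont_raster(Q, cell_size_of(lu))
}

#' Grade a habitat-quality surface
#'
#' Fixed bins: poor `[0, 0.4)`, moderate `[0.4, 0.6)`, good `[0.6, 0.8)`,
#' excellent `[0.8, 1]` (left-closed, top bin closed, so every value maps
#' to exactly one grade).
#'
#' @param Q Quality `cont_raster`.
#' @return Integer matrix raster (1 = poor .. 4 = excellent) with attribute
#'   `grade_labels`.
#' @export
grade_quality <- function(Q) {
  q <- values_of(Q)
  g <- matrix(NA_integer_, nrow(q), ncol(q))
  ok <- !is.na(q)
  g[ok] <- findInterval(q[ok], c(0, 0.4, 0.6, 0.8), rightmost.closed = FALSE)
  g[ok & q > 1] <- NA_integer_
  structure(g, grade_labels = c("poor", "moderate", "good", "excellent"),
            cell_size = cell_size_of(Q))
}

#' Assess habitat quality of a land-use map
#'
#' One-call wrapper: builds threat masks, computes degradation, quality and
#' grades.
#'
#' @param lu A `cat_raster`.
#' @param roads Named list of road/railway masks (may be empty).
#' @param sens Sensitivity table.
#' @param params Threat parameter table.
#' @param k Half-saturation constant.
#' @param beta Accessibility level.
#' @return A `habitat_result`: list with `degradation`, `quality`, `grades`,
#'   `k`.
#' @export
assess_habitat <- function(lu, roads = list(), sens = sensitivity_table(),
                           params = threat_params(), k = 0.5, beta = 1) {
  threats <- build_threat_masks(lu, roads, params)
  D <- habitat_degradation(lu, threats, sens, beta)
  Q <- habitat_quality(D, lu, sens, k)
  structure(list(degradation = D, quality = Q, grades = grade_quality(Q),
                 k = k),
            class = "habitat_result")
}

#' @export
print.habitat_result <- function(x, ...) {
  s <- summarize_quality(x$quality, x$grades)
  cat(sprintf("<habitat_result> mean quality %.4f (k = %.3g)\n",
              s$mean_quality, x$k))
  print(round(s$grade_shares, 2))
  invisible(x)
}

#' Summarise a habitat-quality surface
#'
#' @param Q Quality `cont_raster`.
#' @param grades Grade raster from [grade_quality] (recomputed if omitted).
#' @param lu Optional `cat_raster` for per-class mean quality.
#' @return List: `mean_quality` over valid cells, `grade_shares` (named
#'   percentages summing to 100), and `class_mean_quality` when `lu` given.
#' @export
summarize_quality <- function(Q, grades = NULL, lu = NULL) {
  if (is.null(grades)) grades <- grade_quality(Q)
  q <- values_of(Q)
  ok <- !is.na(q)
  shares <- tabulate(grades[ok], nbins = 4L) / sum(ok) * 100
  names(shares) <- attr(grades, "grade_labels")
  out <- list(mean_quality = mean(q[ok]), grade_shares = shares)
  if (!is.null(lu)) {
    cls <- values_of(lu)
    out$class_mean_quality <- stats::setNames(
      vapply(seq_len(N_CLASS), function(k) {
        sel <- ok & !is.na(cls) & cls == k
        if (any(sel)) mean(q[sel]) else NA_real_
      }, 0), land_classes())
  }
  out
}
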