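# Synthetic landscape generator. Emulates the statistical structure the
# downstream stages assume -- a spatially autocorrelated six-class map,
# driver surfaces correlated with class identity, linear road features, and
# an epoch-to-epoch change process governed by a known transition matrix --
# so the whole pipeline is testable without any proprietary raster.
# Every generator is a pure function of (config, seed).

#' Default decadal land-use transition matrix for synthetic worlds
#'
#' A row-stochastic 6x6 matrix emulating an urbanising region: cultivated
#' land leaks mainly to construction land and grassland, construction land
#' is nearly absorbing, unused land slowly shrinks and receives no inflow
#' (which keeps every built-in scenario's demand feasible under its
#' conversion-cost matrix).
#'
#' @return A [transition_matrix] with `period_years = 10`.
#' @export
default_transition <- function() {
  p <- rbind(
    cultivated   = c(0.920, 0.033, 0.012, 0.002, 0.033, 0.000),
    woodland     = c(0.058, 0.892, 0.035, 0.002, 0.013, 0.000),
    grassland    = c(0.028, 0.015, 0.925, 0.002, 0.030, 0.000),
    waters       = c(0.030, 0.005, 0.010, 0.920, 0.035, 0.000),
    construction = c(0.010, 0.002, 0.003, 0.001, 0.984, 0.000),
    unused       = c(0.040, 0.010, 0.020, 0.005, 0.030, 0.895))
  colnames(p) <- land_classes()
  transition_matrix(p, period_years = 10L)
}

#' Configuration of a synthetic landscape
#'
#' @param shape Grid dimensions `c(rows, cols)`; default 200 x 200, a desk
#'   scale that keeps class frequencies stable while tests stay fast.
#' @param cell_size Cell edge in metres (default 100 m).
#' @param seed Integer seed; every generator is deterministic given it.
#' @param true_transition Row-stochastic [transition_matrix] governing the
#'   epoch-to-epoch change process.
#' @param smoothness Correlation length of the random fields, in cells.
#' @param class_prevalence Six target class fractions (sum 1); default
#'   mirrors a cultivated-land dominated agglomeration (46/22/27% cultivated/
#'   woodland/grassland with minor waters, construction and unused land).
#' @return A `synth_config` list.
#' @export
synth_config <- function(shape = c(200L, 200L), cell_size = 100, seed = 42L,
                         true_transition = default_transition(),
                         smoothness = 6,
                         class_prevalence = c(0.40, 0.22, 0.27, 0.02, 0.06, 0.03)) {
  if (length(shape) != 2L || any(shape < 3L))
    stop("shape must be c(rows, cols) with both dimensions >= 3")
  if (abs(sum(class_prevalence) - 1) > 1e-9)
    stop("class_prevalence must sum to 1")
  if (length(class_prevalence) != N_CLASS)
    stop("class_prevalence must have length 6")
  check_row_stochastic(true_transition$probs)
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 seed = as.integer(seed), true_transition = true_transition,
                 smoothness = smoothness,
                 class_prevalence = class_prevalence),
            class = "synth_config")
}

# separable Gaussian smoothing with reflection padding
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(min(r, n))), seq_len(n),
                           n + 1L - rev(seq_len(min(r, n))))
  conv_cols <- function(x) {
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- stats::filter(xp, k, sides = 2L)
    out[(r + 1L):(r + nrow(x)), , drop = FALSE]
  }
  m2 <- conv_cols(m)
  t(conv_cols(t(m2)))
}

# slope as gradient magnitude (rise over run) of a dem by central
# differences, one-sided at the borders
slope_from_dem <- function(dem, cell_size) {
  nr <- nrow(dem); nc <- ncol(dem)
  gy <- dem[c(2:nr, nr), ] - dem[c(1, 1:(nr - 1L)), ]
  gx <- dem[, c(2:nc, nc)] - dem[, c(1, 1:(nc - 1L))]
  deny <- matrix(2, nr, nc); deny[c(1L, nr), ] <- 1
  denx <- matrix(2, nr, nc); denx[, c(1L, nc)] <- 1
  sqrt((gy / (deny * cell_size))^2 + (gx / (denx * cell_size))^2)
}

# unit-variance smoothed Gaussian random field (uses the current RNG stream)
gaussian_field <- function(nr, nc, smoothness) {
  f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
  as.numeric(scale(as.vector(f))) |> matrix(nr, nc)
}

#' Generate random road/railway lines crossing the grid
#'
#' Each line connects random points on two distinct grid borders and is
#' rasterised with Bresenham's algorithm, so every line touches two borders.
#'
#' @param shape `c(rows, cols)`.
#' @param n_lines Number of polylines (>= 0).
#' @param seed Integer seed.
#' @return Logical matrix mask of line cells.
#' @export
gen_roads <- function(shape, n_lines, seed = 42L) {
  nr <- shape[1L]; nc <- shape[2L]
  mask <- matrix(FALSE, nr, nc)
  if (n_lines < 0) stop("n_lines must be >= 0")
  if (n_lines == 0L) return(mask)
  with_seed(seed, {
    for (i in seq_len(n_lines)) {
      borders <- sample(4L, 2L)            # 1 top, 2 bottom, 3 left, 4 right
      pt <- function(b) switch(b,
        c(1L, sample(nc, 1L)), c(nr, sample(nc, 1L)),
        c(sample(nr, 1L), 1L), c(sample(nr, 1L), nc))
      a <- pt(borders[1L]); b <- pt(borders[2L])
      n <- max(abs(a - b)) + 1L
      rr <- round(seq(a[1L], b[1L], length.out = n))
      cc <- round(seq(a[2L], b[2L], length.out = n))
      mask[cbind(rr, cc)] <- TRUE
    }
  })
  mask
}

#' Generate the driver stack of a synthetic landscape
#'
#' Terrain (`dem`, `slope`), socio-economic surfaces (`gdp_density`,
#' `pop_density`, sharing one seeded "urban core" hotspot), and accessibility
#' layers (exact Euclidean distances to generated towns, a river, and three
#' road/railway networks). The feature masks used to build the distance
#' layers are attached as `attr(stack, "masks")` so the habitat stage can
#' reuse the identical road geometry.
#'
#' @param config A [synth_config].
#' @return A [driver_stack] with attribute `masks` (named list of logical
#'   matrices: `towns`, `river`, `national_road`, `provincial_road`,
#'   `railway`).
#' @export
gen_drivers <- function(config) {
  nr <- config$shape[1L]; nc <- config$shape[2L]
  cs <- config$cell_size
  sm <- config$smoothness
  out <- with_seed(config$seed, {
    dem_f <- gaussian_field(nr, nc, sm)
    dem <- (dem_f - min(dem_f)) / diff(range(dem_f)) * 1500   # metres
    slope <- slope_from_dem(dem, cs)

    # shared urban core in the central half of the grid, on lowish terrain
    core <- c(sample(seq(round(nr * 0.25), round(nr * 0.75)), 1L),
              sample(seq(round(nc * 0.25), round(nc * 0.75)), 1L))
    dist2core <- sqrt(outer((seq_len(nr) - core[1L])^2,
                            (seq_len(nc) - core[2L])^2, `+`))
    hotspot <- exp(-(dist2core / (0.2 * max(nr, nc)))^2)
    gdp <- 0.65 * hotspot + 0.35 * (gaussian_field(nr, nc, sm) * 0.5 + 0.5)
    pop <- 0.60 * hotspot + 0.40 * (gaussian_field(nr, nc, sm) * 0.5 + 0.5)

    towns <- matrix(FALSE, nr, nc)
    towns[core[1L], core[2L]] <- TRUE
    w <- pmax(gdp, 0)^3
    sat <- sample(nr * nc, 6L, prob = as.vector(w))
    towns[sat] <- TRUE

    # meandering river: vertical random walk crossing left to right
    river <- matrix(FALSE, nr, nc)
    row <- sample(seq(round(nr * 0.2), round(nr * 0.8)), 1L)
    for (j in seq_len(nc)) {
      row <- min(max(row + sample(-1:1, 1L), 1L), nr)
      river[row, j] <- TRUE
    }
    national <- gen_roads(config$shape, 2L, config$seed + 101L)
    provincial <- gen_roads(config$shape, 3L, config$seed + 202L)
    railway <- gen_roads(config$shape, 1L, config$seed + 303L)

    dist_of <- function(m) distance_transform(m, cs)
    layers <- list(
      dem = cont_raster(dem, cs),
      slope = cont_raster(slope, cs),
      gdp_density = cont_raster(gdp, cs),
      pop_density = cont_raster(pop, cs),
      dist_town = dist_of(towns),
      dist_river = dist_of(river),
      dist_national_road = dist_of(national),
      dist_provincial_road = dist_of(provincial),
      dist_railway = dist_of(railway))
    list(stack = driver_stack(layers),
         masks = list(towns = towns, river = river, national_road = national,
                      provincial_road = provincial, railway = railway))
  })
  structure(out$stack, masks = out$masks,
            class = class(out$stack))
}

# per-class affine score coefficients on the normalised drivers; rows are
# classes, columns drivers. Chosen so class identity is recoverable from the
# drivers: construction tracks the urban core, woodland steep high ground,
# waters valley floors near the river, etc.
score_coefs <- function() {
  d <- driver_names()
  B <- matrix(0, N_CLASS, length(d), dimnames = list(land_classes(), d))
  B["cultivated", c("dem", "slope")] <- c(-0.6, -1.2)
  B["woodland", c("dem", "slope", "dist_town")] <- c(0.6, 1.6, 0.3)
  B["grassland", c("dem", "slope")] <- c(0.9, 0.4)
  B["waters", c("dem", "dist_river")] <- c(-1.8, -2.5)
  B["construction", c("gdp_density", "pop_density", "dist_town")] <-
    c(1.2, 1.2, -1.8)
  B["unused", c("dem", "dist_river", "gdp_density")] <- c(1.1, 0.6, -0.8)
  B
}

#' Generate a six-class land-use map from drivers
#'
#' Each cell takes the argmax of six class scores, each an affine function
#' of the normalised drivers plus a smooth noise field. Class intercepts are
#' calibrated iteratively so realised class fractions track
#' `config$class_prevalence` (within +-0.15).
#'
#' @param drivers A [driver_stack] (typically from [gen_drivers]).
#' @param config A [synth_config].
#' @return A `cat_raster`.
#' @export
gen_landuse <- function(drivers, config) {
  nd <- drivers$normalized
  nr <- nrow(drivers$valid); nc <- ncol(drivers$valid)
  B <- score_coefs()
  with_seed(config$seed + 7L, {
    base <- matrix(0, nr * nc, N_CLASS)
    for (k in seq_len(N_CLASS)) {
      s <- matrix(0, nr, nc)
      for (d in driver_names()) if (B[k, d] != 0) s <- s + B[k, d] * nd[[d]]
      base[, k] <- as.vector(s + 0.35 * gaussian_field(nr, nc, config$smoothness))
    }
    valid <- as.vector(drivers$valid) & !is.na(base[, 1L])
    S <- base[valid, , drop = FALSE]
    # per-class standardisation keeps the argmax competition comparable
    # across classes so the intercept calibration below is well-behaved
    S <- scale(S)
    S[, attr(S, "scaled:scale") == 0] <- 0
    target <- config$class_prevalence
    b0 <- rep(0, N_CLASS)
    eps <- 1e-4
    nv <- nrow(S)
    # Robbins-Monro intercept calibration toward the target fractions
    for (it in seq_len(200L)) {
      cls <- max.col(S + rep(b0, each = nv), ties.method = "first")
      frac <- tabulate(cls, nbins = N_CLASS) / nv
      b0 <- b0 + 0.8 / sqrt(it) * (log(target + eps) - log(frac + eps))
      b0 <- b0 - mean(b0)
    }
    cls <- max.col(S + rep(b0, each = nv), ties.method = "first")
    m <- matrix(NA_integer_, nr, nc)
    m[matrix(valid, nr, nc)] <- cls
    cat_raster(m, config$cell_size)
  })
}

# number of 8-neighbours of each cell equal to class k
neighbour_count <- function(cls, k) {
  nr <- nrow(cls); nc <- ncol(cls)
  ind <- matrix(0L, nr, nc)
  ind[!is.na(cls) & cls == k] <- 1L
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dcc in -1:1) {
    if (dr == 0L && dcc == 0L) next
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + dcc, 1L), nc)
    sh <- ind[rs, cs, drop = FALSE]
    # out-of-grid shifts replicate the border row/col; zero them instead
    if (dr == -1L) sh[1L, ] <- 0L else if (dr == 1L) sh[nr, ] <- 0L
    if (dcc == -1L) sh[, 1L] <- 0L else if (dcc == 1L) sh[, nc] <- 0L
    acc <- acc + sh
  }
  acc
}

#' Advance a land-use map by one epoch under a known transition matrix
#'
#' Per-class change quotas are fixed by largest-remainder apportionment of
#' the transition-matrix rows (so marginal transition frequencies match the
#' matrix up to integer rounding), and the cells that change are drawn with
#' probability weighted towards cells adjacent to the destination class,
#' giving spatially coherent change without distorting the marginals.
#'
#' @param lu_t0 Base-epoch `cat_raster`.
#' @param true_transition A [transition_matrix] (row-stochastic).
#' @param seed Integer seed.
#' @param adjacency_bias Weight multiplier per adjacent destination-class
#'   neighbour (default 8; 0 gives independent per-cell draws).
#' @return A `cat_raster` one epoch later.
#' @export
gen_next_epoch <- function(lu_t0, true_transition, seed = 42L,
                           adjacency_bias = 8) {
  P <- true_transition$probs
  check_row_stochastic(P)
  cls <- values_of(lu_t0)
  out <- cls
  with_seed(seed, {
    for (i in seq_len(N_CLASS)) {
      cells <- which(!is.na(cls) & cls == i)
      if (length(cells) == 0L) next
      quota <- apportion_counts(P[i, ] * length(cells), length(cells))
      pool <- cells
      for (j in sample(setdiff(seq_len(N_CLASS), i))) {
        if (quota[j] == 0L || length(pool) == 0L) next
        nb <- neighbour_count(cls, j)[pool]
        w <- 1 + adjacency_bias * nb
        take <- min(quota[j], length(pool))
        sel <- if (length(pool) == 1L) pool else
          pool[sample.int(length(pool), take, prob = w)]
        out[sel] <- j
        pool <- setdiff(pool, sel)
      }
    }
  })
  cat_raster(out, cell_size_of(lu_t0), attr(lu_t0, "class_labels"))
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: drivers, base-epoch map, next-epoch map and road
#' masks from one config.
#'
#' @param config A [synth_config].
#' @return List with `drivers`, `lu_t0`, `lu_t1`, `roads` (named masks) and
#'   the `config`.
#' @export
gen_world <- function(config = synth_config()) {
  drivers <- gen_drivers(config)
  lu_t0 <- gen_landuse(drivers, config)
  lu_t1 <- gen_next_epoch(lu_t0, config$true_transition, config$seed + 1L)
  masks <- attr(drivers, "masks")
  list(drivers = drivers, lu_t0 = lu_t0, lu_t1 = lu_t1,
       roads = masks[c("national_road", "provincial_road", "railway")],
       config = config)
}
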