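# The cellular-automaton allocator: Moore-neighbourhood effects, the
# adaptive inertia mechanism, conversion-cost masking, and seeded roulette
# competition iterated until every class count meets its projected demand.

#' Default neighbourhood factor parameters
#'
#' Per-class expansion weights of the neighbourhood effect, in class-code
#' order: cultivated 0.2, woodland 0.01, grassland 0.3, waters 0.4,
#' construction 1, unused 0.5. Values near 1 mark classes with strong
#' expansion capacity under human pressure.
#'
#' @return Named numeric vector of length 6.
#' @export
neighborhood_weights <- function() {
  stats::setNames(c(0.2, 0.01, 0.3, 0.4, 1, 0.5), land_classes())
}

#' Cellular-automaton configuration
#'
#' @param window Odd Moore window size `N` (default 3).
#' @param weights Per-class neighbourhood weights in `[0,1]`.
#' @param tol_frac Demand tolerance as a fraction of total valid cells
#'   (default 0.002).
#' @param max_iter Maximum allocation sweeps (default 300).
#' @param omega_floor Small floor added to the neighbourhood effect inside
#'   the allocator only, so a growing class with no neighbours anywhere is
#'   not an absorbing state (default 1e-4).
#' @param strict_inertia Use the printed form of the inertia update in the
#'   worsening-deficit case (ratio `D^{t-2}/D^{t-1}`) instead of the
#'   canonical amplifying form (see [update_inertia]).
#' @param inertia_clip Lower/upper clip of the inertia coefficient.
#' @return A `ca_config` list.
#' @export
ca_config <- function(window = 3L, weights = neighborhood_weights(),
                      tol_frac = 0.002, max_iter = 300L,
                      omega_floor = 1e-4, strict_inertia = FALSE,
                      inertia_clip = c(0.1, 10)) {
  if (window %% 2L != 1L || window < 3L) stop("window must be odd and >= 3")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0,1]")
  if (length(weights) != N_CLASS) stop("need one weight per class")
  structure(list(window = as.integer(window), weights = weights,
                 tol_frac = tol_frac, max_iter = as.integer(max_iter),
                 omega_floor = omega_floor, strict_inertia = strict_inertia,
                 inertia_clip = inertia_clip),
            class = "ca_config")
}

# sum of `m` over every non-centre offset of the (2h+1) window, zeros
# outside the grid
shift_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in -h:h) for (dc in -h:h) {
    if (dr == 0L && dc == 0L) next
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr
    ok_c <- cs >= 1L & cs <= nc
    acc[ok_r, ok_c] <- acc[ok_r, ok_c] + m[rs[ok_r], cs[ok_c], drop = FALSE]
  }
  acc
}

#' Neighbourhood effect of one land class
#'
#' The fraction of class-`k` cells in the Moore window around each cell
#' (centre excluded), scaled by the class's neighbourhood weight. Border
#' cells use the truncated window with their actual in-grid, non-nodata
#' neighbour count as denominator.
#'
#' @param lu A `cat_raster`.
#' @param k Class code or name.
#' @param cfg A [ca_config].
#' @return A `cont_raster` of effects in `[0, w_k]`.
#' @export
neighborhood_effect <- function(lu, k, cfg = ca_config()) {
  k <- class_code(k)
  h <- (cfg$window - 1L) %/% 2L
  ind <- matrix(0, nrow(lu), ncol(lu))
  ind[!is.na(lu) & lu == k] <- 1
  vld <- matrix(0, nrow(lu), ncol(lu))
  vld[!is.na(lu)] <- 1
  num <- shift_sum(ind, h)
  den <- shift_sum(vld, h)
  omega <- ifelse(den > 0, num / den, 0) * cfg$weights[k]
  cont_raster(omega, cell_size_of(lu))
}

#' Adaptive inertia update
#'
#' `d1` is the demand gap (demand minus current count) after the last
#' iteration, `d2` the gap one iteration earlier. The coefficient is
#' unchanged while the gap magnitude is not growing; a worsening surplus
#' (`d1 < d2 < 0`) shrinks it by `d2/d1`; a worsening deficit
#' (`0 < d2 < d1`) amplifies it by `d1/d2` (with `strict = TRUE`, by
#' `d2/d1`, the ratio as printed in the source equation, which would
#' suppress an under-allocated class). The result is clipped to `clip`.
#'
#' @param inertia Current coefficient(s), > 0.
#' @param d1,d2 Demand gaps at the last and second-to-last iteration.
#' @param strict Use the printed-equation ratio in the deficit case.
#' @param clip Two-element lower/upper bound.
#' @return Updated coefficient(s).
#' @export
update_inertia <- function(inertia, d1, d2, strict = FALSE,
                           clip = c(0.1, 10)) {
  out <- inertia
  case2 <- (abs(d1) > abs(d2)) & (d1 < d2) & (d2 < 0)
  case3 <- (abs(d1) > abs(d2)) & (0 < d2) & (d2 < d1)
  out[case2] <- inertia[case2] * d2[case2] / d1[case2]
  out[case3] <- if (strict) inertia[case3] * d2[case3] / d1[case3]
                else inertia[case3] * d1[case3] / d2[case3]
  pmin(pmax(out, clip[1L]), clip[2L])
}

#' Combined transition probability of one cell
#'
#' `TP_k = sp_k * omega_k * I_k` masked by the conversion-cost row of the
#' cell's current class (keeping the current class is always allowed). If
#' every entry is zero the cell retains its class (the allocator treats an
#' all-zero vector as "stay").
#'
#' @param sp Six suitability probabilities.
#' @param omega Six neighbourhood effects.
#' @param inertia Six inertia coefficients.
#' @param cost_row Binary allowance row of the current class.
#' @param current_class Current class code.
#' @return Numeric vector of six scores.
#' @export
combined_probability <- function(sp, omega, inertia, cost_row, current_class) {
  mask <- as.numeric(cost_row == 1)
  mask[current_class] <- 1
  as.numeric(sp * omega * inertia * mask)
}

# per-class omega over the full grid, as an (ncell x 6) matrix
omega_matrix <- function(lu, cfg, floor = 0) {
  out <- matrix(0, length(lu), N_CLASS)
  for (k in seq_len(N_CLASS))
    out[, k] <- as.vector(values_of(neighborhood_effect(lu, k, cfg)))
  if (floor > 0) out <- pmax(out, floor)
  out
}

#' Allocate projected demand onto the map by roulette competition
#'
#' Iterates: recompute neighbourhood effects and adaptive inertia, visit
#' the cells in a fresh seeded random order, and let each cell of an
#' over-demand class draw its next class by roulette over the combined
#' scores of the classes still under demand (cost-mask permitting). A class
#' whose count has met its demand is frozen: its cells are locked and it
#' leaves every candidate set. Stops when every class count is within
#' `tol_frac` of its demand, or after `max_iter` sweeps.
#'
#' @param lu Starting `cat_raster`.
#' @param surfaces A `suitability_surface` aligned with `lu`.
#' @param demand Integer per-class demand; must total the valid cell count.
#' @param scenario A `scenario_spec` (cost matrix).
#' @param cfg A [ca_config].
#' @param seed Integer seed.
#' @param max_iter Override of `cfg$max_iter`.
#' @return A `cat_raster` with attributes `converged` (logical),
#'   `iterations`, and `convergence` (per-iteration class-count data frame).
#' @export
roulette_allocate <- function(lu, surfaces, demand, scenario,
                              cfg = ca_config(), seed = 42L,
                              max_iter = NULL) {
  if (is.null(max_iter)) max_iter <- cfg$max_iter
  valid <- !is.na(lu) & surfaces$valid
  n_valid <- sum(valid)
  demand <- round(demand)
  if (length(demand) != N_CLASS) stop("demand must have 6 entries")
  if (sum(demand) != n_valid)
    stop("demand total (", sum(demand), ") must equal the valid cell count (",
         n_valid, ")")
  counts <- as.integer(tabulate(lu[valid], nbins = N_CLASS))
  cost <- scenario$cost_matrix
  growing <- which(demand > counts)
  for (k in growing) {
    if (all(cost[-k, k] == 0L))
      stop("infeasible demand: no class may convert to ",
           land_classes()[k], " under scenario '", scenario$name, "'")
  }
  sp_full <- matrix(0, length(lu), N_CLASS)
  sp_full[as.vector(surfaces$valid), ] <- surfaces$probs
  cls <- values_of(lu)
  cls[!valid] <- NA_integer_
  visit_pool <- which(as.vector(valid))
  inertia <- rep(1, N_CLASS)
  gap_prev <- demand - counts
  tol <- max(1, round(cfg$tol_frac * n_valid))
  log_rows <- list()
  iter <- 0L
  stalled <- 0L
  converged <- max(abs(gap_prev)) <= tol
  with_seed(seed, {
    while (!converged && iter < max_iter) {
      iter <- iter + 1L
      gap <- demand - counts
      inertia <- update_inertia(inertia, gap, gap_prev,
                                strict = cfg$strict_inertia,
                                clip = cfg$inertia_clip)
      gap_prev <- gap
      omega <- omega_matrix(cat_raster(cls, cell_size_of(lu)), cfg,
                            floor = cfg$omega_floor)
      visit <- sample(visit_pool)
      res <- ca_sweep(as.integer(as.vector(cls)), sp_full, omega, inertia,
                      cost, as.integer(demand), counts, as.integer(visit))
      cls <- matrix(res$classes, nrow(lu), ncol(lu))
      counts <- res$counts
      log_rows[[iter]] <- c(iteration = iter, counts,
                            max_gap = max(abs(demand - counts)))
      converged <- max(abs(demand - counts)) <= tol
      stalled <- if (res$changed == 0L) stalled + 1L else 0L
      if (stalled >= 25L && !converged) break    # persistent stall
    }
  })
  out <- cat_raster(cls, cell_size_of(lu), attr(lu, "class_labels"))
  conv <- if (length(log_rows)) {
    df <- as.data.frame(do.call(rbind, log_rows))
    names(df) <- c("iteration", land_classes(), "max_gap")
    df
  } else data.frame()
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "convergence") <- conv
  out
}

#' Simulate future land use under a scenario
#'
#' Composes the full chain: transition-matrix estimation (or a supplied
#' matrix), scenario probability edits, demand projection over `steps`
#' periods, neural-network suitability surfaces, and roulette allocation.
#' Fully reproducible given `seed`.
#'
#' @param lu_base Base-epoch map the simulation starts from.
#' @param drivers Driver stack aligned with `lu_base`.
#' @param scenario A `scenario_spec` (see [builtin_scenario]).
#' @param steps Demand projection steps (default 3).
#' @param seed Integer seed.
#' @param lu_prev Earlier epoch used to estimate the transition matrix
#'   (required unless `transition` is given).
#' @param transition Optional `transition_matrix` overriding estimation.
#' @param surface Optional precomputed `suitability_surface` (skips ANN
#'   training; useful when comparing scenarios on one landscape).
#' @param n_train,hidden_units,epochs ANN training controls.
#' @param cfg A [ca_config].
#' @return The allocated `cat_raster` (attributes as in
#'   [roulette_allocate], plus `demand`).
#' @export
simulate_landuse <- function(lu_base, drivers, scenario, steps = 3L,
                             seed = 42L, lu_prev = NULL, transition = NULL,
                             surface = NULL, n_train = 3000L,
                             hidden_units = 12L, epochs = 300L,
                             cfg = ca_config()) {
  if (is.null(transition)) {
    if (is.null(lu_prev))
      stop("either lu_prev or transition must be supplied")
    transition <- estimate_transition(lu_prev, lu_base)
  }
  P_s <- apply_scenario(transition, scenario)
  if (is.null(surface)) {
    train <- sample_training(lu_base, drivers, n_train, seed = seed + 11L)
    model <- fit_suitability(train, hidden_units = hidden_units,
                             seed = seed + 12L, epochs = epochs)
    surface <- predict_suitability(model, drivers)
  }
  valid <- !is.na(lu_base) & surface$valid
  counts <- tabulate(lu_base[valid], nbins = N_CLASS)
  demand <- round_demand(project_demand(counts, P_s, steps),
                         total = sum(counts))
  out <- roulette_allocate(lu_base, surface, demand, scenario, cfg,
                           seed = seed + 13L)
  attr(out, "demand") <- stats::setNames(demand, land_classes())
  out
}

#' Cell-wise agreement between two categorical maps
#'
#' Overall accuracy (trace over total) and Cohen's kappa with expected
#' agreement `p_e = sum_i row_i * col_i / n^2`.
#'
#' @param map_a,map_b Aligned `cat_raster` maps.
#' @return List with `confusion` (6x6 counts), `overall_accuracy`, `kappa`.
#' @export
agreement <- function(map_a, map_b) {
  check_aligned(map_a, map_b, "maps")
  ok <- !is.na(map_a) & !is.na(map_b)
  conf <- matrix(0, N_CLASS, N_CLASS,
                 dimnames = list(land_classes(), land_classes()))
  tb <- table(factor(map_a[ok], levels = seq_len(N_CLASS)),
              factor(map_b[ok], levels = seq_len(N_CLASS)))
  conf[] <- as.numeric(tb)
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  list(confusion = conf, overall_accuracy = po, kappa = kappa)
}
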