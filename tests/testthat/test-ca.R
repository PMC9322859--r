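test_that("neighbourhood effect counts Moore-window neighbours", {
  # centre cell ringed by 8 construction cells, weight 1 -> omega = 1
  m <- matrix(5L, 3, 3); m[2, 2] <- 1L
  lu <- cat_raster(m, 100)
  omega <- neighborhood_effect(lu, "construction")
  expect_equal(omega[2, 2], 1)
  # corner cell: truncated window, 2 of its 3 neighbours construction
  expect_equal(omega[1, 1], 2 / 3)
  # all-construction map: the truncated corner window is saturated -> 1
  expect_equal(neighborhood_effect(make_lu(5L), "construction")[1, 1], 1)

  # 4 of 8 neighbours grassland at weight 0.3 -> 0.5 * 0.3 = 0.15
  m2 <- matrix(1L, 3, 3)
  m2[cbind(c(1, 1, 3, 3), c(1, 3, 1, 3))] <- 3L
  omega2 <- neighborhood_effect(cat_raster(m2, 100), "grassland")
  expect_equal(omega2[2, 2], 0.15)

  # no neighbour of the class -> 0
  expect_equal(neighborhood_effect(lu, "waters")[2, 2], 0)
  expect_error(neighborhood_effect(lu, "swamp"), "unknown class")
})

test_that("adaptive inertia follows the three-case update", {
  # |D1| <= |D2|: unchanged
  expect_equal(update_inertia(1.7, -3, -4), 1.7)
  expect_equal(update_inertia(2.0, 0, 0), 2.0)
  # worsening surplus: shrink by D2/D1
  expect_equal(update_inertia(1, -8, -4), 0.5)
  # worsening deficit: amplify by D1/D2 (canonical form)
  expect_equal(update_inertia(1, 8, 4), 2.0)
  # printed-equation mode uses the literal ratio instead
  expect_equal(update_inertia(1, 8, 4, strict = TRUE), 0.5)
  # clipped to [0.1, 10]
  expect_equal(update_inertia(8, 80, 4), 10)
  expect_equal(update_inertia(0.3, -80, -4), 0.1)
  # vectorised over classes
  expect_equal(update_inertia(c(1, 1), c(-8, 8), c(-4, 4)), c(0.5, 2))
})

test_that("combined probability multiplies factors under the cost mask", {
  sp <- c(0.1, 0.5, 0.2, 0.1, 0.05, 0.05)
  omega <- c(0.2, 0.15, 0.1, 0.3, 0.4, 0.1)
  inertia <- c(1, 2, 1, 1, 1, 1)
  cost_row <- c(1, 1, 1, 1, 1, 1)
  tp <- combined_probability(sp, omega, inertia, cost_row, 1L)
  expect_equal(tp[2], 0.5 * 0.15 * 2)       # = 0.15
  # masking: only the current class survives an all-zero cost row
  blocked <- combined_probability(sp, omega, inertia, c(1, 0, 0, 0, 0, 0), 1L)
  expect_true(all(blocked[-1] == 0) && blocked[1] > 0)
  # doubling one inertia doubles that class's score only
  tp2 <- combined_probability(sp, omega, inertia * c(1, 2, 1, 1, 1, 1),
                              cost_row, 1L)
  expect_equal(tp2[2], 2 * tp[2])
  expect_equal(tp2[-2], tp[-2])
})

test_that("allocation is a no-op when demand equals current counts", {
  w <- small_world()
  lu <- w$lu_t1
  demand <- class_counts(lu)
  out <- roulette_allocate(lu, flat_surface(lu), demand,
                           builtin_scenario("natural"), seed = 5L)
  expect_identical(out[, ], lu[, ])
  expect_true(attr(out, "converged"))
  expect_identical(attr(out, "iterations"), 0L)
})

test_that("allocation moves the demanded number of cells on a two-class toy", {
  set.seed(8)
  m <- matrix(ifelse(matrix(runif(2500), 50, 50) < 0.6, 1L, 5L), 50, 50)
  lu <- cat_raster(m, 100)
  counts <- class_counts(lu)
  demand <- counts
  demand[1] <- demand[1] - 100L     # shift 100 cells cultivated -> construction
  demand[5] <- demand[5] + 100L
  out <- roulette_allocate(lu, flat_surface(lu), demand,
                           builtin_scenario("natural"), seed = 9L)
  tol <- max(1, round(0.002 * sum(counts)))
  expect_lte(max(abs(class_counts(out) - demand)), tol)
  expect_identical(sum(class_counts(out)), sum(counts))
})

test_that("cost-forbidden conversions never happen", {
  w <- small_world()
  lu <- w$lu_t1
  counts <- class_counts(lu)
  demand <- counts
  demand[1] <- demand[1] - 60L
  demand[2] <- demand[2] + 30L      # woodland may only gain from waters/unused
  demand[5] <- demand[5] + 30L
  spec <- builtin_scenario("natural")
  out <- roulette_allocate(lu, flat_surface(lu), demand, spec, seed = 10L)
  cross <- table(factor(lu[!is.na(lu)], levels = 1:6),
                 factor(out[!is.na(out)], levels = 1:6))
  expect_equal(sum(cross * (1 - spec$cost_matrix)), 0)
})

test_that("the cell total is conserved at every iteration", {
  w <- small_world()
  lu <- w$lu_t1
  counts <- class_counts(lu)
  demand <- round_demand(project_demand(counts,
    apply_scenario(estimate_transition(w$lu_t0, lu),
                   builtin_scenario("natural")), 3), total = sum(counts))
  out <- roulette_allocate(lu, flat_surface(lu), demand,
                           builtin_scenario("natural"), seed = 11L)
  conv <- attr(out, "convergence")
  expect_gt(nrow(conv), 0)
  totals <- rowSums(conv[, land_classes()])
  expect_true(all(totals == sum(counts)))
})

test_that("infeasible demand is rejected, naming the class", {
  w <- small_world()
  lu <- w$lu_t1
  demand <- class_counts(lu)
  demand[1] <- demand[1] - 50L
  demand[6] <- demand[6] + 50L      # nothing may convert to unused (natural)
  expect_error(roulette_allocate(lu, flat_surface(lu), demand,
                                 builtin_scenario("natural"), seed = 1L),
               "unused")
  expect_error(roulette_allocate(lu, flat_surface(lu),
                                 class_counts(lu) + 5L,
                                 builtin_scenario("natural"), seed = 1L),
               "total")
})

test_that("simulation composes the stages and is reproducible", {
  w <- small_world()
  # identity transition under the natural scenario: demand = current counts,
  # so the output is the base map
  out <- simulate_landuse(w$lu_t1, w$drivers, builtin_scenario("natural"),
                          steps = 3, seed = 3L,
                          transition = transition_matrix(diag(6)),
                          surface = flat_surface(w$lu_t1))
  expect_identical(out[, ], w$lu_t1[, ])

  s1 <- simulate_landuse(w$lu_t1, w$drivers, builtin_scenario("natural"),
                         steps = 2, seed = 23L, lu_prev = w$lu_t0,
                         n_train = 800L, epochs = 100L)
  s2 <- simulate_landuse(w$lu_t1, w$drivers, builtin_scenario("natural"),
                         steps = 2, seed = 23L, lu_prev = w$lu_t0,
                         n_train = 800L, epochs = 100L)
  expect_identical(s1[, ], s2[, ])
  expect_error(simulate_landuse(w$lu_t1, w$drivers,
                                builtin_scenario("natural")),
               "lu_prev or transition")
})

test_that("ecological protection curbs construction growth", {
  w <- small_world()
  P <- estimate_transition(w$lu_t0, w$lu_t1)
  surf <- local({
    train <- sample_training(w$lu_t1, w$drivers, 1500L, seed = 61L)
    predict_suitability(fit_suitability(train, seed = 62L, epochs = 150L),
                        w$drivers)
  })
  grow <- function(spec) {
    out <- simulate_landuse(w$lu_t1, w$drivers, spec, steps = 3, seed = 63L,
                            transition = P, surface = surf)
    class_counts(out)[5] - class_counts(w$lu_t1)[5]
  }
  expect_lt(grow(builtin_scenario("ecological_protection")),
            grow(builtin_scenario("natural")))
})

test_that("agreement returns exact accuracy and kappa on hand cases", {
  w <- small_world()
  self <- agreement(w$lu_t1, w$lu_t1)
  expect_equal(self$overall_accuracy, 1)
  expect_equal(self$kappa, 1)

  # 2-class confusion [[45,5],[15,35]] -> OA 0.80, pe 0.50, kappa 0.60
  a <- cat_raster(matrix(rep(c(1L, 2L), c(50L, 50L)), 10, 10), 100)
  b <- cat_raster(matrix(rep(c(1L, 2L, 1L, 2L), c(45L, 5L, 15L, 35L)),
                         10, 10), 100)
  res <- agreement(a, b)
  expect_equal(res$confusion[1:2, 1:2],
               matrix(c(45, 15, 5, 35), 2, 2), ignore_attr = TRUE)
  expect_equal(res$overall_accuracy, 0.80)
  expect_equal(res$kappa, 0.60)
  expect_error(agreement(a, make_lu(1L, 4L, 4L)), "shape")
})

test_that("label permutation with matched marginals gives kappa near zero", {
  set.seed(77)
  m <- matrix(sample(1:6, 10000, TRUE, prob = c(0.4, 0.2, 0.2, 0.1, 0.05, 0.05)),
              100, 100)
  a <- cat_raster(m, 100)
  b <- cat_raster(matrix(sample(as.vector(m)), 100, 100), 100)
  expect_lt(abs(agreement(a, b)$kappa), 0.05)
})

test_that("kappa never exceeds overall accuracy when chance agreement > 0", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- cat_raster(matrix(sample(1:6, 400, TRUE), 20, 20), 100)
    b <- cat_raster(matrix(sample(1:6, 400, TRUE), 20, 20), 100)
    res <- agreement(a, b)
    expect_lte(res$kappa, res$overall_accuracy + 1e-12)
  }
})
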