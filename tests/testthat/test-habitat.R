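test_that("threat masks are derived from the map with Table parameters", {
  w <- small_world()
  th <- build_threat_masks(w$lu_t1, w$roads)
  expect_setequal(names(th), c("cultivated", "construction", "national_road",
                               "provincial_road", "railway"))
  counts <- class_counts(w$lu_t1)
  expect_equal(sum(th$cultivated$mask), unname(counts["cultivated"]))
  expect_equal(sum(th$construction$mask), unname(counts["construction"]))
  expect_equal(th$construction$d_max_km, 10)
  expect_equal(th$construction$decay, "exponential")
  expect_equal(th$cultivated$weight, 0.7)

  # no construction cells -> that threat is skipped entirely
  lu_nc <- make_lu(c(1L, 2L, 3L), 6L, 6L)
  expect_false("construction" %in% names(build_threat_masks(lu_nc)))
  # all-cultivated map -> mask covers every valid cell
  all_c <- build_threat_masks(make_lu(1L, 5L, 5L))
  expect_true(all(all_c$cultivated$mask))
  expect_error(build_threat_masks(w$lu_t1,
                                  list(railway = matrix(TRUE, 2, 2))),
               "shape")
})

test_that("impact kernels decay as specified", {
  mask <- matrix(FALSE, 9, 41); mask[5, 1] <- TRUE
  lin <- structure(list(name = "cultivated", mask = mask, d_max_km = 3,
                        weight = 0.7, decay = "linear"),
                   class = "threat_source")
  i <- threat_impact(lin, 100)
  expect_equal(i[5, 1], 1)                  # source cell
  expect_equal(i[5, 11], 1 - 1 / 3)         # 1 km of a 3 km range -> 2/3
  expect_equal(i[5, 31], 0)                 # exactly at d_max
  expect_equal(i[5, 41], 0)                 # beyond d_max

  ex <- structure(list(name = "construction", mask = mask, d_max_km = 2,
                       weight = 1, decay = "exponential"),
                  class = "threat_source")
  ie <- threat_impact(ex, 100)
  expect_equal(ie[5, 1], 1)
  expect_equal(ie[5, 11], exp(-2.99 * 0.5))   # 1 km of a 2 km range
  expect_equal(ie[5, 31], 0)                  # 3 km: beyond d_max
  expect_error(threat_impact(structure(list(name = "x",
    mask = matrix(FALSE, 3, 3), d_max_km = 1, weight = 1, decay = "linear"),
    class = "threat_source"), 100), "empty")
})

test_that("the worked degradation-to-quality chain reproduces hand values", {
  # lone cultivated cell; woodland cell exactly 1 km away; no other threats
  m <- matrix(2L, 9, 21)
  m[5, 3] <- 1L
  lu <- cat_raster(m, 100)
  th <- build_threat_masks(lu)            # cultivated only (no construction)
  expect_named(th, "cultivated")
  D <- habitat_degradation(lu, th)
  # weight share 1, impact 2/3, sensitivity woodland-to-cultivated 0.8
  expect_equal(D[5, 13], 2 / 3 * 0.8, tolerance = 1e-9)
  expect_equal(round(D[5, 13], 4), 0.5333)
  Q <- habitat_quality(D, lu, k = 0.5)
  expect_equal(Q[5, 13], 1 * (1 - D[5, 13]^2 / (D[5, 13]^2 + 0.25)))
  expect_equal(round(Q[5, 13], 4), 0.4678)
})

test_that("degradation is zero without threats and on zero-sensitivity classes", {
  lu <- make_lu(c(2L, 3L), 6L, 6L)
  D0 <- habitat_degradation(lu, list())
  expect_true(all(D0[, ] == 0))

  m <- matrix(1L, 7, 7); m[4, 4] <- 5L
  lu2 <- cat_raster(m, 100)
  D <- habitat_degradation(lu2, build_threat_masks(lu2))
  expect_equal(D[4, 4], 0)       # construction row is all-zero sensitivity
  expect_true(all(D[, ] >= 0 & D[, ] <= 1))
})

test_that("quality obeys its closed form and guards its domain", {
  lu <- make_lu(c(2L, 5L), 6L, 6L)        # woodland (H=1), construction (H=0)
  D0 <- cont_raster(matrix(0, 6, 6), 100)
  Q0 <- habitat_quality(D0, lu)
  H <- sensitivity_table()$H
  expect_equal(Q0[lu[, ] == 2L], rep(1, sum(lu[, ] == 2L)))   # Q = H at D = 0
  expect_true(all(Q0[lu[, ] == 5L] == 0))                     # H = 0 -> Q = 0

  Dk <- cont_raster(matrix(0.5, 6, 6), 100)                   # D = k
  Qk <- habitat_quality(Dk, lu, k = 0.5)
  expect_equal(Qk[lu[, ] == 2L], rep(0.5, sum(lu[, ] == 2L))) # Q = H/2
  expect_error(habitat_quality(D0, lu, k = 0), "k must be")
  expect_error(habitat_quality(D0, lu, k = -1), "k must be")
})

test_that("grading uses left-closed bins with a closed top bin", {
  Q <- cont_raster(matrix(c(0, 0.35, 0.4, 0.59, 0.6, 0.79, 0.8, 1, 0.2),
                          3, 3), 100)
  g <- grade_quality(Q)
  labels <- attr(g, "grade_labels")[g[, ]]
  expect_equal(labels[1:8], c("poor", "poor", "moderate", "moderate",
                              "good", "good", "excellent", "excellent"))
})

test_that("quality summaries report means and grade shares", {
  Qc <- cont_raster(matrix(0.7, 5, 5), 100)
  s <- summarize_quality(Qc)
  expect_equal(s$mean_quality, 0.7)
  expect_equal(unname(s$grade_shares["good"]), 100)

  chk <- matrix(0.2, 6, 6)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 0.9
  s2 <- summarize_quality(cont_raster(chk, 100))
  expect_equal(s2$mean_quality, 0.55)
  expect_equal(unname(s2$grade_shares), c(50, 0, 0, 50))
  expect_equal(sum(s2$grade_shares), 100, tolerance = 1e-9)

  w <- small_world()
  hq <- assess_habitat(w$lu_t1, w$roads)
  s3 <- summarize_quality(hq$quality, hq$grades, w$lu_t1)
  expect_equal(sum(s3$grade_shares), 100, tolerance = 1e-9)
  expect_equal(unname(s3$class_mean_quality[c("construction", "unused")]),
               c(0, 0))
})

test_that("growing a threat's footprint never raises quality anywhere", {
  # with the threat table fixed (Eq. 5 normalises weights over the active
  # set), enlarging any source mask can only increase degradation
  w <- small_world()
  before <- assess_habitat(w$lu_t1, w$roads)
  denser <- w$roads
  denser$railway <- denser$railway | gen_roads(dim(w$lu_t1), 2L, seed = 404L)
  after <- assess_habitat(w$lu_t1, denser)
  ok <- !is.na(after$quality)
  expect_true(all(after$quality[ok] <= before$quality[ok] + 1e-12))
  expect_true(any(after$quality[ok] < before$quality[ok]))
})

test_that("quality is bounded by suitability, tight exactly at D = 0", {
  w <- small_world()
  hq <- assess_habitat(w$lu_t1, w$roads)
  H <- sensitivity_table()$H[w$lu_t1[, ]]
  ok <- !is.na(hq$quality)
  expect_true(all(hq$quality[ok] <= H[ok] + 1e-12))
  at_zero <- ok & hq$degradation[, ] == 0
  expect_equal(hq$quality[at_zero], unname(H[at_zero]))
  pos <- ok & hq$degradation[, ] > 0
  expect_true(all(hq$quality[pos] < H[pos] | H[pos] == 0))
})

test_that("halving the half-saturation constant strictly lowers quality", {
  w <- small_world()
  th <- build_threat_masks(w$lu_t1, w$roads)
  D <- habitat_degradation(w$lu_t1, th)
  Q1 <- habitat_quality(D, w$lu_t1, k = 0.5)
  Q2 <- habitat_quality(D, w$lu_t1, k = 0.25)
  sel <- !is.na(D) & D[, ] > 0 & sensitivity_table()$H[w$lu_t1[, ]] > 0
  expect_true(all(Q2[sel] < Q1[sel]))
})
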