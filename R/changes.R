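# Cross-tabulation change accounting: area-flow matrices between epochs,
# per-class gains/losses, percent change, the single-land-use dynamic
# degree, and flow-share attribution of each class's growth.

#' Cross-tabulate two epochs into an area-flow matrix
#'
#' Entry (i, j) is the area (km^2) of cells moving from class i to class j
#' over cells valid in both maps.
#'
#' @param lu_t0,lu_t1 Aligned `cat_raster` maps.
#' @param cell_size Cell edge in metres (default taken from the maps).
#' @return 6x6 labelled matrix in km^2.
#' @export
cross_tabulate <- function(lu_t0, lu_t1, cell_size = cell_size_of(lu_t0)) {
  check_aligned(lu_t0, lu_t1, "epoch maps")
  ok <- !is.na(lu_t0) & !is.na(lu_t1)
  m <- matrix(0, N_CLASS, N_CLASS,
              dimnames = list(land_classes(), land_classes()))
  tb <- table(factor(lu_t0[ok], levels = seq_len(N_CLASS)),
              factor(lu_t1[ok], levels = seq_len(N_CLASS)))
  m[] <- as.numeric(tb)
  m * (cell_size / 1000)^2
}

#' Summarise an area-flow matrix into change accounts
#'
#' For each class: area at both epochs (row/column totals), the area
#' decrease (off-diagonal row sum) and increase (off-diagonal column sum),
#' net change, percent change over the period, and the annualised dynamic
#' degree `K = (U_t1 - U_t0) / U_t0 * 100 / T` (%/yr). Flow shares give the
#' fraction of each class's gain sourced from each donor class.
#'
#' @param area_matrix Square nonnegative flow matrix (km^2), rows = from.
#' @param period_years Period length in years (for the dynamic degree).
#' @return A `change_summary`: list with `by_class` (data frame) and
#'   `flow_shares` (matrix, columns = gaining class, entries sum to 1 over
#'   donors).
#' @export
summarize_changes <- function(area_matrix, period_years = NA_real_) {
  m <- as.matrix(area_matrix)
  if (nrow(m) != ncol(m)) stop("area matrix must be square")
  if (any(m < 0)) stop("area matrix must be nonnegative")
  t0 <- rowSums(m)
  t1 <- colSums(m)
  dec <- t0 - diag(m)
  inc <- t1 - diag(m)
  pct <- ifelse(t0 > 0, (t1 - t0) / t0 * 100, NA_real_)
  dyn <- if (is.na(period_years)) rep(NA_real_, length(t0))
         else pct / period_years
  shares <- sweep(m - diag(diag(m)), 2L, ifelse(inc > 0, inc, NA_real_), `/`)
  by_class <- data.frame(
    class = rownames(m) %||% as.character(seq_len(nrow(m))),
    area_t0 = t0, area_t1 = t1, area_decrease = dec, area_increase = inc,
    net_change = t1 - t0, percent_change = pct, dynamic_degree = dyn,
    row.names = NULL)
  structure(list(by_class = by_class, flow_shares = shares,
                 period_years = period_years),
            class = "change_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.change_summary <- function(x, ...) {
  cat("<change_summary>\n")
  df <- x$by_class
  df[-1L] <- lapply(df[-1L], round, 2)
  print(df)
  invisible(x)
}

#' Compare scenario maps against a base map
#'
#' Per scenario and class: area delta (km^2) and percent change relative to
#' the base map.
#'
#' @param base_lu Base `cat_raster`.
#' @param scenario_maps Named list of aligned `cat_raster` maps.
#' @param cell_size Cell edge in metres.
#' @return Data frame with columns `scenario`, `class`, `area_base`,
#'   `area_scenario`, `delta_km2`, `percent_change`.
#' @export
compare_scenarios <- function(base_lu, scenario_maps,
                              cell_size = cell_size_of(base_lu)) {
  a_base <- class_counts(base_lu) * (cell_size / 1000)^2
  rows <- lapply(names(scenario_maps), function(nm) {
    lu <- scenario_maps[[nm]]
    check_aligned(base_lu, lu, "scenario maps")
    a <- class_counts(lu) * (cell_size / 1000)^2
    data.frame(scenario = nm, class = land_classes(),
               area_base = as.numeric(a_base), area_scenario = as.numeric(a),
               delta_km2 = as.numeric(a - a_base),
               percent_change = ifelse(a_base > 0,
                                       as.numeric(a - a_base) / a_base * 100,
                                       NA_real_),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Packaged 2000-2020 area-flow matrix of the study region
#'
#' The published decadal-scale land-use transition matrix (km^2) of a
#' plains urban agglomeration, shipped as a CSV fixture so its margin
#' identities serve as a permanent regression test of the change
#' accounting.
#'
#' @return 6x6 labelled matrix in km^2.
#' @export
reference_flow_matrix <- function() {
  path <- system.file("extdata", "guanzhong_flow_2000_2020.csv",
                      package = "lusim", mustWork = TRUE)
  as.matrix(utils::read.csv(path, check.names = FALSE, row.names = 1L))
}
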