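# Markov chain demand stage: estimate a transition matrix from a pair of
# maps, edit it under a named policy scenario, and project per-class demand
# forward by iterating the one-step map S_{t+1} = S_t P (rows = source
# class, columns = destination; demand propagates as column sums of flows).

#' Construct a transition matrix
#'
#' @param probs Square row-stochastic matrix (rows = from, cols = to).
#' @param counts Optional matching matrix of cell counts.
#' @param period_years Period length the matrix spans (metadata).
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(probs, counts = NULL, period_years = NA_integer_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("transition matrix must be square")
  check_row_stochastic(probs)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!identical(dim(counts), dim(probs)))
      stop("counts must match probs in shape")
    if (any(counts < 0)) stop("counts must be nonnegative")
  }
  structure(list(probs = probs, counts = counts,
                 period_years = period_years),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, period %s years\n",
              nrow(x$probs), format(x$period_years)))
  print(round(x$probs, 4))
  invisible(x)
}

check_row_stochastic <- function(P, tol = 1e-6) {
  if (any(P < -tol)) stop("transition matrix has negative entries")
  bad <- which(abs(rowSums(P) - 1) > tol)
  if (length(bad) > 0L)
    stop("transition matrix rows must sum to 1 (rows ",
         paste(bad, collapse = ", "), ")")
  invisible(TRUE)
}

#' Estimate the land-use transition matrix from two epochs
#'
#' Counts class-to-class moves over cells valid in both maps and
#' row-normalises. A class absent at the base epoch gets an identity
#' (self-loop) row.
#'
#' @param lu_t0,lu_t1 Aligned `cat_raster` maps.
#' @param period_years Metadata stored on the result.
#' @return A `transition_matrix` with both `probs` and `counts`.
#' @export
estimate_transition <- function(lu_t0, lu_t1, period_years = NA_integer_) {
  check_aligned(lu_t0, lu_t1, "epoch maps")
  ok <- !is.na(lu_t0) & !is.na(lu_t1)
  counts <- matrix(0, N_CLASS, N_CLASS,
                   dimnames = list(land_classes(), land_classes()))
  tb <- table(factor(lu_t0[ok], levels = seq_len(N_CLASS)),
              factor(lu_t1[ok], levels = seq_len(N_CLASS)))
  counts[] <- as.numeric(tb)
  probs <- counts / pmax(rowSums(counts), 1)
  empty <- rowSums(counts) == 0
  probs[empty, ] <- diag(N_CLASS)[empty, , drop = FALSE]
  transition_matrix(probs, counts, period_years)
}

#' Project per-class demand forward
#'
#' Applies the one-step map `steps` times: `S_{t+n} = S_t P^n`. The total is
#' conserved exactly by row-stochasticity.
#'
#' @param S_t Nonnegative per-class vector (cells or km^2).
#' @param P A `transition_matrix` (or bare row-stochastic matrix).
#' @param steps Number of applications (>= 1; three five-year planning steps
#'   in the intended workflow).
#' @return Numeric demand vector, same length and names as `S_t`.
#' @export
project_demand <- function(S_t, P, steps = 1L) {
  if (inherits(P, "transition_matrix")) P <- P$probs
  check_row_stochastic(P)
  if (steps < 1L) stop("steps must be >= 1")
  if (length(S_t) != nrow(P)) stop("demand vector length must match matrix")
  if (any(S_t < 0)) stop("demand entries must be nonnegative")
  S <- as.numeric(S_t)
  for (i in seq_len(steps)) S <- as.numeric(S %*% P)
  stats::setNames(S, rownames(P))
}

# largest-remainder integer apportionment of nonnegative weights to `total`
apportion_counts <- function(x, total) {
  x <- pmax(as.numeric(x), 0)
  if (sum(x) == 0) x <- rep(1, length(x))
  q <- x / sum(x) * total
  base <- floor(q)
  left <- as.integer(round(total - sum(base)))
  if (left > 0L) {
    take <- order(q - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Round a demand vector to integers conserving the total
#'
#' Largest-remainder apportionment so the rounded counts sum exactly to
#' `total` (the valid-cell count the allocator must conserve).
#'
#' @param S Nonnegative demand vector.
#' @param total Required integer sum (default `round(sum(S))`).
#' @return Named integer vector.
#' @export
round_demand <- function(S, total = round(sum(S))) {
  stats::setNames(apportion_counts(S, as.integer(total)), names(S))
}

# ---------------------------------------------------------------------------
# Scenarios

#' Construct a scenario specification
#'
#' A scenario is a set of multiplicative edits to off-diagonal transfer
#' probabilities plus a binary conversion-cost matrix (1 = conversion
#' allowed). Probability mass removed (or added) by an edit is absorbed by
#' the row's diagonal, so restricted land stays in place.
#'
#' @param name Scenario name.
#' @param prob_edits Data frame with columns `from`, `to` (class codes or
#'   names) and `multiplier` (>= 0).
#' @param cost_matrix 6x6 binary matrix, diagonal all 1.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, prob_edits = NULL, cost_matrix = NULL) {
  if (is.null(cost_matrix)) cost_matrix <- matrix(1L, N_CLASS, N_CLASS)
  cost_matrix <- as.matrix(cost_matrix)
  storage.mode(cost_matrix) <- "integer"
  if (!all(cost_matrix %in% c(0L, 1L))) stop("cost matrix must be binary")
  if (any(diag(cost_matrix) != 1L))
    stop("cost matrix diagonal must be all 1 (a class may keep itself)")
  dimnames(cost_matrix) <- list(land_classes(), land_classes())
  if (!is.null(prob_edits)) {
    prob_edits$from <- class_code(prob_edits$from)
    prob_edits$to <- class_code(prob_edits$to)
    if (any(prob_edits$from == prob_edits$to))
      stop("scenario edits must reference off-diagonal entries only")
    if (any(prob_edits$multiplier < 0)) stop("multipliers must be >= 0")
  }
  structure(list(name = name, prob_edits = prob_edits,
                 cost_matrix = cost_matrix),
            class = "scenario_spec")
}

class_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1L | x > N_CLASS)) stop("class code outside 1..6")
    return(x)
  }
  m <- match(as.character(x), land_classes())
  if (any(is.na(m))) stop("unknown class name: ",
                          paste(x[is.na(m)], collapse = ", "))
  m
}

edits_df <- function(...) {
  e <- list(...)
  data.frame(from = vapply(e, `[[`, "", 1L),
             to = vapply(e, `[[`, "", 2L),
             multiplier = as.numeric(vapply(e, `[[`, "", 3L)))
}

# Conversion-cost matrices of the three built-in scenarios
# (rows = from, cols = to; class order cultivated, woodland, grassland,
# waters, construction, unused).
builtin_cost <- function(name) {
  m <- switch(name,
    natural = rbind(
      c(1, 0, 0, 0, 1, 0),
      c(1, 1, 0, 0, 1, 0),
      c(1, 0, 1, 0, 1, 0),
      c(1, 1, 1, 1, 1, 0),
      c(0, 0, 0, 0, 1, 0),
      c(1, 1, 1, 1, 1, 1)),
    cultivated_protection = rbind(
      c(1, 0, 0, 0, 0, 0),
      c(1, 1, 1, 0, 1, 1),
      c(1, 1, 1, 1, 1, 1),
      c(1, 0, 1, 1, 1, 1),
      c(0, 0, 0, 0, 1, 0),
      c(1, 1, 1, 1, 1, 1)),
    ecological_protection = rbind(
      c(1, 1, 1, 1, 1, 0),
      c(0, 1, 0, 0, 0, 0),
      c(0, 1, 1, 1, 0, 0),
      c(0, 0, 1, 1, 0, 0),
      c(0, 0, 0, 0, 1, 0),
      c(1, 1, 1, 1, 1, 1)),
    stop("unknown scenario: ", name))
  dimnames(m) <- list(land_classes(), land_classes())
  m
}

#' Built-in policy scenarios
#'
#' Three named scenarios: `natural` (no probability edits),
#' `cultivated_protection` (cultivated-to-construction transfer cut 40%,
#' cultivated-to-woodland cut 30%), and `ecological_protection` (woodland/
#' grassland transfers to construction cut 80% and to unused land cut 100%,
#' waters-to-construction cut 80%, cultivated-to-woodland raised 30%,
#' cultivated-to-construction cut 30%), each with its binary conversion-cost
#' matrix.
#'
#' @param name One of `"natural"`, `"cultivated_protection"`,
#'   `"ecological_protection"`.
#' @return A `scenario_spec`.
#' @export
builtin_scenario <- function(name = c("natural", "cultivated_protection",
                                      "ecological_protection")) {
  name <- match.arg(name)
  edits <- switch(name,
    natural = NULL,
    cultivated_protection = edits_df(
      list("cultivated", "construction", "0.6"),
      list("cultivated", "woodland", "0.7")),
    ecological_protection = edits_df(
      list("woodland", "construction", "0.2"),
      list("grassland", "construction", "0.2"),
      list("woodland", "unused", "0"),
      list("grassland", "unused", "0"),
      list("waters", "construction", "0.2"),
      list("cultivated", "woodland", "1.3"),
      list("cultivated", "construction", "0.7")))
  scenario_spec(name, edits, builtin_cost(name))
}

#' Apply a scenario's probability edits to a transition matrix
#'
#' Each edited off-diagonal entry is multiplied by its factor; the row's
#' mass change is absorbed by the diagonal (self-retention). If an increase
#' would drive the diagonal negative, entries are clipped at 0 and the row
#' renormalised.
#'
#' @param P A `transition_matrix`.
#' @param spec A `scenario_spec`.
#' @return A new `transition_matrix` (counts dropped).
#' @export
apply_scenario <- function(P, spec) {
  probs <- P$probs
  if (!is.null(spec$prob_edits)) for (r in seq_len(nrow(spec$prob_edits))) {
    i <- spec$prob_edits$from[r]; j <- spec$prob_edits$to[r]
    mult <- spec$prob_edits$multiplier[r]
    delta <- probs[i, j] * (mult - 1)
    probs[i, j] <- probs[i, j] * mult
    probs[i, i] <- probs[i, i] - delta
  }
  for (i in seq_len(nrow(probs))) if (probs[i, i] < 0) {
    probs[i, ] <- pmax(probs[i, ], 0)
    probs[i, ] <- probs[i, ] / sum(probs[i, ])
  }
  transition_matrix(probs, period_years = P$period_years)
}

#' Read / write a labelled transition-matrix CSV
#'
#' @param path CSV path; class names as header row and first column.
#' @return For `read_transition_csv`, a `transition_matrix` when entries are
#'   row-stochastic, otherwise the bare labelled matrix (area variants).
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (all(abs(rowSums(m) - 1) < 1e-6)) transition_matrix(m) else m
}

#' @rdname read_transition_csv
#' @param m Matrix or `transition_matrix` to write.
#' @export
write_transition_csv <- function(m, path) {
  if (inherits(m, "transition_matrix")) m <- m$probs
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
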