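# Land suitability surfaces from a single-hidden-layer neural network:
# sigmoid hidden units fed by the normalised drivers, one output unit per
# land class, per-cell renormalisation so the six class probabilities form a
# simplex (the roulette competition downstream needs comparable scores).
# Implemented from scratch (no neural-net package is available in the
# target environment): full-batch Adam on the multinomial cross-entropy.

#' Sample training cells from a map and its drivers
#'
#' Proportional stratified random sampling over classes: each present class
#' is represented in proportion to its prevalence with a minimum of 10 cells
#' (all cells, with a warning, when a class has fewer). `stratified = FALSE`
#' falls back to uniform random sampling of valid cells.
#'
#' @param lu A `cat_raster`.
#' @param drivers A [driver_stack] aligned with `lu`.
#' @param n Number of cells to sample (<= valid cell count).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default) or sample uniformly.
#' @return Data frame: one column per driver (normalised values) plus
#'   `class` (integer code).
#' @export
sample_training <- function(lu, drivers, n, seed = 42L, stratified = TRUE) {
  if (!identical(dim(lu), dim(drivers$valid)))
    stop("map and drivers have mismatched shapes")
  valid <- !is.na(lu) & drivers$valid
  idx_all <- which(valid)
  if (n > length(idx_all))
    stop("n exceeds the number of valid cells (", length(idx_all), ")")
  cls_all <- lu[idx_all]
  sel <- with_seed(seed, {
    if (!stratified) {
      sort(sample(idx_all, n))
    } else if (n == length(idx_all)) {
      idx_all
    } else {
      present <- sort(unique(cls_all))
      quota <- apportion_counts(tabulate(cls_all, N_CLASS)[present], n)
      quota <- pmax(quota, 10L)
      out <- integer(0)
      for (s in seq_along(present)) {
        pool <- idx_all[cls_all == present[s]]
        if (length(pool) < quota[s]) {
          warning("class ", land_classes()[present[s]], " has only ",
                  length(pool), " cells; taking all")
          out <- c(out, pool)
        } else {
          out <- c(out, sample(pool, quota[s]))
        }
      }
      sort(out)
    }
  })
  feat <- vapply(driver_names(), function(d) drivers$normalized[[d]][sel],
                 numeric(length(sel)))
  df <- as.data.frame(feat)
  df$class <- as.integer(lu[sel])
  df
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the suitability network
#'
#' @param training Data frame from [sample_training] (driver columns +
#'   `class`).
#' @param hidden_units Hidden-layer width (default 12, roughly driver count
#'   + class count, the common setting for this model family).
#' @param seed Integer seed (weights initialisation); default 42.
#' @param epochs Full-batch Adam epochs.
#' @param learning_rate Adam step size.
#' @return A `suitability_model` (weights, layer sizes, driver names, class
#'   codes present in training).
#' @export
fit_suitability <- function(training, hidden_units = 12L, seed = 42L,
                            epochs = 300L, learning_rate = 0.05) {
  feats <- setdiff(names(training), "class")
  X <- as.matrix(training[, feats, drop = FALSE])
  y <- as.integer(training$class)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("training data contain a single class; cannot fit")
  m <- length(classes)
  Y <- matrix(0, nrow(X), m)
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  d <- ncol(X); H <- as.integer(hidden_units)
  n <- nrow(X)
  with_seed(seed, {
    W1 <- matrix(stats::runif(d * H, -0.5, 0.5), d, H) / sqrt(d)
    b1 <- rep(0, H)
    W2 <- matrix(stats::runif(H * m, -0.5, 0.5), H, m) / sqrt(H)
    b2 <- rep(0, m)
    pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mom <- lapply(pars, function(p) p * 0)
    vel <- lapply(pars, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
    for (ep in seq_len(epochs)) {
      Z <- sigmoid(sweep(X %*% pars$W1, 2L, pars$b1, `+`))
      Pr <- softmax_rows(sweep(Z %*% pars$W2, 2L, pars$b2, `+`))
      dO <- (Pr - Y) / n
      dZ <- (dO %*% t(pars$W2)) * Z * (1 - Z)
      grad <- list(W1 = t(X) %*% dZ, b1 = colSums(dZ),
                   W2 = t(Z) %*% dO, b2 = colSums(dO))
      for (nm in names(pars)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^ep)
        vhat <- vel[[nm]] / (1 - beta2^ep)
        pars[[nm]] <- pars[[nm]] - learning_rate * mhat / (sqrt(vhat) + epsa)
      }
    }
    structure(list(W1 = pars$W1, b1 = pars$b1, W2 = pars$W2, b2 = pars$b2,
                   hidden_units = H, features = feats, classes = classes),
              class = "suitability_model")
  })
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("<suitability_model> %d drivers -> %d hidden -> %d classes\n",
              length(x$features), x$hidden_units, length(x$classes)))
  invisible(x)
}

model_forward <- function(model, X) {
  Z <- sigmoid(sweep(X %*% model$W1, 2L, model$b1, `+`))
  softmax_rows(sweep(Z %*% model$W2, 2L, model$b2, `+`))
}

#' Predict per-class suitability probability surfaces
#'
#' Driver layers are matched to the model by name, so layer order is
#' irrelevant. Each valid cell receives six probabilities summing to 1
#' (classes absent from training score 0).
#'
#' @param model A `suitability_model`.
#' @param drivers A [driver_stack] providing every feature the model uses.
#' @return A `suitability_surface`: list with `probs` (valid-cell x 6
#'   matrix), `valid` mask, `dim`, `cell_size`.
#' @export
predict_suitability <- function(model, drivers) {
  missing <- setdiff(model$features, names(drivers$normalized))
  if (length(missing) > 0L)
    stop("missing driver layer(s): ", paste(missing, collapse = ", "))
  valid <- drivers$valid
  X <- vapply(model$features, function(d) drivers$normalized[[d]][valid],
              numeric(sum(valid)))
  Pr <- model_forward(model, X)
  probs <- matrix(0, nrow(Pr), N_CLASS)
  probs[, model$classes] <- Pr
  colnames(probs) <- land_classes()
  structure(list(probs = probs, valid = valid, dim = dim(valid),
                 cell_size = drivers$cell_size),
            class = "suitability_surface")
}

#' Extract one class's suitability surface as a raster
#'
#' @param surface A `suitability_surface`.
#' @param k Class code or name.
#' @return A `cont_raster` of probabilities in `[0,1]`.
#' @export
sp_raster <- function(surface, k) {
  k <- class_code(k)
  m <- matrix(NA_real_, surface$dim[1L], surface$dim[2L])
  m[surface$valid] <- surface$probs[, k]
  cont_raster(m, surface$cell_size)
}

#' Serialise / restore a suitability model as plain text
#'
#' Layout: a YAML document holding layer sizes, feature names, class codes
#' and the flattened weight arrays.
#'
#' @param model A `suitability_model`.
#' @param path Output path.
#' @export
write_suitability_model <- function(model, path) {
  yaml::write_yaml(list(
    hidden_units = model$hidden_units, features = model$features,
    classes = model$classes,
    W1 = as.numeric(model$W1), b1 = as.numeric(model$b1),
    W2 = as.numeric(model$W2), b2 = as.numeric(model$b2)), path,
    precision = 15L)
  invisible(path)
}

#' @rdname write_suitability_model
#' @export
read_suitability_model <- function(path) {
  x <- yaml::read_yaml(path)
  d <- length(x$features); H <- x$hidden_units; m <- length(x$classes)
  structure(list(W1 = matrix(x$W1, d, H), b1 = as.numeric(x$b1),
                 W2 = matrix(x$W2, H, m), b2 = as.numeric(x$b2),
                 hidden_units = as.integer(H), features = x$features,
                 classes = as.integer(x$classes)),
            class = "suitability_model")
}
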