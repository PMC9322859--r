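# Shared fixtures, generated in code and cached for the test run.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_world(synth_config(shape = c(60L, 60L), seed = 101L))
    cache
  }
})

# a raster with every cell the given class (codes recycled over the grid)
make_lu <- function(codes, nr = 3L, nc = 3L, cell_size = 100) {
  cat_raster(matrix(rep_len(codes, nr * nc), nr, nc), cell_size)
}

# minimal flat suitability surface (every class equally likely everywhere)
flat_surface <- function(lu) {
  valid <- !is.na(lu)
  probs <- matrix(1 / 6, sum(valid), 6)
  colnames(probs) <- land_classes()
  structure(list(probs = probs, valid = valid, dim = dim(lu),
                 cell_size = attr(lu, "cell_size")),
            class = "suitability_surface")
}

# brute-force all-pairs Euclidean distance oracle
edt_oracle <- function(mask, cell_size) {
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    out[i, j] <- min(sqrt((src[, 1] - i)^2 + (src[, 2] - j)^2)) * cell_size
  out
}

# random row-stochastic matrix
random_stochastic <- function(n = 6L, concentration = 8) {
  m <- matrix(stats::rexp(n * n), n, n) + diag(n) * concentration
  m / rowSums(m)
}
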