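# Shared in-code fixtures for the test suite. Everything is generated
# deterministically at test time; no data files.

# 6-subject, 4-parcel toy: small enough that every quantity can be
# recomputed by brute force in the tests.
toy_dataset <- function(seed = 101) {
  set.seed(seed)
  n <- 6L; p <- 4L; e <- p * (p - 1L) / 2L
  edges <- matrix(rnorm(n * e), n, e)
  y <- rnorm(n)
  list(edges = edges, y = y, n = n, n_parcels = p, n_edges = e)
}

# n x E noise matrix plus companions constructed orthogonal to y, so that
# only deliberately planted columns can ever be selected.
orthogonalized_edges <- function(n, e, y, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * e), n, e)
  yc <- y - mean(y)
  apply(x, 2L, function(col) col - yc * sum(col * yc) / sum(yc^2))
}

# Dataset whose outcome is an exact linear function of one edge; all other
# edges are orthogonal to y by construction, so the mask is {edge 1} at any
# threshold and the fitted model is exactly recoverable.
exact_linear_dataset <- function(n = 30L, e = 10L, slope = 2, intercept = 1,
                                 seed = 11) {
  set.seed(seed)
  z <- rnorm(n)
  y <- slope * z + intercept
  edges <- orthogonalized_edges(n, e, y, seed = seed + 1L)
  edges[, 1L] <- z
  list(edges = edges, y = y, z = z, slope = slope, intercept = intercept)
}

four_net_atlas <- function() {
  network_atlas(0:3, c("DMN", "DMN", "VIS", "VIS"))
}

expect_same_file <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
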