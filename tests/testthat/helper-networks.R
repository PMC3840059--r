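## Small graph fixtures built in code.

net_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  binary_network(A)
}

k3 <- function() net_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
k4 <- function() net_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)))
k4_minus_edge <- function() net_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
path3 <- function() net_from_edges(3, list(c(1, 2), c(2, 3)))
star5 <- function() net_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
single_edge <- function() net_from_edges(2, list(c(1, 2)))
edgeless <- function(n) binary_network(matrix(0, n, n))
two_triangles <- function() net_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                                   c(4, 5), c(5, 6), c(4, 6)))

random_binary_net <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  binary_network(A)
}

## separable two-class Gaussian features for classifier tests
gaussian_cohort <- function(n_per_class, p, shift, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * p), n_per_class),
             matrix(stats::rnorm(n_per_class * p, mean = shift), n_per_class))
  y <- rep(c(-1, 1), each = n_per_class)
  list(X = X, y = y)
}
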