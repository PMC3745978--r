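# Shared fixtures and independent oracles used across the test files.

# Two well-separated 2-D Gaussian classes (tight within-class spread).
separable_fixture <- function(n = 30, sd = 0.1, gap = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, 0, sd), n, 2),
             matrix(rnorm(2 * n, gap, sd), n, 2))
  labeled_matrix(x, rep(c("A", "B"), each = n))
}

# Balanced fixture whose labels are independent of the features.
null_fixture <- function(n = 40, p = 4, seed = 1) {
  set.seed(seed)
  labeled_matrix(matrix(rnorm(2 * n * p), 2 * n, p),
                 sample(rep(c("A", "B"), each = n)))
}

# Independent geometric-median oracle: Weiszfeld iterative reweighting.
# Minimizes the sum (equivalently mean) of plain Euclidean distances.
geometric_median <- function(x, tol = 1e-10, max_iter = 2000) {
  z <- colMeans(x)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(x, 2, z)^2))
    if (any(d < 1e-12)) d[d < 1e-12] <- 1e-12
    z_new <- colSums(x / d) / sum(1 / d)
    if (sqrt(sum((z_new - z)^2)) < tol) return(z_new)
    z <- z_new
  }
  z
}

# Independent brute-force greedy forward-selection oracle over a
# deterministic set-function scorer; same stopping semantics as the
# package (continue only on strict improvement), implemented separately.
greedy_sfs_oracle <- function(p, score_fn, max_features = p) {
  chosen <- integer(0)
  prev <- -Inf
  repeat {
    remaining <- setdiff(seq_len(p), chosen)
    if (length(remaining) == 0 || length(chosen) >= max_features) break
    vals <- vapply(remaining, function(f) score_fn(c(chosen, f)), numeric(1))
    best <- remaining[which.max(vals)]
    if (max(vals) <= prev) break
    chosen <- c(chosen, best)
    prev <- max(vals)
  }
  chosen
}

# Deterministic scorer built from a random per-subset score table keyed by
# the sorted subset (order-free set function).
random_subset_scorer <- function(p, seed) {
  set.seed(seed)
  tab <- new.env(parent = emptyenv())
  key <- function(s) paste(sort(s), collapse = ",")
  function(subset) {
    k <- key(subset)
    if (is.null(tab[[k]])) tab[[k]] <- runif(1)
    tab[[k]]
  }
}
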