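#' Specification for a synthetic benchmark dataset
#'
#' Describes a Gaussian class-conditional dataset with a known split into
#' class-informative and pure-noise features, the regime the prototype
#' (nearest-center) scorer is designed for. On every informative dimension
#' class `c` is centered at `(c - 1) * class_separation` with unit
#' within-class standard deviation, so `class_separation` is the
#' per-dimension distance between adjacent class means in within-class
#' sigma units; each additional informative dimension increases the joint
#' separation by a factor `sqrt(n_informative)`. Noise dimensions are
#' drawn from one shared `N(0, noise_sigma^2)` regardless of class.
#' Missing cells are inserted uniformly at `missing_rate`.
#'
#' @param n_per_class integer sample counts, one per class.
#' @param n_informative,n_noise feature counts (`n_informative + n_noise
#'   >= 1`).
#' @param class_separation per-dimension mean separation in sigma units.
#' @param noise_sigma standard deviation of noise features.
#' @param missing_rate in `[0, 1)`.
#' @param seed integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_per_class = c(100L, 100L), n_informative = 3L,
                       n_noise = 7L, class_separation = 4,
                       noise_sigma = 1, missing_rate = 0, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) < 2L || any(n_per_class < 1L)) {
    stop("n_per_class needs at least two positive class sizes")
  }
  n_informative <- as.integer(n_informative)
  n_noise <- as.integer(n_noise)
  if (n_informative < 0L || n_noise < 0L || n_informative + n_noise < 1L) {
    stop("n_informative + n_noise must be at least 1")
  }
  if (class_separation < 0) stop("class_separation must be nonnegative")
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  structure(list(n_per_class = n_per_class, n_informative = n_informative,
                 n_noise = n_noise,
                 class_separation = as.double(class_separation),
                 noise_sigma = as.double(noise_sigma),
                 missing_rate = as.double(missing_rate),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic dataset with known informative features
#'
#' Draws the dataset described by a [synth_spec()], randomly permutes the
#' feature columns (so informative features are not trivially the first
#' ones) and records the ground-truth informative column indices. Fully
#' reproducible under the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return List with `data` (a [labeled_matrix()] with classes `"A"`,
#'   `"B"`, ...; missing cells are `NA`), `informative` (sorted
#'   ground-truth column indices) and `mask` (logical missingness matrix).
#' @examples
#' fx <- generate_dataset(synth_spec(n_per_class = c(30, 30), seed = 7))
#' fx$informative
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  k <- length(spec$n_per_class)
  n <- sum(spec$n_per_class)
  p <- spec$n_informative + spec$n_noise
  labels <- rep(LETTERS[seq_len(k)], spec$n_per_class)
  x <- matrix(NA_real_, n, p)
  row0 <- 0L
  for (c in seq_len(k)) {
    nc <- spec$n_per_class[c]
    rows <- row0 + seq_len(nc)
    if (spec$n_informative > 0L) {
      x[rows, seq_len(spec$n_informative)] <-
        rnorm(nc * spec$n_informative, mean = (c - 1) * spec$class_separation,
              sd = 1)
    }
    if (spec$n_noise > 0L) {
      x[rows, spec$n_informative + seq_len(spec$n_noise)] <-
        rnorm(nc * spec$n_noise, mean = 0, sd = spec$noise_sigma)
    }
    row0 <- row0 + nc
  }
  perm <- sample(p)
  x <- x[, perm, drop = FALSE]
  informative <- sort(match(seq_len(spec$n_informative), perm))
  colnames(x) <- paste0("f", seq_len(p))
  mask <- matrix(FALSE, n, p, dimnames = dimnames(x))
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(n * p) < spec$missing_rate, n, p,
                   dimnames = dimnames(x))
    x[mask] <- NA_real_
  }
  list(data = labeled_matrix(x, labels), informative = informative,
       mask = mask)
}
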