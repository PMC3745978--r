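#' Box-bounded continuous search space
#'
#' @param lower,upper numeric vectors of per-dimension bounds,
#'   `lower[j] <= upper[j]`.
#' @return An `abc_search_space` object with elements `lower`, `upper`,
#'   `dimension`.
#' @examples
#' search_space(c(0, 0), c(1, 1))
#' @export
search_space <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper)) stop("bounds must be numeric")
  if (length(lower) != length(upper)) {
    stop("lower and upper bounds must have equal length")
  }
  if (length(lower) == 0L) stop("search space must have at least one dimension")
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower > upper)) {
    stop("each lower bound must not exceed its upper bound")
  }
  structure(list(lower = as.double(lower), upper = as.double(upper),
                 dimension = length(lower)),
            class = "abc_search_space")
}

#' ABC control parameters
#'
#' The artificial bee colony has three control parameters: the number of
#' food sources `SN` (= employed bees = onlooker bees = `colony_size / 2`),
#' the maximum cycle number, and the abandonment `limit` after which a
#' stagnant food source is replaced by a scout. Defaults are colony size 20
#' (so `SN = 10` food sources), 300 cycles and limit 200.
#'
#' @param colony_size even positive integer; `SN = colony_size / 2`.
#' @param max_cycles positive integer, number of search cycles (MCN).
#' @param limit nonnegative integer abandonment threshold.
#' @param seed integer seed for the run's random stream (`NULL` to use the
#'   current RNG state).
#' @return An `abc_config` object; element `sn` holds the food-source count.
#' @export
abc_config <- function(colony_size = 20L, max_cycles = 300L, limit = 200L,
                       seed = 1L) {
  colony_size <- as.integer(colony_size)
  max_cycles <- as.integer(max_cycles)
  limit <- as.integer(limit)
  if (is.na(colony_size) || colony_size < 4L || colony_size %% 2L != 0L) {
    stop("colony_size must be an even integer >= 4")
  }
  if (is.na(max_cycles) || max_cycles < 0L) {
    stop("max_cycles must be a nonnegative integer")
  }
  if (is.na(limit) || limit < 0L) stop("limit must be a nonnegative integer")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(colony_size = colony_size, sn = colony_size %/% 2L,
                 max_cycles = max_cycles, limit = limit, seed = seed),
            class = "abc_config")
}

default_abc_config <- function() abc_config()

#' Nectar fitness of a cost value
#'
#' Maps a nonnegative cost `f` to the fitness (nectar amount)
#' `fit = 1 / (1 + f)`, so that cost 0 has fitness 1 and fitness decreases
#' monotonically with cost.
#'
#' @param cost nonnegative numeric vector.
#' @return Fitness values in `(0, 1]`.
#' @examples
#' fitness_of(c(0, 1, 3)) # 1, 0.5, 0.25
#' @export
fitness_of <- function(cost) {
  if (!is.numeric(cost) || any(is.na(cost)) || any(cost < 0)) {
    stop("cost must be nonnegative")
  }
  1 / (1 + cost)
}

# internal food-source constructor
new_food <- function(position, cost) {
  list(position = as.double(position), cost = cost,
       fitness = fitness_of(cost), trials = 0L)
}

#' Scout initialization of a food source
#'
#' Draws a uniform random position in the box,
#' `z_j = lower_j + u_j (upper_j - lower_j)` with `u_j ~ U(0,1)` per
#' dimension, evaluates the cost function at it and returns a fresh food
#' source with the trial counter at zero. Uses the current R random stream.
#'
#' @param space an [search_space()].
#' @param cost_fn function mapping a position vector to a nonnegative cost.
#' @return A food source: list with `position`, `cost`, `fitness`, `trials`.
#' @export
init_food <- function(space, cost_fn) {
  stopifnot(inherits(space, "abc_search_space"))
  u <- runif(space$dimension)
  pos <- space$lower + u * (space$upper - space$lower)
  new_food(pos, cost_fn(pos))
}

#' Roulette selection probabilities over food sources
#'
#' `p_i = fit_i / sum_n fit_n`: each food source is selected by an onlooker
#' bee with probability proportional to its nectar amount.
#'
#' @param foods nonempty list of food sources (see [init_food()]).
#' @return Numeric vector of probabilities summing to 1.
#' @export
selection_probabilities <- function(foods) {
  if (!is.list(foods) || length(foods) == 0L) {
    stop("foods must be a nonempty list of food sources")
  }
  fits <- vapply(foods, function(f) f$fitness, numeric(1))
  if (any(fits <= 0)) stop("all food sources must have positive fitness")
  fits / sum(fits)
}

#' Candidate position from the neighborhood of a food source
#'
#' Picks one dimension `j` and one partner food `k != i` uniformly at
#' random and perturbs only that coordinate:
#' `v_ij = z_ij + phi (z_ij - z_kj)` with `phi ~ U(-1, 1)`. Coordinates
#' outside the box are clamped to the nearest bound. The population is not
#' modified. `dim`, `partner` and `phi` can be pinned for testing; when
#' `NULL` they are drawn from the current R random stream (in the order
#' dimension, partner, phi).
#'
#' @param foods list of at least two food sources.
#' @param i index of the source being perturbed.
#' @param space the [search_space()] used for clamping.
#' @param dim,partner,phi optional pinned values replacing the random draws.
#' @return Candidate position vector (differs from source in at most one
#'   coordinate).
#' @export
neighbor_move <- function(foods, i, space, dim = NULL, partner = NULL,
                          phi = NULL) {
  sn <- length(foods)
  if (sn < 2L) stop("neighbor_move needs at least two food sources")
  if (i < 1L || i > sn) stop("food index out of range")
  d <- space$dimension
  if (is.null(dim)) {
    j <- as.integer(floor(runif(1) * d)) + 1L
    if (j > d) j <- d
  } else j <- as.integer(dim)
  if (is.null(partner)) {
    k0 <- as.integer(floor(runif(1) * (sn - 1))) + 1L
    if (k0 > sn - 1L) k0 <- sn - 1L
    k <- if (k0 < i) k0 else k0 + 1L
  } else k <- as.integer(partner)
  if (k == i) stop("partner must differ from the perturbed source")
  if (is.null(phi)) phi <- runif(1, -1, 1)
  v <- foods[[i]]$position
  v[j] <- v[j] + phi * (v[j] - foods[[k]]$position[j])
  if (v[j] < space$lower[j]) v[j] <- space$lower[j]
  if (v[j] > space$upper[j]) v[j] <- space$upper[j]
  v
}

#' Greedy selection between a food source and a candidate position
#'
#' Accepts the candidate when its nectar amount is equal or higher, i.e.
#' when its cost is equal or lower; acceptance resets the trial counter,
#' rejection increments it.
#'
#' @param food incumbent food source.
#' @param candidate_position in-bounds candidate position vector.
#' @param cost_fn cost function.
#' @return The updated food source.
#' @export
greedy_replace <- function(food, candidate_position, cost_fn) {
  cand_cost <- cost_fn(candidate_position)
  if (cand_cost <= food$cost) {
    new_food(candidate_position, cand_cost)
  } else {
    food$trials <- food$trials + 1L
    food
  }
}

#' Run the artificial bee colony optimizer
#'
#' Minimizes `cost_fn` over the box `space`. Each cycle runs the employed
#' phase (one [neighbor_move()] + [greedy_replace()] per food source), the
#' onlooker phase (`SN` roulette draws by [selection_probabilities()],
#' computed once at the start of the phase, each followed by a move and
#' greedy selection on the drawn source) and the scout phase (the single
#' food source with the largest trial counter is re-initialized when its
#' counter exceeds `limit`). The best position ever seen is tracked across
#' cycles.
#'
#' The run is deterministic given `config$seed`: all randomness is drawn
#' from R's global stream, seeded at entry, in a fixed documented order
#' (initialization food-by-food and dimension-by-dimension, then per cycle:
#' employed moves, onlooker roulette + moves, scout re-draws).
#'
#' @param cost_fn function mapping an in-box position to a nonnegative cost.
#' @param space an [search_space()].
#' @param config an [abc_config()].
#' @return An `abc_result`: list with `best_position`, `best_cost`, `foods`
#'   (the final `SN` food sources), and `cost_history` (best-ever cost
#'   after initialization and after each cycle; nonincreasing, length
#'   `max_cycles + 1`).
#' @examples
#' sp <- search_space(c(-5, -5), c(5, 5))
#' res <- run_abc(function(z) sum((z - c(1, 2))^2), sp,
#'                abc_config(max_cycles = 50, seed = 7))
#' res$best_cost
#' @export
run_abc <- function(cost_fn, space, config = abc_config()) {
  stopifnot(inherits(space, "abc_search_space"),
            inherits(config, "abc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sn <- config$sn
  foods <- vector("list", sn)
  for (i in seq_len(sn)) foods[[i]] <- init_food(space, cost_fn)

  costs <- vapply(foods, function(f) f$cost, numeric(1))
  b <- which.min(costs)
  best_position <- foods[[b]]$position
  best_cost <- costs[b]
  history <- numeric(config$max_cycles + 1L)
  history[1L] <- best_cost

  for (cyc in seq_len(config$max_cycles)) {
    # employed phase
    for (i in seq_len(sn)) {
      v <- neighbor_move(foods, i, space)
      foods[[i]] <- greedy_replace(foods[[i]], v, cost_fn)
    }
    # onlooker phase: probabilities fixed at phase start
    cum <- cumsum(selection_probabilities(foods))
    for (t in seq_len(sn)) {
      u <- runif(1)
      i <- which(cum >= u)[1L]
      if (is.na(i)) i <- sn
      v <- neighbor_move(foods, i, space)
      foods[[i]] <- greedy_replace(foods[[i]], v, cost_fn)
    }
    # scout phase: at most one per cycle
    trials <- vapply(foods, function(f) f$trials, integer(1))
    s <- which.max(trials)
    if (trials[s] > config$limit) foods[[s]] <- init_food(space, cost_fn)
    # track best-ever
    costs <- vapply(foods, function(f) f$cost, numeric(1))
    b <- which.min(costs)
    if (costs[b] < best_cost) {
      best_cost <- costs[b]
      best_position <- foods[[b]]$position
    }
    history[cyc + 1L] <- best_cost
  }

  structure(list(best_position = best_position, best_cost = best_cost,
                 foods = foods, cost_history = history),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("abc_result: best cost %.6g over %d cycles, %d food sources\n",
              x$best_cost, length(x$cost_history) - 1L, length(x$foods)))
  invisible(x)
}
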