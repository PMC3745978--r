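test_that("fitness maps cost to nectar amount 1/(1+f)", {
  expect_identical(fitness_of(0), 1)
  expect_identical(fitness_of(1), 0.5)
  expect_identical(fitness_of(3), 0.25)
  expect_error(fitness_of(-0.1), "nonnegative")
})

test_that("scout initialization stays in the box and is seeded", {
  cost <- function(z) sum(z^2)
  # degenerate box collapses to its single point
  sp0 <- search_space(c(3, -1), c(3, -1))
  set.seed(1)
  expect_identical(init_food(sp0, cost)$position, c(3, -1))
  # containment over many draws
  sp <- search_space(c(0, 0), c(1, 1))
  set.seed(2)
  for (i in 1:50) {
    f <- init_food(sp, cost)
    expect_true(all(f$position >= 0 & f$position <= 1))
    expect_identical(f$trials, 0L)
    expect_identical(f$fitness, 1 / (1 + f$cost))
  }
  # determinism under seeding
  sp1 <- search_space(0, 10)
  set.seed(7); a <- init_food(sp1, cost)
  set.seed(7); b <- init_food(sp1, cost)
  expect_identical(a, b)
})

test_that("selection probabilities are fitness-proportional and normalized", {
  mk <- function(fit) list(position = 0, cost = 1 / fit - 1, fitness = fit,
                           trials = 0L)
  p <- selection_probabilities(lapply(rep(0.3, 10), mk))
  expect_equal(p, rep(0.1, 10))
  expect_equal(selection_probabilities(list(mk(0.5), mk(0.5))), c(0.5, 0.5))
  expect_equal(selection_probabilities(list(mk(0.75), mk(0.25))),
               c(0.75, 0.25))
  # normalization within 1e-12 on random fitness vectors
  for (s in 1:20) {
    set.seed(s)
    p <- selection_probabilities(lapply(runif(10, 0.01, 1), mk))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  expect_error(selection_probabilities(list()), "nonempty")
})

test_that("neighbor move perturbs one coordinate and clamps to the box", {
  sp <- search_space(c(0, 0), c(1, 1))
  mk <- function(pos) list(position = pos, cost = 0, fitness = 1, trials = 0L)
  # identical positions: zero difference, candidate equals source
  foods <- list(mk(c(0.4, 0.6)), mk(c(0.4, 0.6)))
  set.seed(1)
  expect_identical(neighbor_move(foods, 1, sp), c(0.4, 0.6))
  # pinned randomness: 1-D foods at 0 and 1, phi = +1 from index 1:
  # v = 0 + 1 * (0 - 1) = -1, clamped to the lower bound
  sp1 <- search_space(0, 1)
  foods1 <- list(mk(0), mk(1))
  expect_identical(neighbor_move(foods1, 1, sp1, dim = 1, partner = 2,
                                 phi = 1), 0)
  # unclamped pinned move for the same formula
  sp2 <- search_space(-5, 5)
  expect_identical(neighbor_move(foods1, 1, sp2, dim = 1, partner = 2,
                                 phi = 1), -1)
  # at most one coordinate changes, always within bounds
  set.seed(3)
  foods2 <- list(mk(runif(4)), mk(runif(4)), mk(runif(4)))
  sp4 <- search_space(rep(0, 4), rep(1, 4))
  for (i in 1:50) {
    v <- neighbor_move(foods2, 2, sp4)
    expect_lte(sum(v != foods2[[2]]$position), 1)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(neighbor_move(list(mk(0)), 1, sp1), "at least two")
})

test_that("greedy selection accepts equal-or-better nectar and counts trials", {
  cost_of <- function(v) v[1]
  food <- list(position = 99, cost = 0.5, fitness = 1 / 1.5, trials = 3L)
  # strict improvement: replaced, trials reset
  r <- greedy_replace(food, 0.2, cost_of)
  expect_identical(r$cost, 0.2)
  expect_identical(r$trials, 0L)
  # equal nectar accepted
  r <- greedy_replace(food, 0.5, cost_of)
  expect_identical(r$position, 0.5)
  expect_identical(r$trials, 0L)
  # rejection increments the counter, keeps the incumbent
  r <- greedy_replace(food, 0.9, cost_of)
  expect_identical(r$position, 99)
  expect_identical(r$cost, 0.5)
  expect_identical(r$trials, 4L)
})

test_that("abc run is deterministic, elitist, and respects the box", {
  sp <- search_space(c(-2, -2, -2), c(2, 2, 2))
  cost <- function(z) sum((z - c(1, -1, 0.5))^2)
  cfg <- abc_config(max_cycles = 60, seed = 11)
  r1 <- run_abc(cost, sp, cfg)
  r2 <- run_abc(cost, sp, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$cost_history) <= 0))
  expect_identical(length(r1$cost_history), 61L)
  for (f in r1$foods) {
    expect_true(all(f$position >= -2 & f$position <= 2))
  }
  expect_lte(r1$best_cost, min(vapply(r1$foods, `[[`, numeric(1), "cost")))
})

test_that("zero cycles returns the best of the initial population", {
  sp <- search_space(c(0, 0), c(1, 1))
  cost <- function(z) sum(z^2)
  cfg <- abc_config(max_cycles = 0, seed = 5)
  r <- run_abc(cost, sp, cfg)
  expect_identical(length(r$cost_history), 1L)
  set.seed(cfg$seed)
  init_costs <- replicate(cfg$sn, init_food(sp, cost)$cost)
  expect_identical(r$best_cost, min(init_costs))
})

test_that("limit 0 re-initializes stagnant foods through the scout path", {
  # count cost evaluations: employed + onlooker phases use exactly 2 SN
  # per cycle, so any surplus beyond the initial SN comes from scouts
  sp <- search_space(c(-1, -1), c(1, 1))
  counter <- local({
    n <- 0L
    list(fn = function(z) { n <<- n + 1L; sum(z^2) },
         get = function() n, reset = function() n <<- 0L)
  })
  cfg0 <- abc_config(max_cycles = 50, limit = 0, seed = 3)
  r0 <- run_abc(counter$fn, sp, cfg0)
  base_calls <- cfg0$sn + cfg0$max_cycles * 2L * cfg0$sn
  scouts_limit0 <- counter$get() - base_calls
  expect_gt(scouts_limit0, 0)          # scout path exercised every cycle
  expect_true(all(diff(r0$cost_history) <= 0))
  counter$reset()
  run_abc(counter$fn, sp, abc_config(max_cycles = 50, limit = 10000,
                                     seed = 3))
  expect_identical(counter$get() - base_calls, 0L)  # no scouts below limit
})

test_that("abc converges on separable convex costs in low dimension", {
  ok <- 0
  for (s in 1:20) {
    sp <- search_space(rep(-5, 2), rep(5, 2))
    r <- run_abc(function(z) sum((z - c(1.5, -2.5))^2), sp,
                 abc_config(max_cycles = 150, seed = s))
    if (r$best_cost < 1e-2) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("compiled clustering kernel is bit-identical to the pure-R path", {
  set.seed(42)
  x <- matrix(rnorm(60), 30, 2)
  lm <- labeled_matrix(x, rep(c("A", "B"), 15))
  cfg <- abc_config(max_cycles = 80, seed = 9)
  m_cpp <- train_class_centers(lm, 1:2, cfg, backend = "cpp")
  m_r <- train_class_centers(lm, 1:2, cfg, backend = "r")
  expect_identical(m_cpp, m_r)
})
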