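# Orthogonal arrays, level generation, farthest-vertex restarts, Taguchi
# steps and the full restart loop.

test_that("two-level arrays are balanced and pairwise orthogonal (L4 through L32)", {
  for (nf in c(1, 3, 4, 7, 10, 15, 20, 31)) {
    oa <- orthogonal_array(nf)
    runs <- nrow(oa)
    expect_equal(ncol(oa), nf)
    expect_true(all(oa %in% c(1L, 2L)))
    expect_true(all(colSums(oa == 1L) == runs / 2))   # balance
    if (nf >= 2) {
      for (i in seq_len(nf - 1)) for (j in seq(i + 1, nf)) {
        combos <- table(factor(oa[, i], 1:2), factor(oa[, j], 1:2))
        expect_true(all(combos == runs / 4))          # orthogonality
      }
    }
  }
  expect_equal(dim(orthogonal_array(3)), c(4L, 3L))
  expect_equal(dim(orthogonal_array(20)), c(32L, 20L))
  expect_equal(orthogonal_array(1), matrix(1:2, 2, 1))
  expect_error(orthogonal_array(64), class = "capacity_error")
})

test_that("level generation offsets by 0.2 of the domain width, one unit for exponents, and clamps", {
  lv <- make_levels(0.5, 0, 1)
  expect_equal(unname(lv[, 1]), c(0.3, 0.7))
  # near the lower bound, the box projection clips level 1
  lv2 <- make_levels(0.05, 0, 1)
  expect_equal(unname(lv2[, 1]), c(0, 0.25))
  # integer exponent with bounds [2, 4]
  lv3 <- make_levels(3, 2, 4, integer = TRUE)
  expect_equal(unname(lv3[, 1]), c(2, 4))
  # exponent at its bound clamps one level onto the current value
  lv4 <- make_levels(2, 2, 4, integer = TRUE)
  expect_equal(unname(lv4[, 1]), c(2, 3))
  # box projection is idempotent
  x <- stats::runif(50, -2, 3)
  once <- box_project(x, 0, 1)
  expect_identical(box_project(once, 0, 1), once)
})

test_that("farthest-vertex selection maximizes the minimum weighted distance", {
  store <- matrix(c(0.1, 0.11, 0.9), ncol = 1)
  expect_equal(vvp_select(store, 0, 1)$index, 3L)
  # two vertices: symmetric tie broken at the lowest index
  expect_equal(vvp_select(matrix(c(0.2, 0.8), ncol = 1), 0, 1)$index, 1L)
  # a duplicated vertex has zero min-distance and is never selected over a
  # distinct extreme
  dup <- matrix(c(0.5, 0.5, 0.95), ncol = 1)
  expect_equal(vvp_select(dup, 0, 1)$index, 3L)
  expect_equal(vvp_select(dup, 0, 1, weighting = "uniform")$index, 3L)
  expect_error(vvp_select(matrix(0.5, 1, 1), 0, 1),
               class = "insufficient_vertices")
  # brute-force max-min oracle on random stores (uniform weighting)
  set.seed(31)
  for (rep_ in 1:10) {
    st <- matrix(stats::runif(12), ncol = 2)
    d <- as.matrix(stats::dist(st))
    diag(d) <- Inf
    oracle <- which.max(apply(d, 1, min))
    got <- vvp_select(st, c(0, 0), c(1, 1), weighting = "uniform")$index
    expect_equal(got, unname(oracle))
  }
})

test_that("restart-eligibility masking skips used starts", {
  store <- matrix(c(0.1, 0.5, 0.9), ncol = 1)
  first <- vvp_select(store, 0, 1)$index
  second <- vvp_select(store, 0, 1,
                       eligible = seq_len(3) != first)$index
  expect_false(second == first)
})

test_that("a Taguchi step moves every factor toward the optimum of a separable objective", {
  sph <- function(x) sum((x - 0.5)^2)
  start <- rep(0.9, 4)
  stp <- taguchi_step(sph, start, rep(0, 4), rep(1, 4))
  expect_equal(stp$values, rep(0.7, 4))
  expect_lt(stp$objective, sph(start))
  expect_true(stp$predicted_used)

  # on a separable monotone objective the chosen level is exhaustively
  # optimal: compare against full 2^k enumeration
  lin <- function(x) sum(c(3, -2, 1) * x)
  lv <- make_levels(rep(0.5, 3), rep(0, 3), rep(1, 3))
  combos <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  vals <- apply(combos, 1, function(ix)
    lin(vapply(1:3, function(i) lv[ix[i], i], numeric(1))))
  best <- combos[which.min(vals), ]
  stp2 <- taguchi_step(lin, rep(0.5, 3), rep(0, 3), rep(1, 3))
  expect_equal(stp2$values,
               vapply(1:3, function(i) lv[best[i], i], numeric(1)))
})

test_that("a constant objective returns a proposal no better than the start", {
  flat <- function(x) 1
  stp <- taguchi_step(flat, rep(0.5, 3), rep(0, 3), rep(1, 3))
  expect_equal(stp$objective, 1)
})

test_that("a single-variable step picks the better of the two levels", {
  f <- function(x) (x - 0.62)^2
  stp <- taguchi_step(f, 0.5, 0, 1)
  expect_equal(unname(stp$values), 0.7)   # 0.7 beats 0.3 for a 0.62 target
})

test_that("the restart loop solves the 5-variable sphere to within 0.05", {
  sph <- function(x) sum((x - 0.5)^2)
  res <- taguchi_optimize(sph, rep(0, 5), rep(1, 5), n_init = 10,
                          max_restarts = 10, seed = 1)
  expect_lte(res$best$objective, 0.05)
  expect_gt(sum(res$restarts == "optimum"), 1)
})

test_that("zero restarts return the best initial vertex; reruns are deterministic", {
  sph <- function(x) sum((x - 0.5)^2)
  r0 <- taguchi_optimize(sph, rep(0, 3), rep(1, 3), n_init = 6,
                         max_restarts = 0, seed = 4)
  expect_equal(r0$n_evals, 6L)
  expect_equal(r0$best$objective, min(r0$objectives))

  r1 <- taguchi_optimize(sph, rep(0, 3), rep(1, 3), n_init = 5,
                         max_restarts = 3, seed = 7)
  r2 <- taguchi_optimize(sph, rep(0, 3), rep(1, 3), n_init = 5,
                         max_restarts = 3, seed = 7)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$best, r2$best)
})

test_that("the store holds no duplicate optima and integer variables stay integral", {
  mixed <- function(x) sum((x[1:2] - 0.5)^2) + (x[3] - 3)^2
  res <- taguchi_optimize(mixed, c(0, 0, 2), c(1, 1, 4),
                          integer = c(FALSE, FALSE, TRUE),
                          n_init = 6, max_restarts = 6, seed = 2)
  u <- res$store
  d <- as.matrix(stats::dist(u))
  diag(d) <- Inf
  expect_gt(min(d), 1e-6)
  expect_true(all(res$store[, 3] == round(res$store[, 3])))
  expect_true(all(res$store[, 3] >= 2 & res$store[, 3] <= 4))
  # every logged proposal respects the box bounds
  xs <- as.matrix(res$log[, c("x1", "x2", "x3")])
  expect_true(all(xs >= rep(c(0, 0, 2), each = nrow(xs)) - 1e-12))
  expect_true(all(xs <= rep(c(1, 1, 4), each = nrow(xs)) + 1e-12))
})
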