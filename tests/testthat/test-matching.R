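test_that("cost matrix realizes gamma * distance - confidence", {
  D <- costMatrix(matrix(c(0, 0), 1), matrix(c(3, 4), 1), 0.5, gamma = 1)
  expect_equal(D[1, 1], 5 - 0.5)
  D0 <- costMatrix(matrix(c(1, 2), 1), matrix(c(9, 9), 1), 0.7, gamma = 0)
  expect_equal(D0[1, 1], -0.7)
  # brute-force elementwise recomputation on a random instance
  set.seed(41)
  gt <- matrix(runif(8, 0, 50), 4)
  pr <- matrix(runif(12, 0, 50), 6)
  cf <- runif(6)
  D <- costMatrix(gt, pr, cf, gamma = 0.05)
  for (i in 1:4) for (j in 1:6) {
    expect_equal(D[i, j],
                 0.05 * sqrt(sum((gt[i, ] - pr[j, ])^2)) - cf[j],
                 tolerance = 1e-12)
  }
  expect_error(costMatrix(matrix(0, 3, 2), matrix(0, 2, 2), c(1, 1), 1),
               "infeasible")
})

test_that("hungarianMatch solves simple instances exactly", {
  r <- hungarianMatch(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(r$assignment, c(1L, 2L))
  expect_equal(r$totalCost, 2)
  r2 <- hungarianMatch(matrix(c(0, 5, 5), 1))
  expect_equal(r2$assignment, 1L)
  expect_equal(r2$totalCost, 0)
  expect_error(hungarianMatch(matrix(c(1, NA), 1)), "finite")
  expect_error(hungarianMatch(matrix(0, 3, 2)), "N > M")
})

test_that("hungarianMatch equals exhaustive enumeration on random rectangles", {
  set.seed(42)
  for (k in 1:200) {
    N <- sample(1:5, 1); M <- N + sample(0:2, 1)
    D <- matrix(rnorm(N * M), N, M)
    r <- hungarianMatch(D, canonical = FALSE)
    b <- bruteAssign(D)
    expect_equal(r$totalCost, b$cost, tolerance = 1e-9)
    expect_equal(length(unique(r$assignment)), N)
  }
})

test_that("canonical tie-break yields the lexicographically smallest optimum", {
  # all-equal costs: every assignment is optimal; canonical picks 1,2,3
  D <- matrix(1, 3, 4)
  expect_equal(hungarianMatch(D, canonical = TRUE)$assignment, 1:3)
  # a constructed tie between {1->1,2->2} and {1->2,2->1}
  D2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(hungarianMatch(D2, canonical = TRUE)$assignment, c(1L, 2L))
  # determinism of the plain solver
  set.seed(7)
  D3 <- matrix(rnorm(20), 4, 5)
  expect_identical(hungarianMatch(D3)$assignment, hungarianMatch(D3)$assignment)
})

test_that("coincident high-confidence predictions are matched to their particles", {
  gt <- matrix(c(10, 10, 40, 40, 10, 40), 3, 2, byrow = TRUE)
  pred <- rbind(gt, matrix(c(200, 200, 220, 220), 2, 2, byrow = TRUE))
  conf <- c(1, 1, 1, 0, 0)
  m <- matchPoints(gt, pred, conf, gamma = 0.05)
  expect_equal(m$assignment, 1:3)
})
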