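test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  D <- pairwise_distances(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(D[1, 2], 5)
  expect_equal(pairwise_distances(matrix(1:3, 1)), matrix(0, 1, 1),
               ignore_attr = TRUE)
  set.seed(1)
  for (rep in 1:5) {
    D <- pairwise_distances(random_cloud(8))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
  expect_error(pairwise_distances(rbind(c(0, NA, 0))), "non-finite")
})

test_that("H0 deaths are single-linkage merge heights with n-1 finite bars", {
  d <- rips_h0(rbind(0, 1))
  expect_equal(unname(d$pairs[, "death"]), 1)
  expect_equal(unname(d$pairs[, "birth"]), 0)
  expect_true(d$essential_dropped)
  # collinear points 0, 1, 5: merges at 1 and 4
  d2 <- rips_h0(cbind(c(0, 1, 5)))
  expect_equal(sort(d2$pairs[, "death"]), c(1, 4))
  # independent oracle: hclust single-linkage heights, exact equality
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    cl <- random_cloud(n)
    d <- rips_h0(cl)
    expect_equal(nrow(d$pairs), n - 1L)
    expect_equal(unname(d$pairs[, "death"]), single_linkage_heights(cl),
                 tolerance = 0)
  }
  # degenerate inputs
  expect_equal(nrow(rips_h0(matrix(1, 1, 3))$pairs), 0L)
})

test_that("diagram is invariant to point order", {
  set.seed(3)
  cl <- random_cloud(10)
  d1 <- rips_h0(cl)
  d2 <- rips_h0(cl[sample(10), ])
  expect_equal(d1$pairs, d2$pairs)
})

test_that("deaths scale linearly with the cloud", {
  set.seed(4)
  cl <- random_cloud(9)
  expect_equal(rips_h0(2.5 * cl)$pairs[, "death"],
               2.5 * rips_h0(cl)$pairs[, "death"])
})

test_that("automatic bounds cover the largest pair and fall back to (0, 1)", {
  d <- structure(list(pairs = cbind(birth = 0, death = 2), dimension = 0L,
                      essential_dropped = TRUE), class = "persistence_diagram")
  b <- auto_bounds(d)
  expect_equal(b[1], 0)
  expect_gte(b[2], 2)
  expect_equal(auto_bounds(numeric(0)), c(0, 1))
  # monotone in the max persistence
  expect_gte(auto_bounds(c(1, 3))[2], auto_bounds(c(1, 2))[2])
})

test_that("persistence image integrates weighted Gaussian mass per bin", {
  # single pair (0, 0.5) with bounds (0, 1): weight 0.5 and the Gaussian
  # sits ~7 sigma inside the bounds, so the pixel sum is the full weight
  img <- persistence_image(c(0.5), bounds = c(0, 1))
  expect_length(img$pixels, 50L)
  expect_equal(sum(img$pixels), 0.5, tolerance = 1e-6)
  # empty diagram gives the zero vector
  empty <- rips_h0(matrix(0, 1, 3))
  expect_equal(persistence_image(empty)$pixels, rep(0, 50))
  # linearity: duplicated pair doubles the image exactly
  one <- persistence_image(c(0.4), bounds = c(0, 1))
  two <- persistence_image(c(0.4, 0.4), bounds = c(0, 1))
  expect_equal(two$pixels, 2 * one$pixels)
  expect_error(persistence_image(c(0.4), bounds = c(1, 1)), "bounds")
})

test_that("pixel sum conserves total weighted mass when bounds cover +/- 6 sigma", {
  set.seed(11)
  sigma <- sqrt(0.005)
  for (rep in 1:20) {
    p <- runif(sample(1:8, 1), 0.2, 2)
    bounds <- c(min(p) - 7 * sigma, max(p) + 7 * sigma)
    img <- persistence_image(p, bounds = bounds)
    expect_equal(sum(img$pixels), sum(p / bounds[2]), tolerance = 1e-6)
  }
})

test_that("image pipeline is permutation invariant end to end", {
  set.seed(12)
  cl <- random_cloud(12)
  i1 <- persistence_image(rips_h0(cl))
  i2 <- persistence_image(rips_h0(cl[sample(12), ]))
  expect_equal(i1$pixels, i2$pixels)
  expect_equal(i1$bounds, i2$bounds)
})

test_that("diagram and image exports round-trip through CSV", {
  set.seed(13)
  d <- rips_h0(random_cloud(6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_diagram(d, f)
  back <- read.csv(f)
  expect_equal(back$death, unname(d$pairs[, "death"]))
  expect_true(all(back$dimension == 0))
  img <- persistence_image(d)
  fi <- withr::local_tempfile(fileext = ".csv")
  write_image(img, fi)
  expect_equal(as.numeric(read.csv(fi)[1, ]), img$pixels)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", fi), simplifyVector = TRUE)
  expect_equal(side$variance, 0.005)
})
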