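mahal_points <- seizpred:::mahal_points

test_that("pool statistics match direct two-pass computation", {
  st <- pool_stats(rbind(c(0, 0), c(2, 2)))
  expect_equal(unname(st$mu), c(1, 1))

  # identical samples: zero covariance, pseudo-inverse path
  st0 <- pool_stats(matrix(1, 5, 3))
  expect_true(all(st0$sigma == 0))
  expect_equal(st0$eps, 0)
  expect_equal(mahal_point(c(1, 1, 1), st0), 0)

  set.seed(11)
  X <- matrix(rnorm(80), 20, 4)
  st2 <- pool_stats(X)
  mu <- colMeans(X)
  sig <- matrix(0, 4, 4)
  for (i in 1:20) sig <- sig + tcrossprod(X[i, ] - mu)
  sig <- sig / 19
  expect_lt(max(abs(st2$sigma - sig)), 1e-10)

  expect_error(pool_stats(matrix(1, 1, 3)), class = "seizpred_validation")
})

test_that("point distance reproduces hand-computed cases", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  st <- pool_stats(X)
  expect_equal(mahal_point(c(1, 1), st), 0)
  # sample covariance is diag(4/3): quadratic form (2,0) -> 4/(4/3) = 3
  expect_equal(mahal_point(c(3, 1), st), sqrt(3), tolerance = 1e-5)

  # identity covariance reduces to Euclidean distance
  set.seed(12)
  Z <- matrix(rnorm(4000), 1000, 4)
  Z <- scale(Z, scale = FALSE)
  stI <- pool_stats(Z)
  x <- c(1, -2, 0.5, 3)
  expect_equal(mahal_point(x, stI), sqrt(sum((x - stI$mu)^2)), tolerance = 0.15)

  expect_error(mahal_point(c(1, 2, 3), st), "dimension")
})

test_that("set distance is the mean of point distances", {
  set.seed(13)
  st <- pool_stats(matrix(rnorm(60), 20, 3))
  S <- matrix(rnorm(15), 5, 3)
  oracle <- mean(vapply(seq_len(5), function(i) mahal_point(S[i, ], st), numeric(1)))
  expect_equal(mahal_set(S, st), oracle, tolerance = 1e-12)
  expect_equal(mahal_set(S[1, , drop = FALSE], st), mahal_point(S[1, ], st))
  expect_equal(mahal_set(rbind(st$mu, st$mu), st), 0)
})

test_that("point distance behaves like a metric for fixed covariance", {
  set.seed(14)
  X <- matrix(rnorm(200), 50, 4)
  st <- pool_stats(X)
  dist_m <- function(a, b) sqrt(drop(t(a - b) %*% st$sigma_inv %*% (a - b)))
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(4); cc <- rnorm(4)
    expect_equal(dist_m(a, b), dist_m(b, a), tolerance = 1e-9)
    expect_lte(dist_m(a, cc), dist_m(a, b) + dist_m(b, cc) + 1e-9)
  }
})

test_that("abnormality rule uses a strict inequality for normality", {
  tp <- toy_pools()
  # the pre cluster itself: close to pre, far from inter -> abnormal
  expect_true(is_abnormal(tp$pre$features[1:5, ], tp$pre, tp$inter, lam = 1))
  # the inter cluster: normal
  expect_false(is_abnormal(tp$inter$features[1:5, ], tp$pre, tp$inter, lam = 1))
  # lam = 0 and positive distance to pre -> normal
  expect_false(is_abnormal(tp$inter$features[1:5, ], tp$pre, tp$inter, lam = 0))
  # equality boundary: distance to itself vs lam scaled so the sides match
  S <- tp$inter$features[1:5, ]
  d_pre <- mahal_set(S, pool_stats(tp$pre))
  d_int <- mahal_set(S, pool_stats(tp$inter))
  expect_true(is_abnormal(S, tp$pre, tp$inter, lam = d_pre / d_int))
})

test_that("pool updates sort, retain capacity, and never fabricate samples", {
  # pre pool with mean (1,1) and covariance diag(4/3); points on the x-axis
  # through the mean have distance |dx| * sqrt(3)/2
  pre <- sample_pool(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)), role = "pre")
  at_dist <- function(d) c(1 + d * 2 / sqrt(3), 1)
  inter <- sample_pool(rbind(at_dist(1), at_dist(5)), capacity = 2, role = "inter")
  obs <- rbind(at_dist(3))

  upd <- update_pool_inter(inter, obs, pre, order = "asc")
  expect_equal(nrow(upd$features), 2L)
  expect_true(all(apply(upd$features, 1, function(r)
    any(apply(rbind(inter$features, obs), 1, function(q) all(q == r))))))
  d_kept <- sort(mahal_points(upd$features, pool_stats(pre)))
  expect_equal(d_kept, c(1, 3), tolerance = 1e-4)

  updd <- update_pool_inter(inter, obs, pre, order = "desc")
  expect_equal(sort(mahal_points(updd$features, pool_stats(pre))),
               c(3, 5), tolerance = 1e-4)

  # empty observation set leaves the pool unchanged
  expect_equal(update_pool_inter(inter, NULL, pre)$features, inter$features)

  # mirrored update of the preictal pool
  inter2 <- sample_pool(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)), role = "inter")
  pre2 <- sample_pool(rbind(at_dist(1), at_dist(5)), capacity = 2, role = "pre")
  upd2 <- update_pool_pre(pre2, rbind(at_dist(3)), inter2, order = "asc")
  expect_equal(sort(mahal_points(upd2$features, pool_stats(inter2))),
               c(1, 3), tolerance = 1e-4)
  expect_equal(nrow(upd2$features), 2L)

  expect_error(update_pool_inter(pre2, obs, pre), class = "seizpred_validation")
})

test_that("ties in the retention sort are broken by age, older first", {
  pre <- sample_pool(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)), role = "pre")
  # two pool samples and one observed sample, all at exactly the same
  # distance from the pool mean (1, 1)
  p <- c(3, 1)
  q <- c(-1, 1)
  inter <- sample_pool(rbind(p, q), capacity = 2, role = "inter")
  upd <- update_pool_inter(inter, rbind(p), pre)
  expect_equal(unname(upd$features), unname(inter$features))  # older retained
})
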