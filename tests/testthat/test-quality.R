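# Drift kernel, degradation accumulation, and the quality transform.

test_that("decay factor has the stated closed form and truncation", {
  expect_equal(decay_factor(0), 1)
  # 5% residual at the maximum distance, ~0.224 at one 30-m cell
  expect_equal(decay_factor(60), 0.05, tolerance = 1e-12)
  expect_equal(decay_factor(30), sqrt(0.05), tolerance = 1e-12)
  expect_equal(decay_factor(30), 0.2236, tolerance = 1e-4)
  expect_equal(decay_factor(61), 0)
  expect_equal(decay_factor(90), 0)
  # 1-D cumulative deposition within d_max: integral of the kernel over
  # [0, 60] divided by its total mass on [0, Inf)
  lambda <- DECAY_COEF / 60
  dep <- stats::integrate(function(d) lambda * exp(-lambda * d), 0, 60)$value
  expect_equal(dep, 0.95, tolerance = 1e-9)
})

test_that("zero threats give zero degradation and Q equals H", {
  g <- const_grid(176, 30, 30)
  H <- habitat_map(g)
  D <- degradation(list(), H)
  expect_true(all(unclass(D) == 0))
  Q <- quality(D, H)
  expect_equal(unclass(Q), unclass(H))
})

test_that("a single threat pixel contributes the closed-form decayed amount", {
  g <- const_grid(176, 21, 21)
  H <- habitat_map(g)
  th <- make_threat(g, cells = cbind(11, 11), intensity = 1, weight = 1)
  D <- degradation(list(th), H)
  # kernel mass over the 13-cell truncated neighborhood
  K <- 1 + 4 * exp(-DECAY_COEF * 30 / 60) +
    4 * exp(-DECAY_COEF * sqrt(2) * 30 / 60) + 4 * exp(-DECAY_COEF)
  # unnormalized contribution at a 30-m neighbor is sqrt(0.05) ~ 0.224
  expect_equal(unclass(D)[11, 12] * K, sqrt(0.05), tolerance = 1e-12)
  expect_equal(sqrt(0.05), 0.2236, tolerance = 1e-4)
  # at 60 m (two cells): the 5% residual; beyond 60 m: exactly zero
  expect_equal(unclass(D)[11, 13] * K, 0.05, tolerance = 1e-12)
  expect_equal(unclass(D)[11, 14], 0)
  expect_equal(unclass(D)[14, 14], 0)
})

test_that("a fully threatened neighborhood saturates degradation at 1", {
  g <- const_grid(176, 15, 15)
  H <- habitat_map(g)
  th <- make_threat(g, cells = which(matrix(TRUE, 15, 15)), intensity = 1)
  D <- degradation(list(th), H)
  expect_equal(unclass(D)[8, 8], 1, tolerance = 1e-12)
  expect_true(all(unclass(D) <= 1 + 1e-12))
})

test_that("optimized degradation equals the brute-force oracle", {
  set.seed(99)
  for (n in c(30, 50)) {
    g <- bee_grid(matrix(
      sample(c(176L, 1L, 83L), n * n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
      n, n
    ))
    H <- habitat_map(g)
    corn <- which(unclass(g) == 1L)
    th1 <- make_threat(g, corn, intensity = stats::runif(length(corn)), weight = 0.7)
    th2 <- make_threat(g, sample(seq_len(n * n), 40),
      intensity = 0.5, weight = 0.3, compound = "Bifenthrin"
    )
    D_fast <- degradation(list(th1, th2), H)
    D_slow <- brute_degradation(list(th1, th2), H)
    expect_lt(max(abs(unclass(D_fast) - unclass(D_slow))), 1e-9)
  }
})

test_that("quality transform honors H gating and half-saturation", {
  g <- split_grid(10, 10)
  H <- habitat_map(g)
  # any degradation on non-habitat stays at quality 0
  D <- grid_like_oracle(H, matrix(0.8, 10, 10))
  Q <- quality(D, H)
  expect_true(all(unclass(Q)[unclass(H) == 0] == 0))
  # D = 0 -> Q = H; D = k -> Q = H/2
  expect_equal(
    unclass(quality(grid_like_oracle(H, matrix(0, 10, 10)), H)),
    unclass(H)
  )
  Qk <- quality(grid_like_oracle(H, matrix(0.5, 10, 10)), H, k = 0.5)
  expect_equal(unclass(Qk)[unclass(H) == 1], rep(0.5, sum(unclass(H) == 1)))
  expect_error(quality(D, H, k = 0), "k > 0")
})

test_that("quality is monotone in threat intensity and coverage", {
  g <- const_grid(176, 25, 25)
  H <- habitat_map(g)
  th_a <- make_threat(g, cbind(13, 13), intensity = 0.4)
  # raising a layer's intensity never raises Q anywhere
  th_a_hot <- make_threat(g, cbind(13, 13), intensity = 0.9)
  Q1 <- quality(degradation(list(th_a), H), H)
  Q3 <- quality(degradation(list(th_a_hot), H), H)
  expect_true(all(unclass(Q3) <= unclass(Q1) + 1e-12))
  # adding threat pixels to an existing layer never raises Q anywhere
  th_wide <- make_threat(g, rbind(c(13, 13), c(13, 14)), intensity = 0.4)
  Q4 <- quality(degradation(list(th_wide), H), H)
  expect_true(all(unclass(Q4) <= unclass(Q1) + 1e-12))
  # note: adding a new *weighted layer* renormalizes the weighted mean
  # (InVEST semantics), so degradation is a weighted average across
  # layers, not a sum; check that average structure explicitly
  th_b <- make_threat(g, cbind(13, 14), intensity = 0.8, compound = "Bifenthrin")
  D_a <- degradation(list(th_a), H)
  D_b <- degradation(list(th_b), H)
  D_ab <- degradation(list(th_a, th_b), H)
  expect_equal(unclass(D_ab), (unclass(D_a) + unclass(D_b)) / 2,
    tolerance = 1e-12
  )
})

test_that("degradation decays monotonically away from a treated edge", {
  # grassland block abutting treated cropland: Q rises with distance from
  # the edge up to 60 m, then is flat at H
  g <- split_grid(30, 30) # columns 16:30 corn
  H <- habitat_map(g)
  corn_cells <- which(unclass(g) == 1L)
  th <- make_threat(g, corn_cells, intensity = 1)
  Q <- quality(degradation(list(th), H), H)
  mid <- unclass(Q)[15, 1:15] # a grassland row, moving toward the edge
  # distance to edge decreases with column index -> Q non-increasing
  expect_true(all(diff(mid) <= 1e-12))
  # cells farther than 60 m from the edge keep Q = H = 1 exactly
  expect_true(all(unclass(Q)[15, 1:12] == 1))
  expect_lt(unclass(Q)[15, 15], 1)
})
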