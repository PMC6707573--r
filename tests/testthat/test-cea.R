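test_that("SUR point estimates equal the arm-mean differences", {
  # arm-constant data: deltas are the constant differences, residuals vanish
  d <- two_arm_constant(5258, 5642, 0.6, 0.2)
  fit <- fit_sur(d)
  expect_equal(fit$delta_cost, -384)
  expect_equal(fit$delta_effect, 0.4)
  expect_true(is.na(fit$residual_cor))

  # random data: group-mean-difference oracle to machine precision
  set.seed(11)
  d2 <- data.frame(arm = rep(c("ISMI", "WLC"), each = 50),
                   cost = rexp(100, 1 / 3000), effect = rnorm(100))
  fit2 <- fit_sur(d2)
  oracle_c <- mean(d2$cost[d2$arm == "ISMI"]) - mean(d2$cost[d2$arm == "WLC"])
  oracle_e <- mean(d2$effect[d2$arm == "ISMI"]) - mean(d2$effect[d2$arm == "WLC"])
  expect_equal(fit2$delta_cost, oracle_c, tolerance = 1e-12)
  expect_equal(fit2$delta_effect, oracle_e, tolerance = 1e-12)

  expect_error(fit_sur(d2[d2$arm == "ISMI", ]), "both arms")
})

test_that("independent costs and effects have near-zero residual correlation", {
  set.seed(12)
  n <- 4000
  d <- data.frame(arm = rep(c("ISMI", "WLC"), each = n / 2),
                  cost = rlnorm(n, 8, 1), effect = rnorm(n))
  fit <- fit_sur(d)
  expect_lt(abs(fit$residual_cor), 3 / sqrt(n))
})

test_that("bootstrap clouds are seed-deterministic and consistent", {
  set.seed(13)
  d <- data.frame(arm = rep(c("ISMI", "WLC"), each = 100),
                  cost = rlnorm(200, 8, 0.8), effect = rnorm(200, 0.3))
  c1 <- bootstrap_cloud(d, B = 1, seed = 5)
  c2 <- bootstrap_cloud(d, B = 1, seed = 5)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  const <- two_arm_constant(1000, 500, 1, 0, n_per_arm = 5)
  cc <- bootstrap_cloud(const, B = 50, seed = 1)
  expect_true(all(cc$delta_cost == 500))
  expect_true(all(cc$delta_effect == 1))

  # cloud mean within Monte-Carlo tolerance of the point estimate
  cloud <- bootstrap_cloud(d, B = 1000, seed = 19)
  expect_lt(abs(mean(cloud$delta_cost) - attr(cloud, "delta_cost_hat")),
            3 * sd(cloud$delta_cost) / sqrt(1000))
  expect_lt(abs(mean(cloud$delta_effect) - attr(cloud, "delta_effect_hat")),
            3 * sd(cloud$delta_effect) / sqrt(1000))
})

test_that("draws are stacked equally across imputed datasets", {
  d1 <- two_arm_constant(100, 0, 1, 0)
  d2 <- two_arm_constant(200, 0, 1, 0)
  cloud <- bootstrap_cloud(list(d1, d2), B = 10, seed = 1)
  expect_equal(sum(cloud$delta_cost == 100), 5)
  expect_equal(sum(cloud$delta_cost == 200), 5)
  expect_equal(attr(cloud, "delta_cost_hat"), 150)  # Rubin mean rule
})

test_that("the ICER applies dominance semantics", {
  expect_equal(icer(-386, 0.362)$label, "dominant")
  expect_equal(icer(500, 0.5)$value, 1000)
  expect_equal(icer(500, 0.5)$label, "ratio")
  expect_equal(icer(100, 0)$label, "undefined")
  expect_true(is.na(icer(100, 0)$value))
  expect_equal(icer(100, -0.5)$label, "dominated")
  expect_equal(icer(-100, -0.5)$label, "ratio")   # SW: cost saved per loss
})

test_that("plane quadrants partition the draws and sum to 100", {
  cloud <- structure(data.frame(delta_effect = c(1, 1, -1, -1),
                                delta_cost = c(1, -1, -1, 1)),
                     class = c("icer_cloud", "data.frame"))
  expect_equal(plane_distribution(cloud),
               c(NE = 25, SE = 25, SW = 25, NW = 25))

  se_only <- structure(data.frame(delta_effect = abs(rnorm(40)) + 0.1,
                                  delta_cost = -abs(rnorm(40)) - 0.1),
                       class = c("icer_cloud", "data.frame"))
  expect_equal(unname(plane_distribution(se_only)["SE"]), 100)

  # boundary draws go to the positive-effect (east), negative-cost (south) side
  edge <- structure(data.frame(delta_effect = c(0, 0), delta_cost = c(1, -1)),
                    class = c("icer_cloud", "data.frame"))
  expect_equal(sum(plane_distribution(edge)), 100)
  expect_equal(unname(plane_distribution(edge)[c("NE", "SE")]), c(50, 50))

  set.seed(14)
  rnd <- structure(data.frame(delta_effect = rnorm(501),
                              delta_cost = rnorm(501)),
                   class = c("icer_cloud", "data.frame"))
  expect_equal(sum(plane_distribution(rnd)), 100, tolerance = 1e-9)
})

test_that("a Gaussian cloud with published moments reproduces the quadrant masses", {
  # moments recovered from the printed incremental summaries: cost
  # -386 (-1794 to 1006), QALY effect 0.0074 (-0.0015 to 0.016); mild
  # negative cost-effect correlation
  set.seed(15)
  n <- 2e5
  sd_c <- (1006 + 1794) / (2 * qnorm(0.975))
  sd_e <- (0.016 + 0.0015) / (2 * qnorm(0.975))
  rho <- -0.3
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cloud <- structure(data.frame(delta_effect = 0.0074 + sd_e * z1,
                                delta_cost = -386 + sd_c * z2),
                     class = c("icer_cloud", "data.frame"))
  p <- plane_distribution(cloud)
  expect_equal(unname(p), c(26, 69, 2, 3), tolerance = 2 / 26)  # within 2 points
  expect_lt(max(abs(p - c(NE = 26, SE = 69, SW = 2, NW = 3))), 2)
})

test_that("the CEAC counts positive net monetary benefit", {
  dominant <- structure(data.frame(delta_effect = c(0.5, 1), delta_cost = c(-10, -5)),
                        class = c("icer_cloud", "data.frame"))
  cv <- ceac(dominant, c(0, 100, 1e4))
  expect_equal(cv$probability, c(1, 1, 1))

  single <- structure(data.frame(delta_effect = 1, delta_cost = 1000),
                      class = c("icer_cloud", "data.frame"))
  cv2 <- ceac(single, c(0, 999, 1001))
  expect_equal(cv2$probability, c(0, 0, 1))

  # five enumerated draws against hand-counted NMB signs
  five <- structure(data.frame(delta_effect = c(1, 1, -1, 2, 0.5),
                               delta_cost = c(400, -200, -100, 1500, 600)),
                    class = c("icer_cloud", "data.frame"))
  grid <- c(0, 500, 1000)
  # lambda=0:   NMB>0 for draws with negative cost            -> 2/5
  # lambda=500: NMB = c(100, 700, -400, -500, -350)           -> 2/5
  # lambda=1000: NMB = c(600, 1200, -900, 500, -100)          -> 3/5
  expect_equal(ceac(five, grid)$probability, c(2, 2, 3) / 5)

  # CEAC(0) equals the fraction of cost-saving draws
  set.seed(16)
  rnd <- structure(data.frame(delta_effect = abs(rnorm(300)),
                              delta_cost = rnorm(300, 50, 400)),
                   class = c("icer_cloud", "data.frame"))
  expect_equal(ceac(rnd, 0)$probability, mean(rnd$delta_cost < 0))
  # nondecreasing in lambda when all effects are nonnegative
  probs <- ceac(rnd, seq(0, 5000, by = 250))$probability
  expect_true(all(diff(probs) >= 0))
})

test_that("percentile intervals match order-statistic oracles", {
  const <- structure(data.frame(delta_effect = rep(1, 30),
                                delta_cost = rep(-50, 30)),
                     class = c("icer_cloud", "data.frame"))
  ci <- percentile_ci(const)
  expect_equal(ci$cost, c(-50, -50))
  expect_equal(ci$effect, c(1, 1))

  unif <- structure(data.frame(delta_effect = as.numeric(1:100),
                               delta_cost = as.numeric(1:100)),
                    class = c("icer_cloud", "data.frame"))
  # order-statistic oracle: x_(k) + g * (x_(k+1) - x_(k)) with h = 1 + 99p,
  # which for the sorted values 1..100 collapses to h itself
  manual <- function(p) { h <- 1 + 99 * p; floor(h) + (h - floor(h)) }
  ci2 <- percentile_ci(unif)
  expect_equal(ci2$cost, c(manual(0.025), manual(0.975)))

  set.seed(17)
  z <- rnorm(2e5)
  norm_cloud <- structure(data.frame(delta_effect = z, delta_cost = z),
                          class = c("icer_cloud", "data.frame"))
  ci3 <- percentile_ci(norm_cloud)
  expect_equal(ci3$effect, c(-1.96, 1.96), tolerance = 0.02)

  expect_warning(percentile_ci(structure(
    data.frame(delta_effect = 1:5, delta_cost = 1:5),
    class = c("icer_cloud", "data.frame"))), "20 draws")
})

test_that("dominant clouds report a 'dominant to X' ICER range", {
  set.seed(18)
  de <- abs(rnorm(500, 0.4, 0.1))
  dc <- rnorm(500, -300, 600)
  cloud <- structure(data.frame(delta_effect = de, delta_cost = dc),
                     class = c("icer_cloud", "data.frame"))
  ci <- percentile_ci(cloud)
  expect_identical(ci$icer_range$lower, "dominant")
  ne <- de > 0 & dc > 0
  expect_equal(ci$icer_range$upper,
               unname(quantile(dc[ne] / de[ne], 0.975, type = 7)))
})
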