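test_that("standardization yields exact z-scores", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  # frozen from the hand computation: mean 5, sample sd sqrt(32/7)
  expect_equal(standardize(x),
               c(-1.40312152, -0.46770717, -0.46770717,
                 -0.46770717, 0, 0, 0.93541435, 1.87082869),
               tolerance = 1e-7)
  set.seed(1)
  z <- standardize(rlnorm(50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(c(3, 3, 3)), "constant")
  expect_error(standardize(c(1, 2)), "at least 3")
})

test_that("dot product and Euclidean norm", {
  expect_equal(dot_product(c(1, 0), c(0, 1)), 0)
  expect_equal(dot_product(c(1, 2, 3), c(1, 2, 3)), 14)
  expect_error(dot_product(1:3, 1:4), "equal length")
  expect_equal(euclidean_norm(c(3, 4)), 5)
  expect_equal(euclidean_norm(numeric(3)), 0)
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40)
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]  # brute-force summation
  expect_equal(dot_product(a, b), s, tolerance = 1e-12)
  # algebraic identity: a z-scored vector of length K has norm sqrt(K-1)
  expect_equal(euclidean_norm(standardize(rlnorm(17))), sqrt(16),
               tolerance = 1e-9)
})

test_that("angles between standardized endpoints equal Pearson geometry", {
  a <- standardize(c(1, 5, 2, 8, 3))
  self <- angle_between(a, a)
  expect_equal(self$theta_deg, 0)
  expect_equal(self$sin_theta, 0)
  # orthogonal standardized pair
  u <- standardize(c(1, -1, 1, -1))
  v <- standardize(c(1, 1, -1, -1))
  expect_equal(angle_between(u, v)$theta_deg, 90)
  expect_equal(angle_between(u, v)$sin_theta, 1)
  expect_error(angle_between(c(0, 0, 0), a), "zero-norm")
  # cos(theta) of z-scores == Pearson correlation of the raw vectors
  set.seed(3)
  for (i in 1:100) {
    x <- rlnorm(10 + i %% 20)
    y <- rlnorm(length(x))
    expect_equal(angle_between(standardize(x), standardize(y))$cos_theta,
                 cor(x, y), tolerance = 1e-10)
  }
})

test_that("angles are invariant to positive affine rescaling", {
  set.seed(4)
  x <- rlnorm(15); y <- rlnorm(15)
  base <- angle_between(standardize(x), standardize(y))$theta_deg
  shifted <- angle_between(standardize(3.7 * x + 11), standardize(y))
  expect_equal(shifted$theta_deg, base, tolerance = 1e-9)
})

test_that("perpendicular projection scales values by sin(theta)", {
  # a right angle leaves the endpoint untouched
  u <- standardize(c(1, -1, 1, -1))
  v <- standardize(c(1, 1, -1, -1))
  right <- angle_between(u, v)
  vals <- c(4, 7, 2, 9)
  expect_equal(decompose(vals, right), vals)
  # 30 degrees halves the values
  expect_equal(decompose(10, list(sin_theta = 0.5)), 5)
  # natural-scale variance scales by sin^2(theta); order is preserved
  set.seed(5)
  for (i in 1:20) {
    x <- rlnorm(30)
    y <- rlnorm(30)
    ang <- angle_between(standardize(x), standardize(y))
    out <- decompose(x, ang)
    expect_equal(var(out), ang$sin_theta^2 * var(x), tolerance = 1e-10)
    expect_true(all(out <= x + 1e-12))
    expect_identical(order(out), order(x))
  }
  # (anti)parallel endpoints have no perpendicular component
  x <- rlnorm(12)
  par <- angle_between(standardize(x), standardize(2.5 * x))
  expect_error(decompose(x, par), "parallel")
})

test_that("vbc_transform decomposes per cell and registers 8 angles", {
  ep <- random_endpoint_table(n = 24, seed = 6, rho = 0.5)
  dec <- vbc_transform(ep, vbc_config())
  expect_true(all(c("cmax_perp", "as_slope_perp") %in% names(dec)))
  expect_equal(dec$auc, ep$auc)  # anchor untouched
  ang <- attr(dec, "angles")
  expect_equal(nrow(ang), 8)  # 2 endpoints x 4 period-treatment cells
  expect_true(all(ang$sin_theta >= 0 & ang$sin_theta <= 1))
  expect_true(all(ang$theta_deg >= 0 & ang$theta_deg <= 180))
  # each observation is scaled by its own cell's sine
  for (k in seq_len(nrow(ang))) {
    in_cell <- ep$period == ang$period[k] & ep$treatment == ang$treatment[k]
    col <- ang$endpoint[k]
    expect_equal(dec[[paste0(col, "_perp")]][in_cell],
                 ep[[col]][in_cell] * ang$sin_theta[k], tolerance = 1e-12)
  }
})

test_that("independent endpoints decompose almost unchanged", {
  # K = 100 per cell; uncorrelated with the anchor => sin(theta) near 1
  ep <- random_endpoint_table(n = 200, seed = 7, rho = 0)
  dec <- vbc_transform(ep)
  ang <- attr(dec, "angles")
  expect_lt(mean(abs(ang$sin_theta - 1)), 0.05)
})

test_that("an endpoint proportional to the anchor is degenerate-parallel", {
  ep <- random_endpoint_table(n = 12, seed = 8)
  ep$cmax <- 0.1 * ep$auc
  expect_error(vbc_transform(ep), "parallel")
  expect_error(vbc_config(anchor = "auc", decompose = c("auc", "cmax")),
               "anchor")
  expect_error(vbc_transform(ep, vbc_config(decompose = "nope")),
               "not found")
})

test_that("cosine of independent endpoints concentrates at 0 as K grows", {
  set.seed(9)
  mean_abs_cos <- sapply(c(10, 100, 1000), function(K) {
    mean(replicate(60, {
      angle_between(standardize(rlnorm(K)),
                    standardize(rlnorm(K)))$cos_theta
    }) |> abs())
  })
  expect_true(all(diff(mean_abs_cos) < 0))
  # E|cos| ~ sqrt(2/(pi K)) for independent vectors
  expect_lt(mean_abs_cos[3], 3 / sqrt(1000))
})

test_that("pooled angles give one sine per endpoint", {
  ep <- random_endpoint_table(n = 24, seed = 10, rho = 0.4)
  dec <- vbc_transform(ep, vbc_config(pooling = "pooled"))
  ang <- attr(dec, "angles")
  expect_equal(nrow(ang), 2)
  s <- ang$sin_theta[ang$endpoint == "cmax"]
  expect_equal(dec$cmax_perp, ep$cmax * s, tolerance = 1e-12)
})
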