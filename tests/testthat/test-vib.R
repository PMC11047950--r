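# The patch-level bottleneck layer: posterior prediction, reparameterized
# sampling, KL losses, and gradient correctness.

test_that("latent equals the mean when sampling is suppressed", {
  set.seed(1)
  layer <- pvib_layer(3, 3)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))

  # eps forced to zero in train mode
  out <- pvib_forward(x, layer, mode = "train",
                      eps = array(0, c(5, 4, 3, 2)))
  expect_equal(out$z, out$field$mu)

  # eval mode: no sampling, no epsilon
  out2 <- pvib_forward(x, layer, mode = "eval")
  expect_equal(out2$z, out2$field$mu)
  expect_null(out2$epsilon)
})

test_that("output spatial shape equals input spatial shape, down to 1x1", {
  layer <- pvib_layer(2, 2)
  for (hw in list(c(1, 1), c(1, 7), c(4, 4), c(9, 3))) {
    x <- array(rnorm(prod(hw) * 2), c(hw, 2, 1))
    out <- pvib_forward(x, layer, mode = "eval")
    expect_identical(dim(out$z)[1:2], dim(x)[1:2])
    expect_identical(dim(out$field$sigma), dim(out$field$mu))
  }
})

test_that("sigma is strictly positive by construction", {
  set.seed(2)
  layer <- pvib_layer(2, 2)
  layer$b_ls[] <- -50  # below the clamp
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  out <- pvib_forward(x, layer, mode = "eval")
  expect_true(all(out$field$sigma > 0))
})

test_that("train-mode sampling is seeded and bit-reproducible", {
  layer <- pvib_layer(2, 2)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  set.seed(99); a <- pvib_forward(x, layer, mode = "train")
  set.seed(99); b <- pvib_forward(x, layer, mode = "train")
  expect_identical(a$z, b$z)
  expect_identical(a$epsilon, b$epsilon)
})

test_that("sampled latents recover the posterior moments", {
  layer <- constant_pvib_layer(4, mu0 = 0, sigma0 = 1)
  x <- array(runif(50 * 50 * 4 * 10), c(50, 50, 4, 10))
  set.seed(7)
  out <- pvib_forward(x, layer, mode = "train")
  n <- length(out$z)
  expect_gte(n, 1e5)
  expect_lt(abs(mean(out$z)), 3 / sqrt(n))
  expect_lt(abs(stats::var(as.vector(out$z)) - 1), 3 * sqrt(2 / n))
})

test_that("malformed inputs are rejected", {
  layer <- pvib_layer(3, 3)
  expect_error(pvib_forward(array(0, c(4, 4, 2, 1)), layer), "channels")
  bad <- array(0, c(4, 4, 3, 1)); bad[1] <- NaN
  expect_error(pvib_forward(bad, layer), "non-finite")
})

test_that("KL loss matches hand-computed values and is zero at the prior", {
  expect_identical(
    kl_loss_scale(gaussian_field(array(0, c(3, 5, 2)), array(1, c(3, 5, 2)))),
    0)
  expect_equal(kl_loss_scale(gaussian_field(1, 1)), 1)
  expect_equal(kl_loss_scale(gaussian_field(0, exp(1))), exp(2) - 3)
  expect_error(kl_loss_scale(gaussian_field(0, -1)), "positive")
})

test_that("KL loss is nonnegative with the prior as unique minimum", {
  set.seed(3)
  for (i in 1:25) {
    f <- gaussian_field(array(rnorm(12), c(2, 3, 2)),
                        array(exp(rnorm(12)), c(2, 3, 2)))
    expect_gte(kl_loss_scale(f), 0)
  }
  for (mu in seq(-1, 1, by = 0.5)) {
    for (sg in seq(0.25, 2, by = 0.25)) {
      v <- kl_loss_scale(gaussian_field(mu, sg))
      if (mu == 0 && sg == 1) expect_identical(v, 0) else expect_gt(v, 0)
    }
  }
})

test_that("total KL loss is additive over scales", {
  set.seed(4)
  fields <- lapply(c(4, 2, 1), function(hw) {
    gaussian_field(array(rnorm(hw * hw * 3), c(hw, hw, 3)),
                   array(exp(rnorm(hw * hw * 3, 0, 0.3)), c(hw, hw, 3)))
  })
  per <- vapply(fields, kl_loss_scale, numeric(1))
  expect_equal(kl_loss_total(fields), sum(per))
  expect_equal(kl_loss_total(fields[1]), per[1])
  zero <- gaussian_field(array(0, c(2, 2, 1)), array(1, c(2, 2, 1)))
  expect_identical(kl_loss_total(list(zero, zero, zero)), 0)
  expect_error(kl_loss_total(list()), "at least one")
})

test_that("quadrature oracle reproduces the closed form", {
  expect_lt(abs(kl_oracle(0, 1)), 1e-9)
  expect_equal(kl_oracle(1, 1), 1, tolerance = 1e-9)
  # pinned regression value: 0.5^2 + 0.7^2 - 2*log(0.7) - 1
  expect_equal(kl_oracle(0.5, 0.7), 0.4533498868, tolerance = 1e-8)
})

test_that("analytic KL gradients match finite differences", {
  set.seed(5)
  mu <- array(rnorm(8), c(2, 2, 2))
  sg <- array(exp(rnorm(8, 0, 0.3)), c(2, 2, 2))
  g <- pvib:::kl_grad_scale(gaussian_field(mu, sg))
  gmu_num <- numeric_gradient(function(m) {
    kl_loss_scale(gaussian_field(array(m, dim(mu)), sg))
  }, as.vector(mu))
  gsg_num <- numeric_gradient(function(s) {
    kl_loss_scale(gaussian_field(mu, array(s, dim(sg))))
  }, as.vector(sg))
  expect_lt(max(rel_err(as.vector(g$dmu), gmu_num)), 1e-6)
  expect_lt(max(rel_err(as.vector(g$dsigma), gsg_num)), 1e-6)
})

test_that("layer gradients flow correctly through the reparameterization", {
  set.seed(6)
  layer <- pvib_layer(2, 2)
  layer$w_ls[] <- rnorm(length(layer$w_ls), 0, 0.1)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  eps <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  R <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))

  # scalar objective: sum(z * R) + KL of the posterior
  fwd <- function(l) {
    out <- pvib_forward(x, l, mode = "train", eps = eps)
    sum(out$z * R) + kl_loss_scale(out$field)
  }
  out <- pvib_forward(x, layer, mode = "train", eps = eps)
  kg <- pvib:::kl_grad_scale(out$field)
  g <- pvib:::pvib_backward(R, out$cache, layer,
                            dmu_extra = kg$dmu, dsigma_extra = kg$dsigma)
  for (leaf in c("w_mu", "b_mu", "w_ls", "b_ls")) {
    num <- numeric_gradient(function(v) {
      l2 <- layer; l2[[leaf]][] <- v; fwd(l2)
    }, as.vector(layer[[leaf]]))
    ana <- as.vector(g[[paste0("d", leaf)]])
    expect_lt(max(rel_err(ana, num)), 1e-4)
  }
})
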