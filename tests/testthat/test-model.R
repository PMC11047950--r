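# Model assembly: pyramid shapes, neck and head behavior, forward-pass
# determinism, baseline equivalence, checkpoint round-trips.

test_that("backbone produces the stride-8/16/32 pyramid", {
  cfg <- model_config(num_classes = 4)
  model <- build_model(cfg, seed = 1)
  x <- array(runif(224 * 224 * 2), c(224, 224, 1, 2))
  feats <- backbone_forward(model, x)
  expect_named(feats, c("P2", "P3", "P4"))
  expect_identical(dim(feats$P2)[1:2], c(28L, 28L))
  expect_identical(dim(feats$P3)[1:2], c(14L, 14L))
  expect_identical(dim(feats$P4)[1:2], c(7L, 7L))
  # spatial resolution strictly decreases along the pyramid
  expect_true(dim(feats$P2)[1] > dim(feats$P3)[1])
  expect_true(dim(feats$P3)[1] > dim(feats$P4)[1])
  # one feature map per image
  expect_identical(dim(feats$P2)[4], 2L)
  single <- backbone_forward(model, x[, , , 1, drop = FALSE])
  expect_identical(dim(single$P4)[4], 1L)
})

test_that("single-scale ablation returns only the coarse map", {
  cfg <- tiny_model_config(scales = "P4")
  model <- build_model(cfg, seed = 1)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  feats <- backbone_forward(model, x)
  expect_named(feats, "P4")
})

test_that("configuration errors are caught", {
  expect_error(model_config(4, backbone = "vgg"), "arg")
  expect_error(model_config(4, scales = character(0)), "subset")
  expect_error(model_config(4, scales = c("P2", "P3")), "P4")
  cfg <- model_config(4, backbone = "res2net50")
  expect_error(build_model(cfg), "hook|bundled")
})

test_that("channel attention rescales within channels and fixes zero", {
  set.seed(30)
  x <- array(rnorm(6 * 5 * 8 * 2), c(6, 5, 8, 2))
  k <- eca_kernel_size(8)
  expect_true(k %% 2 == 1)
  w <- rnorm(k)
  out <- pvib:::eca_fwd(x, w)
  # gates in (0,1)
  expect_true(all(out$g > 0 & out$g < 1))
  # output/input ratio is constant within each channel
  for (n in 1:2) for (c in 1:8) {
    ratio <- out$y[, , c, n] / x[, , c, n]
    expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
    expect_equal(ratio[1, 1], out$g[c, n], tolerance = 1e-12)
  }
  # identity gate reproduces the input exactly
  forced <- x * rep(matrix(1, 8, 2), each = 30)
  expect_identical(forced, x)
  # zero input stays zero
  zero <- pvib:::eca_fwd(array(0, dim(x)), w)
  expect_true(all(zero$y == 0))
})

test_that("attention head degenerates to a pooled linear classifier", {
  set.seed(31)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  W <- matrix(rnorm(6), 3, 2); b <- rnorm(2)
  # residual weight 0: logits equal mean-pooled scores plus bias
  l0 <- csra_head(x, W, b, residual_weight = 0)
  M <- matrix(x, 16, 3)
  expect_equal(as.vector(l0), colMeans(M %*% W) + b, tolerance = 1e-12)
  # uniform spatial features: attention score equals the base score
  u <- array(rep(rnorm(3), each = 16), c(4, 4, 3, 1))
  Mu <- matrix(u, 16, 3)
  base <- colMeans(Mu %*% W)
  lu <- csra_head(u, W, b, residual_weight = 0.3)
  expect_equal(as.vector(lu), (1 + 0.3) * base + b, tolerance = 1e-10)
})

test_that("forward pass is deterministic in eval and seeded in train", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  a <- model_forward(model, x, mode = "eval")
  b <- model_forward(model, x, mode = "eval")
  expect_identical(a$probs_per_scale, b$probs_per_scale)
  expect_true(all(unlist(a$probs_per_scale) > 0 &
                    unlist(a$probs_per_scale) < 1))
  set.seed(5); tr1 <- model_forward(model, x, mode = "train")
  set.seed(5); tr2 <- model_forward(model, x, mode = "train")
  expect_identical(tr1$probs_per_scale, tr2$probs_per_scale)
  # posterior fields exist for every active scale
  expect_named(a$fields, c("P2", "P3", "P4"))
})

test_that("disabling the bottleneck yields the baseline with zero KL", {
  cfg <- tiny_model_config(vib_position = "none")
  model <- build_model(cfg, seed = 3)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  fw <- model_forward(model, x, mode = "train")
  expect_length(fw$fields, 0)
  y <- matrix(rbinom(8, 1, 0.5), 2, 4)
  lg <- pvib:::loss_and_grad(model, x, y, loss_config(beta = 0.1))
  expect_identical(lg$breakdown$kl_total, 0)
  expect_equal(lg$breakdown$total, lg$breakdown$cls_total)
})

test_that("bottleneck placement before or after the neck both work", {
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  for (pos in c("before_neck", "after_neck")) {
    model <- build_model(tiny_model_config(vib_position = pos), seed = 4)
    fw <- model_forward(model, x, mode = "eval")
    expect_length(fw$fields, 3)
    expect_true(all(vapply(fw$fields, function(f) all(f$sigma > 0),
                           logical(1))))
  }
})

test_that("per-scale fusion averages probabilities", {
  p <- matrix(0.2, 2, 3); q <- matrix(0.6, 2, 3)
  expect_equal(combine_scale_predictions(list(A = p, B = q)), (p + q) / 2)
  expect_equal(combine_scale_predictions(list(A = p)), p)
  expect_equal(combine_scale_predictions(list(A = p, B = q)),
               combine_scale_predictions(list(B = q, A = p)))
  expect_equal(combine_scale_predictions(list(A = p, B = q), method = "B"), q)
  expect_error(combine_scale_predictions(list(A = p), method = "C"), "scale")
})

test_that("checkpoints round-trip to bit-identical eval outputs", {
  model <- build_model(tiny_model_config(), seed = 6)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  a <- model_forward(model, x)
  b <- model_forward(restored, x)
  expect_identical(a$probs_per_scale, b$probs_per_scale)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(unrelated = TRUE), other)
  expect_error(load_checkpoint(other), "not a pvib checkpoint")
})

test_that("full-model analytic gradients match scale-aware finite differences", {
  set.seed(33)
  model <- build_model(tiny_model_config(num_classes = 2), seed = 8)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  y <- matrix(rbinom(4, 1, 0.5), 2, 2)
  lc <- loss_config(beta = 0.1)
  fw <- pvib:::model_forward_impl(model, x, "train", want_cache = TRUE)
  eps_list <- lapply(fw$fields, function(f) {
    array(rnorm(length(f$mu)), dim = dim(f$mu))
  })
  lg <- pvib:::loss_and_grad(model, x, y, lc, eps_list = eps_list)
  lossfn <- function(params) {
    m2 <- model; m2$params <- params
    pvib:::loss_and_grad(m2, x, y, lc, eps_list = eps_list)$breakdown$total
  }
  for (path in pvib:::flatten_leaf_paths(model$params)) {
    leaf <- model$params[[path]]
    k <- sample(length(leaf), 1)
    h <- max(1e-7, 1e-4 * abs(leaf[k]))
    pp <- model$params
    pp[[path]][k] <- leaf[k] + h; fp <- lossfn(pp)
    pp[[path]][k] <- leaf[k] - h; fm <- lossfn(pp)
    num <- (fp - fm) / (2 * h)
    ana <- lg$grads[[path]][k]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 2e-3)
  }
})

test_that("custom latent channel counts resize the downstream branch", {
  cfg <- tiny_model_config(vib_out_channels = c(P2 = 2L, P3 = 2L, P4 = 2L))
  model <- build_model(cfg, seed = 7)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fw <- model_forward(model, x)
  expect_identical(dim(fw$fields$P2$mu)[3], 2L)
  expect_identical(dim(fw$probs_per_scale$P2), c(1L, 4L))
})
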