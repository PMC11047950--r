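# Shared fixtures: small synthetic configurations and a finite-difference
# utility. Everything is generated in code at test time.

# A low-resolution generator configuration for fast training tests; the
# positive rates are kept away from the default rare-class extreme so that
# small splits do not go single-valued.
tiny_synth_config <- function(image_size = c(32L, 32L),
                              positive_rate = c(0.5, 0.4, 0.3, 0.25), ...) {
  synth_config(image_size = image_size, positive_rate = positive_rate, ...)
}

# A narrow model matching the tiny generator.
tiny_model_config <- function(num_classes = 4, image_size = c(32L, 32L), ...) {
  model_config(num_classes = num_classes, image_size = image_size,
               backbone_channels = c(3L, 4L, 5L, 6L), ...)
}

# A P-VIB layer whose posterior is constant: mu = mu0, sigma = sigma0.
constant_pvib_layer <- function(channels, mu0, sigma0) {
  layer <- pvib_layer(channels, channels)
  layer$w_mu[] <- 0
  layer$b_mu[] <- mu0
  layer$b_ls[] <- log(sigma0)
  layer
}

# Central finite difference of f at x.
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-8)
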