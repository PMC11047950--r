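# Analytic backward pass through the full network and the Adam optimizer.
# Learnable parameters live in a nested list; leaves are double arrays,
# which lets the whole tree be traversed generically.

map_leaves <- function(p, f) {
  if (is.double(p)) return(f(p))
  if (is.list(p)) for (nm in names(p)) p[[nm]] <- map_leaves(p[[nm]], f)
  p
}

flatten_leaf_paths <- function(p, path = character()) {
  if (is.double(p)) return(list(path))
  if (!is.list(p)) return(list())
  out <- list()
  for (nm in names(p)) {
    out <- c(out, flatten_leaf_paths(p[[nm]], c(path, nm)))
  }
  out
}

get_leaf <- function(p, path) p[[path]]
set_leaf <- function(p, path, value) { p[[path]] <- value; p }

# Effective per-active-scale lambda values: a length-3 configuration maps
# positionally onto (P2, P3, P4); otherwise one value per active scale.
lambda_for_scales <- function(loss_cfg, scales) {
  lam <- loss_cfg$lambda_per_scale
  if (length(lam) == 3) {
    unname(vapply(scales, function(s) lam[match(s, SCALE_ORDER)], numeric(1)))
  } else if (length(lam) == length(scales)) {
    lam
  } else {
    stop(sprintf("%d active scales but %d lambda values", length(scales),
                 length(lam)), call. = FALSE)
  }
}

# Combined objective and its gradients for one mini-batch.
# x: [H, W, C, N] raw images; y: N x num_classes binary matrix.
loss_and_grad <- function(model, x, y, loss_cfg, eps_list = NULL,
                          mode = "train") {
  cfg <- model$cfg; params <- model$params
  fw <- model_forward_impl(model, x, mode = mode, eps_list = eps_list,
                           want_cache = TRUE)
  lambdas <- lambda_for_scales(loss_cfg, cfg$scales)
  grads <- map_leaves(params, function(a) a * 0)
  dfeat <- list()
  cls_vec <- numeric(0); kl_vec <- numeric(0)

  for (i in seq_along(cfg$scales)) {
    s <- cfg$scales[i]
    sp <- params$scales[[s]]
    br <- fw$cache$branches[[s]]
    probs <- fw$probs_per_scale[[s]]
    cls_vec[i] <- bias_focal_loss_scale(probs, y, alpha = loss_cfg$alpha,
                                        lambda_l = lambdas[i],
                                        eps = loss_cfg$eps,
                                        lambda_mode = loss_cfg$lambda_mode)
    dp <- bias_focal_grad(probs, y, alpha = loss_cfg$alpha,
                          lambda_l = lambdas[i], eps = loss_cfg$eps,
                          lambda_mode = loss_cfg$lambda_mode)
    dlogit <- dp * probs * (1 - probs)

    hb <- csra_bwd(dlogit, br$head, sp$head, cfg$head_temperature,
                   cfg$head_residual_weight, cfg$head_score_scale)
    grads$scales[[s]]$head$w <- grads$scales[[s]]$head$w + hb$dw
    grads$scales[[s]]$head$b <- grads$scales[[s]]$head$b + hb$db
    dh <- hb$dx

    kl_here <- 0
    if (cfg$vib_position != "none") {
      field <- fw$fields[[s]]
      kl_here <- kl_loss_scale(field)
      kg <- kl_grad_scale(field)
      if (cfg$vib_position == "after_neck") {
        vb <- pvib_backward(dh, br$vib, sp$vib,
                            dmu_extra = loss_cfg$beta * kg$dmu,
                            dsigma_extra = loss_cfg$beta * kg$dsigma)
        grads$scales[[s]]$vib$w_mu <- grads$scales[[s]]$vib$w_mu + vb$dw_mu
        grads$scales[[s]]$vib$b_mu <- grads$scales[[s]]$vib$b_mu + vb$db_mu
        grads$scales[[s]]$vib$w_ls <- grads$scales[[s]]$vib$w_ls + vb$dw_ls
        grads$scales[[s]]$vib$b_ls <- grads$scales[[s]]$vib$b_ls + vb$db_ls
        dh <- vb$dx
      }
    }
    if (cfg$use_neck) {
      eb <- eca_bwd(dh, br$eca, sp$neck$w)
      grads$scales[[s]]$neck$w <- grads$scales[[s]]$neck$w + eb$dw
      dh <- eb$dx
    }
    if (cfg$vib_position == "before_neck") {
      field <- fw$fields[[s]]
      kg <- kl_grad_scale(field)
      vb <- pvib_backward(dh, br$vib, sp$vib,
                          dmu_extra = loss_cfg$beta * kg$dmu,
                          dsigma_extra = loss_cfg$beta * kg$dsigma)
      grads$scales[[s]]$vib$w_mu <- grads$scales[[s]]$vib$w_mu + vb$dw_mu
      grads$scales[[s]]$vib$b_mu <- grads$scales[[s]]$vib$b_mu + vb$db_mu
      grads$scales[[s]]$vib$w_ls <- grads$scales[[s]]$vib$w_ls + vb$dw_ls
      grads$scales[[s]]$vib$b_ls <- grads$scales[[s]]$vib$b_ls + vb$db_ls
      dh <- vb$dx
    }
    kl_vec[i] <- kl_here
    dfeat[[s]] <- dh
  }

  # trunk backward: accumulate branch gradients down the pyramid
  tc <- fw$cache$trunk$caches
  tp <- params$trunk
  zero_or <- function(s, like) if (!is.null(dfeat[[s]])) dfeat[[s]] else like * 0
  d5 <- zero_or("P4", fw$cache$trunk$feats$P4)
  g5 <- conv_block_bwd(d5, tc[[5]], tp$b4)
  d4 <- g5$dx + zero_or("P3", fw$cache$trunk$feats$P3)
  g4 <- conv_block_bwd(d4, tc[[4]], tp$b3)
  d3 <- g4$dx + zero_or("P2", fw$cache$trunk$feats$P2)
  g3 <- conv_block_bwd(d3, tc[[3]], tp$b2)
  g2 <- conv_block_bwd(g3$dx, tc[[2]], tp$stem2)
  g1 <- conv_block_bwd(g2$dx, tc[[1]], tp$stem1, want_dx = FALSE)
  for (blk in list(list("b4", g5), list("b3", g4), list("b2", g3),
                   list("stem2", g2), list("stem1", g1))) {
    nm <- blk[[1]]; g <- blk[[2]]
    grads$trunk[[nm]]$w <- grads$trunk[[nm]]$w + g$dw
    grads$trunk[[nm]]$b <- grads$trunk[[nm]]$b + g$db
    grads$trunk[[nm]]$gamma <- grads$trunk[[nm]]$gamma + g$dgamma
    grads$trunk[[nm]]$beta <- grads$trunk[[nm]]$beta + g$dbeta
  }

  breakdown <- total_loss(cls_vec, kl_vec, loss_cfg$beta)
  list(breakdown = breakdown, grads = grads,
       probs_per_scale = fw$probs_per_scale, fields = fw$fields)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  z <- map_leaves(params, function(a) a * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (path in flatten_leaf_paths(params)) {
    g <- get_leaf(grads, path)
    m <- beta1 * get_leaf(state$m, path) + (1 - beta1) * g
    v <- beta2 * get_leaf(state$v, path) + (1 - beta2) * g * g
    state$m <- set_leaf(state$m, path, m)
    state$v <- set_leaf(state$v, path, v)
    p <- get_leaf(params, path) - lr * (m / c1) / (sqrt(v / c2) + eps)
    params <- set_leaf(params, path, p)
  }
  list(params = params, state = state)
}
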