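# Internal neural-network plumbing for the convolutional activity model.
#
# Activations are (B*L, C) matrices with rows ordered batch-major
# (row = (b-1)*L + p); model inputs/gradients cross the boundary as
# (4, L, B) cubes. All heavy lifting is im2col/col2im/max-pool and fused
# column-affine ops (C++) plus BLAS matmuls.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# (B*L, C) matrix -> (C, L, B) cube
mat2cube <- function(Z, B, L) {
  C <- ncol(Z)
  aperm(array(Z, dim = c(L, B, C)), c(3, 1, 2))
}

# (C, L, B) cube -> (B*L, C) matrix
cube2mat <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
}

# flatten (B*L, C) -> (B, L*C) with channel-major feature blocks
flatten_mat <- function(Z, B, L) {
  C <- ncol(Z)
  t(matrix(aperm(array(Z, dim = c(L, B, C)), c(1, 3, 2)), L * C, B))
}

unflatten_mat <- function(FM, B, L) {
  C <- ncol(FM) / L
  A <- array(t(FM), dim = c(L, C, B))
  matrix(aperm(A, c(1, 3, 2)), nrow = B * L, ncol = C)
}

# full forward pass; conv bias is folded into the batch-norm affine
nn_forward <- function(model, X, training = FALSE, keep_cache = TRUE) {
  cfg <- model$config
  p <- model$params
  B <- dim(X)[3]
  cache <- list(B = B, training = training, conv = vector("list", 3))
  cur <- cube2mat(X)
  L <- dim(X)[2]
  bn_stats <- model$bn_stats
  for (i in 1:3) {
    k <- cfg$kernels[i]
    Lout <- L - k + 1
    M <- cpp_im2col_mat(cur, B, L, k)
    Z <- M %*% p[[paste0("conv", i, "_W")]]
    bias <- p[[paste0("conv", i, "_b")]]
    if (training) {
      mu <- colMeans(Z) + bias
      v <- colMeans(Z^2) + 2 * bias * colMeans(Z) + bias^2 - mu^2
      bn_stats[[i]]$mean <- (1 - BN_MOMENTUM) * bn_stats[[i]]$mean + BN_MOMENTUM * mu
      bn_stats[[i]]$var <- (1 - BN_MOMENTUM) * bn_stats[[i]]$var + BN_MOMENTUM * v
    } else {
      mu <- bn_stats[[i]]$mean
      v <- bn_stats[[i]]$var
    }
    inv <- 1 / sqrt(v + BN_EPS)
    gamma <- p[[paste0("bn", i, "_gamma")]]
    beta <- p[[paste0("bn", i, "_beta")]]
    # y = gamma * ((Z + bias) - mu) * inv + beta, fused with the ReLU
    A <- cpp_affine_cols(Z, gamma * inv, beta + gamma * inv * (bias - mu), TRUE)
    pool <- cpp_maxpool(A, B, Lout, cfg$pools[i])
    Lp <- Lout / cfg$pools[i]
    if (keep_cache) {
      cache$conv[[i]] <- list(M = M, Z = Z, mu = mu, inv = inv, bias = bias,
                              A = A, pool_idx = pool$idx,
                              Lin = L, Lout = Lout, Lp = Lp, Cin = ncol(cur))
    }
    cur <- pool$y
    L <- Lp
  }
  FM <- flatten_mat(cur, B, L)
  H1 <- cpp_affine_cols(FM %*% p$fc_W, rep(1, cfg$hidden), p$fc_b, TRUE)
  H <- H1
  if (training && cfg$dropout > 0) {
    mask <- matrix(runif(length(H)) >= cfg$dropout, nrow(H)) / (1 - cfg$dropout)
    H <- H * mask
    cache$fc_dropmask <- mask
  }
  if (keep_cache) {
    cache$FM <- FM; cache$fc_mask <- H1 > 0; cache$H <- H; cache$Lp3 <- L
    cache$branch <- vector("list", cfg$n_outputs)
  }
  out <- matrix(0, B, cfg$n_outputs)
  alpha <- cfg$branch_alpha %||% 0
  for (o in seq_len(cfg$n_outputs)) {
    h <- H
    bc <- list()
    for (l in 1:4) {
      W <- p[[sprintf("br%d_%d_W", o, l)]]
      b <- p[[sprintf("br%d_%d_b", o, l)]]
      z <- cpp_affine_cols(h %*% W, rep(1, ncol(W)), b, l < 4, alpha)
      bc[[l]] <- list(input = h, mask = if (l < 4) z > 0 else NULL)
      h <- z
    }
    out[, o] <- h[, 1]
    if (keep_cache) cache$branch[[o]] <- bc
  }
  colnames(out) <- cfg$cell_types
  list(pred = out, cache = if (keep_cache) cache else NULL,
       bn_stats = bn_stats)
}

# backward pass; dY is (B, n_outputs)
nn_backward <- function(model, cache, dY, wrt = c("params", "input")) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  want_params <- "params" %in% wrt
  grads <- if (want_params) list() else NULL
  dH <- matrix(0, B, cfg$hidden)
  alpha <- cfg$branch_alpha %||% 0
  for (o in seq_len(cfg$n_outputs)) {
    dh <- matrix(dY[, o], B, 1)
    for (l in 4:1) {
      bc <- cache$branch[[o]][[l]]
      W <- p[[sprintf("br%d_%d_W", o, l)]]
      if (l < 4) dh <- dh * (alpha + (1 - alpha) * bc$mask)
      if (want_params) {
        grads[[sprintf("br%d_%d_W", o, l)]] <- crossprod(bc$input, dh)
        grads[[sprintf("br%d_%d_b", o, l)]] <- colSums(dh)
      }
      dh <- tcrossprod(dh, W)
    }
    dH <- dH + dh
  }
  if (!is.null(cache$fc_dropmask)) dH <- dH * cache$fc_dropmask
  dH1 <- dH * cache$fc_mask
  if (want_params) {
    grads$fc_W <- crossprod(cache$FM, dH1)
    grads$fc_b <- colSums(dH1)
  }
  dFM <- tcrossprod(dH1, p$fc_W)
  dcur <- unflatten_mat(dFM, B, cache$Lp3)
  for (i in 3:1) {
    cv <- cache$conv[[i]]
    dA <- cpp_maxpool_relu_bw(dcur, cv$pool_idx, B * cv$Lout, cv$A)
    gamma <- p[[paste0("bn", i, "_gamma")]]
    bnb <- cpp_bn_bw(cv$Z, dA, cv$inv, gamma, cv$bias, cv$mu, cache$training)
    dZ <- bnb$dZ
    if (want_params) {
      grads[[paste0("bn", i, "_gamma")]] <- drop(bnb$dgamma)
      grads[[paste0("bn", i, "_beta")]] <- drop(bnb$dbeta)
    }
    if (want_params) {
      grads[[paste0("conv", i, "_W")]] <- crossprod(cv$M, dZ)
      grads[[paste0("conv", i, "_b")]] <- colSums(dZ)
    }
    if (i > 1 || "input" %in% wrt) {
      dM <- tcrossprod(dZ, p[[paste0("conv", i, "_W")]])
      dcur <- cpp_col2im_mat(dM, B, cv$Lin, cfg$kernels[i])
    }
  }
  list(grads = grads,
       dX = if ("input" %in% wrt) mat2cube(dcur, B, cache$conv[[1]]$Lin) else NULL)
}

# Adam optimizer state over a flat named parameter list
adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

cosine_lr <- function(step, total, lr_max, lr_min = 1e-6, warmup = 0) {
  if (warmup > 0 && step <= warmup) return(lr_max * step / warmup)
  prog <- (min(step, total) - warmup) / max(total - warmup, 1)
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * prog))
}

# global gradient-norm clipping
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    s <- max_norm / total
    grads <- lapply(grads, function(g) g * s)
  }
  grads
}
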