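#' Configuration of the convolutional activity predictor
#'
#' The model has three functional segments: (1) three convolutional
#' blocks, each convolution followed by batch normalization, ReLU and
#' max-value pooling; (2) a flatten plus one fully connected layer mixing
#' positional and feature information; (3) one branch per output cell
#' type, each a stack of four independent linear transforms (ReLU between
#' them) ending in a scalar log2FC prediction. The default sizing is in
#' the Basset family and satisfies the pooling arithmetic for a 600-nt
#' input; any alternative config is accepted as long as each pooled
#' length is an integer.
#'
#' @param input_length model input length in nt (insert plus flanks).
#' @param n_outputs number of cell types predicted.
#' @param cell_types optional cell-type names (length `n_outputs`).
#' @param channels,kernels,pools integer vectors of length 3 for the
#'   convolutional stack.
#' @param hidden width of the fully connected layer.
#' @param branch_width width of the per-output branch layers.
#' @param dropout dropout rate applied after the fully connected layer
#'   during training.
#' @param branch_alpha leaky-ReLU slope in the per-output branches
#'   (keeps a branch trainable even if all its units switch off early).
#' @param batch_size,epochs,lr training defaults (MSE loss, Adam with a
#'   cosine-annealed learning rate).
#' @param flank_length length of each constant flank; must satisfy
#'   `input_length = 2*flank_length + 200` for 200-nt inserts (0 means
#'   the model consumes bare inserts).
#' @return a `predictor_config` list.
#' @export
predictor_config <- function(input_length = 600, n_outputs = 3,
                             cell_types = NULL,
                             channels = c(300, 200, 200),
                             kernels = c(19, 11, 7),
                             pools = c(3, 4, 4),
                             hidden = 300, branch_width = 100,
                             dropout = 0, branch_alpha = 0.1,
                             batch_size = 128, epochs = 10, lr = 0.01,
                             flank_length = (input_length - 200) / 2) {
  stopifnot(length(channels) == 3, length(kernels) == 3, length(pools) == 3)
  L <- input_length
  for (i in 1:3) {
    L <- L - kernels[i] + 1
    if (L <= 0) stop(sprintf("conv layer %d: kernel wider than its input", i))
    if (L %% pools[i] != 0) {
      stop(sprintf("conv layer %d: length %d not divisible by pool width %d (flatten contract)",
                   i, L, pools[i]))
    }
    L <- L / pools[i]
  }
  if (is.null(cell_types)) cell_types <- paste0("cell", seq_len(n_outputs))
  stopifnot(length(cell_types) == n_outputs)
  structure(list(input_length = input_length, n_outputs = n_outputs,
                 cell_types = cell_types, channels = channels,
                 kernels = kernels, pools = pools, hidden = hidden,
                 branch_width = branch_width, dropout = dropout,
                 branch_alpha = branch_alpha,
                 batch_size = batch_size, epochs = epochs, lr = lr,
                 flank_length = flank_length, final_length = L),
            class = "predictor_config")
}

#' Build an untrained activity model
#'
#' Allocates and He-initializes all parameters; the same seed always
#' yields identical initial parameters.
#'
#' @param config a [predictor_config()].
#' @param seed RNG seed for initialization.
#' @param flanks flank pair used to pad inserts (list with `flank5`,
#'   `flank3`); defaults to [default_flanks()] trimmed to
#'   `config$flank_length`.
#' @return an object of class `activity_model`.
#' @export
build_activity_model <- function(config, seed = 1,
                                 flanks = default_flanks(config$flank_length)) {
  stopifnot(inherits(config, "predictor_config"))
  if (nchar(flanks$flank5) != config$flank_length ||
      nchar(flanks$flank3) != config$flank_length) {
    stop("flank lengths do not match the model input contract")
  }
  with_seed(seed, {
    p <- list()
    cin <- 4
    for (i in 1:3) {
      fan <- cin * config$kernels[i]
      p[[paste0("conv", i, "_W")]] <- matrix(rnorm(fan * config$channels[i], 0, sqrt(2 / fan)),
                                             fan, config$channels[i])
      p[[paste0("conv", i, "_b")]] <- numeric(config$channels[i])
      p[[paste0("bn", i, "_gamma")]] <- rep(1, config$channels[i])
      p[[paste0("bn", i, "_beta")]] <- numeric(config$channels[i])
      cin <- config$channels[i]
    }
    flat <- config$final_length * config$channels[3]
    p$fc_W <- matrix(rnorm(flat * config$hidden, 0, sqrt(2 / flat)), flat, config$hidden)
    p$fc_b <- numeric(config$hidden)
    for (o in seq_len(config$n_outputs)) {
      widths <- c(config$hidden, config$branch_width, config$branch_width,
                  config$branch_width, 1)
      for (l in 1:4) {
        p[[sprintf("br%d_%d_W", o, l)]] <-
          matrix(rnorm(widths[l] * widths[l + 1], 0, sqrt(2 / widths[l])),
                 widths[l], widths[l + 1])
        p[[sprintf("br%d_%d_b", o, l)]] <- numeric(widths[l + 1])
      }
    }
    bn_stats <- lapply(1:3, function(i) {
      list(mean = numeric(config$channels[i]), var = rep(1, config$channels[i]))
    })
    structure(list(config = config, params = p, bn_stats = bn_stats,
                   flanks = flanks, seed = seed, trained_epochs = 0,
                   metrics = NULL),
              class = "activity_model")
  })
}

#' @export
print.activity_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<activity_model> input %d nt -> %d outputs (%s); conv %s / kernels %s; %d epochs trained\n",
              cfg$input_length, cfg$n_outputs,
              paste(cfg$cell_types, collapse = ","),
              paste(cfg$channels, collapse = "/"),
              paste(cfg$kernels, collapse = "/"),
              x$trained_epochs))
  invisible(x)
}

## generic forward/backward interface -----------------------------------------

# raw forward on a (4, input_length, B) cube, eval mode; no rc handling
model_forward <- function(model, X, keep_cache = FALSE) UseMethod("model_forward")

#' @export
model_forward.activity_model <- function(model, X, keep_cache = FALSE) {
  nn_forward(model, X, training = FALSE, keep_cache = keep_cache)
}

# gradient with respect to the input cube given output cotangent d_out
model_input_grad <- function(model, X, d_out) UseMethod("model_input_grad")

#' @export
model_input_grad.activity_model <- function(model, X, d_out) {
  fw <- nn_forward(model, X, training = FALSE, keep_cache = TRUE)
  bw <- nn_backward(model, fw$cache, d_out, wrt = "input")
  list(pred = fw$pred, dX = bw$dX)
}

## linear reference model ------------------------------------------------------

#' Linear sequence scorer
#'
#' An activity model that is exactly linear in the one-hot input:
#' `pred[cell] = sum(W_cell * X) + b_cell`. Used as a reference model in
#' tests and as a closed-form oracle for attribution methods (integrated
#' gradients of a linear function have an exact solution).
#'
#' @param weights list of 4 x L weight matrices, one per cell type (rows
#'   A,C,G,T).
#' @param bias numeric vector of per-cell intercepts.
#' @param cell_types optional names.
#' @return an object of class `linear_activity_model`.
#' @export
linear_activity_model <- function(weights, bias = numeric(length(weights)),
                                  cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- paste0("cell", seq_along(weights))
  L <- ncol(weights[[1]])
  config <- list(input_length = L, n_outputs = length(weights),
                 cell_types = cell_types, flank_length = 0)
  structure(list(weights = weights, bias = bias, config = config,
                 flanks = list(flank5 = "", flank3 = "")),
            class = "linear_activity_model")
}

#' @export
model_forward.linear_activity_model <- function(model, X, keep_cache = FALSE) {
  B <- dim(X)[3]
  pred <- vapply(seq_along(model$weights), function(ci) {
    w <- model$weights[[ci]]
    vapply(seq_len(B), function(b) sum(w * X[, , b]), numeric(1)) + model$bias[ci]
  }, numeric(B))
  pred <- matrix(pred, nrow = B)
  colnames(pred) <- model$config$cell_types
  list(pred = pred)
}

#' @export
model_input_grad.linear_activity_model <- function(model, X, d_out) {
  B <- dim(X)[3]
  dX <- array(0, dim(X))
  for (ci in seq_along(model$weights)) {
    w <- model$weights[[ci]]
    for (b in seq_len(B)) dX[, , b] <- dX[, , b] + d_out[b, ci] * w
  }
  list(pred = model_forward(model, X)$pred, dX = dX)
}

## user-facing prediction ------------------------------------------------------

# pad a cube of inserts with the model's constant flanks
pad_cube <- function(model, Xins) {
  fl <- model$config$flank_length
  if (fl == 0) return(Xins)
  B <- dim(Xins)[3]
  f5 <- encode_batch(rep(model$flanks$flank5, B))
  f3 <- encode_batch(rep(model$flanks$flank3, B))
  X <- array(0, c(4, fl + dim(Xins)[2] + fl, B))
  X[, seq_len(fl), ] <- f5
  X[, fl + seq_len(dim(Xins)[2]), ] <- Xins
  X[, fl + dim(Xins)[2] + seq_len(fl), ] <- f3
  X
}

#' Predict MPRA activity for a batch of inserts
#'
#' Each insert is padded with the model's constant flanks to the model
#' input length, the model is applied to the forward and the
#' reverse-complement padded sequence, and the two outputs are averaged,
#' making predictions strand-symmetric by construction. Optionally the
#' averaged predictions are clipped into `clamp`.
#'
#' @param model an `activity_model` (or `linear_activity_model`).
#' @param inserts character vector of insert sequences, a single
#'   `onehot_seq`, or a (4, L, B) one-hot cube.
#' @param clamp optional interval, e.g. `c(-2, 6)`; `NULL` leaves
#'   predictions unclipped.
#' @param average_rc average over both strands (default TRUE).
#' @param batch_size internal batch size.
#' @return an n x n_cell matrix of predicted log2FC.
#' @export
predict_activity <- function(model, inserts, clamp = NULL, average_rc = TRUE,
                             batch_size = 256) {
  X <- inserts_to_cube(model, inserts)
  B <- dim(X)[3]
  out <- matrix(0, B, model$config$n_outputs)
  for (start in seq(1, B, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, B)
    Xp <- pad_cube(model, X[, , ix, drop = FALSE])
    pred <- model_forward(model, Xp)$pred
    if (average_rc) {
      pred_rc <- model_forward(model, rc_batch(Xp))$pred
      pred <- (pred + pred_rc) / 2
    }
    out[ix, ] <- pred
  }
  if (!is.null(clamp)) out <- pmin(pmax(out, clamp[1]), clamp[2])
  colnames(out) <- model$config$cell_types
  rownames(out) <- if (is.character(inserts)) names(inserts) else NULL
  out
}

inserts_to_cube <- function(model, inserts) {
  expect_len <- model$config$input_length - 2 * model$config$flank_length
  if (is.character(inserts)) {
    if (any(nchar(inserts) != expect_len)) {
      stop(sprintf("inserts must be %d nt for this model", expect_len))
    }
    encode_batch(inserts)
  } else if (length(dim(inserts)) == 3) {
    stopifnot(dim(inserts)[2] == expect_len)
    inserts
  } else {  # single one-hot matrix (L x 4)
    m <- unclass(inserts)
    stopifnot(nrow(m) == expect_len)
    array(t(m), c(4, nrow(m), 1))
  }
}

# strand-averaged forward pass on an insert cube (no clamping)
insert_forward <- function(model, Xins, average_rc = TRUE) {
  Xp <- pad_cube(model, Xins)
  pred <- model_forward(model, Xp)$pred
  if (average_rc) {
    pred <- (pred + model_forward(model, rc_batch(Xp))$pred) / 2
  }
  pred
}

#' Gradient of model outputs with respect to an insert batch
#'
#' Computes predictions (strand-averaged when `average_rc`) and the
#' gradient of `sum(d_out * pred)` with respect to the one-hot insert,
#' back-propagating through both strand orientations and the constant
#' flanks. This is the gradient access used by the gradient-based
#' designer and by attribution.
#'
#' @param model an activity model.
#' @param Xins (4, L, B) one-hot (or relaxed) insert cube.
#' @param d_out (B, n_outputs) cotangent matrix.
#' @param average_rc average over both strands (default TRUE).
#' @return list with `pred` (B x n_outputs) and `dX` (4, L, B).
#' @export
insert_gradient <- function(model, Xins, d_out, average_rc = TRUE) {
  Xp <- pad_cube(model, Xins)
  fl <- model$config$flank_length
  L <- dim(Xins)[2]
  ins_ix <- fl + seq_len(L)
  if (!average_rc) {
    g <- model_input_grad(model, Xp, d_out)
    return(list(pred = g$pred, dX = g$dX[, ins_ix, , drop = FALSE]))
  }
  gf <- model_input_grad(model, Xp, d_out / 2)
  gr <- model_input_grad(model, rc_batch(Xp), d_out / 2)
  pred <- gf$pred + gr$pred
  dXp <- gf$dX + rc_batch(gr$dX)
  list(pred = pred, dX = dXp[, ins_ix, , drop = FALSE])
}
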