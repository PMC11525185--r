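#' Train the activity model
#'
#' Minimizes mean-squared error of the per-cell-type log2FC predictions
#' over the (augmented) training set with Adam and a cosine-annealed
#' learning rate. After each epoch the validation loss and per-cell-type
#' Pearson r (computed through the strand-averaged [predict_activity()]
#' path) are logged, and the parameters achieving the lowest validation
#' loss are the ones returned (early model selection).
#'
#' @param model an untrained (or partially trained) [build_activity_model()].
#' @param split a [make_split()] result; train/val tables need `sequence`
#'   and `log2fc_<cell>` columns with cell names matching the model
#'   config. Apply [augment_training()] first if augmentation is wanted.
#' @param epochs,batch_size,lr override the config defaults.
#' @param warmup_steps linear learning-rate warmup before the cosine
#'   decay (stabilizes the first passes through the data).
#' @param clip_norm global gradient-norm clip (NULL disables).
#' @param seed RNG seed for shuffling/dropout.
#' @param verbose print per-epoch metrics.
#' @return the trained model, with a `metrics` data.frame attached
#'   (epoch, train_loss, val_loss, and per-cell `val_r_<cell>`).
#' @export
train_activity_model <- function(model, split, epochs = NULL,
                                 batch_size = NULL, lr = NULL,
                                 warmup_steps = 100, clip_norm = 2,
                                 seed = 1, verbose = FALSE) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- lr %||% cfg$lr
  if (epochs == 0) return(model)
  cells <- cfg$cell_types
  tr <- split$train
  padded <- paste0(model$flanks$flank5, tr$sequence, model$flanks$flank3)
  targ <- as.matrix(tr[, paste0("log2fc_", cells), drop = FALSE])
  n <- length(padded)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- steps_per_epoch * epochs
  has_val <- !is.null(split$val) && nrow(split$val) > 0
  with_seed(seed, {
    state <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, bn = model$bn_stats)
    metrics <- NULL
    step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bi in seq_len(steps_per_epoch)) {
        ix <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, n)]
        X <- encode_batch(padded[ix])
        fw <- nn_forward(model, X, training = TRUE, keep_cache = TRUE)
        model$bn_stats <- fw$bn_stats
        resid <- fw$pred - targ[ix, , drop = FALSE]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d step %d (batch size %d); try a lower learning rate",
                       ep, bi, length(ix)))
        }
        ep_loss <- ep_loss + loss
        dY <- 2 * resid / length(resid)
        bw <- nn_backward(model, fw$cache, dY, wrt = "params")
        step <- step + 1
        upd <- adam_step(model$params, clip_grads(bw$grads, clip_norm), state,
                         lr = cosine_lr(step, total_steps, lr, warmup = warmup_steps))
        model$params <- upd$params
        state <- upd$state
      }
      ep_loss <- ep_loss / steps_per_epoch
      row <- data.frame(epoch = ep, train_loss = ep_loss, val_loss = NA_real_)
      if (has_val) {
        vp <- predict_activity(model, split$val$sequence, batch_size = 512)
        vt <- as.matrix(split$val[, paste0("log2fc_", cells), drop = FALSE])
        row$val_loss <- mean((vp - vt)^2)
        for (ci in seq_along(cells)) {
          r <- suppressWarnings(cor(vp[, ci], vt[, ci]))
          if (is.na(r)) warning(sprintf("validation r undefined for %s (constant predictions or targets)", cells[ci]))
          row[[paste0("val_r_", cells[ci])]] <- r
        }
        if (row$val_loss < best$loss) {
          best <- list(loss = row$val_loss, params = model$params,
                       bn = model$bn_stats)
        }
      }
      metrics <- rbind(metrics, row)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f r [%s]", ep, ep_loss,
                        row$val_loss,
                        paste(sprintf("%.3f", unlist(row[grep("val_r_", names(row))])),
                              collapse = " ")))
      }
    }
    if (has_val && is.finite(best$loss)) {
      model$params <- best$params
      model$bn_stats <- best$bn
    }
    model$trained_epochs <- model$trained_epochs + epochs
    model$metrics <- metrics
    model
  })
}

#' Desk-scale surrogate-model configuration
#'
#' A compact configuration of the activity model sized so that training
#' on a few tens of thousands of synthetic oligos finishes in minutes on
#' one CPU: bare 200-nt inserts (no flanks), a 32/24/24-channel
#' convolutional stack and small dense layers. Used throughout the test
#' suite; the full-size default of [predictor_config()] keeps the 600-nt
#' contract.
#'
#' @param cell_types cell-type names.
#' @export
surrogate_config <- function(cell_types = c("cellA", "cellB", "cellC")) {
  predictor_config(input_length = 200, n_outputs = length(cell_types),
                   cell_types = cell_types,
                   channels = c(32, 24, 24), kernels = c(11, 7, 5),
                   pools = c(5, 2, 2), hidden = 96, branch_width = 32,
                   flank_length = 0, batch_size = 256, dropout = 0,
                   epochs = 7, lr = 0.025)
}

#' Simulate, split and train a surrogate activity model
#'
#' End-to-end parameter-recovery experiment on synthetic MPRA data:
#' draws a grammar, simulates `n` oligos, applies the chromosome split
#' and training-set augmentation, trains a [surrogate_config()] model and
#' reports held-out per-cell-type Pearson r.
#'
#' @param n number of simulated oligos.
#' @param seed root seed; grammar, simulation, initialization and
#'   training seeds are derived from it by fixed offsets.
#' @param grammar optional pre-built [synth_grammar()].
#' @param epochs training epochs.
#' @param verbose print per-epoch metrics.
#' @return list: `model`, `grammar`, `split`, `sim` (table +
#'   annotations), `test_r` (named per-cell vector).
#' @export
surrogate_experiment <- function(n = 20000, seed = 1, grammar = NULL,
                                 epochs = 7, verbose = FALSE) {
  if (is.null(grammar)) grammar <- synth_grammar(seed = seed)
  sim <- simulate_mpra(grammar, n = n, seed = seed + 1)
  split <- augment_training(make_split(sim$table))
  cfg <- surrogate_config(grammar$cell_types)
  model <- build_activity_model(cfg, seed = seed + 2)
  model <- train_activity_model(model, split, epochs = epochs,
                                seed = seed + 3, verbose = verbose)
  tp <- predict_activity(model, split$test$sequence)
  tt <- as.matrix(split$test[, paste0("log2fc_", grammar$cell_types)])
  test_r <- setNames(diag(cor(tp, tt)), grammar$cell_types)
  list(model = model, grammar = grammar, split = split, sim = sim,
       test_r = test_r)
}

#' Scan genomic sequence for cell-type-specific windows
#'
#' Tiles every contig of a FASTA file into windows (default 200 nt with a
#' 50-nt stride), predicts activity for each window, scores it with the
#' specificity objective (default bent-MinGap toward `target`), and
#' returns the windows ranked by score. Windows containing N are encoded
#' with all-zero rows and scored like any other window unless `skip_n`.
#'
#' @param model an activity model.
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences.
#' @param target target cell type (index or name).
#' @param window,stride tiling parameters (nt).
#' @param objective `"bent_min_gap"` or `"min_gap"`, or a function
#'   mapping the prediction matrix to a score vector.
#' @param clamp clamp interval passed to the objective.
#' @param top_k keep only the best `top_k` windows (NULL = all).
#' @param skip_n drop windows containing N.
#' @return a data.frame: chrom, start, end, per-cell predictions, score;
#'   sorted by descending score.
#' @export
genome_scan <- function(model, fasta, target = 1, window = 200, stride = 50,
                        objective = "bent_min_gap", clamp = c(-2, 6),
                        top_k = NULL, skip_n = FALSE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    read_fasta(fasta)
  } else fasta
  if (is.null(names(seqs))) names(seqs) <- paste0("contig_", seq_along(seqs))
  score_fn <- if (is.function(objective)) {
    objective
  } else if (objective == "bent_min_gap") {
    function(p) bent_min_gap(p, target = target, clamp = clamp)
  } else if (objective == "min_gap") {
    function(p) min_gap(p, target = target)
  } else stop("unknown objective")
  out <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (L < window) {
      message(sprintf("contig %s shorter than window (%d < %d); skipped", nm, L, window))
      next
    }
    starts <- seq(1, L - window + 1, by = stride)
    subs <- substring(s, starts, starts + window - 1)
    if (skip_n) {
      keep <- !grepl("[Nn]", subs)
      starts <- starts[keep]; subs <- subs[keep]
      if (!length(starts)) next
    }
    pred <- predict_activity(model, subs)
    out[[nm]] <- data.frame(chrom = nm, start = starts - 1L,
                            end = starts - 1L + window,
                            pred, score = score_fn(pred),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top_k)) res <- head(res, top_k)
  res
}
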