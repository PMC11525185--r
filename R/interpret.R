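#' Sampled integrated gradients (SIG) attribution
#'
#' Integrated-gradients attribution computed along the straight path in
#' logit (log-probability) space from the uniform background (the zero
#' matrix) to `logit_scale` times the one-hot of the sequence, which
#' concentrates nearly all probability mass on the observed bases. At
#' each path point the logits are soft-maxed into a position probability
#' matrix, a batch of one-hot sequences is sampled from it and fed
#' through the model (so the model only ever sees vertices of the
#' simplex), and gradients are taken with respect to the logits via the
#' straight-through estimator. Averaging over samples and path points and
#' scaling by the path length yields *hypothetical* contribution scores
#' for all four bases at every position; masking by the one-hot gives the
#' contribution scores of the observed sequence.
#'
#' @param model an activity model.
#' @param seq a single insert sequence (string or `onehot_seq`).
#' @param n_path_points path points for the integral (midpoint rule).
#' @param samples_per_point one-hot samples per path point.
#' @param logit_scale endpoint scale in logit space (10 puts ~0.999
#'   probability on the observed base).
#' @param cells cell types to attribute (indices or names; default all).
#' @param average_rc attribute through the strand-averaged prediction.
#' @param return_se also return the per-entry Monte-Carlo standard error.
#' @param seed RNG seed.
#' @return an object of class `contribution_map`: list with
#'   `hypothetical` and `masked` (arrays n_cells x L x 4), `seq_id`,
#'   `sequence`, `cells`, and optionally `se`.
#' @export
sampled_integrated_gradients <- function(model, seq, n_path_points = 32,
                                         samples_per_point = 16,
                                         logit_scale = 10, cells = NULL,
                                         average_rc = TRUE, return_se = FALSE,
                                         seed = 1) {
  x <- if (is.character(seq)) encode_onehot(seq) else seq
  onehot <- unclass(x)                    # L x 4
  L <- nrow(onehot)
  cell_names <- model$config$cell_types
  if (is.null(cells)) cells <- seq_along(cell_names)
  if (is.character(cells)) cells <- match(cells, cell_names)
  n_out <- model$config$n_outputs
  hyp <- array(0, c(length(cells), L, 4))
  sev <- if (return_se) array(0, c(length(cells), L, 4)) else NULL
  with_seed(seed, {
    alphas <- (seq_len(n_path_points) - 0.5) / n_path_points
    for (ci in seq_along(cells)) {
      cc <- cells[ci]
      acc <- matrix(0, L, 4)
      acc2 <- matrix(0, L, 4)
      nacc <- 0
      for (a in alphas) {
        theta <- a * logit_scale * onehot
        p <- softmax_rows(theta)
        X <- sample_onehot_cube(p, samples_per_point)
        d_out <- matrix(0, samples_per_point, n_out)
        d_out[, cc] <- 1
        g <- insert_gradient(model, X, d_out, average_rc = average_rc)
        if (any(!is.finite(g$dX))) {
          stop(sprintf("non-finite gradients at path point alpha=%.3f", a))
        }
        for (b in seq_len(samples_per_point)) {
          gb <- t(g$dX[, , b])            # L x 4, straight-through to p
          gtheta <- p * (gb - rowSums(p * gb))  # softmax backward
          acc <- acc + gtheta
          acc2 <- acc2 + gtheta^2
          nacc <- nacc + 1
        }
      }
      mean_g <- acc / nacc
      hyp[ci, , ] <- logit_scale * mean_g
      if (return_se) {
        varg <- pmax(acc2 / nacc - mean_g^2, 0)
        sev[ci, , ] <- logit_scale * sqrt(varg / nacc)
      }
    }
  })
  masked <- hyp * rep(aperm(array(onehot, c(L, 4, length(cells))), c(3, 1, 2)), 1)
  structure(list(hypothetical = hyp, masked = masked,
                 seq_id = attr(x, "name") %||% "seq",
                 sequence = decode_onehot(onehot),
                 cells = cell_names[cells],
                 se = sev),
            class = "contribution_map")
}

#' Per-position contribution track of a map
#'
#' Masked contributions summed over the base axis: one score per
#' position, the input for block calling.
#'
#' @param map a `contribution_map`.
#' @param cell cell type (index or name within the map).
#' @export
contribution_track <- function(map, cell = 1) {
  if (is.character(cell)) cell <- match(cell, map$cells)
  rowSums(map$masked[cell, , ])
}

# 1-D Gaussian smoothing with reflect boundary handling
gaussian_smooth <- function(x, sigma, truncate = 4) {
  lw <- as.integer(truncate * sigma + 0.5)
  w <- exp(-0.5 * ((-lw:lw) / sigma)^2)
  w <- w / sum(w)
  n <- length(x)
  padded <- c(x[lw:1], x, x[n:(n - lw + 1)])
  out <- stats::filter(padded, w, sides = 2)
  as.numeric(out)[(lw + 1):(lw + n)]
}

#' Call contribution blocks
#'
#' Smooths a per-position contribution track with a Gaussian filter
#' (sigma 1.15) and calls a positive block wherever the smoothed signal
#' exceeds `thresh` for at least `min_run` contiguous positions, and a
#' negative block wherever it stays below `-thresh` likewise (the
#' symmetric convention: a negative block marks genuinely repressive
#' signal, not weak positive signal).
#'
#' @param scores numeric per-position contribution track (see
#'   [contribution_track()]).
#' @param sigma Gaussian sigma (positions).
#' @param thresh block threshold on the smoothed signal.
#' @param min_run minimum run length (positions).
#' @return data.frame with `start` (0-based), `end` (half-open), `sign`
#'   (`"+"`/`"-"`) and `mean_score` (mean smoothed signal in the block).
#' @export
call_blocks <- function(scores, sigma = 1.15, thresh = 0.015, min_run = 4) {
  sm <- gaussian_smooth(scores, sigma)
  out <- list()
  for (sgn in c("+", "-")) {
    above <- if (sgn == "+") sm > thresh else sm < -thresh
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= min_run)
    for (i in keep) {
      out[[length(out) + 1]] <- data.frame(
        start = starts[i] - 1L, end = ends[i], sign = sgn,
        mean_score = mean(sm[starts[i]:ends[i]]))
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      sign = character(0), mean_score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Ablate contribution blocks in silico
#'
#' Replaces the positions of positive blocks, negative blocks, or
#' randomly chosen positions outside any block with uniform-random bases
#' and reports the predicted activity change (disrupted minus original).
#' Outside-mode coverage is matched to the upper half of the observed
#' block-coverage distribution with a minimum of five positions;
#' sequences where that is infeasible are recorded as skipped.
#'
#' @param model an activity model.
#' @param seqs named character vector of sequences.
#' @param blocks_list list (parallel to `seqs`) of [call_blocks()]
#'   results.
#' @param mode `"positive"`, `"negative"`, or `"outside"`.
#' @param n_random replicate randomizations averaged per sequence.
#' @param seed RNG seed.
#' @return data.frame with `seq_id`, `n_positions`, `skipped`, and one
#'   `delta_<cell>` column per cell type.
#' @export
ablate_blocks <- function(model, seqs, blocks_list,
                          mode = c("positive", "negative", "outside"),
                          n_random = 1, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  # pooled block coverage sizes for outside-mode matching
  coverages <- unlist(lapply(blocks_list, function(b) {
    if (nrow(b)) sum(b$end - b$start) else NULL
  }))
  upper_cov <- if (length(coverages)) coverages[coverages >= median(coverages)] else integer(0)
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(seqs)) {
      s <- seqs[i]
      blocks <- blocks_list[[i]]
      L <- nchar(s)
      if (mode %in% c("positive", "negative")) {
        bb <- blocks[blocks$sign == if (mode == "positive") "+" else "-", , drop = FALSE]
        if (!nrow(bb)) next
        pos <- unlist(mapply(function(a, b) (a + 1):b, bb$start, bb$end, SIMPLIFY = FALSE))
      } else {
        inblock <- unique(unlist(mapply(function(a, b) (a + 1):b,
                                        blocks$start, blocks$end, SIMPLIFY = FALSE)))
        outside <- setdiff(seq_len(L), inblock)
        want <- if (length(upper_cov)) sample(upper_cov, 1) else 5L
        want <- max(5L, min(want, length(outside)))
        if (length(outside) < 5L) {
          rows[[length(rows) + 1]] <- data.frame(seq_id = names(seqs)[i],
                                                 n_positions = 0L, skipped = TRUE)
          next
        }
        pos <- sample(outside, want)
      }
      preds <- 0
      for (r in seq_len(n_random)) {
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- sample(DNA_BASES, length(pos), replace = TRUE)
        preds <- preds + predict_activity(model, paste(ch, collapse = ""))
      }
      delta <- preds / n_random - predict_activity(model, s)
      row <- data.frame(seq_id = names(seqs)[i], n_positions = length(pos),
                        skipped = FALSE)
      for (ci in seq_len(ncol(delta))) row[[paste0("delta_", colnames(delta)[ci])]] <- delta[1, ci]
      rows[[length(rows) + 1]] <- row
    }
    if (!length(rows)) return(data.frame())
    out <- do.call(rbind, lapply(rows, function(r) {
      # align columns across skipped/unskipped rows
      for (cc in paste0("delta_", model$config$cell_types)) {
        if (is.null(r[[cc]])) r[[cc]] <- NA_real_
      }
      r
    }))
    rownames(out) <- NULL
    out
  })
}

#' Convert an attribution pattern to PWM/PPM form
#'
#' A pattern living in hypothetical-contribution-score space (w x 4) is
#' scaled into a PWM by dividing by the maximum position score sum and
#' multiplying by 10; the PPM is the row-wise softmax of that PWM. For a
#' negative-polarity pattern, positions whose contribution (from
#' `contrib`, the masked contribution-score-space pattern, or the
#' pattern's own row sums) is negative first have their sign flipped and
#' their magnitude compensated by 1.2 before the same conversion.
#' Scaling the input pattern by any positive constant leaves the result
#' unchanged.
#'
#' @param pattern w x 4 hypothetical scores.
#' @param polarity `"positive"` or `"negative"`.
#' @param contrib optional w x 4 contribution-score-space pattern used to
#'   determine the negative portions.
#' @param id motif identifier.
#' @param neg_compensation magnitude factor for flipped portions.
#' @return a [motif_model()] whose `pwm` is the scaled pattern, `ppm` its
#'   row softmax and `cwm` the original pattern.
#' @export
pattern_to_pwm <- function(pattern, polarity = c("positive", "negative"),
                           contrib = NULL, id = "pattern",
                           neg_compensation = 1.2) {
  polarity <- match.arg(polarity)
  pattern <- as.matrix(pattern)
  stopifnot(ncol(pattern) == 4)
  if (all(pattern == 0)) stop("all-zero pattern")
  work <- pattern
  if (polarity == "negative") {
    ref <- if (is.null(contrib)) pattern else as.matrix(contrib)
    neg_pos <- rowSums(ref) < 0
    work[neg_pos, ] <- -neg_compensation * work[neg_pos, ]
  }
  max_sum <- max(rowSums(work))
  if (max_sum <= 0) stop("pattern has no positive position score sum after sign handling")
  pwm <- 10 * work / max_sum
  ppm <- softmax_rows(pwm)
  m <- motif_model(ppm, id = id, cwm = pattern, source = "discovered")
  m$pwm <- pwm
  m$consensus_score <- sum(apply(pwm, 1, max))
  m
}

#' Predicted effect of a motif embedded in random background
#'
#' Builds a 200 x 4 PPM that is uniform everywhere except the motif's PPM
#' centered in the middle, samples `n` sequences from it and from the
#' all-uniform baseline, predicts both batches, and reports the
#' per-cell-type mean difference with its standard error.
#'
#' @param model an activity model.
#' @param motif a [motif_model()].
#' @param n sequences per batch (default 5000).
#' @param length background length.
#' @param seed RNG seed.
#' @return data.frame per cell type: mean with motif, baseline mean,
#'   `delta`, `se`.
#' @export
motif_embed_background <- function(model, motif, n = 5000, length = 200,
                                   seed = 1) {
  stopifnot(motif$width <= length)
  ppm <- matrix(0.25, length, 4)
  st <- floor((length - motif$width) / 2)
  ppm[st + seq_len(motif$width), ] <- motif$ppm
  seqs <- sample_from_ppm(ppm, n, seed = seed)
  base <- sample_from_ppm(matrix(0.25, length, 4), n, seed = seed + 1)
  pm <- predict_activity(model, seqs)
  pb <- predict_activity(model, base)
  data.frame(cell = colnames(pm),
             mean_motif = colMeans(pm),
             mean_baseline = colMeans(pb),
             delta = colMeans(pm) - colMeans(pb),
             se = sqrt(apply(pm, 2, var) / n + apply(pb, 2, var) / n),
             row.names = NULL)
}

#' In-silico motif ablation
#'
#' For each sequence carrying at least one hit of the motif, all hit
#' spans (overlaps merged) are replaced with uniform-random segments,
#' predictions are averaged over `n_random` independent replacements,
#' and the original prediction is subtracted.
#'
#' @param model an activity model.
#' @param seqs named character vector.
#' @param hits data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open, clipped to the sequence).
#' @param n_random replicate randomizations (default 5).
#' @param seed RNG seed.
#' @return data.frame: `seq_id`, `n_hits`, `delta_<cell>` columns.
#'   Sequences without hits are absent.
#' @export
motif_ablation <- function(model, seqs, hits, n_random = 5, seed = 1) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  with_seed(seed, {
    rows <- list()
    for (id in intersect(names(seqs), unique(hits$seq_id))) {
      s <- seqs[[id]]
      L <- nchar(s)
      h <- hits[hits$seq_id == id, , drop = FALSE]
      h$start <- pmax(h$start, 0L); h$end <- pmin(h$end, L)
      h <- h[h$end > h$start, , drop = FALSE]
      if (!nrow(h)) next
      # merge overlapping spans
      h <- h[order(h$start), , drop = FALSE]
      spans <- list(c(h$start[1], h$end[1]))
      for (i in seq_len(nrow(h))[-1]) {
        last <- spans[[length(spans)]]
        if (h$start[i] <= last[2]) {
          spans[[length(spans)]][2] <- max(last[2], h$end[i])
        } else spans[[length(spans) + 1]] <- c(h$start[i], h$end[i])
      }
      pos <- unlist(lapply(spans, function(sp) (sp[1] + 1):sp[2]))
      preds <- 0
      for (r in seq_len(n_random)) {
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- sample(DNA_BASES, length(pos), replace = TRUE)
        preds <- preds + predict_activity(model, paste(ch, collapse = ""))
      }
      delta <- preds / n_random - predict_activity(model, s)
      row <- data.frame(seq_id = id, n_hits = nrow(h))
      for (ci in seq_len(ncol(delta))) row[[paste0("delta_", colnames(delta)[ci])]] <- delta[1, ci]
      rows[[length(rows) + 1]] <- row
    }
    if (!length(rows)) return(data.frame())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Motif contribution summary
#'
#' For each motif and cell type, the weighted mean over its hit instances
#' of the masked contribution score summed inside the hit span, weighted
#' by the hit's match coefficient (Pearson r). The overall regulatory
#' directionality of a motif (activator/repressor) is the sign of the
#' mean of those weighted averages across cell types.
#'
#' @param hits data.frame from [contribution_motif_scan()]: `seq_id`,
#'   `cell`, `motif`, `start`, `end`, `r`.
#' @param maps named list of `contribution_map`s keyed by `seq_id`.
#' @param use `"masked"` (default) or `"hypothetical"` score source.
#' @return list with `by_cell` (motif, cell, weighted_mean, n) and
#'   `directionality` (motif, mean_contribution, direction). Motifs with
#'   zero hits are absent.
#' @export
motif_contribution_summary <- function(hits, maps, use = c("masked", "hypothetical")) {
  use <- match.arg(use)
  if (!nrow(hits)) return(list(by_cell = data.frame(), directionality = data.frame()))
  sums <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    m <- maps[[hits$seq_id[i]]]
    ci <- match(hits$cell[i], m$cells)
    L <- dim(m$masked)[2]
    a <- max(hits$start[i] + 1L, 1L); b <- min(hits$end[i], L)
    sums[i] <- if (b >= a) sum(m[[use]][ci, a:b, ]) else 0
  }
  hits$contrib_sum <- sums
  by_cell <- do.call(rbind, lapply(split(hits, list(hits$motif, hits$cell), drop = TRUE),
                                   function(g) {
    data.frame(motif = g$motif[1], cell = g$cell[1],
               weighted_mean = sum(g$r * g$contrib_sum) / sum(g$r),
               n = nrow(g))
  }))
  rownames(by_cell) <- NULL
  direction <- do.call(rbind, lapply(split(by_cell, by_cell$motif), function(g) {
    mc <- mean(g$weighted_mean)
    data.frame(motif = g$motif[1], mean_contribution = mc,
               direction = if (mc >= 0) "activator" else "repressor")
  }))
  rownames(direction) <- NULL
  list(by_cell = by_cell, directionality = direction)
}

#' Motif co-occurrence percentages
#'
#' A motif pair co-occurs in a sequence when the sequence has at least
#' one hit of each motif. For each group of sequence ids the symmetric
#' matrix of co-occurrence percentages is returned.
#'
#' @param hits data.frame with `seq_id` and `motif`.
#' @param groups named list of sequence-id vectors (a partition).
#' @return named list of motif x motif percentage matrices.
#' @export
motif_cooccurrence <- function(hits, groups) {
  motifs <- sort(unique(hits$motif))
  lapply(groups, function(ids) {
    M <- matrix(NA_real_, length(motifs), length(motifs),
                dimnames = list(motifs, motifs))
    if (!length(ids)) {
      warning("empty group; returning NaN matrix")
      M[] <- NaN
      return(M)
    }
    present <- vapply(motifs, function(m) {
      ids %in% unique(hits$seq_id[hits$motif == m])
    }, logical(length(ids)))
    present <- matrix(present, nrow = length(ids))
    M[] <- 100 * (t(present) %*% present) / length(ids)
    M
  })
}

#' Saturation-mutagenesis effect map
#'
#' Effects are variant activity minus the reference activity; the
#' per-position summary is the negative mean effect (the logo-height
#' convention: a position where every substitution loses activity gets a
#' positive summary).
#'
#' @param ref_activity reference sequence activity (single cell type).
#' @param variants data.frame with `position` (0-based), `alt` (base) and
#'   `activity`; a complete scan has 3 variants at each position.
#' @param n_positions expected number of positions (default 200; NULL
#'   skips the completeness check).
#' @return list with `effects` (variants plus `effect` column) and
#'   `per_position` (position, mean_effect, summary = -mean_effect).
#' @export
saturation_effects <- function(ref_activity, variants, n_positions = 200) {
  counts <- table(variants$position)
  if (!is.null(n_positions)) {
    expect <- as.character(0:(n_positions - 1))
    missing <- setdiff(expect, names(counts))
    bad <- names(counts)[counts != 3]
    if (length(missing) || length(bad)) {
      stop(sprintf("incomplete scan: positions missing [%s], not 3 variants at [%s]",
                   paste(head(missing, 5), collapse = ","),
                   paste(head(bad, 5), collapse = ",")))
    }
  }
  variants$effect <- variants$activity - ref_activity
  per_pos <- do.call(rbind, lapply(split(variants, variants$position), function(g) {
    data.frame(position = g$position[1], mean_effect = mean(g$effect),
               summary = -mean(g$effect))
  }))
  per_pos <- per_pos[order(per_pos$position), , drop = FALSE]
  rownames(per_pos) <- NULL
  list(effects = variants, per_position = per_pos)
}

#' k-mer nearest-neighbour diversity
#'
#' Represents each sequence by its k-mer count vector and reports the
#' mean Manhattan distance to its `n_neighbors` nearest neighbours (self
#' excluded). Identical sequence sets score 0; more diverse sets score
#' higher.
#'
#' @param sequences character vector (length > `n_neighbors`).
#' @param k k-mer size (default 4).
#' @param n_neighbors neighbours averaged (default 4).
#' @return numeric vector of per-sequence mean distances.
#' @export
kmer_diversity <- function(sequences, k = 4, n_neighbors = 4) {
  n <- length(sequences)
  if (n <= n_neighbors) stop("need more sequences than neighbours")
  vocab <- sort(unique(unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    unique(substring(s, 1:(L - k + 1), k:L))
  }))))
  counts <- t(vapply(sequences, function(s) {
    L <- nchar(s)
    words <- substring(s, 1:(L - k + 1), k:L)
    tab <- table(factor(words, levels = vocab))
    as.numeric(tab)
  }, numeric(length(vocab))))
  D <- as.matrix(dist(counts, method = "manhattan"))
  diag(D) <- Inf
  apply(D, 1, function(row) mean(sort(row)[seq_len(n_neighbors)]))
}
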