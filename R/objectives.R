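#' MinGap specificity objective
#'
#' Activity in the target cell type minus the maximum off-target
#' activity. Positive values mean the target cell type leads all others.
#'
#' @param a numeric activity vector (one value per cell type), or a
#'   matrix with one row per sequence.
#' @param target index (or name) of the target cell type.
#' @return a numeric value (or vector for matrix input).
#' @export
min_gap <- function(a, target) {
  if (is.matrix(a)) return(apply(a, 1, min_gap, target = target))
  if (length(a) < 2) stop("min_gap needs at least two cell types")
  if (is.character(target)) target <- match(target, names(a))
  a[target] - max(a[-target])
}

#' Bending function
#'
#' `g(x) = x - exp(-x) + 1`: approximately `x + 1` for large positive x
#' and strongly negative for negative x, so that an objective built from
#' `g` rewards driving off-target activity low rather than just far from
#' the target.
#'
#' @param x numeric.
#' @export
bend <- function(x) x - exp(-x) + 1

# derivative of the bending function
bend_grad <- function(x) 1 + exp(-x)

#' Bent-MinGap objective
#'
#' Activities are clamped into `clamp`, then the bending function is
#' applied to the target activity and to the maximum off-target activity:
#' `g(y+) - g(y-)`.
#'
#' @inheritParams min_gap
#' @param clamp numeric interval into which activities are clipped before
#'   bending (default `c(-2, 6)`); `NULL` disables clamping.
#' @export
bent_min_gap <- function(a, target, clamp = c(-2, 6)) {
  if (is.matrix(a)) return(apply(a, 1, bent_min_gap, target = target, clamp = clamp))
  if (length(a) < 2) stop("bent_min_gap needs at least two cell types")
  if (is.character(target)) target <- match(target, names(a))
  if (!is.null(clamp)) a <- pmin(pmax(a, clamp[1]), clamp[2])
  bend(a[target]) - bend(max(a[-target]))
}

#' Motif penalty of a sequence batch
#'
#' Given an ordered motif pool of size `m` with per-motif score thresholds
#' `t_i`, the penalty is
#' `1/(m*n) * sum_i (m - i + 1)^(1/3) * sum_{j: s_j >= t_i} s_j`,
#' where `j` runs over every window of every batch sequence and of their
#' reverse complements, and `s_j` is the PWM match score. The cube-root
#' weighting emphasizes motifs added to the pool earlier. For `m = 1` the
#' penalty reduces to the per-sequence mean of the above-threshold score
#' sum.
#'
#' @param batch character vector of sequences (or list of one-hot
#'   matrices).
#' @param pool a [penalty_pool()].
#' @return a non-negative number.
#' @export
motif_penalty <- function(batch, pool) {
  m <- length(pool$motifs)
  if (!m) stop("penalty pool is empty")
  n <- length(batch)
  total <- 0
  for (i in seq_len(m)) {
    motif <- pool$motifs[[i]]
    t_i <- pool$thresholds[i]
    s_i <- 0
    for (s in batch) {
      x <- if (is.character(s)) encode_onehot(s) else s
      if (motif$width > nrow(x)) {
        warning(sprintf("motif %s wider than sequence; contributes 0", motif$id))
        next
      }
      sc <- c(pwm_window_scores(motif$pwm, x),
              pwm_window_scores(rc_matrix(motif$pwm), x))
      s_i <- s_i + sum(sc[sc >= t_i])
    }
    total <- total + (m - i + 1)^(1 / 3) * s_i
  }
  total / (m * n)
}

#' Ordered motif pool for penalization
#'
#' The pool order is the inclusion order of the motifs (earlier motifs are
#' weighted more strongly by [motif_penalty()]); thresholds are expressed
#' as a fraction of each motif's consensus score.
#'
#' @param motifs list of [motif_model()] objects.
#' @param threshold_frac fraction(s) of the consensus score used as the
#'   match-score threshold (0 penalizes every positive-scoring window;
#'   0.25 only reasonably strong matches).
#' @export
penalty_pool <- function(motifs, threshold_frac = 0.25) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  frac <- rep_len(threshold_frac, length(motifs))
  structure(list(
    motifs = motifs,
    thresholds = vapply(seq_along(motifs),
                        function(i) frac[i] * motifs[[i]]$consensus_score,
                        numeric(1)),
    threshold_frac = frac), class = "penalty_pool")
}

#' Motif-presence score of a sequence
#'
#' Sum of all motif-match scores passing the Patser score threshold,
#' divided by the maximum possible motif score (the consensus match
#' score). A sequence equal to the consensus scores 1; a sequence
#' carrying two consensus copies scores 2; a sequence with no passing
#' window scores 0. Both strands are scanned.
#'
#' @param seq DNA string or one-hot matrix.
#' @param motif a [motif_model()].
#' @param threshold match-score threshold (default: Patser).
#' @export
motif_presence_score <- function(seq, motif, threshold = patser_threshold(motif)) {
  hits <- pwm_scan(motif, seq, threshold = threshold)
  if (!nrow(hits)) return(0)
  sum(hits$score) / motif$consensus_score
}

#' Propeller coordinates of a three-cell activity vector
#'
#' Maps a triple of activities to the propeller coordinate system: the
#' axis is the cell type with the maximum activity, the radial distance is
#' MaxGap (maximum minus minimum), and the angle of deviation from the
#' axis is `60 * (median - min) / (max - min)` degrees, bending toward the
#' axis of the median cell type. A degenerate triple (MaxGap 0) is placed
#' at angle 0 on the axis of the first (lowest-index) cell type. Adding a
#' constant to all three activities leaves the coordinates unchanged.
#'
#' @param a numeric vector of exactly 3 activities, or a 3-column matrix.
#' @return a data.frame with columns `axis` (argmax index), `median_axis`,
#'   `radius`, `angle_deg`, `min_activity`, `tie` (argmax tie flag).
#' @export
propeller <- function(a) {
  if (is.matrix(a)) {
    out <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) propeller(a[i, ])))
    rownames(out) <- rownames(a)
    return(out)
  }
  stopifnot(length(a) == 3)
  ord <- order(a, decreasing = TRUE)
  axis <- which(a == max(a))[1]        # ties -> lowest index
  tie <- sum(a == max(a)) > 1
  radius <- max(a) - min(a)
  med <- median(a)
  med_axis <- setdiff(order(abs(a - med))[1:2], axis)[1]
  if (radius == 0) {
    angle <- 0
    med_axis <- axis
  } else {
    angle <- 60 * (med - min(a)) / radius
  }
  data.frame(axis = axis, median_axis = med_axis, radius = radius,
             angle_deg = angle, min_activity = min(a), tie = tie)
}

#' Cell-type specificity call for a three-cell activity vector
#'
#' A sequence is called specific when (1) MaxGap (max - min activity)
#' strictly exceeds `maxgap_min`, and (2) MinGap/MaxGap strictly exceeds
#' 0.5 -- i.e. the maximum off-target cell type sits closer to the minimum
#' than to the target, equivalently the propeller deviation angle is below
#' 30 degrees. The target is taken to be the cell type with the maximum
#' activity (MinGap = max - median); when `designed_target` is given and
#' differs from the argmax, the call is flagged as reassigned. Stringent
#' calling uses `maxgap_min = 4` (a fourfold increase over the lenient 1).
#'
#' @param a numeric vector of 3 activities (or a 3-column matrix).
#' @param maxgap_min minimum MaxGap (strict; default 1, stringent 4).
#' @param ratio_min minimum MinGap/MaxGap ratio (strict; default 0.5).
#' @param designed_target optional intended target cell index (or vector).
#' @return a data.frame with `specific`, `effective_target`, `reassigned`,
#'   `max_gap`, `min_gap_over_max_gap`.
#' @export
classify_specific <- function(a, maxgap_min = 1, ratio_min = 0.5,
                              designed_target = NULL) {
  if (is.matrix(a)) {
    dt <- designed_target
    if (!is.null(dt)) dt <- rep_len(dt, nrow(a))
    out <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
      classify_specific(a[i, ], maxgap_min, ratio_min,
                        if (is.null(dt)) NULL else dt[i])
    }))
    rownames(out) <- rownames(a)
    return(out)
  }
  stopifnot(length(a) == 3)
  mx <- max(a); mn <- min(a); md <- median(a)
  max_gap <- mx - mn
  min_gap_val <- mx - md
  ratio <- if (max_gap > 0) min_gap_val / max_gap else NA_real_
  specific <- isTRUE(max_gap > maxgap_min && !is.na(ratio) && ratio > ratio_min)
  eff <- which(a == mx)[1]
  data.frame(specific = specific, effective_target = eff,
             reassigned = if (is.null(designed_target)) NA else eff != designed_target,
             max_gap = max_gap, min_gap_over_max_gap = ratio)
}

#' Library-level specificity report
#'
#' Applies the replicate-SE filter, classifies each oligo with
#' [classify_specific()] at lenient and stringent thresholds, and reports
#' per-group percentages of specific sequences plus the number of
#' sequences that pass only by having their target reassigned to the
#' argmax cell type.
#'
#' @param table MPRA data.frame with 3 `log2fc_` columns, `se_` columns,
#'   a `group` column (design method) and a `designed_target` column
#'   (cell-type name or index).
#' @param apply_se_filter apply [se_filter()] before counting (default
#'   TRUE).
#' @param max_se SE threshold.
#' @return a list: `by_group` (group, n, pct_specific_lenient,
#'   pct_specific_stringent), `reassigned_lenient`,
#'   `reassigned_stringent`, and the per-oligo `calls` table.
#' @export
specificity_report <- function(table, apply_se_filter = TRUE, max_se = 1) {
  if (apply_se_filter) table <- se_filter(table, max_se)
  cells <- mpra_cell_types(table)
  stopifnot(length(cells) == 3)
  act <- log2fc_matrix(table)
  tgt <- table$designed_target
  if (is.character(tgt)) tgt <- match(tgt, cells)
  len <- classify_specific(act, maxgap_min = 1, designed_target = tgt)
  str <- classify_specific(act, maxgap_min = 4, designed_target = tgt)
  calls <- data.frame(oligo_id = table$oligo_id, group = table$group,
                      designed_target = tgt,
                      specific_lenient = len$specific,
                      specific_stringent = str$specific,
                      effective_target = len$effective_target,
                      reassigned = len$reassigned)
  by_group <- do.call(rbind, lapply(split(calls, calls$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               pct_specific_lenient = round(100 * mean(g$specific_lenient), 1),
               pct_specific_stringent = round(100 * mean(g$specific_stringent), 1))
  }))
  rownames(by_group) <- NULL
  list(by_group = by_group,
       reassigned_lenient = sum(len$specific & len$reassigned, na.rm = TRUE),
       reassigned_stringent = sum(str$specific & str$reassigned, na.rm = TRUE),
       calls = calls)
}

#' Propeller dot plot
#'
#' Renders activity triples in the propeller coordinate system: three
#' axes at 120-degree spacing (axis 1 up), radial distance = MaxGap,
#' angular deviation from the winning axis toward the median axis.
#'
#' @param act 3-column activity matrix.
#' @param cells axis labels.
#' @param col point colors (defaults to the winning axis).
#' @param ... passed to [graphics::plot()].
#' @export
plot_propeller <- function(act, cells = colnames(act), ...) {
  pr <- propeller(act)
  axis_ang <- c(90, 210, 330) * pi / 180   # axes for cells 1..3
  # deviation sign: toward the median axis (clockwise or counterclockwise)
  delta <- ifelse(((pr$median_axis - pr$axis) %% 3) == 1, -1, 1)
  theta <- axis_ang[pr$axis] + delta * pr$angle_deg * pi / 180
  xx <- pr$radius * cos(theta)
  yy <- pr$radius * sin(theta)
  rmax <- max(pr$radius, 1)
  graphics::plot(xx, yy, asp = 1, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor(c("#1b9e77", "#d95f02", "#7570b3")[pr$axis], 0.6),
                 xlab = "", ylab = "", axes = FALSE, ...)
  for (i in 1:3) {
    graphics::segments(0, 0, rmax * cos(axis_ang[i]), rmax * sin(axis_ang[i]), col = "grey60")
    graphics::text(1.08 * rmax * cos(axis_ang[i]), 1.08 * rmax * sin(axis_ang[i]),
                   labels = if (is.null(cells)) paste0("cell", i) else cells[i])
  }
  invisible(pr)
}
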