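#' Construct a motif model
#'
#' A motif is carried in up to three linked forms: a position probability
#' matrix (PPM), a position weight matrix (PWM, log2-odds of each base
#' against the uniform 0.25 background) and, optionally, a contribution
#' weight matrix (CWM) for motifs derived from attribution maps. The
#' consensus score is the maximum attainable PWM match score.
#'
#' @param ppm w x 4 matrix of per-position base probabilities (columns
#'   A,C,G,T); rows must sum to 1 within 1e-6.
#' @param id motif identifier.
#' @param cwm optional w x 4 contribution weight matrix.
#' @param source `"supplied"` or `"discovered"`.
#' @param pseudo pseudocount mixed into the PPM before taking logs
#'   (fraction of a uniform distribution; avoids -Inf weights).
#' @return an object of class `motif_model` with elements `ppm`, `pwm`,
#'   `cwm`, `consensus_score`, `width`, `id`, `source`.
#' @export
motif_model <- function(ppm, id = "motif", cwm = NULL, source = "supplied",
                        pseudo = 1e-3) {
  ppm <- as.matrix(ppm)
  stopifnot(ncol(ppm) == 4, nrow(ppm) >= 1)
  if (nrow(ppm) > 30 || nrow(ppm) < 1)
    stop("motif width must be between 1 and 30")
  if (any(ppm < 0)) stop("negative probabilities in PPM")
  if (any(abs(rowSums(ppm) - 1) > 1e-6)) stop("PPM rows must sum to 1")
  colnames(ppm) <- DNA_BASES
  p <- (1 - pseudo) * ppm + pseudo * 0.25
  pwm <- log2(p / 0.25)
  structure(list(ppm = ppm, pwm = pwm, cwm = cwm,
                 consensus_score = sum(apply(pwm, 1, max)),
                 width = nrow(ppm), id = id, source = source),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model %s> width %d, consensus score %.3f, consensus %s\n",
              x$id, x$width, x$consensus_score, consensus_seq(x)))
  invisible(x)
}

#' Consensus sequence of a motif
#' @param motif a [motif_model()].
#' @export
consensus_seq <- function(motif) {
  paste(DNA_BASES[apply(motif$ppm, 1, which.max)], collapse = "")
}

# reverse complement of a w x 4 matrix in motif orientation
rc_matrix <- function(m) {
  out <- m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

#' Patser-style score threshold
#'
#' Computes the exact distribution of PWM match scores under the
#' background (uniform by default) by dynamic programming on a discretized
#' score grid, and returns the smallest score `t` whose upper-tail
#' probability satisfies `P(S >= t) <= 2^(-IC)`, where IC is the motif's
#' total information content in bits.
#'
#' @param motif a [motif_model()].
#' @param background base probabilities (length 4).
#' @param precision score discretization steps per unit.
#' @export
patser_threshold <- function(motif, background = rep(0.25, 4), precision = 1000) {
  pwm <- motif$pwm
  ic <- sum(motif$ppm * log2(pmax(motif$ppm, 1e-12) / 0.25))
  qi <- round(pwm * precision)
  lo <- sum(apply(qi, 1, min)); hi <- sum(apply(qi, 1, max))
  dist <- numeric(hi - lo + 1)
  # DP over positions: dist[s] = P(sum of discretized scores = s + lo - 1)
  cur <- c(1)
  cur_lo <- 0
  for (i in seq_len(nrow(qi))) {
    nxt_lo <- cur_lo + min(qi[i, ])
    nxt <- numeric(length(cur) + max(qi[i, ]) - min(qi[i, ]))
    for (b in 1:4) {
      off <- qi[i, b] - min(qi[i, ])
      nxt[(1 + off):(length(cur) + off)] <-
        nxt[(1 + off):(length(cur) + off)] + cur * background[b]
    }
    cur <- nxt
    cur_lo <- nxt_lo
  }
  tail_p <- rev(cumsum(rev(cur)))
  target <- 2^(-ic)
  j <- which(tail_p <= target)
  if (!length(j)) return(motif$consensus_score)
  (cur_lo + j[1] - 1) / precision
}

# per-window PWM scores of a one-hot matrix (forward strand only);
# returns numeric vector of length L - w + 1
pwm_window_scores <- function(weights, x) {
  m <- unclass(x)
  w <- nrow(weights)
  L <- nrow(m)
  if (w > L) return(numeric(0))
  S <- m %*% t(weights)           # L x w: S[i, p] = score of base i at motif pos p
  nw <- L - w + 1
  out <- numeric(nw)
  for (p in seq_len(w)) out <- out + S[p:(p + nw - 1), p]
  out
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands and returns matches at or above the
#' threshold, sorted by start then strand (`+` before `-`). Coordinates
#' are 0-based half-open.
#'
#' @param motif a [motif_model()].
#' @param x an `onehot_seq`, one-hot matrix, or DNA string.
#' @param threshold minimum PWM score; defaults to the Patser threshold.
#' @param seq_id identifier recorded in the output.
#' @return a data.frame with columns `seq_id, start, end, strand, score`.
#' @export
pwm_scan <- function(motif, x, threshold = patser_threshold(motif),
                     seq_id = NULL) {
  if (is.character(x)) x <- encode_onehot(x, name = seq_id)
  if (is.null(seq_id)) seq_id <- attr(x, "name") %||% "seq"
  w <- motif$width
  L <- nrow(x)
  fwd <- pwm_window_scores(motif$pwm, x)
  rev_ <- pwm_window_scores(rc_matrix(motif$pwm), x)
  hitf <- which(fwd >= threshold)
  hitr <- which(rev_ >= threshold)
  out <- data.frame(
    seq_id = rep(seq_id, length(hitf) + length(hitr)),
    start = c(hitf - 1L, hitr - 1L),
    end = c(hitf - 1L + w, hitr - 1L + w),
    strand = c(rep("+", length(hitf)), rep("-", length(hitr))),
    score = c(fwd[hitf], rev_[hitr]),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand, out$score), , drop = FALSE]
}

#' Sample sequences from a position probability matrix
#'
#' Independent per-position categorical draws.
#'
#' @param ppm w x 4 probability matrix (rows sum to 1).
#' @param n number of sequences to draw.
#' @param seed optional RNG seed (scoped; the caller's RNG state is
#'   untouched).
#' @return a character vector of `n` sequences of length `nrow(ppm)`.
#' @export
sample_from_ppm <- function(ppm, n, seed = NULL) {
  ppm <- as.matrix(ppm)
  if (any(ppm < 0)) stop("negative probabilities")
  stopifnot(all(abs(rowSums(ppm) - 1) < 1e-6))
  with_seed(seed, {
    w <- nrow(ppm)
    # one multinomial draw per (position, sequence)
    idx <- vapply(seq_len(w), function(i) {
      sample.int(4, n, replace = TRUE, prob = ppm[i, ])
    }, integer(n))
    idx <- matrix(idx, nrow = n)  # n x w
    apply(idx, 1, function(r) paste(DNA_BASES[r], collapse = ""))
  })
}

#' Write motifs in MEME minimal format
#'
#' @param motifs a list of [motif_model()] objects (or a single one).
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$width), con)
    for (i in seq_len(m$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         m$ppm[i, 1], m$ppm[i, 2], m$ppm[i, 3], m$ppm[i, 4]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME-format motif file.
#'
#' @param path MEME file.
#' @return a list of [motif_model()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\b", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1
      if (j > length(lines)) break
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1):(j + w)]
      ppm <- do.call(rbind, lapply(rows, function(r) {
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      }))
      ppm <- ppm / rowSums(ppm)  # guard against rounding in the file
      out[[length(out) + 1]] <- motif_model(ppm, id = id, source = "supplied")
      i <- j + w
    }
    i <- i + 1
  }
  out
}

#' Export scored matches as BED6
#'
#' Scores are scaled into BED's 0-1000 integer range; the raw score is
#' kept in a 7th column.
#'
#' @param matches data.frame as returned by [pwm_scan()].
#' @param path output file.
#' @export
write_bed <- function(matches, path) {
  if (!nrow(matches)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  smax <- max(abs(matches$score), 1e-9)
  bed <- data.frame(chrom = matches$seq_id,
                    start = matches$start,
                    end = matches$end,
                    name = if (!is.null(matches$motif)) matches$motif else "match",
                    score = pmin(1000L, as.integer(round(1000 * abs(matches$score) / smax))),
                    strand = matches$strand,
                    raw = matches$score)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
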