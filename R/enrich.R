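#' Motif enrichment by seed-and-extend
#'
#' A built-in enrichment backend for the penalization track: for each
#' width, the most over-represented words (foreground vs background, both
#' strands, with pseudocounts) seed a PPM that is polished by a few EM
#' rounds over the foreground's best-matching windows, and the polished
#' candidates are ranked by their fold-enrichment. The background
#' defaults to a per-sequence shuffle of the foreground (base composition
#' preserved). Output from an external discovery tool in MEME format can
#' be used interchangeably via [read_meme()].
#'
#' @param foreground character vector of sequences.
#' @param background optional character vector; default shuffles the
#'   foreground.
#' @param n_motifs maximum number of motifs returned (default 10).
#' @param widths motif widths to try (default 8:15).
#' @param min_enrichment minimum fold-enrichment for a seed to be
#'   reported; below it the motif list may be empty.
#' @param em_rounds EM polishing rounds.
#' @param seed RNG seed (controls the default background shuffle).
#' @return a list of [motif_model()] objects (`source = "discovered"`),
#'   ranked by enrichment (stored in attribute `enrichment`), possibly
#'   empty.
#' @export
enrich_motifs <- function(foreground, background = NULL, n_motifs = 10,
                          widths = 8:15, min_enrichment = 2, em_rounds = 3,
                          seed = 1) {
  if (!length(foreground)) stop("foreground is empty")
  if (min(nchar(foreground)) < min(widths))
    stop("foreground sequences shorter than the minimum motif width")
  with_seed(seed, {
    if (is.null(background)) {
      background <- vapply(foreground, function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    fg2 <- c(foreground, reverse_complement(foreground))
    bg2 <- c(background, reverse_complement(background))
    candidates <- list()
    for (w in widths) {
      if (w > min(nchar(foreground))) next
      fg_counts <- kmer_table(fg2, w)
      bg_counts <- kmer_table(bg2, w)
      fg_tot <- sum(fg_counts); bg_tot <- sum(bg_counts)
      common <- names(fg_counts)
      bgc <- bg_counts[common]; bgc[is.na(bgc)] <- 0
      enr <- (fg_counts / fg_tot) / ((bgc + 1) / (bg_tot + length(bgc)))
      enr <- enr[fg_counts >= 3]
      if (!length(enr)) next
      top <- names(sort(enr, decreasing = TRUE))[1:min(3, length(enr))]
      for (word in top) {
        cand <- polish_seed(word, foreground, em_rounds)
        if (!is.null(cand)) {
          attr(cand, "enrichment") <- unname(enr[word])
          candidates[[length(candidates) + 1]] <- cand
        }
      }
    }
    if (!length(candidates)) return(list())
    score <- vapply(candidates, function(m) attr(m, "enrichment"), numeric(1))
    ord <- order(-score)
    selected <- list()
    for (i in ord) {
      if (score[i] < min_enrichment) break
      m <- candidates[[i]]
      dup <- any(vapply(selected, function(s) motifs_similar(s, m), logical(1)))
      if (!dup) selected[[length(selected) + 1]] <- m
      if (length(selected) >= n_motifs) break
    }
    for (i in seq_along(selected)) selected[[i]]$id <- sprintf("enr_%02d", i)
    selected
  })
}

kmer_table <- function(seqs, w) {
  words <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(character(0))
    substring(s, 1:(L - w + 1), w:L)
  }))
  words <- words[!grepl("N", words, fixed = TRUE)]
  table_to_named(table(words))
}

table_to_named <- function(tb) {
  out <- as.numeric(tb)
  names(out) <- names(tb)
  out
}

# seed word -> PPM polished by EM over best foreground windows
polish_seed <- function(word, foreground, em_rounds) {
  w <- nchar(word)
  seed_ppm <- matrix(0.05 / 3, w, 4)
  hit <- match(strsplit(word, "")[[1]], DNA_BASES)
  seed_ppm[cbind(seq_len(w), hit)] <- 0.95
  m <- motif_model(seed_ppm, id = word, source = "discovered")
  for (r in seq_len(em_rounds)) {
    thr <- 0.6 * m$consensus_score
    windows <- list()
    for (s in foreground) {
      hits <- pwm_scan(m, s, threshold = thr)
      if (!nrow(hits)) next
      best <- hits[which.max(hits$score), ]
      win <- substr(s, best$start + 1, best$end)
      if (best$strand == "-") win <- reverse_complement(win)
      windows[[length(windows) + 1]] <- win
    }
    if (length(windows) < 3) return(NULL)
    counts <- matrix(1, w, 4)  # +1 pseudocount
    for (win in windows) {
      b <- match(strsplit(win, "")[[1]], DNA_BASES)
      ok <- !is.na(b)
      counts[cbind(which(ok), b[ok])] <- counts[cbind(which(ok), b[ok])] + 1
    }
    m <- motif_model(counts / rowSums(counts), id = word, source = "discovered")
  }
  m
}

# two motifs are 'similar' if their consensus sequences overlap heavily
motifs_similar <- function(a, b, min_frac = 0.7) {
  ca <- consensus_seq(a); cb <- consensus_seq(b)
  if (nchar(ca) > nchar(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  for (s in c(cb, reverse_complement(cb))) {
    for (off in 0:(nchar(s) - nchar(ca))) {
      frag <- substr(s, off + 1, off + nchar(ca))
      if (mean(strsplit(frag, "")[[1]] == strsplit(ca, "")[[1]]) >= min_frac) return(TRUE)
    }
  }
  FALSE
}

#' Iterative motif-penalization track
#'
#' Round 0 designs a batch of unpenalized sequences with the
#' gradient-based designer; the batch is analysed for motif enrichment
#' and the top motif is appended to the penalty pool; each subsequent
#' round designs a smaller batch penalizing the growing pool. The pool
#' thresholds are a fraction of each motif's consensus score (the paper
#' uses 0 for targets whose dominant motif has strong suboptimal
#' instances, 0.25 otherwise). The track halts early, returning partial
#' results, if a round yields no designs or enrichment finds no motif.
#'
#' @param model an activity model.
#' @param target target cell type.
#' @param rounds number of penalized rounds (default 5).
#' @param n_round0 designs attempted in round 0 (default 500).
#' @param n_round designs attempted in each penalized round (default 250).
#' @param threshold_frac penalty threshold fraction of consensus score.
#' @param steps,n_samples,collect_min passed to [design_fast_seqprop()].
#' @param widths,n_enrich passed to [enrich_motifs()].
#' @param seed RNG seed (round r uses `seed + r`).
#' @return a list of class `penalization_track`: `rounds` (list of
#'   design_results), `pool` (final [penalty_pool()]), `motifs` (the
#'   per-round top motifs).
#' @export
penalization_track <- function(model, target = 1, rounds = 5, n_round0 = 500,
                               n_round = 250, threshold_frac = 0.25,
                               steps = 300, n_samples = 20, collect_min = 3.6,
                               widths = 8:15, n_enrich = 10, seed = 1) {
  results <- list()
  motifs <- list()
  res0 <- design_fast_seqprop(model, target, n_runs = n_round0, steps = steps,
                              n_samples = n_samples, collect_min = collect_min,
                              seed = seed)
  results[["round0"]] <- res0
  for (r in seq_len(rounds)) {
    prev <- results[[length(results)]]
    if (!length(prev$sequences)) {
      message(sprintf("round %d: previous round produced no designs; halting", r))
      break
    }
    found <- enrich_motifs(prev$sequences, widths = widths,
                           n_motifs = n_enrich, seed = seed + 1000 + r)
    if (!length(found)) {
      message(sprintf("round %d: no enriched motif found; halting", r))
      break
    }
    motifs[[r]] <- found[[1]]
    motifs[[r]]$id <- sprintf("pwm_%d", r)
    pool <- penalty_pool(motifs, threshold_frac = threshold_frac)
    res <- design_fast_seqprop(model, target, n_runs = n_round, steps = steps,
                               n_samples = n_samples, collect_min = collect_min,
                               penalty = pool, seed = seed + r)
    results[[sprintf("round%d", r)]] <- res
  }
  structure(list(rounds = results,
                 pool = if (length(motifs)) penalty_pool(motifs, threshold_frac) else NULL,
                 motifs = motifs),
            class = "penalization_track")
}
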