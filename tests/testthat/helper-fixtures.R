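# Shared fixtures, built in code at test time.

# a small but real convolutional model (untrained unless asked)
tiny_model <- function(n_out = 3, seed = 1, cell_types = NULL) {
  cfg <- predictor_config(input_length = 200, n_outputs = n_out,
                          cell_types = cell_types,
                          channels = c(6, 6, 6), kernels = c(11, 9, 6),
                          pools = c(2, 3, 2), hidden = 16, branch_width = 8,
                          flank_length = 0)
  build_activity_model(cfg, seed = seed)
}

# linear scorer: cell 1 rewards a planted consensus-like weight pattern,
# remaining cells are zero or opposed
linear_toy <- function(L = 200, cells = 3, seed = 1) {
  set.seed(seed)
  W <- lapply(seq_len(cells), function(ci) matrix(rnorm(4 * L, 0, 0.05), 4, L))
  linear_activity_model(W)
}

# linear scorer whose first output counts a base (translation invariant)
base_counter_model <- function(base = "G", per_base = 0.05, cells = 2, L = 200) {
  W <- lapply(seq_len(cells), function(ci) matrix(0, 4, L))
  bi <- match(base, c("A", "C", "G", "T"))
  W[[1]][bi, ] <- per_base
  linear_activity_model(W)
}

# sharp motif for scanning tests
sharp_motif <- function(consensus, id = "m", sharp = 0.97) {
  w <- nchar(consensus)
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  ppm <- matrix((1 - sharp) / 3, w, 4)
  ppm[cbind(seq_len(w), idx)] <- sharp
  motif_model(ppm, id = id)
}

# random DNA with a consensus embedded at a known 0-based position
embed_at <- function(consensus, pos0, L = 200, seed = 1) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s[(pos0 + 1):(pos0 + nchar(consensus))] <- strsplit(consensus, "")[[1]]
  paste(s, collapse = "")
}

# brute-force PWM window scores for the scan oracle
brute_pwm_hits <- function(motif, seq, threshold) {
  m <- unclass(encode_onehot(seq))
  w <- motif$width
  L <- nrow(m)
  res <- list()
  for (strand in c("+", "-")) {
    wt <- if (strand == "+") motif$pwm else motif$pwm[w:1, 4:1]
    for (j in 1:(L - w + 1)) {
      sc <- 0
      for (p in 1:w) sc <- sc + sum(m[j + p - 1, ] * wt[p, ])
      if (sc >= threshold) {
        res[[length(res) + 1]] <- data.frame(start = j - 1L, end = j - 1L + w,
                                             strand = strand, score = sc)
      }
    }
  }
  if (!length(res)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0), score = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$strand, out$score), , drop = FALSE]
}

# minimal MPRA table builder
mpra_row <- function(id, l2fc, se = c(0.1, 0.1, 0.1), plasmid = 50,
                     rna = c(10, 10, 10), lib = "libA", chrom = "1",
                     sequence = NULL) {
  if (is.null(sequence)) sequence <- strrep("ACGT", 50)
  data.frame(oligo_id = id, sequence = sequence, chrom = chrom,
             source_library = lib, plasmid_count = plasmid,
             log2fc_cellA = l2fc[1], se_cellA = se[1], rna_cellA = rna[1],
             log2fc_cellB = l2fc[2], se_cellB = se[2], rna_cellB = rna[2],
             log2fc_cellC = l2fc[3], se_cellC = se[3], rna_cellC = rna[3],
             stringsAsFactors = FALSE)
}
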