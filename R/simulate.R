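#' Synthetic regulatory grammar
#'
#' Defines the planted activator/repressor motif vocabulary of a simulated
#' MPRA: per simulated cell type, a set of activator motifs (positive
#' log2FC effects) and repressor motifs (negative effects), a baseline
#' activity, measurement noise, and a saturation cap on the summed
#' effects. The defaults emulate a three-cell-type assay in which each
#' cell type responds to two private activators and one private
#' repressor, with effect sizes in the range seen for strong MPRA
#' activators (1.5-3.5 log2FC units) and replicate-level noise of 0.25.
#'
#' @param cell_types names of the simulated cell types.
#' @param n_activators,n_repressors motifs per cell type.
#' @param activator_range,repressor_range effect-size ranges (log2FC).
#' @param baseline baseline log2FC of a motif-free sequence.
#' @param noise_sd Gaussian measurement noise (log2FC units).
#' @param cap saturation cap applied to the summed motif effects.
#' @param motif_width motif width in nt.
#' @param sharpness probability mass on the consensus base at each motif
#'   position (the rest is spread evenly).
#' @param seed RNG seed for drawing the motif vocabulary.
#' @return an object of class `synth_grammar`.
#' @export
synth_grammar <- function(cell_types = c("cellA", "cellB", "cellC"),
                          n_activators = 2, n_repressors = 1,
                          activator_range = c(1.5, 3.5),
                          repressor_range = c(-2.5, -1),
                          baseline = 0, noise_sd = 0.25, cap = 6,
                          motif_width = 12, sharpness = 0.97, seed = 1) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    motifs <- list()
    for (ct in cell_types) {
      for (i in seq_len(n_activators)) {
        id <- sprintf("%s_act%d", ct, i)
        motifs[[id]] <- list(
          motif = random_sharp_motif(motif_width, sharpness, id),
          cell = ct, role = "activator",
          effect = runif(1, activator_range[1], activator_range[2]))
      }
      for (i in seq_len(n_repressors)) {
        id <- sprintf("%s_rep%d", ct, i)
        motifs[[id]] <- list(
          motif = random_sharp_motif(motif_width, sharpness, id),
          cell = ct, role = "repressor",
          effect = runif(1, repressor_range[1], repressor_range[2]))
      }
    }
    structure(list(cell_types = cell_types, motifs = motifs,
                   baseline = baseline, noise_sd = noise_sd, cap = cap),
              class = "synth_grammar")
  })
}

# a motif with one dominant base per position
random_sharp_motif <- function(width, sharpness, id) {
  cons <- sample.int(4, width, replace = TRUE)
  ppm <- matrix((1 - sharpness) / 3, width, 4)
  ppm[cbind(seq_len(width), cons)] <- sharpness
  motif_model(ppm, id = id, source = "supplied")
}

#' @export
print.synth_grammar <- function(x, ...) {
  cat(sprintf("<synth_grammar> %d cell types, %d motifs, baseline %.2f, noise %.2f\n",
              length(x$cell_types), length(x$motifs), x$baseline, x$noise_sd))
  invisible(x)
}

#' Simulate an MPRA table with planted motifs
#'
#' Draws random 200-mers, plants 0-4 motif instances (sampled from the
#' grammar vocabulary) at random non-overlapping positions and strands,
#' and assigns per-cell-type log2FC as
#' `baseline + min(sum of effects, cap) + N(0, noise_sd)`, where each
#' motif contributes its effect only in its own cell type. Plasmid and
#' RNA counts, replicate standard errors and chromosomes are simulated so
#' that the full preprocessing path is exercised.
#'
#' @param grammar a [synth_grammar()].
#' @param n number of oligos.
#' @param seed RNG seed; a fixed seed gives a byte-identical table.
#' @param length oligo length (default 200).
#' @param max_motifs maximum planted instances per oligo.
#' @param library_name value for `source_library`.
#' @return a list with `table` (MPRA data.frame) and `annotations`
#'   (data.frame of planted instances: oligo_id, motif, cell, role,
#'   effect, start, strand).
#' @export
simulate_mpra <- function(grammar, n, seed = 1, length = 200, max_motifs = 4,
                          library_name = "synth") {
  stopifnot(n >= 1)
  widths <- vapply(grammar$motifs, function(m) m$motif$width, integer(1))
  if (any(widths > length)) stop("motif wider than the simulated oligo")
  cells <- grammar$cell_types
  with_seed(seed, {
    seqs <- character(n)
    ann <- vector("list", n)
    eff <- matrix(0, n, length(cells), dimnames = list(NULL, cells))
    motif_ids <- names(grammar$motifs)
    for (i in seq_len(n)) {
      s <- sample(DNA_BASES, length, replace = TRUE)
      k <- sample.int(max_motifs + 1L, 1L) - 1L
      placed <- matrix(numeric(0), ncol = 2)  # start, end (1-based closed)
      rows <- list()
      for (j in seq_len(k)) {
        mid <- sample(motif_ids, 1)
        m <- grammar$motifs[[mid]]
        w <- m$motif$width
        ok <- FALSE
        for (try in 1:20) {
          st <- sample.int(length - w + 1L, 1L)
          if (!nrow(placed) || all(st > placed[, 2] | (st + w - 1L) < placed[, 1])) {
            ok <- TRUE; break
          }
        }
        if (!ok) next  # bounded retries; skip this instance
        strand <- sample(c("+", "-"), 1)
        inst <- sample_from_ppm(m$motif$ppm, 1)
        if (strand == "-") inst <- reverse_complement(inst)
        s[st:(st + w - 1L)] <- strsplit(inst, "")[[1]]
        placed <- rbind(placed, c(st, st + w - 1L))
        eff[i, m$cell] <- eff[i, m$cell] + m$effect
        rows[[length(rows) + 1]] <- data.frame(
          oligo_id = sprintf("oligo_%06d", i), motif = mid, cell = m$cell,
          role = m$role, effect = m$effect, start = st - 1L,
          end = st - 1L + w, strand = strand, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
      ann[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    sat <- pmin(eff, grammar$cap)
    act <- grammar$baseline + sat
    if (grammar$noise_sd > 0)
      act <- act + matrix(rnorm(n * ncol(eff), 0, grammar$noise_sd), n)
    tab <- data.frame(
      oligo_id = sprintf("oligo_%06d", seq_len(n)),
      sequence = seqs,
      chrom = as.character(sample(c(1:22, "X"), n, replace = TRUE)),
      source_library = library_name,
      plasmid_count = 20L + rpois(n, 40),
      stringsAsFactors = FALSE
    )
    for (ci in seq_along(cells)) {
      tab[[paste0("log2fc_", cells[ci])]] <- act[, ci]
      tab[[paste0("se_", cells[ci])]] <- round(abs(rnorm(n, 0.15, 0.05)) + 0.01, 4)
      tab[[paste0("rna_", cells[ci])]] <- 1L + rpois(n, 30)
    }
    anns <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
    if (is.null(anns)) {
      anns <- data.frame(oligo_id = character(0), motif = character(0),
                         cell = character(0), role = character(0),
                         effect = numeric(0), start = integer(0),
                         end = integer(0), strand = character(0))
    }
    list(table = tab, annotations = anns)
  })
}
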