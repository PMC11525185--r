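#' MPRA table conventions
#'
#' MPRA tables are plain data.frames with one row per oligo and columns:
#' `oligo_id`, `sequence` (200-nt string), `chrom`, `source_library`,
#' `plasmid_count`, and per cell type `log2fc_<cell>`, `se_<cell>`,
#' `rna_<cell>`. Helper accessors find the cell-type columns by prefix.
#'
#' @param table an MPRA data.frame.
#' @return character vector of cell-type names.
#' @export
mpra_cell_types <- function(table) {
  sub("^log2fc_", "", grep("^log2fc_", names(table), value = TRUE))
}

log2fc_matrix <- function(table) {
  cells <- mpra_cell_types(table)
  as.matrix(table[, paste0("log2fc_", cells), drop = FALSE])
}

#' Count-filter, aggregate and outlier-filter MPRA tables
#'
#' Applies the preprocessing rules used to assemble a training table from
#' multiple MPRA libraries:
#' \enumerate{
#'   \item records with `plasmid_count < 20` or a zero RNA count in any
#'     cell type are discarded;
#'   \item an oligo present in several libraries of the top precedence
#'     tier has its log2FC values averaged across those libraries; copies
#'     of the oligo in lower-precedence tiers are dropped (each tier is
#'     consulted only if no higher tier carried the oligo);
#'   \item oligos whose log2FC falls more than 6 standard deviations below
#'     the global (per cell type, post-count-filter) mean in any cell type
#'     are discarded.
#' }
#'
#' @param tables a list of MPRA data.frames, each with `source_library`
#'   set; may also be a single table.
#' @param precedence character vector of library names ordered from the
#'   highest-priority tier down. Libraries sharing the same precedence can
#'   be expressed by a list of character vectors, e.g.
#'   `list(c("ukbb1","ukbb2"), "gtex")`.
#' @param min_plasmid plasmid count threshold (default 20).
#' @param sd_cut lower outlier cut in standard deviations (default 6).
#' @return a filtered, aggregated MPRA data.frame.
#' @export
filter_and_aggregate <- function(tables, precedence = NULL, min_plasmid = 20,
                                 sd_cut = 6) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  if (!nrow(tab)) return(tab)
  if (is.null(precedence)) precedence <- list(unique(tab$source_library))
  if (!is.list(precedence)) precedence <- as.list(precedence)
  known <- unlist(precedence)
  if (any(!tab$source_library %in% known)) {
    stop(sprintf("library '%s' not in precedence list",
                 setdiff(unique(tab$source_library), known)[1]))
  }
  cells <- mpra_cell_types(tab)
  rna <- as.matrix(tab[, paste0("rna_", cells), drop = FALSE])
  keep <- tab$plasmid_count >= min_plasmid & apply(rna > 0, 1, all)
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(tab)

  # precedence resolution: walk tiers top-down; within a tier, average
  pieces <- list()
  seen <- character(0)
  for (tier in precedence) {
    sub <- tab[tab$source_library %in% tier & !tab$oligo_id %in% seen, , drop = FALSE]
    if (!nrow(sub)) next
    dup <- duplicated(sub$oligo_id) | duplicated(sub$oligo_id, fromLast = TRUE)
    uniq <- sub[!dup, , drop = FALSE]
    if (any(dup)) {
      d <- sub[dup, , drop = FALSE]
      agg <- do.call(rbind, lapply(split(d, d$oligo_id), function(g) {
        r <- g[1, , drop = FALSE]
        for (cc in cells) {
          r[[paste0("log2fc_", cc)]] <- mean(g[[paste0("log2fc_", cc)]])
          if (paste0("se_", cc) %in% names(g))
            r[[paste0("se_", cc)]] <- max(g[[paste0("se_", cc)]])
        }
        r
      }))
      uniq <- rbind(uniq, agg)
    }
    pieces[[length(pieces) + 1]] <- uniq
    seen <- c(seen, unique(sub$oligo_id))
  }
  tab <- do.call(rbind, pieces)
  tab <- tab[order(tab$oligo_id), , drop = FALSE]
  rownames(tab) <- NULL

  # low-tail outlier filter, per cell type over the aggregated table
  lf <- log2fc_matrix(tab)
  mu <- colMeans(lf); s <- apply(lf, 2, sd)
  s[is.na(s)] <- 0
  low <- sweep(lf, 2, mu - sd_cut * s, `<`)
  tab[!apply(low, 1, any), , drop = FALSE]
}

#' Filter oligos by replicate standard error
#'
#' Removes records whose replicate log2FC standard error exceeds `max_se`
#' in any cell type (strictly greater than; SE exactly at the bound is
#' kept).
#'
#' @param table an MPRA data.frame with `se_<cell>` columns.
#' @param max_se threshold (default 1).
#' @export
se_filter <- function(table, max_se = 1) {
  cells <- mpra_cell_types(table)
  se <- as.matrix(table[, paste0("se_", cells), drop = FALSE])
  table[!apply(se > max_se, 1, any), , drop = FALSE]
}

#' Chromosome-based train/validation/test split
#'
#' Split assignment is a pure function of the chromosome: validation and
#' test chromosomes are held out, everything else trains.
#'
#' @param table an MPRA data.frame with a `chrom` column.
#' @param val_chroms chromosomes held out for validation (default 19, 21, X).
#' @param test_chroms chromosomes held out for the test set (default 7, 13).
#' @return a list of class `training_split` with `train`, `val`, `test`.
#' @export
make_split <- function(table, val_chroms = c("19", "21", "X"),
                       test_chroms = c("7", "13")) {
  if (length(intersect(val_chroms, test_chroms)))
    stop("a chromosome cannot be in both held-out sets")
  chrom <- sub("^chr", "", as.character(table$chrom))
  grp <- ifelse(chrom %in% test_chroms, "test",
                ifelse(chrom %in% val_chroms, "val", "train"))
  structure(list(train = table[grp == "train", , drop = FALSE],
                 val   = table[grp == "val", , drop = FALSE],
                 test  = table[grp == "test", , drop = FALSE]),
            class = "training_split")
}

#' @export
print.training_split <- function(x, ...) {
  cat(sprintf("<training_split> train %d / val %d / test %d records\n",
              nrow(x$train), nrow(x$val), nrow(x$test)))
  invisible(x)
}

#' Augment the training set
#'
#' Adds a reverse-complement copy of every training record, and one
#' duplicate (forward orientation) of every record whose log2FC exceeds
#' `dup_threshold` in any cell type. Validation and test sets are left
#' untouched. An `augmentation` column records the origin of each row
#' (`"fwd"`, `"rc"`, `"dup"`).
#'
#' @param split a [make_split()] result.
#' @param dup_threshold log2FC threshold for the activity duplicate.
#' @param rc add reverse-complement copies (default TRUE).
#' @param dup_rc if TRUE the high-activity duplicate is also added in
#'   reverse-complement orientation (default FALSE).
#' @export
augment_training <- function(split, dup_threshold = 0.5, rc = TRUE,
                             dup_rc = FALSE) {
  tr <- split$train
  tr$augmentation <- "fwd"
  out <- list(tr)
  if (rc) {
    rcrec <- tr
    rcrec$sequence <- reverse_complement(tr$sequence)
    rcrec$augmentation <- "rc"
    out <- c(out, list(rcrec))
  }
  hot <- apply(log2fc_matrix(tr) > dup_threshold, 1, any)
  if (any(hot)) {
    dup <- tr[hot, , drop = FALSE]
    dup$augmentation <- "dup"
    out <- c(out, list(dup))
    if (dup_rc) {
      duprc <- dup
      duprc$sequence <- reverse_complement(dup$sequence)
      duprc$augmentation <- "dup_rc"
      out <- c(out, list(duprc))
    }
  }
  split$train <- do.call(rbind, out)
  rownames(split$train) <- NULL
  split
}

#' Read / write MPRA tables as TSV
#'
#' @param path TSV file with a header row.
#' @export
read_mpra_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if ("chrom" %in% names(tab)) tab$chrom <- as.character(tab$chrom)
  tab
}

#' @rdname read_mpra_table
#' @param table MPRA data.frame to write.
#' @export
write_mpra_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
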