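#' @useDynLib credesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom median sd cor quantile rpois setNames var dist filter
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' Encodes a DNA string into an L x 4 binary matrix with column order
#' A, C, G, T. `N` (unknown base) encodes as an all-zero row, so an
#' encoded row sums to 1 for a called base and 0 for an unknown one.
#' Lower-case (soft-masked) bases are accepted and treated as upper-case.
#'
#' @param seq a single DNA string over `A,C,G,T,N` (any case).
#' @param name optional identifier attached to the result.
#' @return an object of class `onehot_seq`: the L x 4 matrix with
#'   attributes `name`.
#' @export
encode_onehot <- function(seq, name = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < 1L) stop("sequence must have length >= 1")
  bad <- which(!chars %in% c(DNA_BASES, "N"))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1]], bad[1]))
  }
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  hit <- match(chars, DNA_BASES)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  structure(m, name = name, class = c("onehot_seq", "matrix", "array"))
}

#' Decode a one-hot matrix back to a DNA string
#'
#' All-zero rows decode to `N`.
#'
#' @param x an L x 4 one-hot matrix (`onehot_seq` or plain matrix).
#' @return a single DNA string.
#' @export
decode_onehot <- function(x) {
  x <- unclass(x)
  idx <- max.col(x, ties.method = "first")
  base <- DNA_BASES[idx]
  base[rowSums(x) == 0] <- "N"
  paste(base, collapse = "")
}

#' Reverse complement
#'
#' For a one-hot matrix: rows are reversed and the base columns swapped
#' (A with T, C with G); all-zero (N) rows stay all-zero. For a character
#' vector each string is reverse-complemented.
#'
#' @param x an `onehot_seq`/matrix or a character vector of DNA strings.
#' @return an object of the same type as the input.
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    return(vapply(x, function(s) {
      chars <- rev(strsplit(s, "")[[1]])
      comp <- chartr("ACGTacgtN", "TGCAtgcaN", paste(chars, collapse = ""))
      comp
    }, character(1), USE.NAMES = FALSE))
  }
  cls <- class(x)
  m <- unclass(x)
  out <- m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  colnames(out) <- DNA_BASES
  structure(out, name = attr(x, "name"), class = cls)
}

#' Default reporter-backbone flanking sequences
#'
#' A fixed, documented pair of 200-nt constant flanks used to pad 200-nt
#' inserts to the 600-nt model input. The true reporter-vector backbone
#' differs between labs; these defaults guarantee determinism and can be
#' overridden anywhere a flank pair is accepted (pass your own vector
#' sequence when you have it).
#'
#' @param length flank length in nt (default 200; 0 gives empty flanks).
#' @return a list with character elements `flank5` and `flank3`.
#' @export
default_flanks <- function(length = 200) {
  f5 <- "GAGTTCTTGGGTGATGTAATGCGTGTAATTTGCATGCATGGAGGATCCACTGCCGCAATGGCACTCACGACAAAGCATAGTGATAATAAGGGGTCACTATTTAGTACTATCGTACCGCCTTACTCATTAAGCGATTACCCCCGAACCACCACAGTGCATTCCAGGACAATGGTTGCGATTCGGATTACTGGACCCCTCCC"
  f3 <- "AGAGTGACCCTAATCAGGCGGTTGTAGGTAATTGGTTGAAATAGATATAGGCAAACATGGAGCCGATAAATTACAGAACTGGCGTCAGGAACATGACTTTACTATGGGATCTTGGAGCCGTTTAGTAAAATCTATGGCGCACGAGGTTGTCAGTCCCAGGGCGAGATTGCGAAGGATGCCAGCTGAGCAGTAGAGAGTTC"
  stopifnot(length >= 0, length <= 200)
  if (length == 0) return(list(flank5 = "", flank3 = ""))
  # 5' flank keeps its 3'-most bases (adjacent to the insert), 3' flank its 5'-most
  list(flank5 = substr(f5, 200 - length + 1, 200),
       flank3 = substr(f3, 1, length))
}

#' Pad an insert with constant flanks
#'
#' Concatenates `flank5 || insert || flank3`. Inputs may be DNA strings or
#' one-hot matrices (mixed inputs are encoded as needed); the result type
#' follows the insert.
#'
#' @param insert the (typically 200-nt) insert.
#' @param flanks a list with `flank5`/`flank3` strings, as returned by
#'   [default_flanks()].
#' @param input_length required total output length; an error is raised on
#'   mismatch (the model's input contract). `NULL` skips the check.
#' @export
pad_with_flanks <- function(insert, flanks = default_flanks(), input_length = NULL) {
  as_str <- is.character(insert)
  ins <- if (as_str) insert else decode_onehot(insert)
  out <- paste0(flanks$flank5, ins, flanks$flank3)
  if (!is.null(input_length) && nchar(out) != input_length) {
    stop(sprintf("padded length %d does not match model input length %d",
                 nchar(out), input_length))
  }
  if (as_str) out else encode_onehot(out, name = attr(insert, "name"))
}

## batch helpers (internal) ---------------------------------------------------

# character vector -> (4, L, B) cube
encode_batch <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) <= 1L)
  cpp_encode_batch(as.character(seqs))
}

# reverse complement of a (4, L, B) cube
rc_batch <- function(X) {
  X[c(4, 3, 2, 1), rev(seq_len(dim(X)[2])), , drop = FALSE]
}

#' Random DNA sequences
#'
#' Uniform random sequences over A,C,G,T, used for design initialization
#' and random baselines.
#'
#' @param n number of sequences.
#' @param length sequence length in nt.
#' @return a character vector of length `n`.
#' @export
random_sequences <- function(n, length = 200) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Exact size of the DNA sequence space
#'
#' Computes 4^L exactly with schoolbook big-integer arithmetic and reports
#' it in scientific notation: for L = 200 there are over 2.58e120 possible
#' sequences.
#'
#' @param length sequence length in nt.
#' @param sig_digits significant digits for the scientific mantissa.
#' @return a list: `digits` (the full decimal string), `mantissa`,
#'   `exponent`.
#' @export
sequence_space_size <- function(length = 200, sig_digits = 3) {
  # big integer as vector of base-1e4 limbs, least-significant first
  mul_small <- function(x, m) {
    carry <- 0
    for (i in seq_along(x)) {
      v <- x[i] * m + carry
      x[i] <- v %% 10000
      carry <- v %/% 10000
    }
    while (carry > 0) {
      x <- c(x, carry %% 10000)
      carry <- carry %/% 10000
    }
    x
  }
  x <- 1
  for (i in seq_len(length)) x <- mul_small(x, 4)
  limbs <- rev(x)
  digits <- paste0(limbs[1], paste(sprintf("%04d", limbs[-1]), collapse = ""))
  exponent <- nchar(digits) - 1L
  mant <- as.numeric(paste0(substr(digits, 1, 1), ".",
                            substr(digits, 2, sig_digits + 2)))
  mant <- round(mant, sig_digits - 1)
  if (mant >= 10) { # rounding carried over
    mant <- mant / 10
    exponent <- exponent + 1L
  }
  list(digits = digits, mantissa = mant, exponent = exponent)
}

#' Read sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector.
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# scoped RNG: run fn under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
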