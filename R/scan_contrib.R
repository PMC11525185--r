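#' Contribution-score motif scan
#'
#' Matches motifs given in contribution-weight-matrix (CWM) form against
#' hypothetical contribution maps. Each map is zero-padded by `pad`
#' positions on both sides; for every window and orientation the Pearson
#' correlation between the window's hypothetical scores and the motif's
#' CWM is computed; per (cell type, motif) a coefficient threshold
#' `min(r_cap, mu + sd_mult * sigma)` is derived from a random sample of
#' the coefficient distribution, and every window at or above it is
#' emitted as a hit. Windows with zero variance have an undefined
#' correlation and are excluded.
#'
#' @param motifs list of [motif_model()] objects with a `cwm`.
#' @param maps list of `contribution_map`s (see
#'   [sampled_integrated_gradients()]).
#' @param pad zero padding on each side (default 5).
#' @param r_cap hard cap on the threshold (default 0.75).
#' @param sd_mult multiplier on the coefficient standard deviation.
#' @param sample_n coefficients sampled per (cell, motif) to estimate the
#'   threshold (the full set is used when smaller).
#' @param seed RNG seed for the threshold subsample.
#' @return data.frame of hits: `seq_id`, `cell`, `motif`, `start`, `end`
#'   (0-based, relative to the unpadded sequence; may extend past its
#'   edges by up to `pad`), `strand`, `r`, plus a `thresholds` attribute.
#' @export
contribution_motif_scan <- function(motifs, maps, pad = 5, r_cap = 0.75,
                                    sd_mult = 4, sample_n = 500000, seed = 1) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  for (m in motifs) if (is.null(m$cwm)) stop(sprintf("motif %s has no cwm", m$id))
  if (inherits(maps, "contribution_map")) maps <- list(maps)
  cells <- maps[[1]]$cells
  out <- list()
  thresholds <- list()
  for (mi in seq_along(motifs)) {
    motif <- motifs[[mi]]
    w <- nrow(motif$cwm)
    Lp <- dim(maps[[1]]$hypothetical)[2] + 2 * pad
    if (w > Lp) stop(sprintf("motif %s longer than the padded maps", motif$id))
    for (ci in seq_along(cells)) {
      coefs <- list()   # per map: list(r_fwd, r_rev)
      for (si in seq_along(maps)) {
        H <- rbind(matrix(0, pad, 4),
                   matrix(maps[[si]]$hypothetical[ci, , ], ncol = 4),
                   matrix(0, pad, 4))
        coefs[[si]] <- list(
          fwd = window_pearson(H, motif$cwm),
          rev = window_pearson(H, rc_matrix(motif$cwm)))
      }
      allr <- unlist(coefs)
      allr <- allr[is.finite(allr)]
      if (!length(allr)) next
      thr <- with_seed(seed, {
        samp <- if (length(allr) > sample_n) sample(allr, sample_n) else allr
        min(r_cap, mean(samp) + sd_mult * sd(samp))
      })
      thresholds[[paste(cells[ci], motif$id, sep = ".")]] <- thr
      for (si in seq_along(maps)) {
        for (strand in c("+", "-")) {
          rv <- if (strand == "+") coefs[[si]]$fwd else coefs[[si]]$rev
          hit <- which(is.finite(rv) & rv >= thr)
          if (!length(hit)) next
          out[[length(out) + 1]] <- data.frame(
            seq_id = maps[[si]]$seq_id, cell = cells[ci], motif = motif$id,
            start = hit - 1L - pad, end = hit - 1L - pad + w,
            strand = strand, r = rv[hit], stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(seq_id = character(0), cell = character(0), motif = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               r = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "thresholds") <- unlist(thresholds)
  res
}

# Pearson correlation of every length-w window of H (L x 4) with W (w x 4);
# NA where the window has zero variance
window_pearson <- function(H, W) {
  w <- nrow(W)
  L <- nrow(H)
  if (w > L) return(numeric(0))
  nw <- L - w + 1
  nEl <- 4 * w
  S <- H %*% t(W)                    # L x w
  cross <- numeric(nw)
  for (p in seq_len(w)) cross <- cross + S[p:(p + nw - 1), p]
  rs <- rowSums(H); rs2 <- rowSums(H^2)
  sumx <- sliding_sum(rs, w)
  sumx2 <- sliding_sum(rs2, w)
  sy <- sum(W); sy2 <- sum(W^2)
  vx <- sumx2 - sumx^2 / nEl
  vy <- sy2 - sy^2 / nEl
  num <- cross - sumx * sy / nEl
  den <- sqrt(pmax(vx, 0) * max(vy, 0))
  r <- num / den
  r[vx <= 1e-12 | vy <= 1e-12] <- NA_real_
  r
}

sliding_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Motif-count matrix from scan hits
#'
#' Builds the non-negative sequences x motifs count matrix consumed by
#' [nmf_programs()]. Hits of the same motif at the same location in
#' different cell types are counted once.
#'
#' @param hits data.frame from [contribution_motif_scan()].
#' @param seq_ids row universe (defaults to the ids present).
#' @param motifs column universe (defaults to the motifs present).
#' @export
motif_count_matrix <- function(hits, seq_ids = NULL, motifs = NULL) {
  if (is.null(seq_ids)) seq_ids <- sort(unique(hits$seq_id))
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  X <- matrix(0, length(seq_ids), length(motifs),
              dimnames = list(seq_ids, motifs))
  if (nrow(hits)) {
    key <- unique(hits[, c("seq_id", "motif", "start", "strand")])
    tab <- table(key$seq_id, key$motif)
    X[rownames(tab), colnames(tab)] <- tab[, , drop = FALSE]
  }
  X
}

#' Non-negative matrix factorization of motif programs
#'
#' Decomposes a sequences x motifs count matrix `X >= 0` into `W %*% H`
#' with `W, H >= 0` by Frobenius-loss multiplicative updates from a
#' deterministic SVD-based (NNDSVD) initialization. The reconstruction
#' error is monitored every iteration and is non-increasing. For
#' reporting, the coefficient matrix is row-normalized to sum to 1. When
#' per-motif contribution signatures are supplied, each program's
#' function is their H-weighted average with contributions clipped to an
#' upper bound of 3.
#'
#' @param X n x f non-negative matrix.
#' @param k number of programs (default 12).
#' @param max_iter,tol multiplicative-update controls.
#' @param motif_contrib optional f x n_cells matrix of per-motif mean
#'   contributions (see [motif_contribution_summary()]).
#' @param contrib_clip upper clip on contributions (default 3).
#' @param seed unused by the deterministic init; kept for interface
#'   stability.
#' @return list of class `program_decomposition`: `W`, `H`, `W_norm`,
#'   `k`, `error_trace`, and `program_function` when signatures are
#'   given.
#' @export
nmf_programs <- function(X, k = 12, max_iter = 2000, tol = 1e-6,
                         motif_contrib = NULL, contrib_clip = 3, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  if (k > min(dim(X))) stop("k exceeds min(dim(X))")
  eps <- 1e-10
  init <- nndsvd_init(X, k)
  W <- init$W; H <- init$H
  err <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W, W %*% H) + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    e <- sqrt(sum((X - W %*% H)^2))
    err <- c(err, e)
    if (is.finite(prev) && abs(prev - e) < tol * max(prev, 1)) break
    prev <- e
  }
  Wn <- W
  rs <- rowSums(Wn)
  Wn[rs > 0, ] <- Wn[rs > 0, , drop = FALSE] / rs[rs > 0]
  out <- list(W = W, H = H, W_norm = Wn, k = k, error_trace = err)
  if (!is.null(motif_contrib)) {
    mc <- pmin(as.matrix(motif_contrib), contrib_clip)
    pf <- matrix(0, k, ncol(mc), dimnames = list(NULL, colnames(mc)))
    for (p in seq_len(k)) {
      wts <- H[p, ]
      pf[p, ] <- if (sum(wts) > 0) colSums(wts * mc) / sum(wts) else 0
    }
    out$program_function <- pf
  }
  structure(out, class = "program_decomposition")
}

# NNDSVD initialization (deterministic; zeros filled with the matrix mean)
nndsvd_init <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      if (nup * nvp > 0) {
        W[, j] <- sqrt(sv$d[j] * nup * nvp) * up / nup
        H[j, ] <- sqrt(sv$d[j] * nup * nvp) * vp / nvp
      }
    } else {
      W[, j] <- sqrt(sv$d[j] * nun * nvn) * un / nun
      H[j, ] <- sqrt(sv$d[j] * nun * nvn) * vn / nvn
    }
  }
  avg <- mean(X)
  W[W <= 0] <- avg / 100
  H[H <= 0] <- avg / 100
  list(W = W, H = H)
}
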