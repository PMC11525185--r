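test_that("SIG matches the closed-form path integral for a linear scorer", {
  L <- 60
  set.seed(3)
  W <- list(matrix(rnorm(4 * L, 0, 0.3), 4, L), matrix(0, 4, L))
  lmod <- linear_activity_model(W)
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  onehot <- unclass(encode_onehot(s))
  C <- 10
  # oracle: deterministic quadrature of the expected-gradient line integral
  Weff <- (W[[1]] + W[[1]][4:1, L:1]) / 2    # strand-averaged effective weights
  alphas <- seq(1e-4, 1 - 1e-4, length.out = 2000)
  hyp_oracle <- matrix(0, L, 4)
  for (a in alphas) {
    theta <- a * C * onehot
    p <- exp(theta) / rowSums(exp(theta))
    drift <- rowSums(p * t(Weff))
    hyp_oracle <- hyp_oracle + p * (t(Weff) - drift)
  }
  hyp_oracle <- C * hyp_oracle / length(alphas)
  sig <- sampled_integrated_gradients(lmod, s, n_path_points = 24,
                                      samples_per_point = 24, logit_scale = C,
                                      cells = 1, return_se = TRUE, seed = 7)
  got <- matrix(sig$hypothetical[1, , ], ncol = 4)
  se <- matrix(sig$se[1, , ], ncol = 4)
  # every entry within 3 Monte-Carlo standard errors (plus tiny slack for
  # the quadrature itself)
  expect_true(all(abs(got - hyp_oracle) <= 3 * se + 1e-3))
  # masked scores are the hypothetical scores at observed bases only
  expect_equal(sig$masked[1, , ], sig$hypothetical[1, , ] * onehot,
               ignore_attr = TRUE)
  expect_true(all(rowSums(matrix(sig$masked[1, , ], ncol = 4) != 0) <= 1))
  # approximate completeness: masked sum ~ f(x) - E_background[f]
  fx <- sum(Weff * t(onehot))
  fbg <- sum(colMeans(Weff) )
  expect_lt(abs(sum(sig$masked[1, , ]) - (fx - fbg)),
            0.15 * max(abs(fx - fbg), 1))
  # reproducibility
  sig2 <- sampled_integrated_gradients(lmod, s, n_path_points = 24,
                                       samples_per_point = 24, logit_scale = C,
                                       cells = 1, seed = 7)
  expect_equal(sig2$hypothetical, sig$hypothetical)
})

test_that("SIG of a constant model is exactly zero", {
  L <- 40
  lmod <- linear_activity_model(list(matrix(0, 4, L), matrix(0, 4, L)),
                                bias = c(2, -1))
  s <- strrep("ACGT", 10)
  sig <- sampled_integrated_gradients(lmod, s, n_path_points = 6,
                                      samples_per_point = 4, seed = 1)
  expect_true(all(sig$hypothetical == 0))
})

test_that("block calling thresholds smoothed runs of contribution", {
  expect_equal(nrow(call_blocks(rep(0, 200))), 0)
  x <- rep(0, 200); x[51:60] <- 0.1
  b <- call_blocks(x)
  expect_equal(nrow(b), 1)
  expect_equal(b$sign, "+")
  expect_lte(b$start, 51)
  expect_gte(b$end, 58)
  # negative blocks are symmetric
  bn <- call_blocks(-x)
  expect_equal(bn$sign, "-")
  expect_equal(bn$start, b$start)
  # a short spike fails the minimum run length after smoothing
  y <- rep(0, 200); y[100] <- 0.02
  expect_equal(nrow(call_blocks(y)), 0)
  # translation equivariance
  x2 <- rep(0, 200); x2[61:70] <- 0.1
  b2 <- call_blocks(x2)
  expect_equal(b2$start, b$start + 10)
  expect_equal(b2$end, b$end + 10)
})

test_that("Gaussian smoothing agrees with a dense convolution oracle", {
  set.seed(6)
  x <- rnorm(80)
  sm <- credesign:::gaussian_smooth(x, sigma = 1.15)
  lw <- as.integer(4 * 1.15 + 0.5)
  w <- exp(-0.5 * ((-lw:lw) / 1.15)^2); w <- w / sum(w)
  padded <- c(rev(x[1:lw]), x, rev(x[(80 - lw + 1):80]))
  oracle <- vapply(seq_along(x), function(i) sum(padded[i:(i + 2 * lw)] * w),
                   numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-12)
})

test_that("block ablation lowers activity when positive blocks are destroyed", {
  m <- base_counter_model("G", per_base = 0.05)
  set.seed(4)
  seqs <- character(6); blocks <- vector("list", 6)
  for (i in 1:6) {
    ch <- sample(c("A", "C", "T"), 200, TRUE)
    ch[80:110] <- "G"
    seqs[i] <- paste(ch, collapse = "")
    track <- rep(0, 200); track[80:110] <- 0.05
    blocks[[i]] <- call_blocks(track)
  }
  names(seqs) <- paste0("s", 1:6)
  ab <- ablate_blocks(m, seqs, blocks, mode = "positive", n_random = 3, seed = 2)
  expect_equal(nrow(ab), 6)
  expect_true(all(ab$delta_cell1 < 0))
  # no negative blocks -> empty result
  abn <- ablate_blocks(m, seqs, blocks, mode = "negative", seed = 2)
  expect_equal(nrow(abn), 0)
  # outside mode disrupts at least five positions away from blocks
  abo <- ablate_blocks(m, seqs, blocks, mode = "outside", seed = 2)
  expect_true(all(abo$n_positions[!abo$skipped] >= 5))
})

test_that("pattern-to-PWM conversion is scale-free and argmax-preserving", {
  set.seed(9)
  pat <- matrix(rnorm(10 * 4, 0, 0.1), 10, 4) + 0.05
  m1 <- pattern_to_pwm(pat, "positive", id = "p")
  m2 <- pattern_to_pwm(pat * 7.3, "positive", id = "p")
  expect_equal(m1$pwm, m2$pwm, tolerance = 1e-12)
  expect_equal(apply(m1$ppm, 1, which.max), apply(pat, 1, which.max))
  # uniform rows give uniform probabilities
  mu <- pattern_to_pwm(matrix(0.2, 6, 4), "positive")
  expect_true(all(abs(mu$ppm - 0.25) < 1e-12))
  expect_error(pattern_to_pwm(matrix(0, 5, 4), "positive"), "all-zero")
  # negative polarity flips repressive positions before conversion
  neg <- matrix(0.1, 8, 4)
  neg[3:5, ] <- -0.12
  mn <- pattern_to_pwm(neg, "negative", id = "n")
  expect_true(all(mn$pwm[3:5, ] > 0))   # flipped and compensated by 1.2
  expect_equal(mn$cwm, neg)             # original pattern kept as the CWM
})

test_that("the contribution scan matches a brute-force Pearson oracle", {
  set.seed(12)
  L <- 50; cells <- c("x", "y")
  for (rep_i in 1:10) {
    w <- sample(6:10, 1)
    cwm <- matrix(rnorm(w * 4), w, 4)
    motif <- motif_model(matrix(0.25, w, 4), id = "m")
    motif$cwm <- cwm
    hyp <- array(rnorm(2 * L * 4, 0, 0.5), c(2, L, 4))
    map <- structure(list(hypothetical = hyp, masked = hyp, seq_id = "s",
                          cells = cells), class = "contribution_map")
    hits <- contribution_motif_scan(motif, list(map), pad = 5, r_cap = 0.4,
                                    sd_mult = 2, seed = 1)
    # oracle: all windows, all orientations, plain cor()
    thr <- attr(hits, "thresholds")
    for (ci in 1:2) {
      H <- rbind(matrix(0, 5, 4), matrix(hyp[ci, , ], ncol = 4), matrix(0, 5, 4))
      want <- list()
      for (strand in c("+", "-")) {
        WW <- if (strand == "+") cwm else cwm[w:1, 4:1]
        for (j in 1:(nrow(H) - w + 1)) {
          win <- H[j:(j + w - 1), ]
          if (sd(win) < 1e-12) next
          r <- cor(as.vector(win), as.vector(WW))
          if (is.finite(r) && r >= thr[paste(cells[ci], "m", sep = ".")]) {
            want[[length(want) + 1]] <- data.frame(start = j - 1L - 5L,
                                                   strand = strand, r = r)
          }
        }
      }
      got <- hits[hits$cell == cells[ci], ]
      nwant <- if (length(want)) nrow(do.call(rbind, want)) else 0
      expect_equal(nrow(got), nwant)
      if (nwant > 0) {
        wdf <- do.call(rbind, want)
        wdf <- wdf[order(wdf$start, wdf$strand), ]
        gdf <- got[order(got$start, got$strand), ]
        expect_equal(gdf$start, wdf$start)
        expect_equal(gdf$r, wdf$r, tolerance = 1e-10)
      }
    }
  }
})

test_that("a window equal to the CWM is always a hit; flat windows never are", {
  w <- 8; L <- 40
  set.seed(5)
  cwm <- matrix(rnorm(w * 4), w, 4)
  motif <- motif_model(matrix(0.25, w, 4), id = "self")
  motif$cwm <- cwm
  hyp <- array(0, c(1, L, 4))
  hyp[1, 11:(10 + w), ] <- cwm         # exact copy at 0-based position 10
  map <- structure(list(hypothetical = hyp, masked = hyp, seq_id = "s",
                        cells = "x"), class = "contribution_map")
  hits <- contribution_motif_scan(motif, list(map), seed = 1)
  self_hit <- hits[hits$start == 10 & hits$strand == "+", ]
  expect_equal(nrow(self_hit), 1)
  expect_equal(self_hit$r, 1, tolerance = 1e-12)
  # all-zero maps produce no hits (zero-variance windows are excluded)
  map0 <- structure(list(hypothetical = array(0, c(1, L, 4)),
                         masked = array(0, c(1, L, 4)), seq_id = "z",
                         cells = "x"), class = "contribution_map")
  expect_equal(nrow(contribution_motif_scan(motif, list(map0), seed = 1)), 0)
})

test_that("motif embedding in random background detects a linear activator", {
  m <- base_counter_model("G", per_base = 0.05)
  gmot <- sharp_motif("GGGGGGGG", sharp = 0.97)
  res <- motif_embed_background(m, gmot, n = 400, length = 200, seed = 2)
  expect_gt(res$delta[1], 3 * res$se[1])
  # a uniform 'motif' is indistinguishable from background
  unif <- motif_model(matrix(0.25, 8, 4), id = "unif")
  res0 <- motif_embed_background(m, unif, n = 400, length = 200, seed = 2)
  expect_lt(abs(res0$delta[1]), 3 * res0$se[1])
})

test_that("motif ablation removes merged hit spans and lowers linear activity", {
  m <- base_counter_model("G", per_base = 0.05)
  set.seed(8)
  base <- sample(c("A", "C", "T"), 200, TRUE)
  ch <- base; ch[50:70] <- "G"
  seqs <- c(s1 = paste(ch, collapse = ""), s2 = paste(base, collapse = ""))
  hits <- data.frame(seq_id = c("s1", "s1"), start = c(49L, 60L),
                     end = c(65L, 70L))   # overlapping -> merged 49..70
  out <- motif_ablation(m, seqs, hits, n_random = 4, seed = 3)
  expect_equal(out$seq_id, "s1")          # s2 has no hits and is excluded
  expect_lt(out$delta_cell1, 0)
  out2 <- motif_ablation(m, seqs, hits, n_random = 4, seed = 3)
  expect_identical(out, out2)
})

test_that("motif contribution summaries weight instances and call direction", {
  L <- 30
  mk_map <- function(id, val) {
    hyp <- array(0, c(2, L, 4))
    hyp[1, 5:10, 1] <- val
    hyp[2, 5:10, 1] <- -val / 2
    structure(list(hypothetical = hyp, masked = hyp, seq_id = id,
                   cells = c("x", "y")), class = "contribution_map")
  }
  maps <- list(a = mk_map("a", 0.3), b = mk_map("b", 0.6))
  hits <- data.frame(seq_id = c("a", "b"), cell = "x", motif = "m1",
                     start = 4L, end = 10L, strand = "+", r = c(0.8, 0.4))
  out <- motif_contribution_summary(hits, maps)
  sums <- c(a = 6 * 0.3, b = 6 * 0.6)
  expect_equal(out$by_cell$weighted_mean,
               sum(c(0.8, 0.4) * sums) / 1.2, tolerance = 1e-10)
  expect_equal(out$directionality$direction, "activator")
  # a single instance reduces to its own contribution sum
  one <- motif_contribution_summary(hits[1, ], maps)
  expect_equal(one$by_cell$weighted_mean, sums[["a"]])
  # negative sums give a repressor call
  hits_y <- transform(hits, cell = "y")
  outy <- motif_contribution_summary(hits_y, maps)
  expect_equal(outy$directionality$direction, "repressor")
})

test_that("co-occurrence percentages come from exact set intersections", {
  hits <- data.frame(seq_id = c("s1", "s1", "s2", "s3", "s4"),
                     motif = c("A", "B", "A", "B", "A"))
  groups <- list(g1 = c("s1", "s2", "s3", "s4"))
  M <- motif_cooccurrence(hits, groups)$g1
  expect_equal(M["A", "A"], 75)        # s1, s2, s4
  expect_equal(M["B", "B"], 50)        # s1, s3
  expect_equal(M["A", "B"], 25)        # only s1 has both
  expect_equal(M["A", "B"], M["B", "A"])
  expect_warning(M0 <- motif_cooccurrence(hits, list(bad = character(0)))$bad,
                 "empty group")
  expect_true(all(is.nan(M0)))
})

test_that("NMF recovers block structure with a monotone objective", {
  set.seed(14)
  X <- matrix(0, 40, 6)
  X[1:20, 1:3] <- matrix(rpois(60, 3), 20, 3)
  X[21:40, 4:6] <- matrix(rpois(60, 3), 20, 3)
  dec <- nmf_programs(X, k = 2, max_iter = 500)
  expect_true(all(dec$W >= 0))
  expect_true(all(dec$H >= 0))
  expect_true(all(diff(dec$error_trace) <= 1e-8))
  # each program's dominant motifs lie in a single block
  blocks <- apply(dec$H, 1, function(h) {
    top <- order(-h)[1:3]
    if (all(top <= 3)) 1L else if (all(top >= 4)) 2L else NA_integer_
  })
  expect_setequal(blocks, c(1L, 2L))
  # rows of the normalized coefficient matrix sum to 1
  expect_true(all(abs(rowSums(dec$W_norm) - 1) < 1e-8))
  # the block-1 sequences load on the block-1 program
  p1 <- blocks == 1L
  expect_true(mean(dec$W_norm[1:20, p1]) > mean(dec$W_norm[21:40, p1]))
  # reconstruction error shrinks with k
  e1 <- min(nmf_programs(X, k = 1, max_iter = 300)$error_trace)
  e6 <- min(nmf_programs(X, k = 6, max_iter = 300)$error_trace)
  expect_lte(e6, e1)
  expect_error(nmf_programs(X, k = 10), "exceeds")
  # deterministic initialization makes runs identical
  dec2 <- nmf_programs(X, k = 2, max_iter = 500)
  expect_identical(dec$W, dec2$W)
  # program function: H-weighted average of clipped contributions
  contrib <- matrix(c(5, 1, 1, -2, -2, -2), 6, 1)  # first motif clipped at 3
  decf <- nmf_programs(X, k = 2, max_iter = 200, motif_contrib = contrib)
  expect_equal(dim(decf$program_function), c(2, 1))
  expect_true(all(decf$program_function <= 3))
})

test_that("the motif-count matrix counts deduplicated hit loci", {
  hits <- data.frame(seq_id = c("s1", "s1", "s1", "s2"),
                     cell = c("x", "y", "x", "x"),
                     motif = c("A", "A", "A", "B"),
                     start = c(3L, 3L, 9L, 0L),
                     end = c(9L, 9L, 15L, 6L),
                     strand = "+", r = 0.9)
  X <- motif_count_matrix(hits)
  expect_equal(X["s1", "A"], 2)  # same locus across cells counted once
  expect_equal(X["s2", "B"], 1)
  expect_equal(X["s2", "A"], 0)
})

test_that("saturation-mutagenesis effects subtract the reference with the logo sign", {
  pos <- rep(0:199, each = 3)
  variants <- data.frame(position = pos, alt = c("A", "C", "G"),
                         activity = 2)
  out <- saturation_effects(ref_activity = 2, variants)
  expect_true(all(out$effects$effect == 0))
  expect_true(all(out$per_position$summary == 0))
  # a position where every substitution drops activity by 2 summarizes as +2
  variants2 <- variants
  variants2$activity[variants2$position == 50] <- 0
  out2 <- saturation_effects(2, variants2)
  expect_equal(out2$per_position$summary[out2$per_position$position == 50], 2)
  expect_equal(nrow(out2$effects), 600)
  expect_error(saturation_effects(2, variants[-(1:2), ]), "incomplete")
})

test_that("k-mer diversity is zero for clones and invariant to input order", {
  seqs <- rep(strrep("ACGT", 50), 6)
  expect_true(all(kmer_diversity(seqs) == 0))
  set.seed(20)
  pool <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), character(1))
  d1 <- kmer_diversity(pool)
  d2 <- kmer_diversity(rev(pool))
  expect_equal(unname(d1), unname(rev(d2)))
  # a single substitution moves the 4-mer profile by at most 2k
  s1 <- pool[1]
  ch <- strsplit(s1, "")[[1]]
  ch[100] <- setdiff(c("A", "C", "G", "T"), ch[100])[1]
  s2 <- paste(ch, collapse = "")
  two <- c(s1, s2, pool[2:5])
  dd <- kmer_diversity(two, k = 4, n_neighbors = 1)
  expect_lte(dd[1], 2 * 4)
  expect_error(kmer_diversity(pool[1:3], n_neighbors = 4), "more sequences")
})
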