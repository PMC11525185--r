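test_that("MinGap measures target minus the leading off-target", {
  expect_equal(min_gap(c(5, 3, 1), 1), 2)
  expect_equal(min_gap(c(1, 4, 2), 1), -3)
  expect_equal(min_gap(c(5, 3, 1) + 7.3, 1), 2)   # translation invariant
  expect_error(min_gap(3, 1), "two cell types")
  m <- rbind(c(5, 3, 1), c(0, 2, 1))
  expect_equal(min_gap(m, 2), c(-2, 1))
})

test_that("the bending function matches its closed form and asymptote", {
  expect_equal(bend(0), 0)
  expect_equal(bend(1), 2 - exp(-1))
  expect_lt(abs(bend(10) - 11), 1e-4)
  x <- seq(-50, 50, length.out = 400)
  expect_true(all(is.finite(bend(x))))
  expect_true(all(diff(bend(x)) > 0))  # strictly increasing
})

test_that("bent-MinGap clamps then bends, and rewards raising the target", {
  expect_equal(bent_min_gap(c(0, 0, 0), 1), 0)
  expect_equal(bent_min_gap(c(10, 0, 0), 1), bend(6) - bend(0))
  a <- c(1, 0.5, -1)
  vals <- sapply(seq(1, 5.9, by = 0.5), function(t) {
    b <- a; b[1] <- t; bent_min_gap(b, 1)
  })
  expect_true(all(diff(vals) > 0))
  # unlike MinGap, bent-MinGap is not translation invariant
  expect_false(isTRUE(all.equal(bent_min_gap(c(2, 0, 0), 1),
                                bent_min_gap(c(4, 2, 2), 1))))
})

test_that("the motif penalty implements the weighted above-threshold sum", {
  mA <- sharp_motif("ACGGTACGGT", id = "a", sharp = 0.99)
  mB <- sharp_motif("TTGACCGGTT", id = "b", sharp = 0.99)
  batch <- c(embed_at("ACGGTACGGT", 30, seed = 1),
             embed_at("ACGGTACGGT", 120, seed = 2))
  thr_a <- 0.9 * mA$consensus_score
  # m = 1: total above-threshold score divided by batch size
  pool1 <- penalty_pool(list(mA), threshold_frac = 0.9)
  hand <- 0
  for (s in batch) {
    hits <- pwm_scan(mA, s, threshold = thr_a)
    hand <- hand + sum(hits$score)
  }
  expect_equal(motif_penalty(batch, pool1), hand / 2, tolerance = 1e-10)
  # m = 2 with hits only for motif 1: weight (2-1+1)^(1/3) and 1/(m n)
  pool2 <- penalty_pool(list(mA, mB), threshold_frac = 0.9)
  expect_equal(motif_penalty(batch, pool2), 2^(1/3) * hand / (2 * 2),
               tolerance = 1e-10)
  # nothing passes an impossible threshold
  pool_inf <- penalty_pool(list(mA), threshold_frac = 2)
  expect_equal(motif_penalty(batch, pool_inf), 0)
  # adding an above-threshold hit never lowers the penalty
  batch2 <- c(batch, embed_at("ACGGTACGGT", 60, seed = 3))
  expect_gte(motif_penalty(batch2, pool1) * 3, motif_penalty(batch, pool1) * 2)
})

test_that("the penalty gradient matches finite differences off the threshold", {
  mA <- sharp_motif("ACGGTACG", id = "a")
  pool <- penalty_pool(list(mA), threshold_frac = 0.5)
  set.seed(2)
  X <- credesign:::encode_batch(c(embed_at("ACGGTACG", 20, L = 60, seed = 4)))
  pg <- credesign:::motif_penalty_grad(X, pool)
  h <- 1e-6
  for (t in 1:6) {
    b <- sample(4, 1); i <- sample(60, 1)
    Xp <- X; Xp[b, i, 1] <- Xp[b, i, 1] + h
    Xm <- X; Xm[b, i, 1] <- Xm[b, i, 1] - h
    fd <- (credesign:::motif_penalty_grad(Xp, pool)$value -
             credesign:::motif_penalty_grad(Xm, pool)$value) / (2 * h)
    expect_equal(pg$dX[b, i, 1], fd, tolerance = 1e-5)
  }
})

test_that("motif presence score is the normalized above-threshold score sum", {
  m <- sharp_motif("ACGGTTACGG", sharp = 0.99)
  cons <- consensus_seq(m)
  expect_equal(motif_presence_score(cons, m), 1.0, tolerance = 1e-9)
  two <- paste0(cons, strrep("T", 8), cons)
  expect_equal(motif_presence_score(two, m,
                                    threshold = 0.95 * m$consensus_score), 2.0,
               tolerance = 1e-2)
  set.seed(3)
  rnd <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  expect_equal(motif_presence_score(rnd, m, threshold = 0.9 * m$consensus_score), 0)
})

test_that("propeller coordinates reproduce the worked example and its invariances", {
  p <- propeller(c(5, 3, 1))
  expect_equal(p$radius, 4)
  expect_equal(p$angle_deg, 30)
  expect_equal(p$axis, 1)
  expect_equal(p$median_axis, 2)
  # (x+4, x+2, x) maps to the same point for any x
  for (x in c(-3, 0, 2.7)) {
    q <- propeller(c(x + 4, x + 2, x))
    expect_equal(q$radius, 4)
    expect_equal(q$angle_deg, 30)
    expect_equal(q$axis, 1)
  }
  d <- propeller(c(2, 2, 2))
  expect_equal(d$radius, 0)
  expect_equal(d$angle_deg, 0)
  set.seed(5)
  A <- matrix(rnorm(300), ncol = 3)
  pr1 <- propeller(A)
  pr2 <- propeller(A + 3.3)
  expect_equal(pr1$radius, pr2$radius)
  expect_equal(pr1$angle_deg, pr2$angle_deg)
  expect_true(all(pr1$radius >= 0))
  expect_true(all(pr1$angle_deg >= 0 & pr1$angle_deg <= 60))
})

test_that("specificity calls use strict thresholds on MaxGap and the gap ratio", {
  # ratio exactly 0.5 fails the strict inequality
  c1 <- classify_specific(c(5, 3, 1))
  expect_false(c1$specific)
  expect_equal(c1$max_gap, 4)
  expect_equal(c1$min_gap_over_max_gap, 0.5)
  # clear case passes lenient but sits on the stringent MaxGap boundary
  c2 <- classify_specific(c(5, 1.5, 1))
  expect_true(c2$specific)
  expect_false(classify_specific(c(5, 1.5, 1), maxgap_min = 4)$specific)
  expect_true(classify_specific(c(6, 1.5, 1), maxgap_min = 4)$specific)
  expect_false(classify_specific(c(0, 0, 0))$specific)
  # reassignment: argmax is the effective target
  c3 <- classify_specific(c(1, 6, 1.5), designed_target = 1)
  expect_true(c3$specific)
  expect_true(c3$reassigned)
  expect_equal(c3$effective_target, 2)
})

test_that("specificity calls agree with the propeller-angle rederivation", {
  set.seed(11)
  A <- matrix(rnorm(30000, 0, 2), ncol = 3)
  calls <- classify_specific(A)
  # oracle: specific <=> radius > 1 and deviation angle < 30 degrees
  mx <- apply(A, 1, max); mn <- apply(A, 1, min); md <- apply(A, 1, median)
  angle <- ifelse(mx > mn, 60 * (md - mn) / (mx - mn), 0)
  oracle <- (mx - mn > 1) & (angle < 30) & (mx > mn)
  expect_equal(calls$specific, unname(oracle))
})

test_that("the library-level specificity report counts groups and reassignments", {
  rows <- rbind(
    mpra_row("s1", c(5, 1, 0)), mpra_row("s2", c(6, 0, 1)),
    mpra_row("s3", c(5, 3, 1)),                       # ratio 0.5: not specific
    mpra_row("s4", c(0.5, 0.2, 0.1)),                 # MaxGap too small
    mpra_row("n1", c(1, 5, 0.5)),                     # specific but designed for cell 1
    mpra_row("n2", c(2, 2, 2)),
    mpra_row("n3", c(3, 0.4, 0.2), se = c(0.2, 0.2, 1.4))  # removed by SE filter
  )
  rows$group <- c(rep("synthetic", 4), rep("natural", 3))
  rows$designed_target <- c(1, 1, 1, 1, 1, 1, 1)
  rep <- specificity_report(rows)
  syn <- rep$by_group[rep$by_group$group == "synthetic", ]
  nat <- rep$by_group[rep$by_group$group == "natural", ]
  expect_equal(syn$n, 4)
  expect_equal(syn$pct_specific_lenient, 50.0)   # s1, s2 of 4
  expect_equal(nat$n, 2)                         # n3 filtered out
  expect_equal(nat$pct_specific_lenient, 50.0)   # n1 of 2
  expect_equal(rep$reassigned_lenient, 1)        # n1
  expect_equal(rep$reassigned_stringent, 1)      # n1 MaxGap 4.5 passes > 4 too
  # skipping the SE filter keeps n3
  rep2 <- specificity_report(rows, apply_se_filter = FALSE)
  expect_equal(sum(rep2$by_group$n), 7)
})

test_that("the propeller plot renders without error and returns coordinates", {
  set.seed(2)
  A <- matrix(rnorm(60), ncol = 3)
  path <- tempfile(fileext = ".png")
  grDevices::png(path)
  pr <- plot_propeller(A, cells = c("K562", "HepG2", "SK-N-SH"))
  grDevices::dev.off()
  expect_equal(nrow(pr), 20)
  expect_true(file.exists(path))
})
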