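#' Annealing temperature schedule
#'
#' `tau(s) = 1 / (1 + s^0.501)`: strictly decreasing from `tau(0) = 1`,
#' with a diverging infinite sum (the exponent barely exceeds 1/2), so
#' the chain cools slowly enough to keep escaping local optima early on.
#'
#' @param s step number (integer >= 0).
#' @export
anneal_temperature <- function(s) 1 / (1 + s^0.501)

# Metropolis-Hastings acceptance for a symmetric proposal kernel
mh_accept <- function(dE, tau) {
  dE <= 0 || stats::runif(1) < exp(-dE / tau)
}

new_design_result <- function(sequences, activities, objective, trace,
                              rejected_count, config) {
  structure(list(sequences = sequences, activities = activities,
                 objective = objective, trace = trace,
                 rejected_count = rejected_count, config = config),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %s: %d accepted, %d rejected; best objective %s\n",
              x$config$algorithm, length(x$sequences), x$rejected_count,
              if (length(x$objective)) sprintf("%.3f", max(x$objective)) else "NA"))
  invisible(x)
}

# objective value and cotangent for a batch of (unclamped) predictions
bent_min_gap_grad <- function(pred, target, clamp = c(-2, 6)) {
  a <- pred
  if (!is.null(clamp)) a <- pmin(pmax(a, clamp[1]), clamp[2])
  n <- nrow(a)
  obj <- numeric(n)
  d <- matrix(0, n, ncol(a))
  for (i in seq_len(n)) {
    off <- setdiff(seq_len(ncol(a)), target)
    j <- off[which.max(a[i, off])]
    obj[i] <- bend(a[i, target]) - bend(a[i, j])
    in_t <- is.null(clamp) || (pred[i, target] > clamp[1] && pred[i, target] < clamp[2])
    in_j <- is.null(clamp) || (pred[i, j] > clamp[1] && pred[i, j] < clamp[2])
    if (in_t) d[i, target] <- bend_grad(a[i, target])
    if (in_j) d[i, j] <- -bend_grad(a[i, j])
  }
  list(value = obj, d_pred = d)
}

# value and input-gradient of the motif penalty for a batch cube
motif_penalty_grad <- function(X, pool) {
  m <- length(pool$motifs)
  B <- dim(X)[3]
  L <- dim(X)[2]
  dX <- array(0, dim(X))
  total <- 0
  for (i in seq_len(m)) {
    motif <- pool$motifs[[i]]
    wfac <- (m - i + 1)^(1 / 3)
    t_i <- pool$thresholds[i]
    w <- motif$width
    if (w > L) next
    for (orient in 1:2) {
      wt <- if (orient == 1) motif$pwm else rc_matrix(motif$pwm)
      wt_t <- t(wt)  # 4 x w
      for (b in seq_len(B)) {
        x <- t(X[, , b])  # L x 4
        sc <- pwm_window_scores(wt, x)
        hit <- which(sc >= t_i)
        if (!length(hit)) next
        total <- total + wfac * sum(sc[hit])
        for (h in hit) {
          dX[, h:(h + w - 1), b] <- dX[, h:(h + w - 1), b] + wfac * wt_t
        }
      }
    }
  }
  scale <- 1 / (m * B)
  list(value = total * scale, dX = dX * scale)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# instance normalization over the length axis, per base channel, no affine
instance_norm <- function(theta, eps = 1e-5) {
  mu <- colMeans(theta)
  v <- colMeans(theta^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  z <- sweep(sweep(theta, 2, mu, `-`), 2, inv, `*`)
  list(z = z, inv = inv)
}

instance_norm_bw <- function(z, inv, dz) {
  t1 <- sweep(dz, 2, colMeans(dz), `-`)
  t2 <- sweep(z, 2, colMeans(dz * z), `*`)
  sweep(t1 - t2, 2, inv, `*`)
}

sample_onehot_cube <- function(p, n_samples) {
  L <- nrow(p)
  X <- array(0, c(4, L, n_samples))
  for (i in seq_len(L)) {
    b <- sample.int(4, n_samples, replace = TRUE, prob = p[i, ])
    X[cbind(b, i, seq_len(n_samples))] <- 1
  }
  X
}

#' Gradient-based sequence design (Fast SeqProp)
#'
#' Optimizes a learnable L x 4 logit matrix: at each step the logits are
#' instance-normalized (no learnable affine), soft-maxed into a position
#' probability matrix, a batch of one-hot sequences is sampled from it,
#' and the loss is the negative mean bent-MinGap of the samples (plus the
#' motif penalty when a pool is given). Gradients flow through the
#' sampling with the straight-through estimator (the sampled one-hot's
#' gradient is applied to the softmax probabilities unchanged). Logits
#' are initialized from a standard normal and updated with Adam under a
#' cosine-annealed learning rate. After the final step, 20 sequences are
#' sampled from the learned distribution and the best by bent-MinGap is
#' collected unless its objective is below `collect_min`.
#'
#' @param model an activity model with gradient access.
#' @param target target cell type (index or name).
#' @param n_runs number of independent runs (each contributes at most one
#'   sequence).
#' @param steps optimization steps per run (default 300).
#' @param n_samples one-hot samples per step (default 20).
#' @param lr,lr_min Adam learning rate and its cosine floor.
#' @param clamp prediction clamp interval.
#' @param collect_min bent-MinGap collection threshold (default 3.6);
#'   `-Inf` collects every run's best.
#' @param penalty optional [penalty_pool()] added to the loss.
#' @param penalty_weight multiplier on the penalty term.
#' @param length insert length (default 200).
#' @param seed RNG seed.
#' @return a `design_result`; `trace` holds the per-step mean objective
#'   of each run and `ppms` the learned per-run L x 4 nucleotide
#'   distributions.
#' @export
design_fast_seqprop <- function(model, target = 1, n_runs = 1, steps = 300,
                                n_samples = 20, lr = 0.5, lr_min = 1e-6,
                                clamp = c(-2, 6), collect_min = 3.6,
                                penalty = NULL, penalty_weight = 1,
                                length = 200, seed = 1) {
  if (is.character(target)) target <- match(target, model$config$cell_types)
  if (is.null(utils::getS3method("model_input_grad", class(model)[1], optional = TRUE)))
    stop("model does not provide gradient access (no model_input_grad method)")
  with_seed(seed, {
    seqs <- character(0); objs <- numeric(0); acts <- NULL
    traces <- list(); ppms <- list(); rejected <- 0
    for (run in seq_len(n_runs)) {
      theta <- matrix(rnorm(length * 4), length, 4)
      ad <- adam_init(list(theta = theta))
      tr <- numeric(steps)
      for (s in seq_len(steps)) {
        ino <- instance_norm(theta)
        p <- softmax_rows(ino$z)
        X <- sample_onehot_cube(p, n_samples)
        og <- bent_min_gap_grad_model(model, X, target, clamp)
        tr[s] <- mean(og$value)
        dX <- -og$dX / n_samples        # loss = -mean objective
        if (!is.null(penalty)) {
          pg <- motif_penalty_grad(X, penalty)
          dX <- dX + penalty_weight * pg$dX
        }
        # straight-through: gradient w.r.t. the sample applied to p
        dp <- matrix(0, length, 4)
        for (b in seq_len(n_samples)) dp <- dp + t(dX[, , b])
        dz <- p * (dp - rowSums(p * dp))  # softmax backward, per row
        dtheta <- instance_norm_bw(ino$z, ino$inv, dz)
        upd <- adam_step(list(theta = theta), list(theta = dtheta), ad,
                         lr = cosine_lr(s, steps, lr, lr_min))
        theta <- upd$params$theta
        ad <- upd$state
      }
      ino <- instance_norm(theta)
      p <- softmax_rows(ino$z)
      ppms[[run]] <- p
      Xf <- sample_onehot_cube(p, 20)
      cand <- vapply(seq_len(20), function(b) decode_onehot(t(Xf[, , b])), character(1))
      pred <- predict_activity(model, cand, clamp = clamp)
      val <- bent_min_gap(pred, target, clamp = NULL)  # already clamped
      best <- which.max(val)
      traces[[run]] <- tr
      if (val[best] >= collect_min) {
        seqs <- c(seqs, cand[best])
        objs <- c(objs, val[best])
        acts <- rbind(acts, pred[best, , drop = FALSE])
      } else {
        rejected <- rejected + 1
      }
    }
    res <- new_design_result(seqs, acts, objs, traces, rejected,
                             list(algorithm = "fast_seqprop", target = target,
                                  steps = steps, n_samples = n_samples, lr = lr,
                                  clamp = clamp, collect_min = collect_min,
                                  penalized = !is.null(penalty), seed = seed))
    res$ppms <- ppms   # learned per-run nucleotide distributions
    res
  })
}

# objective + insert gradient through the model (both strands)
bent_min_gap_grad_model <- function(model, X, target, clamp) {
  pred <- insert_forward(model, X, average_rc = TRUE)
  og <- bent_min_gap_grad(pred, target, clamp)
  g <- insert_gradient(model, X, d_out = og$d_pred, average_rc = TRUE)
  list(value = og$value, dX = g$dX, pred = pred)
}

#' Evolutionary sequence design (AdaLead)
#'
#' Adaptive greedy evolutionary search: per generation, parents within
#' `threshold` of the generation's best fitness are recombined (per-site
#' crossover at `recomb_rate`) and mutated (`mu` expected substitutions
#' per child), and each child is greedily rolled out for up to `rho`
#' additional mutation rounds while its fitness improves. Fitness is the
#' bent-MinGap of the clamped predictions. One run returns at most one
#' sequence: the best of the final population, unless its (unbent)
#' MinGap is below `collect_min_mingap`.
#'
#' @param model an activity model.
#' @param target target cell type (index or name).
#' @param n_seeds population size (default 20 random sequences).
#' @param generations number of generations (default 30).
#' @param mu expected mutations per child.
#' @param recomb_rate per-position recombination rate.
#' @param threshold parent-selection band as a fraction of |best fitness|.
#' @param rho greedy rollout depth bound.
#' @param clamp prediction clamp interval.
#' @param collect_min_mingap MinGap collection threshold (default 2).
#' @param length insert length.
#' @param seed RNG seed.
#' @export
design_adalead <- function(model, target = 1, n_seeds = 20, generations = 30,
                           mu = 1, recomb_rate = 0.1, threshold = 0.25,
                           rho = 2, clamp = c(-2, 6), collect_min_mingap = 2,
                           length = 200, seed = 1) {
  if (is.character(target)) target <- match(target, model$config$cell_types)
  fitness <- function(ss) {
    pred <- predict_activity(model, ss, clamp = clamp)
    bent_min_gap(pred, target, clamp = NULL)
  }
  mutate <- function(s, expected = mu) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(base::length(ch)) < expected / base::length(ch))
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
    paste(ch, collapse = "")
  }
  with_seed(seed, {
    pop <- random_sequences(n_seeds, length)
    fit <- fitness(pop)
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      if (base::length(unique(pop)) == 1) {
        message(sprintf("population collapsed at generation %d; stopping early", g))
        trace <- trace[seq_len(g - 1)]
        break
      }
      fmax <- max(fit)
      band <- fmax - threshold * abs(fmax)
      parents <- pop[fit >= band]
      if (!base::length(parents)) parents <- pop[which.max(fit)]
      children <- character(n_seeds)
      for (ci in seq_len(n_seeds)) {
        p1 <- sample(parents, 1)
        child <- if (runif(1) < 0.5 && base::length(parents) > 1) {
          p2 <- sample(setdiff(parents, p1), 1)
          a <- strsplit(p1, "")[[1]]; b <- strsplit(p2, "")[[1]]
          swap <- runif(base::length(a)) < recomb_rate
          a[swap] <- b[swap]
          paste(a, collapse = "")
        } else p1
        children[ci] <- mutate(child)
      }
      cfit <- fitness(children)
      # greedy rollout, depth-bounded by rho
      for (ci in seq_len(n_seeds)) {
        cur <- children[ci]; curf <- cfit[ci]
        for (d in seq_len(rho)) {
          cand <- mutate(cur)
          candf <- fitness(cand)
          if (candf > curf) { cur <- cand; curf <- candf } else break
        }
        children[ci] <- cur; cfit[ci] <- curf
      }
      allseq <- c(pop, children); allfit <- c(fit, cfit)
      keep <- order(-allfit)[seq_len(n_seeds)]
      pop <- allseq[keep]; fit <- allfit[keep]
      trace[g] <- max(fit)
    }
    best <- which.max(fit)
    pred <- predict_activity(model, pop[best], clamp = clamp)
    mg <- min_gap(drop(pred), target)
    accept <- mg >= collect_min_mingap
    new_design_result(
      if (accept) pop[best] else character(0),
      if (accept) pred else NULL,
      if (accept) fit[best] else numeric(0),
      trace, as.integer(!accept),
      list(algorithm = "adalead", target = target, n_seeds = n_seeds,
           generations = generations, mu = mu, recomb_rate = recomb_rate,
           threshold = threshold, rho = rho, clamp = clamp,
           collect_min_mingap = collect_min_mingap, seed = seed))
  })
}

#' Simulated-annealing sequence design
#'
#' Metropolis-Hastings chain on sequence space: proposals mutate three
#' random positions to random different bases (a symmetric kernel);
#' the energy is the negative MinGap (no bending) of the clamped
#' predictions; a proposal with `dE <= 0` is always accepted, otherwise
#' with probability `exp(-dE / tau(s))` under the [anneal_temperature()]
#' schedule. The best sequence visited is returned (configurable to the
#' final state).
#'
#' @param model an activity model.
#' @param target target cell type (index or name).
#' @param steps chain length (default 3000).
#' @param n_mut positions mutated per proposal (default 3).
#' @param clamp prediction clamp interval.
#' @param collect_min MinGap collection threshold (default `-Inf`:
#'   always collect).
#' @param return_best return the best-visited sequence (default) rather
#'   than the final chain state.
#' @param length insert length.
#' @param seed RNG seed.
#' @export
design_simulated_annealing <- function(model, target = 1, steps = 3000,
                                       n_mut = 3, clamp = c(-2, 6),
                                       collect_min = -Inf, return_best = TRUE,
                                       length = 200, seed = 1) {
  if (is.character(target)) target <- match(target, model$config$cell_types)
  energy <- function(s) {
    pred <- predict_activity(model, s, clamp = clamp)
    -min_gap(drop(pred), target)
  }
  with_seed(seed, {
    cur <- random_sequences(1, length)
    ecur <- energy(cur)
    best <- cur; ebest <- ecur
    trace <- numeric(steps)
    for (s in seq_len(steps)) {
      ch <- strsplit(cur, "")[[1]]
      pos <- sample.int(length, n_mut)
      for (i in pos) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
      prop <- paste(ch, collapse = "")
      eprop <- energy(prop)
      dE <- eprop - ecur
      if (mh_accept(dE, anneal_temperature(s - 1))) {
        cur <- prop; ecur <- eprop
      }
      if (ecur < ebest) { best <- cur; ebest <- ecur }
      trace[s] <- -ecur
    }
    final <- if (return_best) best else cur
    efinal <- if (return_best) ebest else ecur
    pred <- predict_activity(model, final, clamp = clamp)
    accept <- -efinal >= collect_min
    new_design_result(
      if (accept) final else character(0),
      if (accept) pred else NULL,
      if (accept) -efinal else numeric(0),
      trace, as.integer(!accept),
      list(algorithm = "simulated_annealing", target = target, steps = steps,
           n_mut = n_mut, clamp = clamp, collect_min = collect_min,
           seed = seed))
  })
}
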