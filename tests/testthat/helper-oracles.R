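# Independent oracles, written as literally as possible from the model
# definition and kept structurally different from the package code paths
# they check.

# Second, independent transcription of the mass-action equations: one
# explicit formula per species, no index helpers, no loops shared with the
# package implementation.
oracle_rhs <- function(y, p) {
  G <- y[c("G0", "G1", "G2")]; M <- y[c("M0", "M1", "M2")]
  P <- y[c("P0", "P1", "P2")]; Gs <- y[c("Gs0", "Gs1", "Gs2")]
  Gss <- p$g_t - G - Gs
  # gene i is bound by protein (i + 2) mod 3; protein i binds gene (i+1) mod 3
  Prep <- P[c(3, 1, 2)]                     # repressor of gene i
  dG <- -p$k_on * G * Prep + p$k_off * Gs
  dM <- p$alpha * G - M / p$tau_m
  Gt <- G[c(2, 3, 1)]; Gst <- Gs[c(2, 3, 1)]; Gsst <- Gss[c(2, 3, 1)]
  dP <- p$beta * M - P / p$tau_p - p$k_on * P * (Gt + Gst) +
    p$k_off * Gst + p$k_off2 * Gsst
  dGs <- p$k_on * Prep * (G - Gs) - p$k_off * Gs + p$k_off2 * Gss
  out <- as.vector(rbind(dG, dM, dP, dGs))
  names(out) <- names(y)
  out
}

# Plain-sum ACF at the package's convention, written without FFT and
# without reusing segment_acf() internals.
oracle_acf <- function(x) {
  l <- length(x)
  xc <- x - mean(x)
  v <- sum(xc^2) / l
  sapply(0:(l - 1), function(tau) {
    num <- 0
    for (j in seq_len(l - tau)) num <- num + xc[j] * xc[j + tau]
    (num / (l - tau)) / v
  })
}

# Non-spatial Monte-Carlo of the reaction schedule: same per-step event
# order as the lattice engine but with no positions at all (every protein
# sees every gene), tracking counts only. Used for the well-mixed limit.
oracle_wellmixed <- function(p, n_steps, init_m = 0, init_p = 0) {
  g_occ <- matrix(0L, nrow = 3, ncol = p$g_t) # occupancy per gene copy
  M <- rep(init_m, 3); P <- rep(init_p, 3)
  recM <- matrix(0L, n_steps, 3); recP <- matrix(0L, n_steps, 3)
  for (t in seq_len(n_steps)) {
    new_occ <- matrix(0L, nrow = 3, ncol = p$g_t)
    # transcription by free genes
    newM <- sapply(0:2, function(i) rbinom(1, sum(g_occ[i + 1, ] == 0), p$alpha))
    # mRNA: degrade xor translate
    surv <- rbinom(3, M, 1 - 1 / p$tau_m)
    newP <- rbinom(3, surv, p$beta)
    M <- surv
    # protein degradation (free only)
    P <- rbinom(3, P, 1 - 1 / p$tau_p)
    # binding: every protein is co-located with every gene; candidates in
    # random order, genes tried in id order while capacity remains
    cand <- rep.int(0:2, P)
    if (length(cand) > 1) cand <- cand[sample.int(length(cand))]
    for (ty in cand) {
      tg <- (ty + 1) %% 3
      for (g in seq_len(p$g_t)) {
        if (g_occ[tg + 1, g] + new_occ[tg + 1, g] < 2 &&
            runif(1) < p$k_on) {
          new_occ[tg + 1, g] <- new_occ[tg + 1, g] + 1L
          P[ty + 1] <- P[ty + 1] - 1L
          break
        }
      }
    }
    # unbinding of complexes formed before this step
    for (i in 1:3) for (g in seq_len(p$g_t)) {
      if (new_occ[i, g] > 0 || g_occ[i, g] == 0) next
      poff <- if (g_occ[i, g] == 1) p$k_off else p$k_off2
      if (runif(1) < poff) {
        g_occ[i, g] <- g_occ[i, g] - 1L
        ty <- (i - 1 + 2) %% 3
        P[ty + 1] <- P[ty + 1] + 1L
      }
    }
    # newborn molecules join the pools at the end of the step (inert)
    g_occ <- g_occ + new_occ
    M <- M + newM
    P <- P + newP
    bound <- sapply(0:2, function(ty) sum(g_occ[(ty + 1) %% 3 + 1, ]))
    recM[t, ] <- M
    recP[t, ] <- P + bound
  }
  list(M = recM, P = recP)
}

# Standard error of a mean from a correlated series via batch means.
batch_se <- function(x, n_batches = 30) {
  bs <- floor(length(x) / n_batches)
  means <- sapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  })
  sd(means) / sqrt(n_batches)
}
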