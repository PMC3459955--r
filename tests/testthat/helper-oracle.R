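# Independent brute-force oracle for the triad log-linear likelihood.
#
# Everything here is written from the model definition alone (hardcoded
# cell list, literal mean expressions, dense grid search) so it shares no
# code path with the package's optimizer.

# the 15 Mendelian-compatible (M, P, C) triples in canonical order
ORACLE_CELLS <- matrix(c(
  2, 2, 2,
  2, 1, 2,
  2, 1, 1,
  1, 2, 2,
  1, 2, 1,
  2, 0, 1,
  0, 2, 1,
  1, 1, 2,
  1, 1, 1,
  1, 1, 0,
  1, 0, 1,
  1, 0, 0,
  0, 1, 1,
  0, 1, 0,
  0, 0, 0), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("M", "P", "C")))

# mating-type stratum of each cell (1: 2x2 ... 6: 0x0)
oracle_stratum <- local({
  hi <- pmax(ORACLE_CELLS[, "M"], ORACLE_CELLS[, "P"])
  lo <- pmin(ORACLE_CELLS[, "M"], ORACLE_CELLS[, "P"])
  match(paste0(hi, "x", lo), c("2x2", "2x1", "2x0", "1x1", "1x0", "0x0"))
})

# log relative mean of each cell (stratum intercept excluded), literal form
oracle_logr <- function(c1, c2, a, b, g) {
  M <- ORACLE_CELLS[, "M"]; P <- ORACLE_CELLS[, "P"]; C <- ORACLE_CELLS[, "C"]
  maternal <- (C == 1 & (M == 2 | P == 0)) & !(M == 1 & P == 1)
  lr <- c1 * (C == 1) + c2 * (C == 2) + a * maternal + b * (M == 2) + g * (M == 1)
  # double heterozygote: sum of the two latent origin paths
  i9 <- which(M == 1 & P == 1 & C == 1)
  lr[i9] <- c1 + g + log(exp(a) + 1)
  lr
}

# Poisson log-likelihood (sum n log m - m) with per-stratum intercepts
# maximized in closed form: exp(mu_s) = N_s / sum_s r_i.
oracle_profile_ll <- function(counts, c1, c2, a, b, g) {
  lr <- oracle_logr(c1, c2, a, b, g)
  r <- exp(lr)
  ll <- 0
  for (s in 1:6) {
    idx <- which(oracle_stratum == s)
    Ns <- sum(counts[idx])
    if (Ns == 0) next
    Rs <- sum(r[idx])
    m <- Ns * r[idx] / Rs
    nn <- counts[idx]
    ll <- ll + sum(ifelse(nn > 0, nn * log(m), 0)) - Ns
  }
  ll
}

# Dense coarse-to-fine grid search over the free terms. `fixed` pins
# terms (e.g. alpha = 0 for a reduced model); remaining terms are
# searched on a 7-point grid per pass, re-centred and shrunk each pass.
oracle_grid_max <- function(counts,
                            free = c("c1", "c2", "alpha", "beta", "gamma"),
                            fixed = list(), passes = 18) {
  all_terms <- c("c1", "c2", "alpha", "beta", "gamma")
  centre <- setNames(numeric(5), all_terms)
  for (nm in names(fixed)) centre[nm] <- fixed[[nm]]
  width <- 8
  npt <- 7
  best <- c(value = -Inf)
  for (pass in seq_len(passes)) {
    grids <- lapply(all_terms, function(nm) {
      if (nm %in% free) centre[nm] + seq(-width, width, length.out = npt)
      else centre[nm]
    })
    names(grids) <- all_terms
    G <- as.matrix(expand.grid(grids))
    # vectorized profile log-likelihood over all grid rows
    M <- ORACLE_CELLS[, "M"]; P <- ORACLE_CELLS[, "P"]; C <- ORACLE_CELLS[, "C"]
    maternal <- (C == 1 & (M == 2 | P == 0)) & !(M == 1 & P == 1)
    X <- cbind(as.numeric(C == 1), as.numeric(C == 2), as.numeric(maternal),
               as.numeric(M == 2), as.numeric(M == 1))
    LR <- G %*% t(X)
    i9 <- which(M == 1 & P == 1 & C == 1)
    LR[, i9] <- G[, "c1"] + G[, "gamma"] + log(exp(G[, "alpha"]) + 1)
    R <- exp(LR)
    ll <- rep(0, nrow(G))
    for (s in 1:6) {
      idx <- which(oracle_stratum == s)
      Ns <- sum(counts[idx])
      if (Ns == 0) next
      Rs <- rowSums(R[, idx, drop = FALSE])
      nl <- colSums(counts[idx] * t(LR[, idx, drop = FALSE]))
      ll <- ll + nl + Ns * log(Ns) - Ns * log(Rs) - Ns
    }
    k <- which.max(ll)
    centre[free] <- G[k, free]
    best <- c(value = ll[k])
    attr(best, "par") <- centre
    width <- width * 2 / (npt - 1)   # keep the neighbouring grid interval
  }
  list(value = unname(best["value"]), par = attr(best, "par"))
}

# oracle likelihood-ratio statistic for dropping one term from the model
# containing `free` terms
oracle_lrt <- function(counts, term, free = c("c1", "c2", "alpha", "beta", "gamma")) {
  full <- oracle_grid_max(counts, free = free)
  red <- oracle_grid_max(counts, free = setdiff(free, term),
                         fixed = setNames(list(0), term))
  max(0, 2 * (full$value - red$value))
}
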