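# Independent reference implementations used as oracles. These are literal,
# loop-by-loop transcriptions of the published algorithms, kept deliberately
# slow and simple so they share no code with the package implementations.

# Regression ReliefF with exponential rank weighting, one iteration at a time.
# `draws` makes the sampled instance sequence explicit so the oracle and the
# package can be compared on identical draws.
ref_rrelieff <- function(X, y, k, sigma, draws) {
  n <- nrow(X); p <- ncol(X)
  rngs <- apply(X, 2, function(col) diff(range(col)))
  Xs <- X
  for (j in seq_len(p)) {
    if (rngs[j] > 0) Xs[, j] <- (X[, j] - min(X[, j])) / rngs[j]
    else Xs[, j] <- 0
  }
  yr <- diff(range(y))
  N_dC <- 0; N_dA <- numeric(p); N_dCdA <- numeric(p)
  for (it in seq_along(draws)) {
    i <- draws[it]
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(Xs[i, ] - Xs[j, ]))
    ord <- order(d, seq_len(n))
    nbr <- ord[ord != i][seq_len(k)]
    w <- exp(-(seq_len(k) / sigma)^2)
    w <- w / sum(w)
    for (r in seq_len(k)) {
      j <- nbr[r]
      dy <- abs(y[i] - y[j]) / yr
      N_dC <- N_dC + dy * w[r]
      for (a in seq_len(p)) {
        da <- abs(Xs[i, a] - Xs[j, a])
        N_dA[a] <- N_dA[a] + da * w[r]
        N_dCdA[a] <- N_dCdA[a] + dy * da * w[r]
      }
    }
  }
  m <- length(draws)
  W <- N_dCdA / N_dC - (N_dA - N_dCdA) / (m - N_dC)
  W[rngs == 0] <- 0
  W
}

# Univariate orthogonal-scores PLS, literal transcription: center, then per
# component w = X'y/||X'y||, t = Xw, p = X't/t't, q = y't/t't, deflate both.
ref_plsr_coef <- function(X, y, A) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  for (a in seq_len(A)) {
    w <- t(E) %*% f
    w <- w / sqrt(sum(w^2))
    tt <- E %*% w
    pp <- t(E) %*% tt / drop(t(tt) %*% tt)
    qq <- drop(t(f) %*% tt) / drop(t(tt) %*% tt)
    E <- E - tt %*% t(pp)
    f <- f - qq * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qq
  }
  B <- W %*% solve(t(P) %*% W) %*% q
  list(coef = drop(B), intercept = ym - drop(t(B) %*% xm))
}

# small deterministic spectra-like fixture: n smooth curves + planted signal
make_planted_fixture <- function(n, p, informative, noise_sd = 0.05,
                                 seed = 1) {
  set.seed(seed)
  grid <- seq_len(p)
  X <- t(vapply(seq_len(n), function(i) {
    base <- 5 + 2 * sin(grid / p * pi) * stats::rnorm(1, 1, 0.2)
    base + stats::rnorm(p, 0, 0.5)
  }, numeric(p)))
  latent <- stats::rnorm(n)
  X[, informative] <- X[, informative] + latent %o% rep(1, length(informative))
  y <- latent + stats::rnorm(n, 0, noise_sd)
  colnames(X) <- as.character(grid)
  list(X = X, y = y, latent = latent)
}

tiny_config <- function(weeks = c(6L, 9L), ...) {
  synthetic_config(n_accessions_ind = 3, n_accessions_trj = 2,
                   reps_per_accession = 2, extra_rep_accessions = 1,
                   weeks = weeks, vnir_step_nm = 20, swir_step_nm = 50,
                   n_missing_traits = 0, ...)
}
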