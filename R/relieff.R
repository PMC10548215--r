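#' RReliefF attribute weighting for regression
#'
#' The regression Relief estimator with exponential rank-based neighbour
#' weighting ("expRank"). For `m_iterations` instances drawn at random with
#' replacement, the `k_neighbors` nearest neighbours (Manhattan distance on
#' min-max-scaled attributes) contribute with weights
#' `exp(-(rank/sigma)^2)`, normalised to sum to one, to three accumulators:
#' the probability mass of a changed response `N_dC`, of a changed attribute
#' `N_dA[a]`, and of both `N_dCdA[a]`. The final weight of attribute `a` is
#'
#' `W[a] = N_dCdA[a] / N_dC - (N_dA[a] - N_dCdA[a]) / (m - N_dC)`
#'
#' where `m` is the total accumulated weight (the number of iterations, since
#' per-instance neighbour weights are normalised). Attribute and response
#' differences are absolute differences scaled by the attribute/response
#' range, so weights lie in `[-1, 1]`; a constant attribute scores exactly 0.
#'
#' Because sampling is with replacement from a finite set, each instance's
#' neighbourhood contribution is deterministic; the implementation accumulates
#' one contribution per distinct instance and weights it by its draw count,
#' which is algebraically identical to the per-iteration loop and much faster
#' when `m_iterations` is large (the default rule is 100 x n).
#'
#' @param X Numeric predictor matrix (rows = instances, columns = attributes;
#'   column names are wavelengths for spectral use).
#' @param y Numeric response vector.
#' @param k_neighbors Number of nearest neighbours, default 70 (capped at
#'   n - 1).
#' @param sigma Rank-weighting scale, default 20.
#' @param m_iterations Number of sampled instances; default `100 * nrow(X)`.
#' @param seed Integer seed for the instance draws.
#' @return A [selection_result()] with `scores` (one weight per column) and an
#'   empty selection (use [select_wplsr()]).
#' @export
rrelieff_rank <- function(X, y, k_neighbors = 70, sigma = 20,
                          m_iterations = 100 * nrow(X), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (max(y) == min(y)) stop("constant response: RReliefF undefined")
  k <- min(k_neighbors, n - 1L)
  if (n < k + 1) stop("need at least k_neighbors + 1 instances")

  # min-max scale attributes so per-attribute diffs lie in [0, 1]
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  span[const] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
  dy <- abs(outer(y, y, "-")) / (max(y) - min(y))

  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  w_rank <- exp(-(seq_len(k) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)

  draws <- with_seed(seed, sample.int(n, m_iterations, replace = TRUE))
  counts <- tabulate(draws, nbins = n)

  N_dC <- 0
  N_dA <- numeric(p)
  N_dCdA <- numeric(p)
  for (i in which(counts > 0)) {
    ord <- order(D[i, ], seq_len(n))      # deterministic tie-break by index
    nbr <- setdiff(ord, i)[seq_len(k)]
    dA <- abs(sweep(Xs[nbr, , drop = FALSE], 2, Xs[i, ], "-"))  # k x p
    wc <- counts[i] * w_rank
    dyi <- dy[i, nbr]
    N_dC <- N_dC + sum(wc * dyi)
    N_dA <- N_dA + drop(crossprod(dA, wc))
    N_dCdA <- N_dCdA + drop(crossprod(dA, wc * dyi))
  }
  m <- m_iterations
  W <- N_dCdA / N_dC - (N_dA - N_dCdA) / (m - N_dC)
  W[const] <- 0
  names(W) <- colnames(X) %||% as.character(seq_len(p))
  selection_result("rrelieff", W,
                   provenance = list(k_neighbors = k, sigma = sigma,
                                     m_iterations = m_iterations, seed = seed))
}
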