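#' Build an amino-acid substitution rate model
#'
#' Assembles a reversible 20-state continuous-time Markov model from an
#' empirical exchangeability matrix and stationary frequencies, rescaled to
#' one expected substitution per site at stationarity, with discrete-gamma
#' rate heterogeneity across sites.  The eigendecomposition of the rate
#' matrix is cached so transition matrices are cheap to evaluate during
#' likelihood optimization.
#'
#' `"JTT"` and `"Dayhoff"` use the empirical exchangeabilities and
#' frequencies distributed with the phangorn phylogenetics package;
#' `"Poisson"` is the equal-rates, equal-frequencies model whose distance
#' has a 20-state Jukes-Cantor closed form (used as an internal oracle).
#'
#' The K discrete gamma categories follow the standard equal-probability
#' construction: category k's rate is the mean of the gamma(alpha, alpha)
#' distribution over its probability-1/K slice, so the rates average
#' exactly 1.  `alpha = Inf` (or `K = 1`) disables rate heterogeneity.
#'
#' @param name `"JTT"`, `"Dayhoff"` or `"Poisson"`.
#' @param alpha Gamma shape parameter (> 0, or `Inf` for no
#'   heterogeneity).  Smaller values mean stronger among-site variation.
#' @param K Number of discrete gamma categories (>= 1); 4 is the
#'   conventional choice.
#' @return An object of class `rate_model` with fields `name`, `Q`, `pi`,
#'   `alpha`, `K`, `category_rates` and the cached eigensystem.
#' @export
build_rate_model <- function(name = "JTT", alpha = 1, K = 4L) {
  stopifnot(alpha > 0, K >= 1L)
  known <- c("JTT", "Dayhoff", "Poisson")
  if (!name %in% known) {
    stop("unknown rate model '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  if (name == "Poisson") {
    pi <- rep(1 / 20, 20)
    S <- matrix(1, 20, 20); diag(S) <- 0
  } else {
    dat <- get(paste0(".", name), envir = asNamespace("phangorn"))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- dat$Q
    S <- S + t(S)
    pi <- as.numeric(dat$bf)
    pi <- pi / sum(pi)
  }
  Q <- S * rep(pi, each = 20)      # Q_ij = S_ij * pi_j for i != j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu                      # one expected substitution per site
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  # symmetrize for a stable eigendecomposition of the reversible generator
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  rates <- gamma_category_rates(alpha, K)
  structure(list(name = name, Q = Q, pi = setNames(pi, AA_ORDER),
                 alpha = alpha, K = as.integer(K), category_rates = rates,
                 eig_values = eig$values,
                 eig_left = eig$vectors * (1 / sq),    # row-scaled
                 eig_right = t(eig$vectors * sq)),
            class = "rate_model")
}

# Means of the K equal-probability slices of gamma(alpha, rate = alpha);
# closed form via the incomplete-gamma identity, renormalized to mean 1.
gamma_category_rates <- function(alpha, K) {
  if (K == 1L || is.infinite(alpha)) return(rep(1, K))
  q <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  p <- pgamma(q, shape = alpha + 1, rate = alpha)
  r <- K * diff(p)
  r / mean(r)
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s, alpha = %s, K = %d categories\n",
              x$name, format(x$alpha), x$K))
  invisible(x)
}

#' Transition probability matrix of a rate model
#'
#' Evaluates `exp(Q * t * rate)` through the model's cached
#' eigendecomposition; entries are clipped to \[0, 1\] after numerical
#' roundoff.
#'
#' @param model A `rate_model`.
#' @param t Elapsed time in expected substitutions per site (>= 0).
#' @param rate Site-rate multiplier (one of the gamma category rates, or 1).
#' @return A 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "rate_model"), t >= 0, rate > 0)
  P <- model$eig_left %*% (exp(model$eig_values * t * rate) * model$eig_right)
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(model$Q)
  P
}

# Cross-tabulate the usable (no gap, no X) columns of a pairwise alignment
# into a 20x20 count matrix.  Errors distinguish an all-gap overlap from an
# all-ambiguous one.
alignment_pair_counts <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  gap <- a == "-" | b == "-"
  amb <- !gap & (a == "X" | b == "X")
  use <- !gap & !amb
  if (!any(use)) {
    if (all(gap)) stop("no usable columns: all columns contain a gap")
    stop("no usable columns: every ungapped column contains an ambiguous residue")
  }
  ia <- match(a[use], AA_ORDER)
  ib <- match(b[use], AA_ORDER)
  counts <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  tab <- table(factor(ia, levels = 1:20), factor(ib, levels = 1:20))
  counts[] <- as.numeric(tab)
  counts
}

# Log-likelihood of a pair-count matrix at distance t under the model,
# averaging transition probabilities over the gamma rate categories.
pair_loglik <- function(counts, model, t) {
  K <- model$K
  P <- 0
  for (r in model$category_rates) P <- P + transition_matrix(model, t, r)
  P <- P / K
  lp <- log(pmax(model$pi * P, 1e-300))   # pi_a * P_ab, row-weighted
  sum(counts * lp)
}

#' Maximum-likelihood pairwise distance
#'
#' Estimates the expected number of amino-acid substitutions per site
#' separating the two rows of a global alignment, under a reversible
#' empirical substitution model with discrete-gamma rate heterogeneity.
#' Columns containing a gap or an `X` in either row are excluded
#' (complete-column deletion).  The likelihood
#' `L(t) = prod_cols sum_k (1/K) pi_a P(a -> b | t r_k)` is maximized over
#' `[0, t_max]` by a coarse bracketing grid followed by Brent's method.
#'
#' @param aln A `pairwise_alignment`.
#' @param model A `rate_model`.
#' @param t_max Upper bound of the search interval (substitutions/site).
#'   Estimates at the boundary are flagged `converged = FALSE`.
#' @param tol Absolute convergence tolerance on t.
#' @return A list of class `distance_estimate`: `t_hat`, `log_likelihood`,
#'   `converged`, `n_sites`.
#' @export
ml_distance <- function(aln, model, t_max = 20, tol = 1e-6) {
  stopifnot(inherits(model, "rate_model"), t_max > 0, tol > 0)
  counts <- alignment_pair_counts(aln)
  n_sites <- as.integer(sum(counts))
  ll <- function(t) pair_loglik(counts, model, t)
  # coarse bracket: 0 plus a log-spaced grid up to t_max
  grid <- c(0, exp(seq(log(1e-4), log(t_max), length.out = 60)))
  vals <- vapply(grid, ll, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  if (lo == hi) hi <- min(t_max, lo + tol)
  opt <- optimize(ll, interval = c(lo, hi), maximum = TRUE,
                  tol = min(tol, 1e-8))
  t_hat <- opt$maximum
  best_ll <- opt$objective
  # optimize() never returns the exact endpoints; accept 0 if it wins
  if (ll(0) >= best_ll) { t_hat <- 0; best_ll <- ll(0) }
  converged <- t_hat < t_max - 10 * tol
  structure(list(t_hat = t_hat, log_likelihood = best_ll,
                 converged = converged, n_sites = n_sites),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("<distance_estimate> t_hat = %.6f (logL %.3f, %d sites%s)\n",
              x$t_hat, x$log_likelihood, x$n_sites,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
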