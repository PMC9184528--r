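#' Candidate aggregate copy-number states for a region group
#'
#' The HMM state space is a contiguous range of integer aggregate copy
#' numbers chosen from the reference copy number and the observed depth:
#' for every sample the trimmed-mean normalized depth (observed count over
#' expected diploid count, 10% trim) is converted to a copy-number estimate
#' `round(2 * o / e)`; the state range covers all estimates, plus or minus
#' one, is intersected with `[0, ref_cn + max_above_ref]` and always
#' contains `ref_cn`.
#'
#' @param ref_cn Reference copy number of the region group.
#' @param depth An `agg_depth` object.
#' @param nb_models Named list of [fit_nb()] models, one per sample.
#' @param max_above_ref Upper slack above the reference copy number
#'   (default 6).
#' @return Integer vector of states (strictly increasing, contiguous).
#' @export
select_states <- function(ref_cn, depth, nb_models, max_above_ref = 6) {
  keep <- depth$windows$keep
  gc <- depth$windows$gc_percent[keep]
  est <- vapply(depth$samples, function(s) {
    e <- nb_lookup(nb_models[[s]], gc)$mean
    round(2 * mean(depth$counts[keep, s] / pmax(e, 1e-9), trim = 0.1))
  }, numeric(1))
  lo <- max(0L, min(c(est - 1, ref_cn)))
  hi <- min(ref_cn + max_above_ref, max(c(est + 1, ref_cn)))
  as.integer(seq(lo, hi))
}

#' Transition matrix of the aggregate copy-number HMM
#'
#' Transitions between adjacent windows are parametrized by two per-boundary
#' jump parameters in `[0, 1/10]`: the probability of jumping from state `i`
#' to a larger state `j` is `a_up^(j-i)`, to a smaller state `k` is
#' `a_down^(i-k)`, and the diagonal takes the remaining mass, so larger
#' jumps are geometrically less likely.
#'
#' @param a_up,a_down Jump parameters, each in `[0, 0.1]`.
#' @param states Integer vector of states (used for its length and spacing).
#' @return A `K x K` row-stochastic matrix.
#' @export
transition_matrix <- function(a_up, a_down, states) {
  stopifnot(a_up >= 0, a_up <= 0.1, a_down >= 0, a_down <= 0.1)
  K <- length(states)
  d <- outer(states, states, function(i, j) j - i)
  A <- matrix(0, K, K)
  A[d > 0] <- a_up^d[d > 0]
  A[d < 0] <- a_down^(-d[d < 0])
  diag(A) <- 0
  rs <- rowSums(A)
  if (any(rs >= 1)) {
    warning("jump parameters leave no diagonal mass; off-diagonals rescaled")
    bad <- rs >= 1
    A[bad, ] <- A[bad, , drop = FALSE] * (1 - 1e-6) / rs[bad]
    rs <- rowSums(A)
  }
  diag(A) <- 1 - rs
  A
}

#' Emission probability of pooled depth given a copy-number state
#'
#' The background NB distribution describes diploid (copy-number 2) depth;
#' a state `c` scales its size parameter by `c/2` (leaving `prob`
#' unchanged), so the expected depth scales linearly with copy number. A
#' per-window scale factor `m` absorbs window-specific biases shared across
#' samples. Copy number 0 uses a zero-inflated floor distribution
#' (`0.99` point mass at zero plus `0.01` geometric with mean 1) so that a
#' handful of mismapped reads does not zero out the likelihood.
#'
#' @param o Observed counts (non-negative integers).
#' @param size,prob Background NB parameters for the window's GC content.
#' @param c Copy-number state (non-negative integer).
#' @param m Window scale factor (default 1).
#' @param log Return log probabilities?
#' @return Numeric vector of probabilities.
#' @export
emission_prob <- function(o, size, prob, c, m = 1, log = FALSE) {
  if (any(o < 0)) stop_paracn("negative depth observation")
  if (c == 0) {
    p <- 0.99 * (o == 0) + 0.01 * stats::dgeom(o, 0.5)
    return(if (log) base::log(p) else p)
  }
  stats::dnbinom(o, size = size * (c / 2) * m, prob = prob, log = log)
}

# log emission matrix for one sample: windows x states
emission_matrix <- function(o, size, prob, m, states) {
  W <- length(o)
  logb <- matrix(NA_real_, W, length(states))
  for (k in seq_along(states)) {
    logb[, k] <- emission_prob(o, size, prob, states[k], m, log = TRUE)
  }
  if (any(rowall <- apply(!is.finite(logb), 1, all))) {
    stop_paracn("all-zero emission row at window %d", which(rowall)[1])
  }
  logb
}

#' Forward-Backward pass for one sample
#'
#' Scaled (log-space) forward-backward recursions returning the per-window
#' state posteriors `gamma`, the expected transition counts `xi` for each
#' window boundary, and the log-likelihood of the sample's depth vector.
#'
#' @param logb `W x K` matrix of log emission probabilities.
#' @param A_list List of `W - 1` transition matrices (or a single matrix
#'   recycled for every boundary).
#' @param pi Initial state distribution (length `K`).
#' @return List with `gamma` (`W x K`, rows sum to 1), `xi`
#'   (`(W-1) x K x K` array), `loglik`.
#' @export
forward_backward <- function(logb, A_list, pi) {
  W <- nrow(logb); K <- ncol(logb)
  if (is.matrix(A_list)) A_list <- rep(list(A_list), max(W - 1, 0))
  logA <- lapply(A_list, log)
  la <- matrix(-Inf, W, K)
  lb <- matrix(0, W, K)
  la[1, ] <- log(pi) + logb[1, ]
  if (W > 1) {
    for (w in 2:W) {
      for (k in seq_len(K)) {
        la[w, k] <- logsumexp(la[w - 1, ] + logA[[w - 1]][, k]) + logb[w, k]
      }
    }
    for (w in (W - 1):1) {
      for (k in seq_len(K)) {
        lb[w, k] <- logsumexp(logA[[w]][k, ] + logb[w + 1, ] + lb[w + 1, ])
      }
    }
  }
  loglik <- logsumexp(la[W, ])
  lg <- la + lb - loglik
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, dim = c(max(W - 1, 0), K, K))
  if (W > 1) {
    for (w in seq_len(W - 1)) {
      lx <- outer(la[w, ], logb[w + 1, ] + lb[w + 1, ], "+") + logA[[w]] - loglik
      x <- exp(lx)
      xi[w, , ] <- x / sum(x)
    }
  }
  list(gamma = gamma, xi = xi, loglik = loglik)
}

#' Viterbi decoding
#'
#' @inheritParams forward_backward
#' @return Integer vector of state indices (length `W`). Ties resolve to
#'   the smaller state.
#' @export
viterbi <- function(logb, A_list, pi) {
  W <- nrow(logb); K <- ncol(logb)
  if (is.matrix(A_list)) A_list <- rep(list(A_list), max(W - 1, 0))
  logA <- lapply(A_list, log)
  delta <- log(pi) + logb[1, ]
  psi <- matrix(0L, W, K)
  if (W > 1) {
    for (w in 2:W) {
      cand <- delta + logA[[w - 1]]          # K x K: cand[i, k]
      psi[w, ] <- apply(cand, 2, which.max)
      delta <- cand[cbind(psi[w, ], seq_len(K))] + logb[w, ]
    }
  }
  path <- integer(W)
  path[W] <- which.max(delta)
  if (W > 1) for (w in (W - 1):1) path[w] <- psi[w + 1, path[w + 1]]
  path
}

#' Update per-window depth scale factors
#'
#' For every window, the shared scale factor `m_w` is re-estimated by
#' maximizing the posterior-weighted NB log-likelihood
#' `sum_s sum_c gamma[c,w,s] * log NB(o; size * (c/2) * m_w, prob)` with a
#' bounded 1-D search; windows with zero depth in all samples keep their
#' current value.
#'
#' @param counts `W x S` matrix of pooled counts (kept windows).
#' @param gamma `W x K x S` posterior array.
#' @param size_mat,prob_mat `W x S` matrices of per-sample NB parameters.
#' @param states Integer state vector.
#' @param m Current scale factors (length `W`).
#' @param bounds Search bounds (default `[0.1, 10]`).
#' @return Updated numeric vector `m`.
#' @export
update_scale <- function(counts, gamma, size_mat, prob_mat, states, m,
                         bounds = c(0.1, 10)) {
  W <- nrow(counts); S <- ncol(counts)
  pos <- which(states > 0)
  for (w in seq_len(W)) {
    if (all(counts[w, ] == 0)) next
    obj <- function(mw) {
      tot <- 0
      for (s in seq_len(S)) {
        ll <- stats::dnbinom(counts[w, s],
                             size = size_mat[w, s] * (states[pos] / 2) * mw,
                             prob = prob_mat[w, s], log = TRUE)
        tot <- tot + sum(gamma[w, pos, s] * ll)
      }
      -tot
    }
    m[w] <- stats::optimize(obj, interval = bounds)$minimum
  }
  m
}

#' Update transition parameters and the initial distribution
#'
#' Expected jump counts pooled over samples drive a maximum-likelihood fit
#' of the geometric jump parametrization at every window boundary: for each
#' boundary, `a_up` and `a_down` maximize
#' `sum_{i,j} xi[i,j] * log a_ij(a_up, a_down)` (larger jumps weigh their
#' log-parameter by the jump distance), solved by coordinate-wise bounded
#' search and clamped to `[1e-6, 0.1]`. The initial distribution is the
#' pooled first-window posterior with a floor of `1/(10 S)` per state,
#' renormalized.
#'
#' @param xi_sum `(W-1) x K x K` array of expected transition counts summed
#'   over samples.
#' @param gamma1 `K x S` matrix of first-window posteriors per sample.
#' @param states Integer state vector.
#' @param clamp Bounds for the jump parameters.
#' @return List with `pi`, `a_up`, `a_down` (vectors over boundaries).
#' @export
update_transitions_initial <- function(xi_sum, gamma1, states,
                                       clamp = c(1e-6, 0.1)) {
  K <- length(states)
  nb <- dim(xi_sum)[1]
  d <- outer(states, states, function(i, j) j - i)
  a_up <- numeric(nb); a_down <- numeric(nb)
  for (w in seq_len(nb)) {
    x <- xi_sum[w, , ]
    fit1 <- function(au, ad) {    # expected log-likelihood of boundary w
      A <- transition_matrix_unchecked(au, ad, d)
      sum(x[A > 0] * log(A[A > 0])) + if (any(A == 0 & x > 0)) -Inf else 0
    }
    best1d <- function(obj) {   # bounded search, endpoints included
      cand <- c(stats::optimize(obj, interval = clamp)$minimum, clamp)
      cand[which.min(vapply(cand, obj, numeric(1)))]
    }
    au <- 1e-5; ad <- 1e-5
    for (sweep in 1:2) {
      au <- best1d(function(a) -fit1(a, ad))
      ad <- best1d(function(a) -fit1(au, a))
    }
    a_up[w] <- min(max(au, clamp[1]), clamp[2])
    a_down[w] <- min(max(ad, clamp[1]), clamp[2])
  }
  S <- ncol(gamma1)
  pi <- rowSums(gamma1) / S
  pi <- pmax(pi, 1 / (10 * S))
  list(pi = pi / sum(pi), a_up = a_up, a_down = a_down)
}

# transition matrix without domain checks, from a precomputed distance matrix
transition_matrix_unchecked <- function(a_up, a_down, d) {
  A <- matrix(0, nrow(d), ncol(d))
  A[d > 0] <- a_up^d[d > 0]
  A[d < 0] <- a_down^(-d[d < 0])
  diag(A) <- 0
  rs <- rowSums(A)
  if (any(rs >= 1)) A[rs >= 1, ] <- A[rs >= 1, , drop = FALSE] * (1 - 1e-6) / rs[rs >= 1]
  diag(A) <- 1 - rowSums(A)
  A
}

# initial distribution: rare non-reference states with prior mass scaling
# as 1/S, remainder on the reference state
pi_init <- function(states, ref_cn, S) {
  K <- length(states)
  p <- rep(1 / S, K)
  p[states == ref_cn] <- max(1 - (K - 1) / S, 1 / S)
  p / sum(p)
}
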