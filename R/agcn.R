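#' Estimate aggregate copy-number profiles jointly for multiple samples
#'
#' Fits the multi-sample HMM to an aggregate depth matrix: per-sample
#' forward-backward passes alternate with joint updates of the window scale
#' factors, the per-boundary jump parameters and the initial distribution,
#' until the total log-likelihood (summed over samples) improves by less
#' than `tol` or `max_iter` iterations are reached. Each sample's profile
#' is then decoded with the Viterbi algorithm and cut into segments of
#' constant aggregate copy number; a segment's Phred quality is
#' `-10 log10(1 - min_w gamma)` over its windows for the decoded state,
#' capped at 100.
#'
#' @param depth An `agg_depth` object (use [filter_windows()] first).
#' @param nb_models Named list of [fit_nb()] background models, one per
#'   sample.
#' @param ref_cn Reference copy number (default: taken from `depth`).
#' @param states Optional explicit state vector; default [select_states()].
#' @param max_iter,tol Convergence controls (default 30 iterations, total
#'   log-likelihood improvement below 0.01).
#' @return An `agcn_fit` object with elements `profiles` (tibble: `sample`,
#'   `contig`, `start`, `end`, `agg_cn`, `quality`, `n_windows`), `states`,
#'   `params` (`pi`, `a_up`, `a_down`, `m`, plus the window layout),
#'   `gamma`, `paths`, `loglik_trace`, `converged`.
#' @export
run_multi_sample <- function(depth, nb_models, ref_cn = depth$ref_cn,
                             states = NULL, max_iter = 30, tol = 0.01) {
  S <- length(depth$samples)
  stopifnot(S >= 1)
  keep <- which(depth$windows$keep)
  win <- depth$windows[keep, , drop = FALSE]
  W <- nrow(win)
  counts <- depth$counts[keep, , drop = FALSE]
  if (is.null(states)) states <- select_states(ref_cn, depth, nb_models)
  K <- length(states)

  size_mat <- prob_mat <- matrix(NA_real_, W, S, dimnames = list(NULL, depth$samples))
  for (s in seq_len(S)) {
    nb <- nb_lookup(nb_models[[depth$samples[s]]], win$gc_percent)
    size_mat[, s] <- nb$size
    prob_mat[, s] <- nb$prob
  }

  pi <- pi_init(states, ref_cn, S)
  nb_bound <- max(W - 1, 0)
  a_up <- rep(1e-5, nb_bound)
  a_down <- rep(1e-5, nb_bound)
  m <- rep(1, W)

  gamma <- array(NA_real_, dim = c(W, K, S))
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    A_list <- lapply(seq_len(nb_bound), function(w) {
      transition_matrix(a_up[w], a_down[w], states)
    })
    xi_sum <- array(0, dim = c(nb_bound, K, K))
    gamma1 <- matrix(0, K, S)
    total <- 0
    for (s in seq_len(S)) {
      logb <- emission_matrix(counts[, s], size_mat[, s], prob_mat[, s], m, states)
      fb <- forward_backward(logb, A_list, pi)
      gamma[, , s] <- fb$gamma
      gamma1[, s] <- fb$gamma[1, ]
      xi_sum <- xi_sum + fb$xi
      total <- total + fb$loglik
    }
    trace <- c(trace, total)
    if (iter > 1 && total < trace[iter - 1] - 1e-6) {
      message(sprintf("total log-likelihood decreased at iteration %d (%.4f -> %.4f); clamped updates",
                      iter, trace[iter - 1], total))
    }
    if (iter > 1 && abs(total - trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (iter == max_iter) break
    if (K > 1) m <- update_scale(counts, gamma, size_mat, prob_mat, states, m)
    if (nb_bound > 0 && K > 1) {
      upd <- update_transitions_initial(xi_sum, gamma1, states)
      pi <- upd$pi; a_up <- upd$a_up; a_down <- upd$a_down
    }
  }
  if (!converged) warning("aggregate CN fit did not converge within max_iter")

  # a shared event has one breakpoint: within each cluster of elevated
  # boundaries keep only the one carrying the most pooled jump mass
  if (nb_bound > 0 && K > 1) {
    # neutral pass: uniform jump parameters, so the pooled jump mass that
    # places each consensus breakpoint is driven by the emissions alone and
    # not by the boundary the iterative fit happened to elevate first
    A_neutral <- transition_matrix(1e-3, 1e-3, states)
    d <- outer(states, states, function(i, j) j - i)
    up_mass <- down_mass <- matrix(0, nb_bound, S)
    for (s in seq_len(S)) {
      logb <- emission_matrix(counts[, s], size_mat[, s], prob_mat[, s], m, states)
      xi <- forward_backward(logb, A_neutral, pi)$xi
      for (w in seq_len(nb_bound)) {
        up_mass[w, s] <- sum(xi[w, , ][d > 0])
        down_mass[w, s] <- sum(xi[w, , ][d < 0])
      }
    }
    a_up <- consolidate_boundaries(a_up, up_mass)
    a_down <- consolidate_boundaries(a_down, down_mass)
    # re-estimate the kept boundaries under the consolidated sparsity
    # pattern: the full jump mass of each shared event now passes through
    # its consensus breakpoint
    kept_up <- which(a_up > 1e-4)
    kept_down <- which(a_down > 1e-4)
    for (it2 in 1:8) {
      A_list <- lapply(seq_len(nb_bound), function(w) {
        transition_matrix(a_up[w], a_down[w], states)
      })
      xi_sum <- array(0, dim = c(nb_bound, K, K))
      gamma1 <- matrix(0, K, S)
      for (s in seq_len(S)) {
        logb <- emission_matrix(counts[, s], size_mat[, s], prob_mat[, s], m, states)
        fb <- forward_backward(logb, A_list, pi)
        gamma[, , s] <- fb$gamma
        gamma1[, s] <- fb$gamma[1, ]
        xi_sum <- xi_sum + fb$xi
      }
      if (!length(kept_up) && !length(kept_down)) break
      upd <- update_transitions_initial(xi_sum, gamma1, states)
      delta <- max(abs(c(upd$a_up[kept_up] - a_up[kept_up],
                         upd$a_down[kept_down] - a_down[kept_down], 0)))
      a_up[kept_up] <- upd$a_up[kept_up]
      a_down[kept_down] <- upd$a_down[kept_down]
      pi <- upd$pi
      if (delta < 1e-3) break
    }
    # gamma corresponds to the final parameters
    A_list <- lapply(seq_len(nb_bound), function(w) {
      transition_matrix(a_up[w], a_down[w], states)
    })
    for (s in seq_len(S)) {
      logb <- emission_matrix(counts[, s], size_mat[, s], prob_mat[, s], m, states)
      gamma[, , s] <- forward_backward(logb, A_list, pi)$gamma
    }
  }

  A_list <- lapply(seq_len(nb_bound), function(w) {
    transition_matrix(a_up[w], a_down[w], states)
  })
  paths <- matrix(NA_integer_, W, S, dimnames = list(NULL, depth$samples))
  for (s in seq_len(S)) {
    logb <- emission_matrix(counts[, s], size_mat[, s], prob_mat[, s], m, states)
    paths[, s] <- viterbi(logb, A_list, pi)
  }
  profiles <- decode_profiles(paths, gamma, states, win, depth$samples)

  structure(list(
    profiles = profiles, states = states,
    params = list(pi = pi, a_up = a_up, a_down = a_down, m = m,
                  states = states, ref_cn = as.integer(ref_cn),
                  layout = win[, c("contig", "start", "end", "gc_percent")]),
    gamma = gamma, paths = paths, windows = win, counts = counts,
    loglik_trace = trace, converged = converged, samples = depth$samples
  ), class = "agcn_fit")
}

# winner-take-all within clusters of elevated jump boundaries: the joint
# fit spreads elevated jump parameters over neighbouring boundaries, but a
# shared deletion or duplication has a single breakpoint.  Within each
# cluster the consensus boundary maximizes the shared-breakpoint
# likelihood: the product over jumping samples of their (neutral-pass)
# boundary posteriors, i.e. the sum of log per-sample jump masses.  Other
# boundaries in the cluster return to the floor.
consolidate_boundaries <- function(a, mass, elevated = 1e-4, floor = 1e-6,
                                   gap = 2L, jumper_min = 0.5) {
  hot <- which(a > elevated)
  if (!length(hot)) return(a)
  cluster <- cumsum(c(TRUE, diff(hot) > gap))
  for (cl in unique(cluster)) {
    members <- hot[cluster == cl]
    rng <- min(members):max(members)
    sub <- mass[rng, , drop = FALSE]
    jumpers <- which(colSums(sub) > jumper_min)
    score <- if (length(jumpers)) {
      p <- sweep(sub[, jumpers, drop = FALSE], 2,
                 pmax(colSums(sub[, jumpers, drop = FALSE]), 1e-12), "/")
      rowSums(log(p + 1e-12))
    } else {
      rowSums(sub)
    }
    keep <- rng[which.max(score)]
    a[setdiff(members, keep)] <- floor
    a[keep] <- max(a[members])
  }
  a
}

# cut Viterbi paths into constant-CN segments with Phred qualities
decode_profiles <- function(paths, gamma, states, win, samples) {
  out <- list()
  for (s in seq_along(samples)) {
    path <- paths[, s]
    brk <- c(0L, which(diff(path) != 0), length(path))
    for (b in seq_len(length(brk) - 1)) {
      w <- (brk[b] + 1):brk[b + 1]
      st <- path[w[1]]
      minpost <- if (length(states) == 1) 1 else min(gamma[w, st, s])
      out[[length(out) + 1L]] <- tibble::tibble(
        sample = samples[s], contig = win$contig[w[1]],
        start = win$start[w[1]], end = win$end[w[length(w)]],
        agg_cn = states[st],
        quality = phred(1 - minpost),
        n_windows = length(w)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.agcn_fit <- function(x, ...) {
  cat(sprintf("<agcn_fit> %d samples, %d windows, states {%s}, %s after %d iteration(s)\n",
              length(x$samples), nrow(x$windows),
              paste(x$states, collapse = ","),
              if (x$converged) "converged" else "NOT converged",
              length(x$loglik_trace)))
  print(utils::head(x$profiles, 10))
  invisible(x)
}

#' Genotype a single sample with frozen HMM parameters
#'
#' Runs one forward-backward pass and a Viterbi decode for a new sample
#' using model parameters estimated previously on a cohort
#' ([run_multi_sample()]); no parameters are updated. The depth vector must
#' use exactly the window layout the parameters were fitted on.
#'
#' @param counts Integer vector of pooled depth over the kept windows, or a
#'   one-sample `agg_depth`.
#' @param nb_model The sample's [fit_nb()] background model.
#' @param params Frozen parameters (`fit$params` from [run_multi_sample()],
#'   or read back via [read_model_params()]).
#' @param sample Sample label for the output.
#' @return An `agcn_fit`-shaped list for the single sample (profiles, path,
#'   gamma, loglik).
#' @export
run_single_sample <- function(counts, nb_model, params, sample = "sample") {
  if (inherits(counts, "agg_depth")) {
    keep <- counts$windows$keep
    lay <- counts$windows[keep, c("contig", "start", "end")]
    if (!isTRUE(all.equal(as.data.frame(lay),
                          as.data.frame(params$layout[, c("contig", "start", "end")]),
                          check.attributes = FALSE))) {
      stop_paracn("window layout does not match the frozen model parameters")
    }
    counts <- counts$counts[keep, 1]
  }
  if (is.null(params$states) || !length(params$states)) {
    stop_paracn("empty model parameters")
  }
  W <- nrow(params$layout)
  if (length(counts) != W) {
    stop_paracn("depth vector has %d windows but the model expects %d",
                length(counts), W)
  }
  states <- params$states
  nb <- nb_lookup(nb_model, params$layout$gc_percent)
  logb <- emission_matrix(counts, nb$size, nb$prob, params$m, states)
  A_list <- lapply(seq_len(max(W - 1, 0)), function(w) {
    transition_matrix(params$a_up[w], params$a_down[w], states)
  })
  fb <- forward_backward(logb, A_list, params$pi)
  path <- viterbi(logb, A_list, params$pi)
  gamma <- array(fb$gamma, dim = c(W, length(states), 1))
  profiles <- decode_profiles(matrix(path, ncol = 1), gamma, states,
                              params$layout, sample)
  structure(list(profiles = profiles, states = states, params = params,
                 gamma = gamma, paths = matrix(path, ncol = 1,
                                               dimnames = list(NULL, sample)),
                 windows = params$layout,
                 counts = matrix(counts, ncol = 1,
                                 dimnames = list(NULL, sample)),
                 loglik_trace = fb$loglik,
                 converged = TRUE, samples = sample),
            class = "agcn_fit")
}
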