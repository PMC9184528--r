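#' Enumerate paralog-specific copy-number tuples
#'
#' For a region with reference copy number `c_r` (so `c_r / 2` distinct
#' copies) and a sample with aggregate copy number `c_s`, the possible
#' paralog-specific copy numbers are all integer tuples of length `c_r / 2`
#' with non-negative entries summing to `c_s`. There are
#' `choose(c_s + c_r/2 - 1, c_r/2 - 1)` of them; at `c_s = c_r` this equals
#' `choose(3/2 c_r - 1, c_r)`.
#'
#' @param c_r Reference copy number (even, at least 2).
#' @param c_s Aggregate copy number of the sample (non-negative).
#' @return List of integer vectors in lexicographic order.
#' @examples
#' enumerate_tuples(4, 4)   # (0,4) (1,3) (2,2) (3,1) (4,0)
#' @export
enumerate_tuples <- function(c_r, c_s) {
  if (c_r %% 2 != 0) stop_paracn("reference copy number must be even, got %d", c_r)
  stopifnot(c_s >= 0)
  m <- c_r / 2
  rec <- function(k, left) {
    if (k == 1) return(list(as.integer(left)))
    out <- list()
    for (v in 0:left) {
      for (rest in rec(k - 1, left - v)) {
        out[[length(out) + 1L]] <- c(as.integer(v), rest)
      }
    }
    out
  }
  rec(m, c_s)
}

#' Probability of observing each copy-specific allele at a PSV
#'
#' Under a paralog-specific copy-number tuple `t` and PSV reference-allele
#' frequencies `f`, a read covering the PSV comes from copy `j` with
#' probability `t_j / c_s`; a chromosome of copy `j` carries copy `j`'s
#' reference allele with probability `f_j` and otherwise one of the other
#' copies' distinct alleles, uniformly. Alleles shared between copies pool
#' their probability mass at the first copy carrying that allele. A
#' sequencing-error mass `eps` goes to the "other" category.
#'
#' @param t Integer tuple (length `m`, sum `c_s > 0`).
#' @param f Numeric vector of reference-allele frequencies (length `m`).
#' @param alleles Optional character vector of the copies' allele strings
#'   (length `m`); default: all distinct.
#' @param eps Sequencing-error probability (default 0.01).
#' @return Numeric vector of length `m + 1` (copy alleles then "other"),
#'   summing to 1.
#' @export
allele_prob <- function(t, f, alleles = NULL, eps = 0.01) {
  m <- length(t)
  stopifnot(length(f) == m)
  c_s <- sum(t)
  if (c_s == 0) stop_paracn("allele probabilities undefined for aggregate CN 0")
  if (is.null(alleles)) alleles <- as.character(seq_len(m))
  distinct <- unique(alleles)
  # per-copy distribution over distinct allele strings
  p_str <- stats::setNames(numeric(length(distinct)), distinct)
  for (j in seq_len(m)) {
    if (t[j] == 0) next
    wj <- t[j] / c_s
    p_str[alleles[j]] <- p_str[alleles[j]] + wj * f[j]
    alt <- setdiff(distinct, alleles[j])
    if (length(alt)) {
      p_str[alt] <- p_str[alt] + wj * (1 - f[j]) / length(alt)
    } else {
      p_str[alleles[j]] <- p_str[alleles[j]] + wj * (1 - f[j])
    }
  }
  out <- numeric(m + 1)
  first <- !duplicated(alleles)
  out[seq_len(m)][first] <- p_str[alleles[first]] * (1 - eps)
  out[m + 1] <- eps
  out
}

# long counts tibble (sample, psv, allele in 0..m [0 = other], count)
# -> array [psv, allele(m+1), sample]
counts_array <- function(counts, m, samples = sort(unique(counts$sample)),
                         psvs = sort(unique(counts$psv))) {
  arr <- array(0, dim = c(length(psvs), m + 1, length(samples)),
               dimnames = list(psvs, c(seq_len(m), "other"), samples))
  slot <- ifelse(counts$allele == 0, m + 1, counts$allele)
  idx <- cbind(match(counts$psv, psvs), slot, match(counts$sample, samples))
  ok <- !is.na(idx[, 3]) & !is.na(idx[, 1])
  arr[idx[ok, , drop = FALSE]] <- counts$count[ok]
  arr
}

# integer compositions of `total` over k parts (rows of a matrix)
compositions <- function(total, k) {
  do.call(rbind, enumerate_tuples(2L * k, total))
}

# distribution over allele-count compositions of the c_s chromosomes: each
# chromosome of copy j carries copy j's allele with probability f[j] and
# otherwise one of the other distinct alleles uniformly.  This latent
# carriage is what quantizes per-sample allele fractions; the read-level
# marginal of this distribution is allele_prob().
carriage_weights <- function(t, f, alleles, comp) {
  d <- unique(alleles)
  nd <- length(d)
  keys <- apply(comp, 1, paste, collapse = ",")
  w <- stats::setNames(numeric(nrow(comp)), keys)
  cur <- stats::setNames(1, paste(rep(0L, nd), collapse = ","))
  for (j in seq_along(t)) {
    if (t[j] == 0) next
    pj <- rep((1 - f[j]) / max(nd - 1, 1), nd)
    names(pj) <- d
    pj[alleles[j]] <- if (nd == 1) 1 else f[j]
    sub <- compositions(t[j], nd)
    probs <- apply(sub, 1, function(g) stats::dmultinom(g, prob = pj))
    nxt <- numeric(0)
    for (ci in seq_along(cur)) {
      base <- as.integer(strsplit(names(cur)[ci], ",")[[1]])
      for (gi in seq_len(nrow(sub))) {
        key <- paste(base + sub[gi, ], collapse = ",")
        prev <- nxt[key]
        nxt[key] <- (if (is.na(prev)) 0 else prev) + cur[ci] * probs[gi]
      }
    }
    cur <- nxt
  }
  w[names(cur)] <- cur
  w
}

# log P(counts | t, f) for every sample, marginalized over the latent
# chromosome carriage; cv is an S x (m+1) count matrix (copy slots, then
# "other"), reads follow a multinomial with error mass eps on "other"
psv_loglik_samples <- function(cv, t, f, alleles, eps) {
  m <- length(t)
  c_s <- sum(t)
  d <- unique(alleles)
  comp <- compositions(c_s, length(d))
  w <- carriage_weights(t, f, alleles, comp)
  keep <- w > 1e-300
  comp <- comp[keep, , drop = FALSE]
  w <- w[keep]
  slot_of <- match(alleles, d)
  first <- !duplicated(alleles)
  lp <- matrix(log(1e-300), nrow(comp), m + 1)
  for (k in seq_len(m)) {
    if (!first[k]) next
    lp[, k] <- log(pmax((1 - eps) * comp[, slot_of[k]] / c_s, 1e-300))
  }
  lp[, m + 1] <- log(eps)
  scores <- sweep(cv %*% t(lp), 2, log(w), "+")   # S x compositions
  apply(scores, 1, logsumexp)
}

#' Jointly estimate PSV allele frequencies and paralog copy numbers by EM
#'
#' Runs expectation-maximization over the samples whose aggregate copy
#' number equals the reference copy number `c_r`: the per-sample
#' paralog-specific tuples are the hidden variables (uniform prior over
#' [enumerate_tuples()]) and the PSV reference-allele frequency matrix `f`
#' is the unknown parameter. The E-step computes tuple posteriors from the
#' multinomial likelihood of the allele counts under [allele_prob()],
#' independently across PSVs; the M-step updates every `f[v, k]` by bounded
#' 1-D maximization of the expected complete-data log-likelihood
#' (coordinate ascent, updates accepted only when they improve the
#' objective, so the observed-data log-likelihood is non-decreasing).
#' Restarts with randomized initial `f` guard against local optima.
#'
#' Loci with `c_r > max_ref_cn`, more than `max_tuples` tuples, or fewer
#' than `min_samples` eligible samples are skipped (the returned object
#' carries the skip reason).
#'
#' @param counts Long tibble of PSV allele counts for the eligible samples:
#'   columns `sample`, `psv`, `allele` (1-based copy index, 0 = other) and
#'   `count`.
#' @param c_r Reference copy number.
#' @param min_samples Minimum eligible samples (default 50).
#' @param alleles Optional `V x m` character matrix of allele strings (for
#'   PSVs whose alleles are shared between copies).
#' @param eps Sequencing-error mass (default 0.01).
#' @param max_iter,tol EM controls (default 100 iterations, observed
#'   log-likelihood improvement below 1e-3).
#' @param even_prior Prior weight on the even tuple split (default 0.5,
#'   remainder uniform). The likelihood alone cannot distinguish "all
#'   samples at the reference split with marker-like `f`" from "all
#'   samples concentrated on one copy with `f` near 0.5"; the
#'   reference-biased prior resolves this toward the biologically expected
#'   mode, in line with the reference-biased initial distribution of the
#'   copy-number HMM.
#' @param n_restarts Randomized restarts in addition to the `f = 0.9`
#'   start (default 5).
#' @param seed Seed for the restart draws.
#' @param max_ref_cn,max_tuples Skip thresholds (defaults 8 and 500).
#' @param reliable_min_f Reliability threshold on `min_k f[v,k]`
#'   (default 0.95).
#' @return A `pscn_fit`: list with `f` (tibble `psv`, `copy`, `f`),
#'   `f_mat`, `reliable`, `tuples`, `posteriors` (samples x tuples),
#'   `loglik_trace`, `c_r`, `n_samples`, `skip` (`NULL` or the reason).
#' @export
em_fit <- function(counts, c_r, min_samples = 50, alleles = NULL, eps = 0.01,
                   max_iter = 100, tol = 1e-3, even_prior = 0.5,
                   n_restarts = 5, seed = 1,
                   max_ref_cn = 8, max_tuples = 500, reliable_min_f = 0.95) {
  skip <- function(reason) {
    structure(list(f = NULL, f_mat = NULL, reliable = NULL, tuples = NULL,
                   posteriors = NULL, loglik_trace = numeric(0), c_r = c_r,
                   n_samples = length(unique(counts$sample)), skip = reason),
              class = "pscn_fit")
  }
  if (c_r > max_ref_cn) return(skip("ref_cn>8"))
  tuples <- enumerate_tuples(c_r, c_r)
  if (length(tuples) > max_tuples) return(skip("tuples>500"))
  samples <- sort(unique(counts$sample))
  if (length(samples) < min_samples) return(skip("too_few_ref_samples"))

  m <- c_r / 2
  psvs <- sort(unique(counts$psv))
  V <- length(psvs); S <- length(samples); TT <- length(tuples)
  arr <- counts_array(counts, m, samples, psvs)
  prior <- rep(1, TT)
  even <- which(vapply(tuples, function(t) all(t == c_r / m), logical(1)))
  if (length(even) == 1 && TT > 1) {
    prior[] <- (1 - even_prior) / (TT - 1)
    prior[even] <- even_prior
  }
  prior <- prior / sum(prior)
  log_prior <- log(prior)
  if (is.null(alleles)) {
    alleles <- matrix(rep(as.character(seq_len(m)), each = V), V, m)
  }

  run_em <- function(f0) {
    f <- f0
    trace <- numeric(0)
    post <- NULL
    cvs <- lapply(seq_len(V), function(v) t(matrix(arr[v, , ], m + 1, S)))
    for (iter in seq_len(max_iter)) {
      # E-step: per-sample log-likelihood of each tuple
      ll <- matrix(0, S, TT)
      for (v in seq_len(V)) {
        for (ti in seq_len(TT)) {
          ll[, ti] <- ll[, ti] +
            psv_loglik_samples(cvs[[v]], tuples[[ti]], f[v, ], alleles[v, ], eps)
        }
      }
      ll <- sweep(ll, 2, log_prior, "+")
      obs <- sum(apply(ll, 1, logsumexp))
      trace <- c(trace, obs)
      post <- t(apply(ll, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
      if (iter > 1 && trace[iter] - trace[iter - 1] < tol) break
      # M-step: coordinate ascent on f, expected complete-data log-likelihood
      for (v in seq_len(V)) {
        for (k in seq_len(m)) {
          cur <- f[v, k]
          qfun <- function(fk) {
            fv <- f[v, ]; fv[k] <- fk
            sum(vapply(seq_len(TT), function(ti) {
              sum(post[, ti] *
                    psv_loglik_samples(cvs[[v]], tuples[[ti]], fv, alleles[v, ], eps))
            }, numeric(1)))
          }
          opt <- stats::optimize(function(x) -qfun(x), interval = c(0, 1))
          if (qfun(opt$minimum) > qfun(cur)) f[v, k] <- opt$minimum
        }
      }
    }
    list(f = f, trace = trace, post = post)
  }

  starts <- c(list(matrix(0.9, V, m)),
              withr::with_seed(seed, lapply(seq_len(n_restarts), function(i) {
                matrix(stats::runif(V * m, 0.5, 1), V, m)
              })))
  runs <- lapply(starts, run_em)
  best <- runs[[which.max(vapply(runs, function(r) utils::tail(r$trace, 1), numeric(1)))]]

  f_mat <- best$f
  dimnames(f_mat) <- list(psvs, seq_len(m))
  reliable <- apply(f_mat, 1, min) >= reliable_min_f
  post <- best$post
  dimnames(post) <- list(samples, vapply(tuples, tuple_str, character(1)))
  structure(list(
    f = tidyr::pivot_longer(
      tibble::as_tibble(f_mat, rownames = "psv"),
      -"psv", names_to = "copy", values_to = "f") |>
      dplyr::mutate(copy = as.integer(.data$copy)),
    f_mat = f_mat, reliable = reliable, alleles = alleles,
    tuples = tuples, posteriors = post, loglik_trace = best$trace,
    eps = eps, c_r = as.integer(c_r), n_samples = S, skip = NULL
  ), class = "pscn_fit")
}

#' @export
print.pscn_fit <- function(x, ...) {
  if (!is.null(x$skip)) {
    cat(sprintf("<pscn_fit> skipped: %s (c_r=%d, %d samples)\n",
                x$skip, x$c_r, x$n_samples))
  } else {
    cat(sprintf("<pscn_fit> c_r=%d, %d samples, %d PSVs (%d reliable), loglik %.2f after %d EM iteration(s)\n",
                x$c_r, x$n_samples, nrow(x$f_mat), sum(x$reliable),
                utils::tail(x$loglik_trace, 1), length(x$loglik_trace)))
  }
  invisible(x)
}

#' Classify PSVs as reliable copy markers
#'
#' A PSV is reliable when the population frequency of its reference allele
#' is close to 1 on every copy: `min_k f[v, k] >= threshold` (default
#' 0.95). Only reliable PSVs are used when genotyping individual samples.
#'
#' @param f_v Numeric vector (one PSV's frequencies across copies) or a
#'   `V x m` matrix.
#' @param threshold Reliability threshold (default 0.95; a PSV at exactly
#'   0.95 is reliable).
#' @return Logical (vector if `f_v` is a matrix).
#' @export
classify_reliable <- function(f_v, threshold = 0.95) {
  if (is.matrix(f_v)) return(apply(f_v, 1, min) >= threshold)
  min(f_v) >= threshold
}

#' Genotype paralog-specific copy number for individual samples
#'
#' Runs the E-step of the EM model for each sample separately, using only
#' reliable PSVs and the frozen frequency matrix: the posterior over
#' [enumerate_tuples()]`(c_r, c_s)` is computed from the sample's allele
#' counts, with a prior placing weight `even_prior` on the even split when
#' `c_s = c_r` (remainder uniform) and uniform otherwise. Samples at loci
#' with `c_r > 8` or more than 500 tuples, or with fewer than
#' `min_reliable` covered reliable PSVs, are skipped with a reason.
#'
#' @param counts Long tibble of PSV allele counts (`sample`, `psv`,
#'   `allele`, `count`) for the samples to genotype.
#' @param agg_cn Tibble with columns `sample`, `agg_cn` and optionally
#'   `quality` (calls below `min_agg_quality` are skipped).
#' @param fit A fitted `pscn_fit` (for `f_mat`, `reliable`, `c_r`).
#' @param min_reliable Minimum number of covered reliable PSVs (default 3).
#' @param even_prior Prior weight on the even split at `c_s = c_r`
#'   (default 0.5).
#' @param min_agg_quality Minimum aggregate-CN Phred quality (default 20).
#' @param max_ref_cn,max_tuples Skip thresholds (defaults 8 and 500).
#' @return A tibble with one row per sample and copy: `sample`, `copy`,
#'   `paralog_cn`, `quality` (Phred of the marginal posterior), `tuple`,
#'   `posterior`, `agg_cn`, `skip` (`NA` for called samples; skipped
#'   samples get one row with the reason).
#' @export
genotype_sample <- function(counts, agg_cn, fit, min_reliable = 3,
                            even_prior = 0.5, min_agg_quality = 20,
                            max_ref_cn = 8, max_tuples = 500) {
  c_r <- fit$c_r
  m <- c_r / 2
  skipped <- function(s, cs, reason) {
    tibble::tibble(sample = s, copy = NA_integer_, paralog_cn = NA_integer_,
                   quality = NA_real_, tuple = NA_character_,
                   posterior = NA_real_, agg_cn = cs, skip = reason)
  }
  out <- list()
  for (i in seq_len(nrow(agg_cn))) {
    s <- agg_cn$sample[i]
    c_s <- agg_cn$agg_cn[i]
    q <- if ("quality" %in% names(agg_cn)) agg_cn$quality[i] else Inf
    if (!is.na(q) && q < min_agg_quality) {
      message(sprintf("sample %s: aggregate CN quality %.1f below %g; not genotyped",
                      s, q, min_agg_quality))
      next
    }
    if (c_r > max_ref_cn) { out[[length(out) + 1]] <- skipped(s, c_s, "ref_cn>8"); next }
    tuples <- enumerate_tuples(c_r, c_s)
    if (length(tuples) > max_tuples) { out[[length(out) + 1]] <- skipped(s, c_s, "tuples>500"); next }
    if (is.null(fit$f_mat)) { out[[length(out) + 1]] <- skipped(s, c_s, fit$skip %||% "too_few_ref_samples"); next }
    if (c_s == 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        sample = s, copy = seq_len(m), paralog_cn = 0L, quality = phred(0),
        tuple = tuple_str(rep(0L, m)), posterior = 1, agg_cn = c_s,
        skip = NA_character_)
      next
    }
    rel <- which(fit$reliable)
    cnt <- counts[counts$sample == s & counts$psv %in% rownames(fit$f_mat)[rel], , drop = FALSE]
    covered <- unique(cnt$psv[cnt$count > 0])
    if (length(covered) < min_reliable) {
      out[[length(out) + 1]] <- skipped(s, c_s, "too_few_reliable_psvs"); next
    }
    arr <- counts_array(cnt, m, samples = s, psvs = covered)
    vrows <- match(covered, rownames(fit$f_mat))
    prior <- rep(1, length(tuples))
    if (c_s == c_r) {
      even <- which(vapply(tuples, function(t) all(t == c_s / m), logical(1)))
      if (length(even) == 1 && length(tuples) > 1) {
        prior[] <- (1 - even_prior) / (length(tuples) - 1)
        prior[even] <- even_prior
      }
    }
    prior <- prior / sum(prior)
    ll <- log(prior)
    for (vi in seq_along(covered)) {
      v <- vrows[vi]
      cv <- matrix(arr[vi, , 1], 1, m + 1)
      for (ti in seq_along(tuples)) {
        ll[ti] <- ll[ti] + psv_loglik_samples(cv, tuples[[ti]], fit$f_mat[v, ],
                                              fit$alleles[v, ], fit$eps)
      }
    }
    post <- exp(ll - logsumexp(ll))
    best <- which.max(post)
    tmat <- do.call(rbind, tuples)
    qual <- vapply(seq_len(m), function(k) {
      phred(1 - sum(post[tmat[, k] == tmat[best, k]]))
    }, numeric(1))
    out[[length(out) + 1]] <- tibble::tibble(
      sample = s, copy = seq_len(m), paralog_cn = as.integer(tmat[best, ]),
      quality = qual, tuple = tuple_str(tmat[best, ]),
      posterior = post[best], agg_cn = c_s, skip = NA_character_)
  }
  dplyr::bind_rows(out)
}
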