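#' Estimate haploid paralog copy-number frequencies from diploid calls
#'
#' Population frequencies of paralog-specific copy number on a single
#' chromosome are deconvolved from the observed diploid calls under a
#' random-mating model: each diploid tuple is the sum of two independent
#' haploid draws. The mixture weights are fitted by EM over the observed
#' high-quality diploid calls; the observed-data log-likelihood is
#' non-decreasing at every iteration. The support is the set of haploid
#' tuples appearing in at least one decomposition of an observed diploid
#' tuple.
#'
#' @param calls Tibble of diploid calls with a `tuple` column (strings like
#'   `"2,2"`, see [tuple_str()]) and optionally `quality` (calls below
#'   `min_quality` are dropped).
#' @param min_calls Minimum number of usable calls (default 20).
#' @param min_quality Phred threshold on `quality` (default 20).
#' @param max_iter,tol EM controls.
#' @return A `haploid_freqs` object: tibble with columns `tuple` (string)
#'   and `prob`, plus attributes `loglik_trace` and `n_calls`.
#' @export
fit_haploid_freqs <- function(calls, min_calls = 20, min_quality = 20,
                              max_iter = 200, tol = 1e-6) {
  if ("quality" %in% names(calls)) {
    calls <- calls[!is.na(calls$quality) & calls$quality >= min_quality, , drop = FALSE]
  }
  if (nrow(calls) < min_calls) {
    stop_paracn("only %d high-quality diploid calls; need at least %d",
                nrow(calls), min_calls)
  }
  obs <- table(calls$tuple)
  dip <- tuple_parse(names(obs))
  n_d <- as.numeric(obs)

  # support: haploids occurring in some decomposition of an observed diploid
  decos <- lapply(dip, decompositions)
  hap_all <- unique(unlist(lapply(decos, function(d) {
    c(vapply(d, function(p) tuple_str(p[[1]]), character(1)),
      vapply(d, function(p) tuple_str(p[[2]]), character(1)))
  })))
  hap_all <- hap_all[order(hap_all)]          # lexicographic, deterministic
  H <- length(hap_all)
  # initialize from the most balanced split of each observed diploid (the
  # random-mating-friendly basin), with a uniform floor so no support tuple
  # starts at zero; a uniform start can stall at a symmetric stationary point
  q <- rep(0.1 / H, H)
  for (di in seq_along(dip)) {
    dd <- decompositions(dip[[di]])
    bal <- vapply(dd, function(p) sum(abs(p[[1]] - p[[2]])), numeric(1))
    best <- dd[bal == min(bal)]
    for (p in best) {
      i1 <- match(tuple_str(p[[1]]), hap_all)
      i2 <- match(tuple_str(p[[2]]), hap_all)
      q[i1] <- q[i1] + 0.45 * n_d[di] / (sum(n_d) * length(best))
      q[i2] <- q[i2] + 0.45 * n_d[di] / (sum(n_d) * length(best))
    }
  }
  q <- q / sum(q)

  # index decompositions once: for each diploid, pairs (i, j) of haploid ids
  pair_idx <- lapply(decos, function(d) {
    i1 <- match(vapply(d, function(p) tuple_str(p[[1]]), character(1)), hap_all)
    i2 <- match(vapply(d, function(p) tuple_str(p[[2]]), character(1)), hap_all)
    cbind(i1, i2, mult = ifelse(i1 == i2, 1, 2))  # ordered pairs collapsed
  })

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    exp_cnt <- numeric(H)
    ll <- 0
    for (di in seq_along(dip)) {
      idx <- pair_idx[[di]]
      wt <- q[idx[, 1]] * q[idx[, 2]] * idx[, 3]
      tot <- sum(wt)
      if (tot <= 0) { wt <- rep(1 / nrow(idx), nrow(idx)); tot <- 1e-300 }
      ll <- ll + n_d[di] * log(tot)
      r <- wt / sum(wt)
      for (p in seq_len(nrow(idx))) {
        exp_cnt[idx[p, 1]] <- exp_cnt[idx[p, 1]] + n_d[di] * r[p]
        exp_cnt[idx[p, 2]] <- exp_cnt[idx[p, 2]] + n_d[di] * r[p]
      }
    }
    trace <- c(trace, ll)
    q_new <- exp_cnt / sum(exp_cnt)
    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) break
    q <- q_new
  }
  out <- tibble::tibble(tuple = hap_all, prob = q)
  structure(out, class = c("haploid_freqs", class(out)),
            loglik_trace = trace, n_calls = sum(n_d))
}

# all unordered decompositions of a diploid tuple into two haploid tuples
decompositions <- function(d) {
  m <- length(d)
  grids <- lapply(d, function(x) 0:x)
  g <- as.matrix(expand.grid(grids))
  out <- list()
  seen <- character(0)
  for (r in seq_len(nrow(g))) {
    h1 <- as.integer(g[r, ])
    h2 <- as.integer(d - h1)
    key <- paste(sort(c(tuple_str(h1), tuple_str(h2))), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(h1, h2)
  }
  out
}

#' @export
print.haploid_freqs <- function(x, ...) {
  cat(sprintf("<haploid_freqs> %d support tuples from %d diploid calls\n",
              nrow(x), attr(x, "n_calls")))
  print(tibble::as_tibble(x)[order(-x$prob), ], ...)
  invisible(x)
}

#' Probability that a child's paralog copy number is Mendelian-consistent
#'
#' Each parent's diploid tuple is decomposed into pairs of haploid tuples,
#' weighted by the population haploid frequencies conditioned on the
#' parent's call (Bayes); each parent transmits either haploid of its pair
#' with probability 1/2. The reported probability is the total transmission
#' mass producing exactly the child's tuple. A trio is discordant when this
#' probability falls below `threshold` (default 0.01).
#'
#' @param child,mother,father Tuple strings (e.g. `"2,2"`) or integer
#'   vectors, all on the same locus and copy order.
#' @param freqs A `haploid_freqs` object.
#' @param threshold Discordance threshold (default 0.01; a probability of
#'   exactly 0.01 is concordant).
#' @return A one-row tibble: `probability`, `concordant`.
#' @export
trio_probability <- function(child, mother, father, freqs, threshold = 0.01) {
  as_tuple <- function(x) if (is.character(x)) tuple_parse(x)[[1]] else as.integer(x)
  ch <- as_tuple(child); mo <- as_tuple(mother); fa <- as_tuple(father)
  if (length(unique(c(length(ch), length(mo), length(fa)))) != 1) {
    stop_paracn("trio tuples have different numbers of copies")
  }
  qmap <- stats::setNames(freqs$prob, freqs$tuple)
  hap_q <- function(h) {
    p <- qmap[tuple_str(h)]
    if (is.na(p)) 0 else p
  }
  parent_decomp <- function(d) {
    dec <- decompositions(d)
    wt <- vapply(dec, function(p) {
      w <- hap_q(p[[1]]) * hap_q(p[[2]])
      if (!identical(p[[1]], p[[2]])) w <- 2 * w   # ordered pairs collapsed
      w
    }, numeric(1))
    if (sum(wt) <= 0) wt <- rep(1 / length(dec), length(dec))
    list(dec = dec, wt = wt / sum(wt))
  }
  dm <- parent_decomp(mo)
  df <- parent_decomp(fa)
  p <- 0
  for (i in seq_along(dm$dec)) {
    for (j in seq_along(df$dec)) {
      trans <- 0
      for (a in dm$dec[[i]]) {
        for (b in df$dec[[j]]) {
          if (all(a + b == ch)) trans <- trans + 0.25
        }
      }
      p <- p + dm$wt[i] * df$wt[j] * trans
    }
  }
  tibble::tibble(probability = p, concordant = p >= threshold)
}

#' Check Mendelian concordance for a set of trios
#'
#' @param ped Tibble with columns `child`, `mother`, `father` (sample ids).
#' @param calls Tibble of paralog CN calls with columns `sample`, `tuple`
#'   and optionally `quality` (per-sample minimum over copies is compared
#'   to `min_quality`).
#' @param freqs A `haploid_freqs` object (default: fitted from the parents'
#'   calls).
#' @param min_quality Phred threshold; trios with any low-quality member
#'   are reported with `NA` probability.
#' @param threshold Discordance threshold (default 0.01).
#' @return `ped` with `probability` and `concordant` columns.
#' @export
trio_report <- function(ped, calls, freqs = NULL, min_quality = 20,
                        threshold = 0.01) {
  calls <- dplyr::summarise(
    dplyr::group_by(calls, .data$sample),
    tuple = .data$tuple[1],
    quality = if ("quality" %in% names(calls)) min(.data$quality) else Inf,
    .groups = "drop")
  if (is.null(freqs)) {
    parents <- calls[calls$sample %in% c(ped$mother, ped$father), , drop = FALSE]
    freqs <- fit_haploid_freqs(parents, min_quality = min_quality)
  }
  get <- function(s) calls[match(s, calls$sample), , drop = FALSE]
  res <- purrr::pmap(ped, function(child, mother, father, ...) {
    tr <- dplyr::bind_rows(get(child), get(mother), get(father))
    if (any(is.na(tr$tuple)) || any(tr$quality < min_quality)) {
      return(tibble::tibble(probability = NA_real_, concordant = NA))
    }
    trio_probability(tr$tuple[1], tr$tuple[2], tr$tuple[3], freqs, threshold)
  })
  dplyr::bind_cols(ped, dplyr::bind_rows(res))
}
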