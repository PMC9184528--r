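# Independent brute-force oracles used across the suite.

# Exhaustive path-sum HMM oracle: posteriors, log-likelihood and the best
# path by direct enumeration of all K^W state paths.
enumerate_hmm <- function(logb, A_list, pi) {
  W <- nrow(logb); K <- ncol(logb)
  if (is.matrix(A_list)) A_list <- rep(list(A_list), max(W - 1, 0))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), W)))
  lp <- apply(paths, 1, function(s) {
    v <- log(pi[s[1]]) + logb[1, s[1]]
    if (W > 1) for (w in 2:W) {
      v <- v + log(A_list[[w - 1]][s[w - 1], s[w]]) + logb[w, s[w]]
    }
    v
  })
  M <- max(lp)
  loglik <- M + log(sum(exp(lp - M)))
  gamma <- matrix(0, W, K)
  for (w in seq_len(W)) for (k in seq_len(K)) {
    sel <- paths[, w] == k
    if (any(sel)) gamma[w, k] <- exp(log(sum(exp(lp[sel] - M))) + M - loglik)
  }
  list(gamma = gamma, loglik = loglik, best = paths[which.max(lp), ])
}

# random HMM instance generator for the oracle suite
random_hmm_instance <- function(K, W) {
  pi <- as.vector(stats::rgamma(K, 1) + 0.1); pi <- pi / sum(pi)
  A <- matrix(stats::rgamma(K * K, 1) + 0.05, K, K)
  A <- A / rowSums(A)
  logb <- matrix(log(stats::runif(W * K, 0.05, 1)), W, K)
  list(pi = pi, A = A, logb = logb)
}

# connected components of the duplication-overlap graph, brute force
overlap_components <- function(dups) {
  n <- nrow(dups)
  iv <- rbind(
    data.frame(contig = dups$chrom1, s = dups$start1, e = dups$end1, rec = seq_len(n)),
    data.frame(contig = dups$chrom2, s = dups$start2, e = dups$end2, rec = seq_len(n))
  )
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(iv))) for (j in seq_len(nrow(iv))) {
    if (iv$contig[i] == iv$contig[j] && iv$s[i] < iv$e[j] && iv$s[j] < iv$e[i]) {
      adj[iv$rec[i], iv$rec[j]] <- TRUE
    }
  }
  comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  comp
}

# random valid CIGAR over two sequences (internal convention)
random_cigar <- function(n_blocks = 6) {
  ops <- c("=", "X", "I", "D")
  repeat {
    op <- sample(ops, n_blocks, replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15))
    len <- sample(1:20, n_blocks, replace = TRUE)
    # no leading/trailing indel, no adjacent same-side-only ops of same type
    if (op[1] %in% c("=", "X") && op[n_blocks] %in% c("=", "X")) {
      return(paste0(len, op, collapse = ""))
    }
  }
}

# apply PSV alleles of a duplication to the region1 sequence -> region2
apply_psvs_to_seq <- function(s1, psvs, dup) {
  out <- character(0)
  cursor <- dup$start1
  for (i in seq_len(nrow(psvs))) {
    p <- psvs[i, ]
    out <- c(out, substr(s1, cursor - dup$start1 + 1, p$pos - dup$start1))
    out <- c(out, p$allele2)
    cursor <- p$pos + nchar(p$allele1)
  }
  out <- c(out, substr(s1, cursor - dup$start1 + 1, nchar(s1)))
  paste(out, collapse = "")
}
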