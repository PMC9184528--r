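#' Simulate a toy genome with a multi-copy duplication and planted PSVs
#'
#' Generates a single contig containing `n_copies` near-identical copies of
#' a duplicated segment embedded in unique sequence. Copies are identical
#' except at planted PSVs: substitutions and (optionally) 1-bp indels drawn
#' at `psv_density` sites per kb. The exact pairwise alignments between the
#' primary copy and every other copy are returned as self-alignment records
#' (the role an external self-aligner plays on a real genome), so
#' [build_table()] plus [extract_psvs()] on this output recovers the
#' planted PSV set exactly.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_copies Number of copies of the duplicated segment (default 2).
#' @param copy_length Length of the duplicated segment in bp (default 5000).
#' @param flank,spacer Unique sequence before/after and between copies
#'   (defaults 3000 and 2000 bp).
#' @param psv_density Planted PSVs per kb (default 2). A density of 0 with
#'   `similarity < 1` requested is a configuration error.
#' @param psv_indel_frac Fraction of planted PSVs that are 1-bp indels
#'   (default 0; substitutions otherwise).
#' @param similarity Optional target similarity; only used for validation
#'   against `psv_density`.
#' @param minus_strand Place the last copy on the minus strand?
#' @param contig Contig name.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `records`
#'   (self-alignment tibble for [build_table()]), `psvs` (truth tibble:
#'   `pos` on the primary copy, `type`, list-column `alleles` with one
#'   allele per copy), `copies` (tibble `contig`, `start`, `end`,
#'   `strand`), `contig`.
#' @export
sim_genome <- function(seed, n_copies = 2, copy_length = 5000, flank = 3000,
                       spacer = 2000, psv_density = 2, psv_indel_frac = 0,
                       similarity = NULL, minus_strand = FALSE,
                       contig = "sim1") {
  if (psv_density == 0 && !is.null(similarity) && similarity < 1) {
    stop_paracn("psv_density 0 cannot produce similarity below 1")
  }
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rseq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    core <- strsplit(rseq(copy_length), "")[[1]]

    n_psv <- round(psv_density * copy_length / 1000)
    # keep PSVs off the copy edges and 2 bp apart so runs never merge
    cand <- seq(10L, copy_length - 10L, by = 3L)
    pos0 <- sort(sample(cand, min(n_psv, length(cand))))
    type <- if (n_psv > 0) {
      sample(c("sub", "indel"), length(pos0), replace = TRUE,
             prob = c(1 - psv_indel_frac, psv_indel_frac))
    } else character(0)

    # alternative copies: substitute / delete the planted base
    alt_base <- vapply(pos0, function(p) {
      sample(setdiff(bases, core[p + 1L]), 1)
    }, character(1))

    copy_seqs <- list(core)
    for (k in seq_len(n_copies - 1L)) {
      s <- core
      if (length(pos0)) {
        s[pos0 + 1L] <- ifelse(type == "sub", alt_base, NA)  # NA = deleted
      }
      copy_seqs[[k + 1L]] <- s[!is.na(s)]
    }

    # assemble the contig
    pieces <- list(strsplit(rseq(flank), "")[[1]])
    starts <- integer(n_copies)
    at <- flank
    for (k in seq_len(n_copies)) {
      s <- copy_seqs[[k]]
      strand_k <- if (minus_strand && k == n_copies) "-" else "+"
      if (strand_k == "-") {
        s <- rev(c(A = "T", C = "G", G = "C", T = "A")[s])
      }
      starts[k] <- at
      pieces[[length(pieces) + 1L]] <- s
      at <- at + length(s)
      gap <- if (k < n_copies) spacer else flank
      pieces[[length(pieces) + 1L]] <- strsplit(rseq(gap), "")[[1]]
      at <- at + gap
    }
    seq_all <- paste(unlist(pieces), collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(seq_all, contig))

    copies <- tibble::tibble(
      contig = contig, start = starts,
      end = starts + vapply(copy_seqs, length, integer(1)),
      strand = vapply(seq_len(n_copies), function(k) {
        if (minus_strand && k == n_copies) "-" else "+"
      }, character(1))
    )

    # exact alignment CIGAR primary -> copy k (deletions consume region1)
    cigar_k <- function() {
      if (!length(pos0)) return(sprintf("%d=", copy_length))
      ops <- character(0)
      prev <- 0L
      for (i in seq_along(pos0)) {
        gap <- pos0[i] - prev
        if (gap > 0) ops <- c(ops, sprintf("%d=", gap))
        ops <- c(ops, if (type[i] == "sub") "1X" else "1D")
        prev <- pos0[i] + 1L
      }
      if (prev < copy_length) ops <- c(ops, sprintf("%d=", copy_length - prev))
      paste(ops, collapse = "")
    }
    records <- dplyr::bind_rows(lapply(seq_len(n_copies - 1L), function(k) {
      tibble::tibble(
        chrom1 = contig, start1 = copies$start[1], end1 = copies$end[1],
        chrom2 = contig, start2 = copies$start[k + 1L],
        end2 = copies$end[k + 1L], strand = copies$strand[k + 1L],
        cigar = cigar_k()
      )
    }))

    psvs <- tibble::tibble(
      pos = copies$start[1] + pos0, type = type,
      alleles = lapply(seq_along(pos0), function(i) {
        ref <- core[pos0[i] + 1L]
        if (type[i] == "sub") {
          c(ref, rep(alt_base[i], n_copies - 1L))
        } else {      # 1-bp deletion, left-anchored
          anchor <- core[pos0[i]]
          c(paste0(anchor, ref), rep(anchor, n_copies - 1L))
        }
      })
    )
    if (nrow(psvs) > 0 && any(psvs$type == "indel")) {
      psvs$pos[psvs$type == "indel"] <- psvs$pos[psvs$type == "indel"] - 1L
    }
    list(genome = genome, records = records, psvs = psvs, copies = copies,
         contig = contig)
  })
}

#' Simulate paired-end alignment records over an interval
#'
#' Uniformly placed proper read pairs, as [alignment records]
#' [alignment_records]; the fast path for exercising read counting and
#' cross-copy pooling without BAM files ([write_sam()] emits them as SAM
#' when the I/O path itself is under test).
#'
#' @param seed Integer seed.
#' @param contig,start,end Target interval (0-based half-open).
#' @param n_pairs Number of read pairs.
#' @param read_len,frag_len Read and fragment lengths (defaults 150/400).
#' @param sample Sample label.
#' @return Alignment-record tibble, coordinate-sorted.
#' @export
sim_reads <- function(seed, contig, start, end, n_pairs, read_len = 150,
                      frag_len = 400, sample = "s1") {
  withr::with_seed(seed, {
    s1 <- start + sort(sample.int(max(end - start - frag_len, 1L), n_pairs,
                                  replace = TRUE)) - 1L
    r1 <- tibble::tibble(contig = contig, start = s1, end = s1 + read_len,
                         mapq = 60L, proper = TRUE, clipped = FALSE,
                         paired = TRUE, first = TRUE, sample = sample)
    s2 <- s1 + frag_len - read_len
    r2 <- dplyr::mutate(r1, start = s2, end = s2 + read_len, first = FALSE)
    dplyr::arrange(dplyr::bind_rows(r1, r2), .data$start)
  })
}

# smooth unimodal GC bias multiplier over GC 20..80% (1 at GC 45%)
gc_bias <- function(gc, strength = 0.3, center = 45) {
  1 - strength * ((gc - center) / 35)^2
}

#' Construct a negative binomial background model from known parameters
#'
#' Builds an `nb_model` directly from a mean-depth curve and dispersion,
#' e.g. the truth of a simulation, bypassing [fit_nb()].
#'
#' @param mu Mean diploid depth at GC 45% (scalar) or a length-101 vector
#'   over GC 0–100.
#' @param size NB dispersion (size) parameter.
#' @param gc_bias_strength When `mu` is scalar, the GC bias strength used
#'   to bend the mean curve (see the simulator; 0 = flat).
#' @param window_size,sample Metadata.
#' @return An `nb_model`.
#' @export
sim_nb_model <- function(mu, size, gc_bias_strength = 0, window_size = 100,
                         sample = NA_character_) {
  grid <- 0:100
  mean_g <- if (length(mu) == 101) mu else mu * gc_bias(grid, gc_bias_strength)
  mean_g <- pmax(mean_g, 1e-3)
  out <- tibble::tibble(
    gc_percent = grid, size = size, prob = size / (size + mean_g),
    mean = mean_g, n_windows = 0L, fitted = TRUE
  )
  structure(out, class = c("nb_model", class(out)),
            window_size = window_size, sample = sample)
}

#' Simulate background depth windows for one sample
#'
#' @param seed Integer seed.
#' @param n_windows Number of windows.
#' @param mu,size Diploid NB mean (at GC 45%) and dispersion.
#' @param gc_range GC percentages sampled uniformly (default 30:60).
#' @param gc_bias_strength GC bias strength (default 0.3).
#' @return Tibble `gc_percent`, `read_count`, `irregular` for [fit_nb()].
#' @export
sim_background_depth <- function(seed, n_windows = 20000, mu = 10, size = 30,
                                 gc_range = 30:60, gc_bias_strength = 0.3) {
  withr::with_seed(seed, {
    gc <- sample(gc_range, n_windows, replace = TRUE)
    mu_g <- mu * gc_bias(gc, gc_bias_strength)
    tibble::tibble(
      gc_percent = as.integer(gc),
      read_count = stats::rnbinom(n_windows, size = size,
                                  prob = size / (size + mu_g)),
      irregular = FALSE
    )
  })
}

#' Simulate an aggregate depth matrix under known copy-number truth
#'
#' Window counts are drawn from the model's own emission family: NB with
#' size `size * cn/2 * m_w` and the success probability implied by the
#' GC-dependent diploid mean, so a copy-number `c` sample has `c/2` times
#' the diploid expected depth.
#'
#' @param seed Integer seed.
#' @param cn `W x S` integer matrix of true aggregate copy number per
#'   window and sample (or a single value).
#' @param n_windows,n_samples Dimensions when `cn` is scalar.
#' @param mu,size Diploid NB mean (GC 45%) and dispersion.
#' @param gc_range Window GC values are drawn uniformly from this set.
#' @param gc_bias_strength GC bias strength (default 0.3).
#' @param m_w Per-window scale factors (default 1).
#' @param ref_cn Reference copy number recorded in the output.
#' @param contig Window contig name.
#' @return List with `depth` (an `agg_depth`), `cn` (truth matrix),
#'   `windows`.
#' @export
sim_depth <- function(seed, cn, n_windows = NULL, n_samples = NULL,
                      mu = 10, size = 30, gc_range = 35:55,
                      gc_bias_strength = 0.3, m_w = 1, ref_cn = 4,
                      contig = "sim1") {
  if (!is.matrix(cn)) {
    stopifnot(!is.null(n_windows), !is.null(n_samples))
    cn <- matrix(as.integer(cn), n_windows, n_samples)
  }
  W <- nrow(cn); S <- ncol(cn)
  m_w <- rep_len(m_w, W)
  withr::with_seed(seed, {
    gc <- sample(gc_range, W, replace = TRUE)
    mu_g <- mu * gc_bias(gc, gc_bias_strength)
    prob <- size / (size + mu_g)
    counts <- matrix(0L, W, S,
                     dimnames = list(NULL, sprintf("s%03d", seq_len(S))))
    for (s in seq_len(S)) {
      sz <- size * (cn[, s] / 2) * m_w
      pos <- sz > 0
      counts[pos, s] <- stats::rnbinom(sum(pos), size = sz[pos], prob = prob[pos])
    }
    win <- tibble::tibble(
      contig = contig, start = 100L * (seq_len(W) - 1L), end = 100L * seq_len(W),
      gc_percent = as.integer(gc), segment = 1L, keep = TRUE
    )
    list(depth = new_agg_depth(win, counts, ref_cn = ref_cn), cn = cn,
         windows = win)
  })
}

#' Simulate PSV allele counts under known frequencies and tuples
#'
#' Each chromosome of copy `j` carries copy `j`'s reference allele with
#' probability `f[v, j]`, otherwise one of the other copies' alleles
#' uniformly; reads sample chromosomes uniformly and report their allele,
#' with an error mass `eps` diverted to "other". Marginal allele fractions
#' therefore converge to [allele_prob()] as depth grows.
#'
#' @param seed Integer seed.
#' @param f `V x m` matrix of reference-allele frequencies.
#' @param tuples List of integer tuples, one per sample.
#' @param depth Mean reads per PSV (Poisson).
#' @param eps Sequencing error rate (default 0.01).
#' @param samples Sample labels.
#' @return Long counts tibble (`sample`, `psv`, `allele`, `count`) with
#'   `allele` 0 meaning "other".
#' @export
sim_psv_counts <- function(seed, f, tuples, depth = 30, eps = 0.01,
                           samples = sprintf("s%03d", seq_along(tuples))) {
  V <- nrow(f); m <- ncol(f)
  withr::with_seed(seed, {
    out <- vector("list", length(tuples))
    for (s in seq_along(tuples)) {
      t <- tuples[[s]]
      c_s <- sum(t)
      copy_of <- rep(seq_len(m), t)
      rows <- list()
      for (v in seq_len(V)) {
        # per-chromosome allele carriage at this PSV
        carried <- vapply(copy_of, function(j) {
          if (stats::runif(1) < f[v, j]) j
          else sample(setdiff(seq_len(m), j), 1)
        }, integer(1))
        n_reads <- stats::rpois(1, depth)
        cnt <- integer(m + 1)
        if (n_reads > 0 && c_s > 0) {
          src <- sample(carried, n_reads, replace = TRUE)
          err <- stats::runif(n_reads) < eps
          cnt <- tabulate(ifelse(err, m + 1L, src), nbins = m + 1L)
        }
        rows[[v]] <- tibble::tibble(
          sample = samples[s], psv = sprintf("psv%03d", v),
          allele = c(seq_len(m), 0L), count = cnt
        )
      }
      out[[s]] <- dplyr::bind_rows(rows)
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate parent-offspring trios of paralog copy-number calls
#'
#' Parents are two independent haploid draws from `freqs`; each parent
#' transmits one of its haploids (chosen fairly) to the child. A fraction
#' `spike_frac` of children is corrupted by moving one copy-unit between
#' two copies of the true child tuple, producing non-Mendelian calls.
#'
#' @param seed Integer seed.
#' @param freqs A `haploid_freqs` object or tibble (`tuple`, `prob`).
#' @param n_trios Number of trios.
#' @param spike_frac Fraction of children corrupted (default 0).
#' @param quality Phred quality attached to every call (default 100).
#' @return List with `ped` (tibble `child`, `mother`, `father`) and
#'   `calls` (tibble `sample`, `tuple`, `quality`) plus `spiked` (logical
#'   per trio).
#' @export
sim_trios <- function(seed, freqs, n_trios, spike_frac = 0, quality = 100) {
  hap <- tuple_parse(freqs$tuple)
  withr::with_seed(seed, {
    draw <- function() hap[[sample.int(length(hap), 1, prob = freqs$prob)]]
    ped <- tibble::tibble(
      child = sprintf("c%04d", seq_len(n_trios)),
      mother = sprintf("m%04d", seq_len(n_trios)),
      father = sprintf("f%04d", seq_len(n_trios))
    )
    spiked <- stats::runif(n_trios) < spike_frac
    calls <- vector("list", n_trios)
    for (i in seq_len(n_trios)) {
      mh <- list(draw(), draw()); fh <- list(draw(), draw())
      ch <- mh[[sample.int(2, 1)]] + fh[[sample.int(2, 1)]]
      if (spiked[i]) {
        m <- length(ch)
        repeat {
          from <- sample.int(m, 1); to <- sample.int(m, 1)
          if (from != to && ch[from] > 0) break
        }
        ch[from] <- ch[from] - 1L; ch[to] <- ch[to] + 1L
      }
      calls[[i]] <- tibble::tibble(
        sample = c(ped$child[i], ped$mother[i], ped$father[i]),
        tuple = c(tuple_str(ch), tuple_str(mh[[1]] + mh[[2]]),
                  tuple_str(fh[[1]] + fh[[2]])),
        quality = quality
      )
    }
    list(ped = ped, calls = dplyr::bind_rows(calls), spiked = spiked)
  })
}

#' Draw a PSV reference-allele frequency matrix
#'
#' Entries are drawn independently from a small set of frequency classes:
#' fixed reference alleles (`f = 1`), nearly fixed (`f = 0.97`, still
#' reliable), and polymorphic PSV alleles (`f = 0.5`). The default class
#' weights emulate a locus amenable to paralog-specific genotyping, where
#' the large majority of PSVs are reliable copy markers; loci dominated by
#' polymorphic PSVs are the ones the caller skips on real data.
#'
#' @param seed Integer seed.
#' @param n_psvs,n_copies Matrix dimensions.
#' @param values Frequency classes (default `c(1, 0.97, 0.5)`).
#' @param prob Class weights (default `c(0.80, 0.15, 0.05)`).
#' @return A `n_psvs x n_copies` matrix.
#' @export
sim_f_matrix <- function(seed, n_psvs, n_copies = 2, values = c(1, 0.97, 0.5),
                         prob = c(0.80, 0.15, 0.05)) {
  withr::with_seed(seed, {
    matrix(sample(values, n_psvs * n_copies, replace = TRUE, prob = prob),
           n_psvs, n_copies)
  })
}
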