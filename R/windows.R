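#' Alignment records as a tibble
#'
#' Read-level input throughout the package is a plain tibble of alignment
#' records, one row per aligned read, with columns:
#'
#' * `contig`, `start`, `end` — 0-based half-open alignment span,
#' * `mapq` — mapping quality,
#' * `proper` — mapped in a proper pair,
#' * `clipped` — soft-clipped,
#' * `paired` — part of a read pair,
#' * `first` — leftmost (first-in-genome) read of its pair,
#' * optionally `sample`.
#'
#' [read_alignments()] produces this layout from a BAM file; the simulator
#' produces it directly.
#'
#' @name alignment_records
NULL

#' Tile an interval into fixed-length depth windows
#'
#' @param contig Contig name.
#' @param start,end 0-based half-open interval to tile.
#' @param size Window length in bp (default 100). Only full windows are
#'   produced; a trailing remainder shorter than `size` is dropped.
#' @return A tibble with columns `contig`, `start`, `end`.
#' @export
make_windows <- function(contig, start, end, size = 100) {
  stopifnot(end > start, size > 0)
  n <- (end - start) %/% size
  if (n == 0) {
    return(tibble::tibble(contig = character(), start = integer(), end = integer()))
  }
  s <- start + size * (seq_len(n) - 1L)
  tibble::tibble(contig = contig, start = as.integer(s), end = as.integer(s + size))
}

#' Annotate windows with GC content
#'
#' @param windows A window tibble (`contig`, `start`, `end`).
#' @param genome A [Biostrings::DNAStringSet].
#' @return `windows` with an integer `gc_percent` column (0–100, rounded).
#' @export
windows_gc <- function(windows, genome) {
  gc <- integer(nrow(windows))
  for (ctg in unique(windows$contig)) {
    i <- which(windows$contig == ctg)
    v <- Biostrings::Views(genome[[ctg]], start = windows$start[i] + 1L,
                           end = windows$end[i])
    frac <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
    gc[i] <- as.integer(round(100 * frac))
  }
  windows$gc_percent <- gc
  windows
}

# centre of a read span; pairs are represented by their first-in-genome read
read_center <- function(start, end) (start + end) %/% 2L

# index of the window containing each position (NA if none); windows must be
# non-overlapping and sorted within each contig
window_index <- function(contig, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    w <- which(windows$contig == ctg)
    if (!length(w)) next
    if (is.unsorted(windows$start[w])) stop_paracn("windows must be sorted")
    j <- findInterval(pos[i], windows$start[w])
    ok <- j >= 1 & pos[i] < windows$end[w][pmax(j, 1)]
    idx[i[ok]] <- w[j[ok]]
  }
  idx
}

#' Count reads per window
#'
#' Each read pair is counted once, in the window containing the center of
#' the pair's first-in-genome read; unpaired reads are counted by their own
#' center. Windows are half-open, so a center falling exactly on a window
#' start belongs to that window.
#'
#' @param reads An [alignment record][alignment_records] tibble,
#'   coordinate-sorted within each contig.
#' @param windows A window tibble, non-overlapping.
#' @return `windows` with columns `read_count`, `frac_low_mapq`,
#'   `frac_improper`, `frac_clipped`, `irregular` added (see
#'   [flag_irregular()]).
#' @param mapq_threshold Reads with MAPQ below this count as low-MAPQ.
#' @param irregular_frac Fraction of flagged reads at or above which a
#'   window is marked irregular.
#' @export
assign_reads <- function(reads, windows, mapq_threshold = 10,
                         irregular_frac = 0.10) {
  for (ctg in unique(reads$contig)) {
    if (is.unsorted(reads$start[reads$contig == ctg])) {
      stop_paracn("alignment records must be coordinate-sorted (contig '%s')", ctg)
    }
  }
  units <- reads[(!reads$paired) | reads$first, , drop = FALSE]
  idx <- window_index(units$contig, read_center(units$start, units$end), windows)
  units <- units[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]

  n <- nrow(windows)
  count <- tabulate(idx, nbins = n)
  low <- tabulate(idx[units$mapq < mapq_threshold], nbins = n)
  imp <- tabulate(idx[!units$proper & units$paired], nbins = n)
  clp <- tabulate(idx[units$clipped], nbins = n)
  denom <- pmax(count, 1L)

  windows$read_count <- count
  windows$frac_low_mapq <- low / denom
  windows$frac_improper <- imp / denom
  windows$frac_clipped <- clp / denom
  windows$irregular <- flag_irregular(windows$frac_low_mapq,
                                      windows$frac_improper,
                                      windows$frac_clipped,
                                      threshold = irregular_frac)
  windows
}

#' Flag irregular depth windows
#'
#' A window is irregular when at least `threshold` (default 10%) of its
#' reads have low mapping quality, are not mapped in proper pairs, or are
#' soft-clipped. Irregular windows are excluded from background-depth
#' modeling. A window with no reads is regular (all fractions 0).
#'
#' @param frac_low_mapq,frac_improper,frac_clipped Per-window fractions.
#' @param threshold Irregularity threshold (default 0.10).
#' @return Logical vector.
#' @export
flag_irregular <- function(frac_low_mapq, frac_improper, frac_clipped,
                           threshold = 0.10) {
  frac_low_mapq >= threshold | frac_improper >= threshold |
    frac_clipped >= threshold
}

#' Select background depth windows from unique sequence
#'
#' Background (copy-number 2) depth is estimated from fixed-length windows
#' in unique regions of the genome: windows lying within `buffer` bp of any
#' duplication in the homology table are discarded. When a core region set
#' is supplied, additional windows with extreme GC content (at or below /
#' at or above `gc_extreme`) are recruited from a `neighborhood` around each
#' core region, since extreme-GC windows are otherwise scarce.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param table A `homology_table` (may have 0 rows).
#' @param regions Optional tibble (`contig`, `start`, `end`) of core regions;
#'   default: every contig in full (no neighborhood recruitment applies).
#' @param window_size Window length (default 100 bp).
#' @param buffer Minimum distance to any duplication (default 500 bp).
#' @param neighborhood Width of the extreme-GC recruitment zone around core
#'   regions (default 5000 bp).
#' @param gc_extreme Length-2 numeric: GC percentages at or below the first
#'   / at or above the second value count as extreme (default `c(35, 55)`).
#' @param target_count Optional cap: an evenly spaced subset of this size is
#'   returned (deterministic).
#' @return A window tibble with `gc_percent`.
#' @export
select_background_windows <- function(genome, table, regions = NULL,
                                      window_size = 100, buffer = 500,
                                      neighborhood = 5000,
                                      gc_extreme = c(35, 55),
                                      target_count = NULL) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  if (is.null(regions)) {
    core <- tibble::tibble(contig = names(genome), start = 0L, end = as.integer(lens))
    nbhd <- NULL
  } else {
    core <- regions
    nbhd <- dplyr::bind_rows(
      tibble::tibble(contig = regions$contig,
                     start = pmax(0L, regions$start - as.integer(neighborhood)),
                     end = regions$start),
      tibble::tibble(contig = regions$contig, start = regions$end,
                     end = pmin(as.integer(lens[regions$contig]),
                                regions$end + as.integer(neighborhood)))
    )
  }
  tile <- function(rg) {
    dplyr::bind_rows(purrr::pmap(rg, function(contig, start, end, ...) {
      make_windows(contig, start, end, size = window_size)
    }))
  }
  win <- windows_gc(tile(core), genome)
  if (!is.null(nbhd)) {
    extra <- windows_gc(tile(nbhd), genome)
    extra <- extra[extra$gc_percent <= gc_extreme[1] |
                     extra$gc_percent >= gc_extreme[2], , drop = FALSE]
    win <- dplyr::bind_rows(win, extra)
  }
  win <- dplyr::distinct(dplyr::arrange(win, .data$contig, .data$start))

  if (nrow(table) > 0) {
    dup_iv <- tibble::tibble(
      contig = c(table$chrom1, table$chrom2),
      start = c(table$start1, table$start2),
      end = c(table$end1, table$end2)
    )
    near <- rep(FALSE, nrow(win))
    for (ctg in unique(win$contig)) {
      i <- which(win$contig == ctg)
      d <- dup_iv[dup_iv$contig == ctg, , drop = FALSE]
      if (!nrow(d)) next
      hits <- IRanges::overlapsAny(
        IRanges::IRanges(win$start[i] - buffer + 1L, win$end[i] + buffer),
        IRanges::IRanges(d$start + 1L, d$end)
      )
      near[i] <- hits
    }
    win <- win[!near, , drop = FALSE]
  }
  if (nrow(win) == 0) {
    stop_paracn("no unique sequence available for background windows; provide a larger genome or region set")
  }
  if (!is.null(target_count) && nrow(win) > target_count) {
    keep <- unique(round(seq(1, nrow(win), length.out = target_count)))
    win <- win[keep, , drop = FALSE]
  }
  win
}
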