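#' Split a locus into segments of constant reference copy number
#'
#' Finds all duplications overlapping the query locus (short duplications,
#' by default <500 bp, are skipped) and places breakpoints at every change
#' in the set of overlapping duplications. Each resulting segment is
#' annotated with its reference copy number — 2 times the number of copies,
#' so a two-copy duplication has reference copy number 4 — and with the
#' homologous interval of every additional copy, obtained by projecting the
#' segment through the stored alignments.
#'
#' @param locus A one-row tibble (`contig`, `start`, `end`), 0-based
#'   half-open.
#' @param table A `homology_table`.
#' @param min_dup_length Duplications shorter than this are ignored
#'   (default 500 bp).
#' @return A tibble with columns `contig`, `start`, `end`, `ref_cn` and a
#'   list-column `copies` (tibbles with `contig`, `start`, `end`, `strand`,
#'   `dup_id`; the primary interval itself is listed first with `dup_id`
#'   `NA`). Segments partition the locus.
#' @export
segment_locus <- function(locus, table, min_dup_length = 500) {
  stopifnot(nrow(locus) == 1)
  all_dups <- dups_overlapping(table, locus$contig, locus$start, locus$end,
                               include_tangled = TRUE, min_length = min_dup_length)
  tangled <- all_dups[all_dups$tangled, , drop = FALSE]
  dups <- all_dups[!all_dups$tangled, , drop = FALSE]
  if (nrow(tangled) > 0) {
    cov <- IRanges::reduce(IRanges::IRanges(
      pmax(tangled$start1, locus$start) + 1L, pmin(tangled$end1, locus$end)))
    if (sum(IRanges::width(cov)) >= locus$end - locus$start) {
      stop_paracn("region unsuitable: %s is entirely covered by tangled duplications",
                  interval_str(locus$contig, locus$start, locus$end))
    }
  }
  bp <- sort(unique(c(locus$start, locus$end,
                      pmax(dups$start1, locus$start),
                      pmin(dups$end1, locus$end))))
  segs <- tibble::tibble(contig = locus$contig,
                         start = bp[-length(bp)], end = bp[-1])
  segs$copies <- vector("list", nrow(segs))
  segs$ref_cn <- 2L
  for (i in seq_len(nrow(segs))) {
    hit <- which(dups$start1 <= segs$start[i] & dups$end1 >= segs$end[i])
    primary <- tibble::tibble(contig = segs$contig[i], start = segs$start[i],
                              end = segs$end[i], strand = "+", dup_id = NA_integer_)
    proj <- purrr::map(hit, function(j) {
      dup <- dups[j, , drop = FALSE]
      ends <- project_position(dup, c(segs$start[i], segs$end[i] - 1L),
                               gap = "nearest")
      tibble::tibble(contig = dup$chrom2, start = min(ends),
                     end = max(ends) + 1L, strand = dup$strand,
                     dup_id = dup$dup_id)
    })
    segs$copies[[i]] <- dplyr::bind_rows(c(list(primary), proj))
    segs$ref_cn[i] <- 2L * (1L + length(hit))
  }
  segs
}

#' Group same-copy-number segments separated by short gaps
#'
#' Segments of the same reference copy number interrupted only by a short
#' stretch (for example an interspersed repeat) of different copy number are
#' analyzed together: consecutive segments with equal `ref_cn` separated by
#' less than `max_gap` bp are placed in one region group. All downstream
#' modeling runs independently per region group.
#'
#' @param segments Output of [segment_locus()].
#' @param max_gap Gap threshold in bp (default 2000; a gap of exactly
#'   `max_gap` starts a new group).
#' @return `segments` with an integer `group` column.
#' @export
group_segments <- function(segments, max_gap = 2000) {
  segments <- dplyr::arrange(segments, .data$contig, .data$start)
  n <- nrow(segments)
  if (n == 0) { segments$group <- integer(); return(segments) }
  group <- integer(n)
  open <- list()   # per ref_cn: list(group, end)
  next_id <- 1L
  for (i in seq_len(n)) {
    key <- as.character(segments$ref_cn[i])
    prev <- open[[key]]
    if (!is.null(prev) && segments$contig[i] == prev$contig &&
        segments$start[i] - prev$end < max_gap) {
      group[i] <- prev$group
    } else {
      group[i] <- next_id
      next_id <- next_id + 1L
    }
    open[[key]] <- list(group = group[i], end = segments$end[i],
                        contig = segments$contig[i])
  }
  segments$group <- group
  segments
}

#' Pool reads across repeat copies and tabulate aggregate depth
#'
#' For one region group, every read pair aligned to any copy of the
#' duplication is re-mapped onto the primary copy using the stored
#' alignments ([project_position()], nearest aligned base for gap
#' positions, ties leftward) and counted by the first-read-center rule into
#' fixed-length windows. Counts are summed over copies, giving the
#' aggregate depth matrix; per-sample irregularity statistics are
#' recomputed on the pooled reads.
#'
#' @param group_segments Rows of [segment_locus()] output belonging to one
#'   region group.
#' @param reads [Alignment records][alignment_records] with a `sample`
#'   column, covering the primary locus and all copies.
#' @param table The `homology_table` the segments were derived from.
#' @param genome A [Biostrings::DNAStringSet] (for window GC content).
#' @param window_size Window length (must equal the background window
#'   length so pooled counts are comparable to the background NB models).
#' @param mapq_threshold,irregular_frac Irregularity parameters, as in
#'   [assign_reads()].
#' @return An `agg_depth` object: list with `windows` (tibble: `contig`,
#'   `start`, `end`, `gc_percent`, `segment`, `keep`), `counts` and
#'   `irregular` (windows x samples matrices), `samples`, `ref_cn`.
#' @export
pool_and_count <- function(group_segments, reads, table, genome,
                           window_size = 100, mapq_threshold = 10,
                           irregular_frac = 0.10) {
  stopifnot(length(unique(group_segments$ref_cn)) == 1)
  win <- dplyr::bind_rows(purrr::map(seq_len(nrow(group_segments)), function(i) {
    w <- make_windows(group_segments$contig[i], group_segments$start[i],
                      group_segments$end[i], size = window_size)
    w$segment <- i
    w
  }))
  if (nrow(win) == 0) stop_paracn("region group shorter than one window")
  win <- windows_gc(win, genome)

  samples <- sort(unique(reads$sample))
  units <- reads[(!reads$paired) | reads$first, , drop = FALSE]
  units$center <- read_center(units$start, units$end)

  counts <- matrix(0L, nrow(win), length(samples),
                   dimnames = list(NULL, samples))
  flagged <- array(0L, dim = c(nrow(win), length(samples), 3))
  dropped <- 0L

  add_units <- function(u, idx) {
    keep <- !is.na(idx)
    dropped <<- dropped + sum(!keep)
    u <- u[keep, , drop = FALSE]; idx <- idx[keep]
    s <- match(u$sample, samples)
    for (k in seq_len(nrow(u))) {
      counts[idx[k], s[k]] <<- counts[idx[k], s[k]] + 1L
      if (u$mapq[k] < mapq_threshold) flagged[idx[k], s[k], 1] <<- flagged[idx[k], s[k], 1] + 1L
      if (u$paired[k] && !u$proper[k]) flagged[idx[k], s[k], 2] <<- flagged[idx[k], s[k], 2] + 1L
      if (u$clipped[k]) flagged[idx[k], s[k], 3] <<- flagged[idx[k], s[k], 3] + 1L
    }
  }

  seen <- rep(FALSE, nrow(units))
  for (i in seq_len(nrow(group_segments))) {
    copies <- group_segments$copies[[i]]
    for (j in seq_len(nrow(copies))) {
      cp <- copies[j, ]
      sel <- which(!seen & units$contig == cp$contig &
                     units$center >= cp$start & units$center < cp$end)
      if (!length(sel)) next
      seen[sel] <- TRUE
      u <- units[sel, , drop = FALSE]
      if (is.na(cp$dup_id)) {
        idx <- window_index(u$contig, u$center, win)
      } else {
        dup <- dup_swap(table[table$dup_id == cp$dup_id, , drop = FALSE])
        inside <- u$center >= dup$start1 & u$center < dup$end1
        dropped <- dropped + sum(!inside)
        u <- u[inside, , drop = FALSE]
        if (!nrow(u)) next
        proj <- project_position(dup, u$center, gap = "nearest")
        idx <- window_index(rep(dup$chrom2, nrow(u)), proj, win)
      }
      add_units(u, idx)
    }
  }
  if (dropped > 0) {
    message(sprintf("%d read pair(s) projected outside the primary windows were discarded", dropped))
  }
  denom <- pmax(counts, 1L)
  irregular <- flag_irregular(flagged[, , 1] / denom, flagged[, , 2] / denom,
                              flagged[, , 3] / denom, threshold = irregular_frac)
  irregular <- matrix(irregular, nrow(win), length(samples),
                      dimnames = list(NULL, samples))
  win$keep <- TRUE
  new_agg_depth(win, counts, irregular, ref_cn = group_segments$ref_cn[1])
}

new_agg_depth <- function(windows, counts, irregular = NULL, ref_cn = 2L) {
  if (is.null(irregular)) {
    irregular <- matrix(FALSE, nrow(counts), ncol(counts),
                        dimnames = dimnames(counts))
  }
  structure(list(windows = windows, counts = counts, irregular = irregular,
                 samples = colnames(counts), ref_cn = as.integer(ref_cn)),
            class = "agg_depth")
}

#' @export
print.agg_depth <- function(x, ...) {
  cat(sprintf("<agg_depth> %d windows x %d samples, reference CN %d, %d kept\n",
              nrow(x$windows), length(x$samples), x$ref_cn, sum(x$windows$keep)))
  invisible(x)
}

#' Drop windows that are irregular in too many samples
#'
#' A window is dropped when it is irregular (see [flag_irregular()]) in more
#' than `max_frac` of the samples; both immediate flanking windows of a
#' dropped window (within the same segment) are dropped too.
#'
#' @param depth An `agg_depth` object.
#' @param max_frac Fraction of samples above which a window is dropped
#'   (default 0.10; a window irregular in exactly 10% of samples is kept).
#' @return `depth` with updated `windows$keep`.
#' @export
filter_windows <- function(depth, max_frac = 0.10) {
  frac <- rowMeans(depth$irregular)
  bad <- frac > max_frac
  drop <- bad
  seg <- depth$windows$segment %||% rep(1L, nrow(depth$windows))
  i <- which(bad)
  for (j in i) {
    if (j > 1 && seg[j - 1] == seg[j]) drop[j - 1] <- TRUE
    if (j < length(drop) && seg[j + 1] == seg[j]) drop[j + 1] <- TRUE
  }
  depth$windows$keep <- !drop
  if (!any(depth$windows$keep)) stop_paracn("no usable windows after irregularity filtering")
  depth
}
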