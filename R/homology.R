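#' Build a homology table from pairwise self-alignment records
#'
#' The homology table stores pairwise duplications of the reference genome:
#' for every stored record, an alignment (CIGAR), length, sequence similarity
#' and a `tangled` flag. It is the central index from which paralogous
#' regions, constant-copy-number segments and PSVs are derived.
#'
#' Records are filtered on minimum length and minimum similarity. Sequences
#' taking part in more than `max_alignments` pairwise alignments typically
#' correspond to interspersed repeats rather than low-copy repeats; all their
#' records are flagged `tangled` and excluded from copy-number queries (they
#' stay in the table so that queries can warn about them).
#'
#' @param records A data frame of pairwise alignment records with columns
#'   `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`, `strand`
#'   (`"+"`/`"-"`), `cigar`, and optionally `similarity`; or a path to a PAF
#'   file (see [read_paf()]). Coordinates are 0-based half-open. `region1`
#'   is the reference-like side of the CIGAR (see [parse_cigar()]).
#' @param min_length Minimum region1 length (bp) for a record to be stored.
#' @param min_similarity Minimum sequence similarity (matching columns over
#'   aligned columns) for a record to be stored.
#' @param max_alignments Sequences participating in more than this many
#'   pairwise alignments are flagged `tangled`.
#' @param genome_id Identifier of the genome the table was built from.
#' @return A `homology_table`: a tibble of duplications with columns
#'   `dup_id`, `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`,
#'   `strand`, `length`, `similarity`, `cigar`, `tangled`.
#' @examples
#' recs <- tibble::tibble(
#'   chrom1 = "chr1", start1 = 1000L, end1 = 1600L,
#'   chrom2 = "chr1", start2 = 9000L, end2 = 9600L,
#'   strand = "+", cigar = "600="
#' )
#' build_table(recs, min_length = 500, min_similarity = 0.97)
#' @export
build_table <- function(records, min_length = 500, min_similarity = 0.97,
                        max_alignments = 10, genome_id = "unknown") {
  stopifnot(min_length > 0, min_similarity > 0, min_similarity <= 1)
  if (is.character(records)) records <- read_paf(records)
  records <- tibble::as_tibble(records)

  empty <- tibble::tibble(
    dup_id = integer(), chrom1 = character(), start1 = integer(),
    end1 = integer(), chrom2 = character(), start2 = integer(),
    end2 = integer(), strand = character(), length = integer(),
    similarity = double(), cigar = character(), tangled = logical()
  )
  if (nrow(records) == 0) {
    return(new_homology_table(empty, genome_id))
  }

  # validate CIGARs against interval lengths; reject with a logged reason
  ok <- rep(TRUE, nrow(records))
  sim <- if ("similarity" %in% names(records)) records$similarity else rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    blocks <- tryCatch(parse_cigar(records$cigar[i]), error = function(e) NULL)
    if (is.null(blocks) || nrow(blocks) == 0) {
      message(sprintf("record %d rejected: unparseable CIGAR", i)); ok[i] <- FALSE; next
    }
    l1 <- records$end1[i] - records$start1[i]
    l2 <- records$end2[i] - records$start2[i]
    if (cigar_r1_len(blocks) != l1 || cigar_r2_len(blocks) != l2) {
      message(sprintf(
        "record %d rejected: CIGAR consumes %d/%d bp but intervals span %d/%d bp",
        i, cigar_r1_len(blocks), cigar_r2_len(blocks), l1, l2))
      ok[i] <- FALSE; next
    }
    if (is.na(sim[i])) sim[i] <- cigar_similarity(blocks)
    if (is.na(sim[i])) {
      message(sprintf("record %d rejected: similarity unknown (CIGAR uses 'M')", i))
      ok[i] <- FALSE
    }
  }
  records <- records[ok, , drop = FALSE]
  sim <- sim[ok]

  keep <- (records$end1 - records$start1) >= min_length & sim >= min_similarity
  records <- records[keep, , drop = FALSE]
  sim <- sim[keep]
  if (nrow(records) == 0) return(new_homology_table(empty, genome_id))

  tbl <- tibble::tibble(
    dup_id = seq_len(nrow(records)),
    chrom1 = as.character(records$chrom1),
    start1 = as.integer(records$start1), end1 = as.integer(records$end1),
    chrom2 = as.character(records$chrom2),
    start2 = as.integer(records$start2), end2 = as.integer(records$end2),
    strand = as.character(records$strand %||% "+"),
    length = as.integer(records$end1 - records$start1),
    similarity = as.double(sim),
    cigar = as.character(records$cigar),
    tangled = FALSE
  )
  tbl$tangled <- flag_tangled(tbl, max_alignments)
  new_homology_table(tbl, genome_id)
}

new_homology_table <- function(tbl, genome_id) {
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- c("homology_table", class(tbl))
  attr(tbl, "genome_id") <- genome_id
  tbl
}

# flag every record touching a sequence cluster with > max_alignments records
flag_tangled <- function(tbl, max_alignments) {
  iv <- tibble::tibble(
    contig = c(tbl$chrom1, tbl$chrom2),
    start = c(tbl$start1, tbl$start2),
    end = c(tbl$end1, tbl$end2),
    dup = rep(tbl$dup_id, 2)
  )
  tangled <- rep(FALSE, nrow(tbl))
  for (ctg in unique(iv$contig)) {
    sub <- iv[iv$contig == ctg, ]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    cl <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- as.list(S4Vectors::mcols(cl)$revmap)
    for (members in revmap) {
      dups <- unique(sub$dup[members])
      if (length(dups) > max_alignments) {
        tangled[match(dups, tbl$dup_id)] <- TRUE
      }
    }
  }
  tangled
}

#' Query duplications overlapping an interval
#'
#' Returns the stored duplications whose region1 or region2 overlaps the
#' query interval. Each returned record is normalized (via [dup_swap()]) so
#' that region1 is the side overlapping the query.
#'
#' @param table A `homology_table` from [build_table()].
#' @param contig,start,end Query interval (0-based half-open).
#' @param include_tangled Return tangled records too? By default they are
#'   excluded with a warning when present.
#' @param min_length Drop duplications whose overlapping side is shorter
#'   than this many bp.
#' @return A tibble of duplications, region1 overlapping the query.
#' @export
dups_overlapping <- function(table, contig, start, end,
                             include_tangled = FALSE, min_length = 0) {
  hit1 <- table$chrom1 == contig & table$start1 < end & table$end1 > start
  hit2 <- table$chrom2 == contig & table$start2 < end & table$end2 > start
  out <- dplyr::bind_rows(
    table[hit1, , drop = FALSE],
    dup_swap(table[hit2 & !hit1, , drop = FALSE])
  )
  out <- out[out$length >= min_length, , drop = FALSE]
  if (!include_tangled && any(out$tangled)) {
    warning(sprintf("%d tangled duplication(s) overlapping %s excluded",
                    sum(out$tangled), interval_str(contig, start, end)))
    out <- out[!out$tangled, , drop = FALSE]
  }
  out
}

#' Swap the two sides of duplication records
#'
#' Exchanges region1 and region2 and rewrites the CIGAR accordingly, so that
#' coordinate projection can be run in either direction.
#'
#' @param dups One or more rows of a `homology_table`.
#' @return The records with the two regions exchanged.
#' @export
dup_swap <- function(dups) {
  if (nrow(dups) == 0) return(dups)
  out <- dups
  out$chrom1 <- dups$chrom2; out$start1 <- dups$start2; out$end1 <- dups$end2
  out$chrom2 <- dups$chrom1; out$start2 <- dups$start1; out$end2 <- dups$end1
  out$length <- as.integer(dups$end2 - dups$start2)
  out$cigar <- vapply(seq_len(nrow(dups)), function(i) {
    cigar_swap(dups$cigar[i], dups$strand[i])
  }, character(1))
  out
}

#' Project positions between the two copies of a duplication
#'
#' Follows the stored alignment to map genomic positions on region1 to the
#' homologous positions on region2. Match and mismatch columns map one to
#' one. Positions falling in an alignment gap (bases of region1 absent from
#' region2) either return `NA` (`gap = "marker"`) or are assigned the
#' nearest aligned base, ties resolved leftward (`gap = "nearest"`), which
#' is the rule used when pooling reads across copies.
#'
#' @param dup A single duplication record (one row of a `homology_table`).
#' @param pos Integer vector of 0-based positions on region1.
#' @param gap Gap handling: `"marker"` (`NA`) or `"nearest"`.
#' @return Integer vector of 0-based genomic positions on region2 (strand
#'   aware: for `-` strand records positions run rightward on region1 and
#'   leftward on region2).
#' @export
project_position <- function(dup, pos, gap = c("marker", "nearest")) {
  gap <- match.arg(gap)
  stopifnot(nrow(dup) == 1)
  off1 <- as.integer(pos) - dup$start1
  if (any(off1 < 0 | off1 >= dup$end1 - dup$start1)) {
    stop_paracn("position outside region1 %s",
                interval_str(dup$chrom1, dup$start1, dup$end1))
  }
  blocks <- cigar_offsets(parse_cigar(dup$cigar))
  r1s <- blocks$r1_off
  # ties resolve to the last index, so zero-width (I) blocks are never
  # selected: the block found always consumes region1
  idx <- findInterval(off1, r1s)
  off2 <- rep(NA_integer_, length(off1))
  both <- blocks$op[idx] %in% c("=", "X", "M")
  off2[both] <- blocks$r2_off[idx[both]] + (off1[both] - r1s[idx[both]])
  in_gap <- blocks$op[idx] == "D"
  if (any(in_gap) && gap == "nearest") {
    b <- idx[in_gap]
    left_off2 <- blocks$r2_off[b] - 1L             # last aligned base before the gap
    right_off2 <- blocks$r2_off[b]                 # first aligned base after
    dist_left <- off1[in_gap] - r1s[b] + 1L
    dist_right <- r1s[b] + blocks$len[b] - off1[in_gap]
    use_left <- dist_left <= dist_right & left_off2 >= 0L
    r2_len <- cigar_r2_len(blocks)
    off2[in_gap] <- pmin(ifelse(use_left, left_off2, right_off2), r2_len - 1L)
  }
  ifelse(is.na(off2), NA_integer_,
         if (dup$strand == "+") dup$start2 + off2 else dup$end2 - 1L - off2)
}

#' Group pairwise duplications into multi-copy families
#'
#' Duplications with more than two copies appear in the table as several
#' overlapping pairwise records. This takes the transitive closure of the
#' interval-overlap relation between records and returns, for each connected
#' family, the merged list of member copies.
#'
#' @param dups Rows of a `homology_table`.
#' @return A list of tibbles, one per family, each with columns `contig`,
#'   `start`, `end` listing all (merged) copies of the family.
#' @export
merge_multicopy <- function(dups) {
  n <- nrow(dups)
  if (n == 0) return(list())
  iv <- tibble::tibble(
    contig = c(dups$chrom1, dups$chrom2),
    start = c(dups$start1, dups$start2),
    end = c(dups$end1, dups$end2),
    rec = rep(seq_len(n), 2)
  )
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (ctg in unique(iv$contig)) {
    sub <- iv[iv$contig == ctg, ]
    hits <- IRanges::findOverlaps(IRanges::IRanges(sub$start + 1L, sub$end))
    for (k in seq_along(hits)) {
      union2(sub$rec[S4Vectors::queryHits(hits)[k]],
             sub$rec[S4Vectors::subjectHits(hits)[k]])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(members) {
    sub <- iv[iv$rec %in% members, ]
    out <- lapply(split(sub, sub$contig), function(s) {
      red <- IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))
      tibble::tibble(contig = s$contig[1],
                     start = IRanges::start(red) - 1L,
                     end = IRanges::end(red))
    })
    dplyr::arrange(dplyr::bind_rows(out), .data$contig, .data$start)
  }) |> unname()
}
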