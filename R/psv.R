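#' Extract paralogous sequence variants (PSVs) from a duplication
#'
#' PSVs are the positions at which otherwise near-identical repeat copies
#' differ in the reference assembly. They are read directly off the stored
#' alignment of a duplication: every maximal run of non-matching alignment
#' columns (mismatches and/or indels) becomes one PSV. Indel-containing PSVs
#' are anchored at the preceding matched base (VCF-style left anchor), so
#' applying all PSV alleles of a duplication to the region1 sequence
#' reconstructs the region2 sequence exactly.
#'
#' @param dup A single duplication record (one row of a `homology_table`).
#' @param genome A [Biostrings::DNAStringSet] named by contig.
#' @return A tibble with one row per PSV: `chrom`, `pos` (0-based position
#'   on region1, the primary copy), `allele1` (primary reference allele),
#'   `allele2` (paralog allele, oriented along region1: reverse-complemented
#'   relative to the genome for `-` strand records), `chrom2`, `pos2`
#'   (0-based leftmost genome position of the paralogous allele), `strand`.
#'   Positions are strictly increasing.
#' @export
extract_psvs <- function(dup, genome) {
  stopifnot(nrow(dup) == 1)
  for (ctg in unique(c(dup$chrom1, dup$chrom2))) {
    if (!ctg %in% names(genome)) {
      stop_paracn("contig '%s' not present in the genome", ctg)
    }
  }
  s1 <- as.character(Biostrings::subseq(genome[[dup$chrom1]],
                                        dup$start1 + 1L, dup$end1))
  s2raw <- Biostrings::subseq(genome[[dup$chrom2]], dup$start2 + 1L, dup$end2)
  if (dup$strand == "-") s2raw <- Biostrings::reverseComplement(s2raw)
  s2 <- as.character(s2raw)

  blocks <- cigar_offsets(parse_cigar(dup$cigar))
  run_id <- cumsum(c(TRUE, diff(blocks$op == "=") != 0))
  run_id[blocks$op == "="] <- NA

  out <- list()
  for (rid in unique(stats::na.omit(run_id))) {
    b <- blocks[which(run_id == rid), , drop = FALSE]
    r1_off <- b$r1_off[1]
    r2_off <- b$r2_off[1]
    len1 <- sum(b$len[b$op %in% c("X", "M", "D")])
    len2 <- sum(b$len[b$op %in% c("X", "M", "I")])
    if (all(b$op %in% c("X", "M"))) {           # substitution run, no anchor
      a1 <- substr(s1, r1_off + 1L, r1_off + len1)
      a2 <- substr(s2, r2_off + 1L, r2_off + len2)
      pos <- dup$start1 + r1_off
    } else {                                    # indel: left-anchored
      if (r1_off == 0L || r2_off == 0L) {
        warning("indel at alignment start has no anchor base; PSV skipped")
        next
      }
      a1 <- substr(s1, r1_off, r1_off + len1)
      a2 <- substr(s2, r2_off, r2_off + len2)
      pos <- dup$start1 + r1_off - 1L
      r2_off <- r2_off - 1L
      len2 <- len2 + 1L
    }
    if (a1 == a2) next                          # 'M' columns that agree
    pos2 <- if (dup$strand == "+") dup$start2 + r2_off
            else dup$end2 - r2_off - len2
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = dup$chrom1, pos = as.integer(pos), allele1 = a1, allele2 = a2,
      chrom2 = dup$chrom2, pos2 = as.integer(pos2), strand = dup$strand
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    chrom = character(), pos = integer(), allele1 = character(),
    allele2 = character(), chrom2 = character(), pos2 = integer(),
    strand = character()
  )
  dplyr::arrange(res, .data$pos)
}

#' Extend PSV allele lists to every copy of a multi-copy family
#'
#' For duplications with more than two copies, the allele list of each PSV
#' must carry one allele per copy. Given the pairwise duplications that link
#' the primary copy to each other copy, this projects every substitution PSV
#' position onto each copy and reads the reference allele there.
#'
#' @param psvs A tibble of PSVs on the primary copy (union over the pairwise
#'   duplications, e.g. from [extract_psvs()]).
#' @param dups Duplication records all having the primary copy as region1,
#'   one per additional copy, ordered as the copies are ordered.
#' @param genome A [Biostrings::DNAStringSet].
#' @return The PSV tibble with a list-column `alleles`: for each PSV a
#'   character vector of length `nrow(dups) + 1` (primary allele first).
#'   Indel PSVs (allele lengths differing) get `NA` for copies other than
#'   the pair they were called from.
#' @export
extend_psvs <- function(psvs, dups, genome) {
  m <- nrow(dups)
  psvs <- dplyr::distinct(psvs, .data$pos, .keep_all = TRUE) |>
    dplyr::arrange(.data$pos)
  alleles <- vector("list", nrow(psvs))
  for (i in seq_len(nrow(psvs))) {
    a <- c(psvs$allele1[i], rep(NA_character_, m))
    w <- nchar(psvs$allele1[i])
    if (w == nchar(psvs$allele2[i])) {          # substitution PSV
      for (k in seq_len(m)) {
        dup <- dups[k, , drop = FALSE]
        p2 <- project_position(dup, psvs$pos[i], gap = "marker")
        if (is.na(p2)) next
        left <- if (dup$strand == "+") p2 else p2 - w + 1L
        seg <- Biostrings::subseq(genome[[dup$chrom2]], left + 1L, left + w)
        if (dup$strand == "-") seg <- Biostrings::reverseComplement(seg)
        a[k + 1L] <- as.character(seg)
      }
    }
    alleles[[i]] <- a
  }
  psvs$alleles <- alleles
  psvs
}
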