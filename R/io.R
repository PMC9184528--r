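#' Read pairwise self-alignment records from a PAF file
#'
#' Reads minimap2-style PAF with `cg:Z:` CIGAR tags. The PAF query becomes
#' region1 and the target region2; since PAF CIGARs are written in
#' query-consumption convention, `I`/`D` are swapped on input to match the
#' package's region1-as-reference convention (see [parse_cigar()]).
#'
#' @param path PAF file path.
#' @return Tibble of records for [build_table()].
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    tibble::tibble(
      chrom1 = f[1], start1 = as.integer(f[3]), end1 = as.integer(f[4]),
      strand = f[5],
      chrom2 = f[6], start2 = as.integer(f[8]), end2 = as.integer(f[9]),
      cigar = if (length(cg)) cigar_swap_io(sub("^cg:Z:", "", cg[1])) else NA_character_
    )
  })
  dplyr::bind_rows(recs)
}

#' Write self-alignment records as PAF
#'
#' @param records Record tibble (see [build_table()]).
#' @param path Output path.
#' @param contig_lengths Named integer vector of contig lengths.
#' @export
write_paf <- function(records, path, contig_lengths) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    blocks <- parse_cigar(r$cigar)
    nmatch <- sum(blocks$len[blocks$op == "="])
    paste(r$chrom1, contig_lengths[[r$chrom1]], r$start1, r$end1, r$strand,
          r$chrom2, contig_lengths[[r$chrom2]], r$start2, r$end2,
          nmatch, sum(blocks$len), 60,
          paste0("cg:Z:", cigar_swap_io(r$cigar)), sep = "\t")
  }, character(1))
  readr::write_lines(lines, path)
}

# I<->D swap between PAF query convention and the internal convention
cigar_swap_io <- function(cigar) {
  blocks <- parse_cigar(cigar)
  op <- blocks$op
  op[blocks$op == "D"] <- "I"
  op[blocks$op == "I"] <- "D"
  paste0(blocks$len, op, collapse = "")
}

#' Serialize / load a homology table
#'
#' The table is stored as a BED-like TSV (region1 as the first three
#' columns, then region2 with strand, length, similarity, CIGAR and the
#' tangled flag) with the genome id in a header comment. The round trip is
#' lossless.
#'
#' @param table A `homology_table`.
#' @param path File path (`.tsv`; plain text).
#' @export
write_homology_table <- function(table, path) {
  readr::write_lines(sprintf("#genome_id=%s", attr(table, "genome_id") %||% "unknown"), path)
  df <- tibble::as_tibble(table)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_homology_table
#' @export
read_homology_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  gid <- if (startsWith(first, "#genome_id=")) sub("^#genome_id=", "", first) else "unknown"
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          dup_id = "i", chrom1 = "c", start1 = "i", end1 = "i",
                          chrom2 = "c", start2 = "i", end2 = "i", strand = "c",
                          length = "i", similarity = "d", cigar = "c",
                          tangled = "l"))
  for (i in seq_len(nrow(df))) {   # integrity: CIGAR lengths match intervals
    blocks <- parse_cigar(df$cigar[i])
    if (cigar_r1_len(blocks) != df$end1[i] - df$start1[i] ||
        cigar_r2_len(blocks) != df$end2[i] - df$start2[i]) {
      stop_paracn("corrupt homology table: CIGAR/interval mismatch at record %d", i)
    }
  }
  new_homology_table(df, gid)
}

#' Write PSVs as a VCF-like table
#'
#' One line per PSV on the primary copy: 1-based POS, REF = primary allele,
#' ALT = paralog allele(s), INFO carrying the paralogous position(s).
#'
#' @param psvs PSV tibble from [extract_psvs()].
#' @param path Output path.
#' @export
write_psvs <- function(psvs, path) {
  hdr <- c("##fileformat=VCFv4.2-like",
           "#CHROM\tPOS\tID\tREF\tALT\tINFO")
  body <- vapply(seq_len(nrow(psvs)), function(i) {
    p <- psvs[i, ]
    sprintf("%s\t%d\tpsv%d\t%s\t%s\tPOS2=%s:%d;STRAND=%s",
            p$chrom, p$pos + 1L, i, p$allele1, p$allele2,
            p$chrom2, p$pos2 + 1L, p$strand)
  }, character(1))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write alignment records as SAM text
#'
#' @param reads [Alignment records][alignment_records] (one contig set).
#' @param contig_lengths Named integer vector.
#' @param path Output `.sam` path.
#' @param read_len Read length for the CIGAR (records carry spans only).
#' @export
write_sam <- function(reads, contig_lengths, path, read_len = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths), contig_lengths))
  reads <- dplyr::arrange(reads, .data$contig, .data$start)
  # mates are rank-matched within (sample, contig): the k-th first read
  # pairs with the k-th second read
  pair_id <- stats::ave(seq_len(nrow(reads)),
                        reads$sample, reads$contig, reads$first,
                        FUN = seq_along)
  key <- paste(reads$sample, reads$contig, pair_id)
  key_first <- key[reads$first]
  key_second <- key[!reads$first]
  idx_first <- which(reads$first)
  idx_second <- which(!reads$first)
  mate <- integer(nrow(reads))
  mate[idx_first] <- idx_second[match(key[idx_first], key_second)]
  mate[idx_second] <- idx_first[match(key[idx_second], key_first)]
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    flag <- 0L
    if (r$paired) {
      flag <- flag + 1L + (if (r$proper) 2L else 0L) +
        (if (r$first) 64L else 128L + 16L) + (if (r$first) 32L else 0L)
    }
    len <- r$end - r$start
    cig <- if (r$clipped) sprintf("10S%dM", len - 10L) else sprintf("%dM", len)
    mi <- mate[i]
    pnext <- if (r$paired && !is.na(mi)) reads$start[mi] + 1L else 0L
    tlen <- if (r$paired && !is.na(mi)) {
      span <- max(r$end, reads$end[mi]) - min(r$start, reads$start[mi])
      if (r$first) span else -span
    } else 0L
    paste(sprintf("%s_p%06d", r$sample, pair_id[i]), flag, r$contig,
          r$start + 1L, r$mapq, cig,
          if (r$paired && !is.na(mi)) "=" else "*", pnext, tlen, "*", "*",
          sep = "\t")
  }, character(1))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from a BAM file
#'
#' Thin wrapper over `Rsamtools::scanBam()` producing the package's
#' [alignment record][alignment_records] tibble. The first-in-genome read
#' of each pair is identified by a positive template length.
#'
#' @param bam Path to an indexed BAM.
#' @param sample Sample label attached to the records.
#' @return Alignment-record tibble.
#' @export
read_alignments <- function(bam, sample = basename(bam)) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_paracn("reading BAM requires the Rsamtools package")
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag", "cigar", "isize")))[[1]]
  ref_len <- vapply(res$cigar, function(cg) {
    cigar_r1_len(parse_cigar(cg))
  }, integer(1), USE.NAMES = FALSE)
  flag <- res$flag
  paired <- bitwAnd(flag, 1L) > 0
  tibble::tibble(
    contig = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + ref_len,
    mapq = res$mapq,
    proper = bitwAnd(flag, 2L) > 0,
    clipped = grepl("S", res$cigar, fixed = TRUE),
    paired = paired,
    first = ifelse(paired, res$isize > 0, TRUE),
    sample = sample
  ) |> dplyr::arrange(.data$contig, .data$start)
}

#' Persist / load frozen model parameters
#'
#' Model parameters from a multi-sample fit (initial distribution, jump
#' parameters, window scale factors, state space and window layout, plus
#' optionally the PSV frequency matrix) are stored as JSON for later
#' single-sample genotyping.
#'
#' @param fit An `agcn_fit`, or its `params` list.
#' @param path JSON path.
#' @param pscn Optional `pscn_fit` whose `f` matrix is embedded.
#' @export
write_model_params <- function(fit, path, pscn = NULL) {
  params <- if (inherits(fit, "agcn_fit")) fit$params else fit
  obj <- list(
    pi = params$pi, a_up = params$a_up, a_down = params$a_down,
    m = params$m, states = params$states, ref_cn = params$ref_cn,
    layout = as.data.frame(params$layout)
  )
  if (!is.null(pscn) && is.null(pscn$skip)) {
    obj$f <- as.data.frame(tibble::as_tibble(pscn$f_mat, rownames = "psv"))
    obj$reliable <- unname(pscn$reliable)
    obj$eps <- pscn$eps
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- list(pi = obj$pi, a_up = obj$a_up, a_down = obj$a_down,
                 m = obj$m, states = as.integer(obj$states),
                 ref_cn = as.integer(obj$ref_cn),
                 layout = tibble::as_tibble(obj$layout))
  if (!is.null(obj$f)) {
    f_mat <- as.matrix(obj$f[, -1, drop = FALSE])
    rownames(f_mat) <- obj$f$psv
    params$f_mat <- f_mat
    params$reliable <- obj$reliable
    params$eps <- obj$eps
  }
  params
}

#' Write / read an aggregate depth matrix as TSV
#'
#' Window metadata columns first, then one count column per sample.
#'
#' @param depth An `agg_depth`.
#' @param path TSV path.
#' @export
write_depth_matrix <- function(depth, path) {
  df <- dplyr::bind_cols(depth$windows,
                         tibble::as_tibble(depth$counts))
  attr(df, "ref_cn") <- NULL
  readr::write_lines(sprintf("#ref_cn=%d", depth$ref_cn), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  ref_cn <- if (startsWith(first, "#ref_cn=")) as.integer(sub("#ref_cn=", "", first)) else 2L
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  meta_cols <- intersect(c("contig", "start", "end", "gc_percent", "segment", "keep"),
                         names(df))
  win <- df[, meta_cols]
  counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  new_agg_depth(win, counts, ref_cn = ref_cn)
}
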