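#' CIGAR strings for stored duplication alignments
#'
#' Each duplication stores a pairwise alignment between its two copies as a
#' CIGAR-like string. The convention used throughout the package is that
#' **region1 is the reference-like side** of the alignment:
#'
#' * `=` / `X` / `M` consume one base on both regions (match / mismatch /
#'   unspecified),
#' * `D` consumes region1 only (bases present on region1, absent from
#'   region2),
#' * `I` consumes region2 only (bases inserted on region2).
#'
#' PAF `cg:Z:` tags use the opposite (query-consumption) convention with the
#' query as region1; [read_paf()] swaps `I`/`D` on input so that stored
#' records always follow the convention above.
#'
#' @param cigar A CIGAR string, e.g. `"120=1X30=2D10="`.
#' @return `parse_cigar()`: a data frame with columns `op` and `len`.
#' @keywords internal
#' @name cigar
NULL

#' @rdname cigar
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) {
    return(data.frame(op = character(), len = integer()))
  }
  ops <- stringr::str_extract_all(cigar, "\\d+[=XMIDNSH]")[[1]]
  if (sum(nchar(ops)) != nchar(cigar)) {
    stop_paracn("malformed CIGAR string: '%s'", cigar)
  }
  data.frame(
    op = stringr::str_sub(ops, -1L),
    len = as.integer(stringr::str_sub(ops, 1L, -2L))
  )
}

# lengths consumed on each side (region1 = reference-like side)
cigar_r1_len <- function(blocks) sum(blocks$len[blocks$op %in% c("=", "X", "M", "D")])
cigar_r2_len <- function(blocks) sum(blocks$len[blocks$op %in% c("=", "X", "M", "I")])

# fraction of matching columns among all aligned columns (indels included)
cigar_similarity <- function(blocks) {
  if (nrow(blocks) == 0) return(NA_real_)
  if (any(blocks$op == "M")) return(NA_real_)   # match state unknown
  sum(blocks$len[blocks$op == "="]) / sum(blocks$len)
}

# blocks with cumulative start offsets on both sides
cigar_offsets <- function(blocks) {
  r1 <- ifelse(blocks$op %in% c("=", "X", "M", "D"), blocks$len, 0L)
  r2 <- ifelse(blocks$op %in% c("=", "X", "M", "I"), blocks$len, 0L)
  blocks$r1_off <- cumsum(c(0L, r1))[seq_len(nrow(blocks))]
  blocks$r2_off <- cumsum(c(0L, r2))[seq_len(nrow(blocks))]
  blocks
}

# swap the two sides of an alignment: D <-> I.  For '-' strand records the
# column order over region2 runs right-to-left, so the op order is reversed
# to keep region2 (the new region1) walked left-to-right in genome space.
cigar_swap <- function(cigar, strand = "+") {
  blocks <- parse_cigar(cigar)
  op <- blocks$op
  op[blocks$op == "D"] <- "I"
  op[blocks$op == "I"] <- "D"
  blocks$op <- op
  if (strand == "-") blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  paste0(blocks$len, blocks$op, collapse = "")
}
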