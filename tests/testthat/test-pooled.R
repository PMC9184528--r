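# toy genome with one 5 kb two-copy duplication used throughout
pooled_sim <- function(seed = 31, ...) {
  sim <- sim_genome(seed = seed, ...)
  list(sim = sim, table = build_table(sim$records))
}

test_that("loci split into segments of constant reference copy number", {
  ps <- pooled_sim()
  cp <- ps$sim$copies
  # locus with no duplications: single segment at reference CN 2
  far <- tibble::tibble(contig = cp$contig[1], start = 0L, end = 2000L)
  seg0 <- segment_locus(far, ps$table)
  expect_equal(seg0$ref_cn, 2L)
  expect_equal(nrow(seg0), 1L)

  # locus fully inside a two-copy duplication: reference CN 4
  inside <- tibble::tibble(contig = cp$contig[1], start = cp$start[1],
                           end = cp$end[1])
  seg1 <- segment_locus(inside, ps$table)
  expect_equal(seg1$ref_cn, 4L)
  expect_equal(nrow(seg1$copies[[1]]), 2L)

  # duplication covering the middle of the locus: CN 2, 4, 2
  wide <- tibble::tibble(contig = cp$contig[1], start = cp$start[1] - 1000L,
                         end = cp$end[1] + 1000L)
  seg2 <- segment_locus(wide, ps$table)
  expect_equal(seg2$ref_cn, c(2L, 4L, 2L))
  # partition: contiguous and covering
  expect_equal(seg2$start[-1], seg2$end[-nrow(seg2)])
  expect_equal(c(seg2$start[1], seg2$end[nrow(seg2)]), c(wide$start, wide$end))

  # duplications shorter than 500 bp are skipped
  short <- pooled_sim(seed = 32, copy_length = 400)
  loc <- tibble::tibble(contig = "sim1", start = short$sim$copies$start[1] - 500L,
                        end = short$sim$copies$end[1] + 500L)
  expect_equal(segment_locus(loc, short$table)$ref_cn, 2L)
})

test_that("segment grouping uses a strict 2 kb gap rule", {
  seg <- tibble::tibble(
    contig = "c1", start = c(0L, 5000L, 6999L), end = c(1000L, 5100L, 8000L),
    ref_cn = c(4L, 2L, 4L), copies = list(NULL, NULL, NULL)
  )
  # gap between the CN-4 segments: 6999 - 1000 = 5999 -> separate groups
  g1 <- group_segments(seg)
  expect_equal(g1$group[1] == g1$group[3], FALSE)
  # gap of 1999 bp: one group, the interrupting CN-2 segment stays apart
  seg2 <- dplyr::mutate(seg, start = c(0L, 1200L, 2999L), end = c(1000L, 2500L, 4000L))
  g2 <- group_segments(seg2)
  expect_true(g2$group[1] == g2$group[3])
  expect_false(g2$group[2] %in% g2$group[c(1, 3)])
  # gap of exactly 2000 bp: two groups
  seg3 <- dplyr::mutate(seg, start = c(0L, 1200L, 3000L), end = c(1000L, 2500L, 4000L))
  g3 <- group_segments(seg3)
  expect_false(g3$group[1] == g3$group[3])
  # single segment: single group
  expect_equal(group_segments(seg[1, ])$group, 1L)
})

test_that("reads from all copies pool onto the primary copy additively", {
  ps <- pooled_sim(seed = 33, psv_density = 1)
  cp <- ps$sim$copies
  loc <- tibble::tibble(contig = cp$contig[1], start = cp$start[1], end = cp$end[1])
  grp <- group_segments(segment_locus(loc, ps$table))
  r1 <- sim_reads(1, cp$contig[1], cp$start[1], cp$end[1], 300, sample = "sA")
  r2 <- sim_reads(2, cp$contig[1], cp$start[2], cp$end[2], 200, sample = "sA")
  reads <- dplyr::arrange(dplyr::bind_rows(r1, r2), contig, start)
  depth <- pool_and_count(grp, reads, ps$table, ps$sim$genome)
  # conservation: pairs landing in the windowed span are all counted
  expect_equal(sum(depth$counts[, "sA"]), 500, tolerance = 0.03)
  expect_s3_class(depth$windows, "tbl_df")

  # empty read set: zero matrix
  d0 <- pool_and_count(grp, reads[0, ], ps$table, ps$sim$genome)
  expect_true(all(d0$counts == 0))
})

test_that("pooling two copies sequenced at depth d gives window means near 2d", {
  ps <- pooled_sim(seed = 34, copy_length = 6000, psv_density = 1)
  cp <- ps$sim$copies
  loc <- tibble::tibble(contig = cp$contig[1], start = cp$start[1], end = cp$end[1])
  grp <- group_segments(segment_locus(loc, ps$table))
  # ~10 pairs per 100 bp window on each copy
  n_pairs <- 10 * 6000 / 100
  reads <- dplyr::arrange(dplyr::bind_rows(
    sim_reads(11, cp$contig[1], cp$start[1], cp$end[1], n_pairs, sample = "sA"),
    sim_reads(12, cp$contig[1], cp$start[2], cp$end[2], n_pairs, sample = "sA")
  ), contig, start)
  depth <- pool_and_count(grp, reads, ps$table, ps$sim$genome)
  inner <- depth$counts[5:(nrow(depth$windows) - 5), 1]   # avoid edge loss
  expect_equal(mean(inner), 20, tolerance = 0.10)
})

test_that("window filtering drops >10%-irregular windows with their neighbors", {
  win <- make_windows("c1", 0L, 1000L, 100)
  win$segment <- 1L; win$gc_percent <- 45L; win$keep <- TRUE
  counts <- matrix(10L, 10, 100)
  irr <- matrix(FALSE, 10, 100)
  irr[5, 1:11] <- TRUE                       # irregular in 11% of samples
  d <- paracn:::new_agg_depth(win, counts, irr, ref_cn = 4L)
  expect_equal(which(!filter_windows(d)$windows$keep), 4:6)
  # exactly 10%: kept
  irr[5, ] <- FALSE; irr[5, 1:10] <- TRUE
  d2 <- paracn:::new_agg_depth(win, counts, irr, ref_cn = 4L)
  expect_true(all(filter_windows(d2)$windows$keep))
  # all windows dropped is an error
  irr[, ] <- TRUE
  d3 <- paracn:::new_agg_depth(win, counts, irr, ref_cn = 4L)
  expect_error(filter_windows(d3), "no usable windows")
})

test_that("reads whose projected center hits an alignment gap take the nearest base", {
  # duplication with a 20 bp gap in region2, covered by reads on region2
  s <- paste(rep("ACGT", 500), collapse = "")          # 2000 bp
  seq1 <- substr(s, 1, 1000)
  seq2 <- paste0(substr(seq1, 1, 490), substr(seq1, 511, 1000))   # 980 bp
  pad <- paste(rep("T", 500), collapse = "")
  g <- Biostrings::DNAStringSet(c(gg = paste0(seq1, pad, seq2, pad)))
  dup <- tibble::tibble(dup_id = 1L, chrom1 = "gg", start1 = 0L, end1 = 1000L,
                        chrom2 = "gg", start2 = 1500L, end2 = 2480L,
                        strand = "+", length = 1000L, similarity = 0.98,
                        cigar = "490=20D490=", tangled = FALSE)
  tbl <- paracn:::new_homology_table(dup, "toy")
  loc <- tibble::tibble(contig = "gg", start = 0L, end = 1000L)
  grp <- group_segments(segment_locus(loc, tbl))
  # one pair on region2 with first-read center just right of the gap
  reads <- tibble::tibble(contig = "gg", start = 1920L, end = 2020L, mapq = 60L,
                          proper = TRUE, clipped = FALSE, paired = FALSE,
                          first = TRUE, sample = "sA")
  depth <- pool_and_count(grp, reads, tbl, g)
  # center 1970 -> region2 offset 470 -> region1 470: window [400,500)
  expect_equal(which(depth$counts[, 1] == 1L), 5L)
})
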