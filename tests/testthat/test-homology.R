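test_that("build_table filters records and handles empty input", {
  empty <- build_table(tibble::tibble(), min_length = 500, min_similarity = 0.97)
  expect_s3_class(empty, "homology_table")
  expect_equal(nrow(empty), 0L)

  rec <- tibble::tibble(
    chrom1 = "c1", start1 = 1000L, end1 = 1600L,
    chrom2 = "c1", start2 = 9000L, end2 = 9600L,
    strand = "+", cigar = "600="
  )
  tbl <- build_table(rec, min_length = 500, min_similarity = 0.97)
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$similarity, 1.0)
  expect_false(tbl$tangled)

  # below min length or similarity: excluded
  short <- dplyr::mutate(rec, end1 = start1 + 400L, end2 = start2 + 400L,
                         cigar = "400=")
  expect_equal(nrow(build_table(short)), 0L)
  dissim <- dplyr::mutate(rec, cigar = "300=30X270=")  # 95% similar
  expect_equal(nrow(build_table(dissim, min_similarity = 0.97)), 0L)
  expect_equal(nrow(build_table(dissim, min_similarity = 0.95)), 1L)
})

test_that("malformed CIGARs are rejected with a logged reason", {
  bad <- tibble::tibble(
    chrom1 = "c1", start1 = 0L, end1 = 600L,
    chrom2 = "c1", start2 = 9000L, end2 = 9600L,
    strand = "+", cigar = "599="     # consumes 599, interval is 600
  )
  expect_message(tbl <- build_table(bad), "rejected")
  expect_equal(nrow(tbl), 0L)
})

test_that("sequences in more than 10 pairwise alignments are flagged tangled", {
  # one 600 bp segment aligned to 11 distinct partners
  recs <- tibble::tibble(
    chrom1 = "c1", start1 = 0L, end1 = 600L,
    chrom2 = "c1", start2 = 10000L * (1:11), end2 = 10000L * (1:11) + 600L,
    strand = "+", cigar = "600="
  )
  tbl <- build_table(recs)
  expect_equal(nrow(tbl), 11L)
  expect_true(all(tbl$tangled))
  # tangled records stay in the table but are excluded from queries (warning)
  expect_warning(hits <- dups_overlapping(tbl, "c1", 0, 600), "tangled")
  expect_equal(nrow(hits), 0L)
  # with 10 partners nothing is flagged
  tbl10 <- build_table(recs[1:10, ])
  expect_false(any(tbl10$tangled))
})

test_that("project_position follows the alignment", {
  dup <- tibble::tibble(
    dup_id = 1L, chrom1 = "c1", start1 = 0L, end1 = 100L,
    chrom2 = "c1", start2 = 5000L, end2 = 5100L, strand = "+",
    length = 100L, similarity = 1, cigar = "100=", tangled = FALSE
  )
  expect_equal(project_position(dup, 10L), 5010L)

  # 1 bp of region1 absent from region2 after 10 matched bases
  del <- dplyr::mutate(dup, end1 = 21L, end2 = 5020L, cigar = "10=1D10=")
  expect_equal(project_position(del, 15L), 5000L + 14L)
  expect_true(is.na(project_position(del, 10L)))              # gap marker
  expect_equal(project_position(del, 10L, gap = "nearest"), 5009L)
  expect_error(project_position(del, 30L), "outside region1")
})

test_that("projection and back-projection are inverse on match columns", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      cig <- random_cigar()
      blocks <- paracn:::parse_cigar(cig)
      l1 <- paracn:::cigar_r1_len(blocks)
      l2 <- paracn:::cigar_r2_len(blocks)
      strand <- sample(c("+", "-"), 1)
      dup <- tibble::tibble(
        dup_id = 1L, chrom1 = "c1", start1 = 100L, end1 = 100L + l1,
        chrom2 = "c2", start2 = 2000L, end2 = 2000L + l2, strand = strand,
        length = l1, similarity = 1, cigar = cig, tangled = FALSE
      )
      pos <- 100L + seq(0L, l1 - 1L)
      fwd <- project_position(dup, pos, gap = "marker")
      back <- dup_swap(dup)
      ok <- !is.na(fwd)
      expect_gt(sum(ok), 0)
      expect_equal(project_position(back, fwd[ok], gap = "marker"), pos[ok])
    }
  })
})

test_that("multi-copy grouping equals connected components of the overlap graph", {
  mk <- function(c1, s1, c2, s2, len = 600L) tibble::tibble(
    dup_id = NA_integer_, chrom1 = c1, start1 = s1, end1 = s1 + len,
    chrom2 = c2, start2 = s2, end2 = s2 + len, strand = "+",
    length = len, similarity = 1, cigar = sprintf("%d=", len), tangled = FALSE
  )
  # A<->B and B<->C overlap on B: one family {A,B,C}
  d <- dplyr::bind_rows(mk("c1", 0L, "c1", 10000L), mk("c1", 10000L, "c1", 20000L))
  d$dup_id <- 1:2
  fam <- merge_multicopy(d)
  expect_length(fam, 1)
  expect_equal(nrow(fam[[1]]), 3L)
  # disjoint pairs: two families
  d2 <- dplyr::bind_rows(mk("c1", 0L, "c1", 10000L), mk("c1", 30000L, "c1", 40000L))
  d2$dup_id <- 1:2
  expect_length(merge_multicopy(d2), 2)
  # single pair: one family of two copies
  d3 <- mk("c1", 0L, "c1", 10000L); d3$dup_id <- 1L
  fam3 <- merge_multicopy(d3)
  expect_length(fam3, 1)
  expect_equal(nrow(fam3[[1]]), 2L)

  # randomized: number of families equals graph components
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(3:12, 1)
      d <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        mk("c1", sample(0:40, 1) * 1000L, "c1", sample(0:40, 1) * 1000L)
      }))
      d$dup_id <- seq_len(n)
      expect_length(merge_multicopy(d), length(unique(overlap_components(d))))
    }
  })
})

test_that("homology table serialization round-trips losslessly", {
  g <- sim_genome(seed = 11, psv_density = 2, psv_indel_frac = 0.2)
  tbl <- build_table(g$records, genome_id = "toy1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_homology_table(tbl, path)
  back <- read_homology_table(path)
  expect_equal(attr(back, "genome_id"), "toy1")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tbl))
})

test_that("interval queries return exactly the overlapping duplications", {
  g <- sim_genome(seed = 3, n_copies = 3)
  tbl <- build_table(g$records)
  cp <- g$copies
  hits <- dups_overlapping(tbl, cp$contig[1], cp$start[1], cp$end[1])
  expect_equal(nrow(hits), 2L)     # primary pairs with copies 2 and 3
  # query on copy 2 returns swapped records with region1 on copy 2
  hits2 <- dups_overlapping(tbl, cp$contig[2], cp$start[2], cp$end[2])
  expect_true(all(hits2$start1 >= cp$start[2] - 10 & hits2$end1 <= cp$end[2] + 10))
  # far away: nothing
  expect_equal(nrow(dups_overlapping(tbl, "sim1", 0, 50)), 0L)
})
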