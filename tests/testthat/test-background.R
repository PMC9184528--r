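mkread <- function(start, end, mapq = 60L, proper = TRUE, clipped = FALSE,
                   paired = TRUE, first = TRUE, contig = "c1") {
  tibble::tibble(contig = contig, start = start, end = end, mapq = mapq,
                 proper = proper, clipped = clipped, paired = paired,
                 first = first, sample = "s1")
}

test_that("read pairs are counted by the first-read-center rule", {
  win <- make_windows("c1", 0L, 200L, size = 100)
  # pair whose first read spans [100,200): center 150 -> second window
  reads <- dplyr::bind_rows(mkread(100L, 200L), mkread(300L, 400L, first = FALSE))
  cnt <- assign_reads(dplyr::arrange(reads, start), win)
  expect_equal(cnt$read_count, c(0L, 1L))

  # empty input: all zero
  cnt0 <- assign_reads(mkread(integer(0), integer(0)), win)
  expect_equal(cnt0$read_count, c(0L, 0L))

  # center exactly at a window start belongs to that window (half-open)
  reads2 <- mkread(50L, 150L)   # center 100
  expect_equal(assign_reads(reads2, win)$read_count, c(0L, 1L))

  # unsorted input is rejected
  bad <- dplyr::bind_rows(mkread(300L, 400L), mkread(100L, 200L))
  expect_error(assign_reads(bad, win), "sorted")
})

test_that("unpaired reads count by their own center and totals are conserved", {
  win <- make_windows("c1", 0L, 1000L, size = 100)
  withr::with_seed(5, {
    n <- 300
    s <- sort(sample(0:850, n, replace = TRUE))
    reads <- mkread(as.integer(s), as.integer(s + 100L),
                    paired = sample(c(TRUE, FALSE), n, replace = TRUE))
    reads$first <- TRUE
    cnt <- assign_reads(reads, win)
    expect_equal(sum(cnt$read_count), n)   # every unit lands in some window
  })
})

test_that("irregular windows follow the 10% rule", {
  expect_true(flag_irregular(10 / 100, 0, 0))      # exactly 10% is irregular
  expect_false(flag_irregular(0, 0, 9 / 100))      # 9% clipped: regular
  expect_false(flag_irregular(0, 0, 0))            # clean window
  expect_true(flag_irregular(0, 0.5, 0))
  # zero-read windows are regular: fractions are defined as 0
  win <- make_windows("c1", 0L, 100L, 100)
  cnt <- assign_reads(mkread(integer(0), integer(0)), win)
  expect_false(cnt$irregular)
})

test_that("background windows avoid duplications with a 500 bp buffer", {
  sim <- sim_genome(seed = 8, copy_length = 1000, flank = 8000, spacer = 3000)
  tbl <- build_table(sim$records)
  win <- select_background_windows(sim$genome, tbl)
  # no window within 500 bp of either copy
  for (i in seq_len(nrow(sim$copies))) {
    expect_false(any(win$start < sim$copies$end[i] + 500 &
                       win$end > sim$copies$start[i] - 500))
  }
  # all-unique genome with a target count
  g <- sim_genome(seed = 9, psv_density = 0, n_copies = 2,
                  copy_length = 600, flank = 6000, spacer = 1000)
  empty_tbl <- build_table(tibble::tibble())
  win50 <- select_background_windows(g$genome, empty_tbl, target_count = 50)
  expect_equal(nrow(win50), 50L)
  expect_true(all(diff(win50$start) >= 100))       # non-overlapping

  # extreme-GC windows are recruited only from the neighborhood
  regions <- tibble::tibble(contig = names(g$genome), start = 6000L, end = 8000L)
  wnb <- select_background_windows(g$genome, empty_tbl, regions = regions)
  outside <- wnb[wnb$start < 6000 | wnb$start >= 8000, ]
  if (nrow(outside)) {
    expect_true(all(outside$gc_percent <= 35 | outside$gc_percent >= 55))
  }
})

test_that("NB fitting recovers simulated parameters by maximum likelihood", {
  withr::with_seed(101, {
    x <- rnbinom(10000, size = 10, prob = 0.4)   # mean 15
    d <- tibble::tibble(gc_percent = 40L, read_count = x, irregular = FALSE)
    m <- fit_nb(d)
    row <- m[m$gc_percent == 40, ]
    expect_lt(abs(row$size - 10) / 10, 0.10)
    expect_lt(abs(row$mean - 15) / 15, 0.02)
    # agreement with an independent ML fitter
    ref <- MASS::fitdistr(x, "negative binomial")
    expect_lt(abs(row$size - ref$estimate[["size"]]) / ref$estimate[["size"]], 0.01)
    # fitted likelihood is at least the moment-matched likelihood
    mm_size <- mean(x)^2 / (var(x) - mean(x))
    ll <- function(size) sum(dnbinom(x, size = size, mu = mean(x), log = TRUE))
    expect_gte(ll(row$size), ll(mm_size) - 1e-6)
  })
})

test_that("underdispersed counts fall back to the Poisson limit", {
  d <- tibble::tibble(gc_percent = 40L, read_count = rep(12L, 200), irregular = FALSE)
  m <- fit_nb(d, min_windows = 100)
  row <- m[m$gc_percent == 40, ]
  expect_equal(row$mean, 12)
  expect_gt(row$size, 1e5)
  # all-irregular input is an error
  d$irregular <- TRUE
  expect_error(fit_nb(d), "irregular")
})

test_that("GC strata are fitted separately and sparse strata borrow neighbors", {
  withr::with_seed(55, {
    d <- dplyr::bind_rows(
      tibble::tibble(gc_percent = 35L,
                     read_count = rnbinom(5000, size = 8, mu = 30),
                     irregular = FALSE),
      tibble::tibble(gc_percent = 50L,
                     read_count = rnbinom(5000, size = 8, mu = 15),
                     irregular = FALSE),
      tibble::tibble(gc_percent = 42L,                     # too few to fit
                     read_count = rnbinom(10, size = 8, mu = 22),
                     irregular = FALSE)
    )
    m <- fit_nb(d)
    expect_gt(m$mean[m$gc_percent == 35], m$mean[m$gc_percent == 50])
    expect_false(m$fitted[m$gc_percent == 42])
    # borrowed mean lies between the fitted neighbors
    expect_true(m$mean[m$gc_percent == 42] < m$mean[m$gc_percent == 35] &&
                  m$mean[m$gc_percent == 42] > m$mean[m$gc_percent == 50])
    # lookup matches the table
    expect_equal(nb_lookup(m, c(35, 42, 50))$mean,
                 m$mean[match(c(35, 42, 50), m$gc_percent)])
  })
})

test_that("doubling all counts doubles the fitted mean in every stratum", {
  withr::with_seed(77, {
    d <- dplyr::bind_rows(lapply(c(38L, 45L, 52L), function(g) {
      tibble::tibble(gc_percent = g,
                     read_count = rnbinom(2000, size = 6, mu = 10 + g / 10),
                     irregular = FALSE)
    }))
    m1 <- fit_nb(d)
    m2 <- fit_nb(dplyr::mutate(d, read_count = read_count * 2L))
    f1 <- m1[m1$fitted, ]; f2 <- m2[m2$fitted, ]
    expect_equal(f2$mean / f1$mean, rep(2, nrow(f1)), tolerance = 1e-6)
  })
})
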