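test_that("tuple enumeration matches the stars-and-bars closed form", {
  t44 <- enumerate_tuples(4, 4)
  expect_equal(t44, list(c(0L, 4L), c(1L, 3L), c(2L, 2L), c(3L, 1L), c(4L, 0L)))
  expect_equal(enumerate_tuples(4, 0), list(c(0L, 0L)))
  expect_length(enumerate_tuples(6, 6), 28)              # C(8, 2)
  # closed form over the whole supported range
  for (c_r in c(4L, 6L, 8L)) {
    m <- c_r / 2
    for (c_s in 0:12) {
      tt <- enumerate_tuples(c_r, c_s)
      expect_length(tt, choose(c_s + m - 1, m - 1))
      expect_true(all(vapply(tt, sum, integer(1)) == c_s))
      expect_false(any(duplicated(vapply(tt, tuple_str, character(1)))))
    }
    # at c_s = c_r this also equals choose(3/2 c_r - 1, c_r)
    expect_length(enumerate_tuples(c_r, c_r), choose(3 * c_r / 2 - 1, c_r))
  }
  expect_error(enumerate_tuples(5, 4), "even")
})

test_that("allele probabilities mix copies by dosage and frequency", {
  eps <- 0.01
  # perfect markers, balanced tuple: half the reads per allele
  p <- allele_prob(c(2, 2), c(1, 1), eps = eps)
  expect_equal(p[1], 0.5 * (1 - eps))
  expect_equal(p[2], 0.5 * (1 - eps))
  expect_equal(sum(p), 1)
  # unbalanced tuple: dosage fractions
  p31 <- allele_prob(c(3, 1), c(1, 1), eps = eps)
  expect_equal(p31[1], 0.75 * (1 - eps))
  # copy 2 always carries copy 1's allele when f2 = 0
  p10 <- allele_prob(c(2, 2), c(1, 0), eps = eps)
  expect_equal(p10[1], 1 - eps)
  expect_equal(p10[2], 0)
  # normalization over random inputs
  withr::with_seed(88, {
    for (i in 1:20) {
      m <- sample(2:4, 1)
      t <- as.integer(rmultinom(1, sample(1:8, 1), rep(1, m)))
      if (sum(t) == 0) next
      expect_equal(sum(allele_prob(t, runif(m))), 1, tolerance = 1e-12)
    }
  })
  expect_error(allele_prob(c(0, 0), c(1, 1)), "aggregate CN 0")
})

test_that("relabeling copies permutes allele probabilities consistently", {
  withr::with_seed(12, {
    t <- c(3L, 1L, 2L); f <- c(0.98, 0.7, 1.0)
    p <- allele_prob(t, f)
    perm <- c(2, 3, 1)
    pp <- allele_prob(t[perm], f[perm])
    expect_equal(pp[1:3], p[perm], tolerance = 1e-12)
  })
})

test_that("EM recovers the frequency matrix and classifies reliability", {
  S <- 60; V <- 10
  f_true <- sim_f_matrix(2024, V)
  tuples <- rep(list(c(2L, 2L)), S)
  counts <- sim_psv_counts(7, f_true, tuples, depth = 30)
  fit <- em_fit(counts, c_r = 4, min_samples = 50, n_restarts = 2, seed = 3)
  expect_null(fit$skip)
  # marker-like entries are recovered tightly; polymorphic entries are
  # information-limited and get a looser band
  marker <- f_true >= 0.97
  expect_true(all(abs(fit$f_mat - f_true)[marker] <= 0.05))
  expect_true(all(abs(fit$f_mat - f_true)[!marker] <= 0.25))
  # reliability agrees with truth for rows far from the 0.95 threshold
  # (true 0.97 rows sit ~1 standard error from it at this cohort size)
  clear <- apply(f_true, 1, min) < 0.90 | apply(f_true, 1, min) >= 0.99
  expect_equal(unname(fit$reliable[clear]),
               unname(apply(f_true, 1, min)[clear] >= 0.95))
  # log-likelihood is monotone non-decreasing
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("balanced symmetric counts give a copy-exchange-symmetric fit", {
  S <- 50; V <- 3
  # perfectly balanced deterministic counts at every PSV
  counts <- tidyr::expand_grid(
    sample = sprintf("s%02d", 1:S), psv = sprintf("psv%03d", 1:V),
    allele = c(1L, 2L, 0L))
  counts$count <- ifelse(counts$allele == 0, 0L, 15L)
  fit <- em_fit(counts, c_r = 4, min_samples = 50, n_restarts = 0)
  expect_true(all(abs(fit$f_mat[, 1] - fit$f_mat[, 2]) < 1e-3))
})

test_that("skip rules guard high copy numbers and small cohorts", {
  counts <- tibble::tibble(sample = sprintf("s%02d", 1:10), psv = "psv001",
                           allele = 1L, count = 10L)
  expect_equal(em_fit(counts, c_r = 10)$skip, "ref_cn>8")
  expect_equal(em_fit(counts, c_r = 4)$skip, "too_few_ref_samples")
  # tuple-count cap, checked against the closed form
  expect_equal(em_fit(counts, c_r = 8, max_tuples = 100)$skip, "tuples>500")
})

test_that("reliable PSV classification uses the 0.95 boundary inclusively", {
  expect_true(classify_reliable(c(1.0, 1.0)))
  expect_true(classify_reliable(c(0.95, 0.99)))
  expect_false(classify_reliable(c(0.949, 1.0)))
  m <- rbind(c(1, 1), c(0.95, 0.99), c(0.949, 1))
  expect_equal(unname(classify_reliable(m)), c(TRUE, TRUE, FALSE))
})

test_that("single samples are genotyped from reliable PSVs only", {
  withr::with_seed(77, {
    S <- 55; V <- 6
    f_true <- matrix(1, V, 2)
    tuples <- rep(list(c(2L, 2L)), S)
    counts <- sim_psv_counts(8, f_true, tuples, depth = 30)
    fit <- em_fit(counts, c_r = 4, min_samples = 50, n_restarts = 1, seed = 9)

    # c_s = 3 sample with counts 2:1 favouring copy 1 -> tuple (2,1)
    c31 <- dplyr::bind_rows(lapply(1:V, function(v) tibble::tibble(
      sample = "new1", psv = sprintf("psv%03d", v),
      allele = c(1L, 2L, 0L), count = c(20L, 10L, 0L))))
    call <- genotype_sample(c31, tibble::tibble(sample = "new1", agg_cn = 3L), fit)
    expect_equal(call$paralog_cn, c(2L, 1L))
    expect_equal(unique(call$tuple), "2,1")

    # balanced deep counts at c_s = 4 -> (2,2) with high quality
    c22 <- dplyr::bind_rows(lapply(1:V, function(v) tibble::tibble(
      sample = "new2", psv = sprintf("psv%03d", v),
      allele = c(1L, 2L, 0L), count = c(50L, 50L, 0L))))
    call2 <- genotype_sample(c22, tibble::tibble(sample = "new2", agg_cn = 4L), fit)
    expect_equal(call2$paralog_cn, c(2L, 2L))
    expect_true(all(call2$quality >= 20))

    # skip reasons
    skip1 <- genotype_sample(c22, tibble::tibble(sample = "new2", agg_cn = 4L),
                             fit, max_ref_cn = 2)
    expect_equal(skip1$skip, "ref_cn>8")
    empty <- dplyr::mutate(c22, count = 0L)
    skip2 <- genotype_sample(empty, tibble::tibble(sample = "new2", agg_cn = 4L), fit)
    expect_equal(skip2$skip, "too_few_reliable_psvs")
    # low-quality aggregate CN calls are not genotyped
    expect_message(
      none <- genotype_sample(c22, tibble::tibble(sample = "new2", agg_cn = 4L,
                                                  quality = 5), fit),
      "not genotyped")
    expect_equal(nrow(none), 0L)
  })
})
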