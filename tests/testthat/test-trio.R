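test_that("haploid frequencies deconvolve from diploid calls", {
  # all diploid calls (2,2): haploid mass concentrates on (1,1)
  calls <- tibble::tibble(tuple = rep("2,2", 40), quality = 100)
  fr <- fit_haploid_freqs(calls)
  expect_gte(fr$prob[fr$tuple == "1,1"], 0.99)

  # a 50/50 (2,2)/(1,3) mixture is not a convolution square; the ML fit is
  # the analytic optimum q(1,1) = 3/4, q(0,2) = 1/4
  calls2 <- tibble::tibble(tuple = rep(c("2,2", "1,3"), each = 50), quality = 100)
  fr2 <- fit_haploid_freqs(calls2)
  expect_equal(fr2$prob[fr2$tuple == "1,1"], 0.75, tolerance = 1e-3)
  expect_equal(fr2$prob[fr2$tuple == "0,2"], 0.25, tolerance = 1e-3)

  # goodness of fit: diploids generated by random mating re-convolve to the
  # true diploid law within sampling error
  q_true <- c("1,1" = 0.6, "0,2" = 0.3, "2,1" = 0.1)
  hap_true <- tuple_parse(names(q_true))
  dips <- withr::with_seed(11, {
    vapply(1:400, function(i) {
      h <- hap_true[sample.int(3, 2, replace = TRUE, prob = q_true)]
      tuple_str(h[[1]] + h[[2]])
    }, character(1))
  })
  fr3 <- fit_haploid_freqs(tibble::tibble(tuple = dips, quality = 100))
  hap <- tuple_parse(fr3$tuple)
  reconv <- new.env()
  for (i in seq_along(hap)) for (j in seq_along(hap)) {
    key <- tuple_str(hap[[i]] + hap[[j]])
    prev <- reconv[[key]]
    reconv[[key]] <- (if (is.null(prev)) 0 else prev) + fr3$prob[i] * fr3$prob[j]
  }
  for (key in c("2,2", "1,3", "3,2")) {
    truth <- 0
    for (i in 1:3) for (j in 1:3) {
      if (tuple_str(hap_true[[i]] + hap_true[[j]]) == key) {
        truth <- truth + q_true[i] * q_true[j]
      }
    }
    expect_equal(reconv[[key]], unname(truth), tolerance = 0.1)
  }

  # log-likelihood non-decreasing; support is lexicographically ordered
  expect_true(all(diff(attr(fr2, "loglik_trace")) > -1e-9))
  expect_equal(fr2$tuple, sort(fr2$tuple))

  # too few calls is an error; low-quality calls are dropped first
  expect_error(fit_haploid_freqs(tibble::tibble(tuple = rep("2,2", 10))), "at least")
  lowq <- tibble::tibble(tuple = rep("2,2", 40), quality = c(rep(100, 15), rep(5, 25)))
  expect_error(fit_haploid_freqs(lowq), "at least")
})

test_that("trio probabilities follow Mendelian transmission", {
  delta11 <- structure(tibble::tibble(tuple = "1,1", prob = 1),
                       class = c("haploid_freqs", "tbl_df", "tbl", "data.frame"))
  # everyone (2,2) under delta freqs: certain concordance
  v <- trio_probability("2,2", "2,2", "2,2", delta11)
  expect_equal(v$probability, 1)
  expect_true(v$concordant)
  # child (4,0) cannot arise from (2,2) x (2,2) parents
  v2 <- trio_probability("4,0", "2,2", "2,2", delta11)
  expect_equal(v2$probability, 0)
  expect_false(v2$concordant)
  expect_error(trio_probability("2,2,0", "2,2", "2,2", delta11), "different numbers")
})

test_that("trio probability matches brute-force transmission enumeration", {
  withr::with_seed(606, {
    for (rep in 1:10) {
      m <- 2
      hap <- enumerate_tuples(2 * m, sample(1:2, 1))
      hap <- hap[sample(seq_along(hap), min(4, length(hap)))]
      pr <- rgamma(length(hap), 1) + 0.05
      freqs <- structure(
        tibble::tibble(tuple = vapply(hap, tuple_str, character(1)), prob = pr / sum(pr)),
        class = c("haploid_freqs", "tbl_df", "tbl", "data.frame"))
      mo <- hap[[sample(length(hap), 1)]] + hap[[sample(length(hap), 1)]]
      fa <- hap[[sample(length(hap), 1)]] + hap[[sample(length(hap), 1)]]
      ch <- hap[[sample(length(hap), 1)]] + hap[[sample(length(hap), 1)]]

      # oracle: enumerate ordered haploid pairs per parent with Bayes weights
      qm <- stats::setNames(freqs$prob, freqs$tuple)
      qof <- function(h) { p <- qm[tuple_str(h)]; if (is.na(p)) 0 else unname(p) }
      ordered_pairs <- function(d) {
        out <- list(); wt <- numeric(0)
        for (i in seq_along(hap)) for (j in seq_along(hap)) {
          if (all(hap[[i]] + hap[[j]] == d)) {
            out[[length(out) + 1]] <- c(i, j)
            wt <- c(wt, qof(hap[[i]]) * qof(hap[[j]]))
          }
        }
        list(p = out, w = wt / sum(wt))
      }
      pm <- ordered_pairs(mo); pf <- ordered_pairs(fa)
      p_oracle <- 0
      for (i in seq_along(pm$p)) for (j in seq_along(pf$p)) {
        for (a in pm$p[[i]]) for (b in pf$p[[j]]) {
          if (all(hap[[a]] + hap[[b]] == ch)) {
            p_oracle <- p_oracle + pm$w[i] * pf$w[j] * 0.25
          }
        }
      }
      got <- trio_probability(ch, mo, fa, freqs)$probability
      expect_equal(got, p_oracle, tolerance = 1e-12)
      # mother/father exchangeability
      expect_equal(trio_probability(ch, fa, mo, freqs)$probability, got,
                   tolerance = 1e-12)
    }
  })
})

test_that("simulated Mendelian trios are concordant, spiked children are not", {
  freqs <- structure(
    tibble::tibble(tuple = c("1,1", "0,2", "2,1"), prob = c(0.7, 0.2, 0.1)),
    class = c("haploid_freqs", "tbl_df", "tbl", "data.frame"))
  sim <- sim_trios(99, freqs, n_trios = 120, spike_frac = 0)
  rep <- trio_report(sim$ped, sim$calls)
  expect_gte(mean(rep$concordant), 0.99)

  # children made impossible under concentrated freqs: all discordant
  delta <- structure(tibble::tibble(tuple = "1,1", prob = 1),
                     class = c("haploid_freqs", "tbl_df", "tbl", "data.frame"))
  sim2 <- sim_trios(100, delta, n_trios = 40, spike_frac = 1)
  rep2 <- trio_report(sim2$ped, sim2$calls, freqs = delta)
  expect_true(all(!rep2$concordant))
})
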