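#' Fit GC-stratified negative binomial background depth models
#'
#' Read depth in unique (copy-number 2) regions is modeled per sample with a
#' negative binomial (NB) distribution, one set of parameters per GC-content
#' value, which captures the overdispersion of sequencing depth relative to
#' Poisson. For each GC value with at least `min_windows` regular windows,
#' `(size, prob)` are estimated by maximum likelihood: the mean is profiled
#' (`prob = size / (size + mean)` keeps the fitted mean equal to the
#' empirical mean) and the likelihood is maximized over `log(size)` by 1-D
#' optimization. When the empirical variance does not exceed the mean the
#' fit falls back to the Poisson limit (very large `size`, mean matched).
#' GC values with too few windows borrow parameters from fitted neighbors:
#' the log-mean is interpolated linearly and the dispersion is taken from
#' the nearest fitted GC value.
#'
#' @param depth A tibble of background windows with columns `gc_percent`,
#'   `read_count` and `irregular` (e.g. [assign_reads()] output on windows
#'   from [select_background_windows()]).
#' @param min_windows Minimum number of regular windows for a GC value to
#'   be fitted directly (default 100).
#' @param window_size Window length the counts were tabulated at (recorded
#'   in the model).
#' @param sample Optional sample label.
#' @return An `nb_model`: a tibble with one row per GC percent 0–100 and
#'   columns `gc_percent`, `size`, `prob`, `mean`, `n_windows`, `fitted`.
#' @examples
#' d <- tibble::tibble(gc_percent = 40L,
#'                     read_count = rnbinom(500, size = 10, prob = 0.4),
#'                     irregular = FALSE)
#' fit_nb(d)
#' @export
fit_nb <- function(depth, min_windows = 100, window_size = 100, sample = NA_character_) {
  reg <- depth[!depth$irregular, , drop = FALSE]
  if (nrow(reg) == 0) stop_paracn("all background windows are irregular")
  by_gc <- split(reg$read_count, reg$gc_percent)
  n_win <- vapply(by_gc, length, integer(1))
  gc_vals <- as.integer(names(by_gc))

  fit_gc <- gc_vals[n_win >= min_windows]
  if (!length(fit_gc)) {
    # degenerate toy inputs: fit the single best-covered GC value
    fit_gc <- gc_vals[which.max(n_win)]
  }
  fits <- lapply(as.character(fit_gc), function(g) fit_nb_one(by_gc[[g]]))
  fit_mean <- vapply(fits, `[[`, numeric(1), "mean")
  fit_size <- vapply(fits, `[[`, numeric(1), "size")

  grid <- 0:100
  mean_g <- if (length(fit_gc) == 1) {
    rep(fit_mean, length(grid))
  } else {
    exp(stats::approx(fit_gc, log(pmax(fit_mean, 1e-8)), xout = grid,
                      rule = 2, ties = "ordered")$y)
  }
  nearest <- vapply(grid, function(g) fit_gc[which.min(abs(fit_gc - g))], numeric(1))
  size_g <- fit_size[match(nearest, fit_gc)]
  # direct fits override interpolation
  direct <- match(fit_gc, grid)
  mean_g[direct] <- fit_mean
  size_g[direct] <- fit_size
  prob_g <- size_g / (size_g + mean_g)

  out <- tibble::tibble(
    gc_percent = grid,
    size = size_g, prob = prob_g, mean = mean_g,
    n_windows = as.integer(ifelse(grid %in% gc_vals, n_win[match(grid, gc_vals)], 0L)),
    fitted = grid %in% fit_gc
  )
  structure(out, class = c("nb_model", class(out)),
            window_size = window_size, sample = sample)
}

# maximum-likelihood NB fit for one GC stratum, mean profiled
fit_nb_one <- function(x) {
  m <- mean(x)
  if (m <= 0) m <- 1e-6
  v <- stats::var(x)
  if (is.na(v) || v <= m) {                  # Poisson limit
    size <- 1e6
    return(list(size = size, prob = size / (size + m), mean = m))
  }
  nll <- function(log_size) {
    -sum(stats::dnbinom(x, size = exp(log_size), mu = m, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(-7, 14))
  size <- exp(opt$minimum)
  list(size = size, prob = size / (size + m), mean = m)
}

#' Look up NB parameters for given GC values
#'
#' @param model An `nb_model`.
#' @param gc Integer vector of GC percentages.
#' @return A tibble with columns `size`, `prob`, `mean` (one row per `gc`).
#' @export
nb_lookup <- function(model, gc) {
  i <- match(pmin(pmax(as.integer(round(gc)), 0L), 100L), model$gc_percent)
  tibble::tibble(size = model$size[i], prob = model$prob[i], mean = model$mean[i])
}

#' @export
print.nb_model <- function(x, ...) {
  f <- sum(x$fitted)
  cat(sprintf("<nb_model> sample=%s, window=%d bp, %d GC value(s) fitted directly\n",
              attr(x, "sample"), attr(x, "window_size"), f))
  print(tibble::as_tibble(x)[x$fitted, ], ...)
  invisible(x)
}
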