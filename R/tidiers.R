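#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-term content of a fit as a tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x A fitted object (`nb_model`, `agcn_fit`, `pscn_fit`,
#'   `haploid_freqs`).
#' @param ... Unused.
#' @return A tibble.
#' @name paracn-tidiers
NULL

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
tidy.nb_model <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
glance.nb_model <- function(x, ...) {
  tibble::tibble(
    sample = attr(x, "sample"), window_size = attr(x, "window_size"),
    n_gc_fitted = sum(x$fitted), n_windows = sum(x$n_windows),
    mean_depth_gc45 = x$mean[x$gc_percent == 45]
  )
}

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
tidy.agcn_fit <- function(x, ...) x$profiles

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
glance.agcn_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$samples), n_windows = nrow(x$windows),
    n_states = length(x$states),
    loglik = utils::tail(x$loglik_trace, 1),
    iterations = length(x$loglik_trace), converged = x$converged
  )
}

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
tidy.pscn_fit <- function(x, ...) {
  if (!is.null(x$skip)) return(tibble::tibble())
  dplyr::mutate(x$f, reliable = x$reliable[match(.data$psv, names(x$reliable))])
}

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
glance.pscn_fit <- function(x, ...) {
  tibble::tibble(
    c_r = x$c_r, n_samples = x$n_samples,
    n_psvs = if (is.null(x$f_mat)) 0L else nrow(x$f_mat),
    n_reliable = if (is.null(x$reliable)) 0L else sum(x$reliable),
    loglik = if (length(x$loglik_trace)) utils::tail(x$loglik_trace, 1) else NA_real_,
    iterations = length(x$loglik_trace),
    skip = x$skip %||% NA_character_
  )
}

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
tidy.haploid_freqs <- function(x, ...) tibble::as_tibble(x)

#' @rdname paracn-tidiers
#' @export
#' @exportS3Method
glance.haploid_freqs <- function(x, ...) {
  tibble::tibble(
    n_support = nrow(x), n_calls = attr(x, "n_calls"),
    loglik = utils::tail(attr(x, "loglik_trace"), 1),
    iterations = length(attr(x, "loglik_trace"))
  )
}

#' Plot an aggregate copy-number fit
#'
#' Shows per-sample normalized depth (points) along the region with the
#' decoded copy-number profile (steps). With many samples, set `samples`
#' to a subset.
#'
#' @param object An `agcn_fit`.
#' @param nb_models The background models used in the fit (for depth
#'   normalization); omit to plot raw counts.
#' @param samples Samples to show (default: up to 8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method
autoplot.agcn_fit <- function(object, nb_models = NULL, samples = NULL, ...) {
  if (is.null(samples)) samples <- utils::head(object$samples, 8)
  win <- object$windows
  df <- purrr::map_dfr(samples, function(s) {
    cnt <- NULL
    # normalized depth: 2 * observed / expected diploid depth
    if (!is.null(nb_models)) {
      e <- nb_lookup(nb_models[[s]], win$gc_percent)$mean
      cnt <- 2 * object_counts(object, s) / pmax(e, 1e-9)
    }
    tibble::tibble(sample = s, pos = (win$start + win$end) / 2,
                   depth = cnt %||% object_counts(object, s),
                   cn = object$states[object$paths[, s]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$depth), size = 0.5, alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$cn), colour = "firebrick") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "position (bp)",
                  y = if (is.null(nb_models)) "pooled depth" else "normalized depth (CN units)") +
    ggplot2::theme_minimal()
}

object_counts <- function(fit, s) {
  if (!is.null(fit$counts)) fit$counts[, s] else rep(NA_real_, nrow(fit$windows))
}

#' Plot a background NB depth model
#'
#' Mean depth against GC content with a one-standard-deviation ribbon.
#'
#' @param object An `nb_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method
autoplot.nb_model <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$sd <- sqrt(df$mean + df$mean^2 / df$size)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc_percent, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$fitted & df$n_windows > 0, ]) +
    ggplot2::labs(x = "GC content (%)", y = "mean depth per window") +
    ggplot2::theme_minimal()
}

#' Plot PSV allele frequencies
#'
#' Tile map of the fitted `f` matrix with reliable PSVs outlined.
#'
#' @param object A `pscn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method
autoplot.pscn_fit <- function(object, ...) {
  if (!is.null(object$skip)) stop_paracn("nothing to plot: fit skipped (%s)", object$skip)
  df <- tidy.pscn_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$copy), y = .data$psv,
                                   fill = .data$f)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$reliable), linewidth = 0.6) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white", high = "steelblue") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey80")) +
    ggplot2::labs(x = "copy", y = "PSV", fill = "f") +
    ggplot2::theme_minimal()
}
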