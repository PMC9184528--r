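#' Run the whole copy-number pipeline on a cohort
#'
#' Orchestrates the stages in order: homology table (if raw records are
#' given), background NB models per sample, locus segmentation and region
#' grouping, cross-copy pooling, the multi-sample aggregate CN fit,
#' paralog-specific genotyping from PSV allele counts (when supplied) and
#' trio concordance (when a pedigree is supplied). All stages are
#' deterministic for fixed inputs and seed.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param table A `homology_table`, or raw records for [build_table()].
#' @param locus One-row tibble (`contig`, `start`, `end`).
#' @param reads [Alignment records][alignment_records] with `sample`
#'   column covering the locus and its copies, plus unique background
#'   sequence.
#' @param psv_counts Optional long PSV allele-count tibble (`sample`,
#'   `psv`, `allele`, `count`).
#' @param ped Optional pedigree tibble (`child`, `mother`, `father`).
#' @param min_em_samples Minimum reference-CN samples for the EM stage.
#' @param seed Seed passed to the EM restarts.
#' @param window_size Window length (default 100 bp).
#' @return List with elements `table`, `segments`, `nb_models`, `depth`,
#'   `agcn`, `pscn`, `calls`, `trios` (stages not run are `NULL`) and
#'   `manifest` (tibble of stage completion).
#' @export
run_pipeline <- function(genome, table, locus, reads, psv_counts = NULL,
                         ped = NULL, min_em_samples = 50, seed = 1,
                         window_size = 100) {
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)

  if (!inherits(table, "homology_table")) table <- build_table(table)
  done("table")

  bg_win <- select_background_windows(genome, table, window_size = window_size)
  samples <- sort(unique(reads$sample))
  nb_models <- lapply(samples, function(s) {
    d <- assign_reads(reads[reads$sample == s, , drop = FALSE], bg_win)
    fit_nb(dplyr::rename(d, read_count = "read_count"), min_windows = 50,
           window_size = window_size, sample = s)
  })
  names(nb_models) <- samples
  done("background")

  segments <- group_segments(segment_locus(locus, table))
  dup_groups <- unique(segments$group[segments$ref_cn > 2])
  grp <- segments[segments$group == dup_groups[1], , drop = FALSE]
  depth <- pool_and_count(grp, reads, table, genome, window_size = window_size)
  depth <- filter_windows(depth)
  done("pool")

  agcn <- run_multi_sample(depth, nb_models, ref_cn = grp$ref_cn[1])
  done("agcn")

  pscn <- NULL; calls <- NULL; trios <- NULL
  if (!is.null(psv_counts)) {
    cn_per_sample <- dplyr::summarise(
      dplyr::group_by(agcn$profiles, .data$sample),
      agg_cn = .data$agg_cn[which.max(.data$n_windows)],
      quality = min(.data$quality), .groups = "drop")
    ref_samples <- cn_per_sample$sample[cn_per_sample$agg_cn == grp$ref_cn[1] &
                                          cn_per_sample$quality >= 20]
    pscn <- em_fit(psv_counts[psv_counts$sample %in% ref_samples, , drop = FALSE],
                   c_r = grp$ref_cn[1], min_samples = min_em_samples, seed = seed)
    done("pscn_em")
    calls <- genotype_sample(psv_counts, cn_per_sample, pscn)
    done("pscn_calls")
    if (!is.null(ped) && nrow(calls) > 0) {
      trios <- trio_report(ped, calls[is.na(calls$skip), , drop = FALSE])
      done("trio")
    }
  }
  manifest <- tibble::tibble(stage = stages, completed = TRUE)
  list(table = table, segments = segments, nb_models = nb_models,
       depth = depth, agcn = agcn, pscn = pscn, calls = calls,
       trios = trios, manifest = manifest)
}
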