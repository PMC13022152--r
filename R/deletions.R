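#' Fit the concordant insert-size model
#'
#' Robust location/scale of the template lengths of properly oriented
#' (forward-reverse) pairs: median and 1.4826 * MAD, with the scale floored
#' at 1 so degenerate (constant) inputs stay usable.
#'
#' @param pairs Pairs tibble (see \code{\link{read_pairs_tsv}}).
#' @return Object of class \code{insert_size_model} with fields \code{mean},
#'   \code{sd}, \code{n_observations}.
#' @examples
#' p <- tibble::tibble(accession = "a", chrom = "c", left_pos = 1L,
#'                     right_pos = 251L, orientation = "FR",
#'                     template_length = c(398L, 401L, 400L))
#' fit_insert_model(p)
#' @export
fit_insert_model <- function(pairs) {
  fr <- dplyr::filter(pairs, .data$orientation == "FR")
  assert_that(nrow(fr) >= 2,
              "need at least two properly oriented pairs to fit the insert model")
  tl <- fr$template_length
  structure(list(mean = median(tl), sd = max(1, mad(tl)),
                 n_observations = length(tl)),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat("<insert_size_model> mean ", format(x$mean), " sd ", format(x$sd),
      " (n = ", x$n_observations, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.insert_size_model <- function(x, ...) {
  tibble(term = c("mean", "sd"), estimate = c(x$mean, x$sd))
}

#' @export
glance.insert_size_model <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, n_observations = x$n_observations)
}

#' Call long deletions from discordant read pairs
#'
#' A pair is discordant iff properly oriented (FR) and its template length
#' exceeds \code{mean + k_sigma * sd} of the fitted insert model -- the
#' larger insert size of properly oriented pairs indicating a possible
#' deletion between the mates. Discordant pairs are clustered while their
#' inner spans (between mate inner ends) mutually overlap; the call interval
#' is the intersection of the cluster's inner spans (the maximal region
#' consistent with every supporting pair), the size estimate is the median
#' discordant template length minus the model mean, and clusters with fewer
#' than \code{min_support} pairs are suppressed. \code{coverage_drop} flags
#' calls whose interior read depth falls below 10\% of the flanking depth.
#'
#' @param pairs Pairs tibble for one accession.
#' @param model An \code{\link{insert_size_model}}.
#' @param read_length Read length (bp) used to compute inner spans.
#' @param min_support Minimum discordant pairs per call (default 3).
#' @param k_sigma Discordance threshold in model SDs (default 4).
#' @return Tibble of calls: \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{support}, \code{size_estimate}, \code{coverage_drop}.
#' @export
detect_deletions <- function(pairs, model, read_length = 150L,
                             min_support = 3L, k_sigma = 4) {
  stopifnot(inherits(model, "insert_size_model"))
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer(), size_estimate = double(),
                  coverage_drop = logical())
  fr <- dplyr::filter(pairs, .data$orientation == "FR")
  if (nrow(fr) == 0) return(empty)
  cutoff <- model$mean + k_sigma * model$sd
  disc <- fr |>
    mutate(inner_start = .data$left_pos + read_length,
           inner_end = .data$right_pos - 1L) |>
    dplyr::filter(.data$template_length > cutoff,
                  .data$inner_start <= .data$inner_end) |>
    arrange(.data$inner_start, .data$inner_end)
  if (nrow(disc) == 0) return(empty)

  cluster_id <- integer(nrow(disc))
  cid <- 1L
  cs <- disc$inner_start[1]; ce <- disc$inner_end[1]
  cluster_id[1] <- cid
  for (i in seq_len(nrow(disc))[-1]) {
    if (disc$inner_start[i] <= ce) {
      cs <- max(cs, disc$inner_start[i])
      ce <- min(ce, disc$inner_end[i])
      cluster_id[i] <- cid
    } else {
      cid <- cid + 1L
      cs <- disc$inner_start[i]; ce <- disc$inner_end[i]
      cluster_id[i] <- cid
    }
  }
  calls <- disc |>
    mutate(.cluster = cluster_id) |>
    group_by(.data$.cluster) |>
    summarise(chrom = .data$chrom[1],
              start = max(.data$inner_start),
              end = min(.data$inner_end),
              support = dplyr::n(),
              size_estimate = median(.data$template_length) - model$mean,
              .groups = "drop") |>
    dplyr::filter(.data$support >= min_support) |>
    select(-".cluster")
  if (nrow(calls) == 0) return(empty)

  depth_in <- function(lo, hi) {
    if (hi < lo) return(0)
    width <- hi - lo + 1
    starts <- c(fr$left_pos, fr$right_pos)
    ends <- starts + read_length - 1L
    ov <- pmax(0, pmin(ends, hi) - pmax(starts, lo) + 1)
    sum(ov) / width
  }
  calls |>
    mutate(coverage_drop = purrr::map2_lgl(.data$start, .data$end, function(s, e) {
      w <- e - s + 1L
      inside <- depth_in(s, e)
      flank <- depth_in(s - w, s - 1L) / 2 + depth_in(e + 1L, e + w) / 2
      flank > 0 && inside < 0.1 * flank
    })) |>
    arrange(.data$start)
}

#' Refine deletion breakpoints by exact flank matching
#'
#' When both the reference and the deletion-carrying sequence are available,
#' the exact breakpoints follow from the longest shared prefix and suffix:
#' the deleted interval starts one base past the common prefix (leftmost
#' placement under breakpoint microhomology).
#'
#' @param reference,edited Character scalar sequences; \code{edited} must be
#'   shorter.
#' @return Tibble with \code{start}, \code{end} of the deleted reference
#'   interval (1-based inclusive).
#' @export
refine_deletion_breakpoints <- function(reference, edited) {
  lr <- nchar(reference); le <- nchar(edited)
  assert_that(lr > le, "edited sequence must be shorter than the reference")
  r <- seq_to_chars(reference); e <- seq_to_chars(edited)
  pmax_len <- le
  mism <- which(r[seq_len(pmax_len)] != e[seq_len(pmax_len)])
  prefix <- if (length(mism) == 0) pmax_len else mism[1] - 1L
  mism_s <- which(rev(r)[seq_len(pmax_len)] != rev(e)[seq_len(pmax_len)])
  suffix <- if (length(mism_s) == 0) pmax_len else mism_s[1] - 1L
  suffix <- min(suffix, le - prefix)
  tibble(start = prefix + 1L, end = lr - suffix)
}

#' Write deletion calls as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param calls Deletion-call tibble.
#' @param path Output path.
#' @export
write_deletions_bed <- function(calls, path) {
  bed <- calls |>
    mutate(bed_start = .data$start - 1L, bed_end = .data$end,
           name = paste0("del_", row_number()),
           score = .data$support) |>
    select("chrom", "bed_start", "bed_end", "name", "score")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
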