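# Exact tandem-repeat scanning at 100% identity.
#
# A reported locus is a maximal run of >= 2 full copies of a unit whose
# MINIMAL period lies within [min_period, max_period]; the minimal-period
# rule keeps homopolymers and dinucleotide runs from surfacing as
# period-8 repeats. Fractional trailing copies are allowed.

# minimal period of a character vector (smallest q with t[i] == t[i-q]);
# the search can stop at `upto` when a period of that size is known to hold
minimal_period <- function(tchars, upto = length(tchars) - 1L) {
  len <- length(tchars)
  for (q in seq_len(min(upto, len - 1L))) {
    if (all(tchars[(q + 1):len] == tchars[seq_len(len - q)])) return(q)
  }
  len
}

#' Scan a sequence for exact short-period tandem repeats
#'
#' Finds all maximal runs where each base equals the base \code{p} positions
#' earlier, for periods \code{p} in \code{[min_period, max_period]}, with at
#' least two full copies at 100\% identity. Runs whose minimal period falls
#' outside the range are excluded; each locus is reported once at its
#' minimal period with its left-most maximal extent.
#'
#' @param sequence Character scalar over A/C/G/T.
#' @param min_period,max_period Period bounds in bp (defaults 8 and 10).
#' @return Tibble of loci: \code{start}, \code{end} (1-based inclusive),
#'   \code{period} (minimal), \code{unit}, \code{copies} (fractional),
#'   \code{span}.
#' @examples
#' scan_trs(strrep("ACGTACGG", 2))  # one period-8 locus, 2 copies
#' scan_trs(strrep("A", 40))        # empty: minimal period 1
#' @export
scan_trs <- function(sequence, min_period = 8L, max_period = 10L) {
  s <- seq_to_chars(toupper(sequence))
  n <- length(s)
  out <- list()
  for (p in seq.int(min_period, max_period)) {
    if (n < 2 * p) next
    m <- s[(p + 1):n] == s[seq_len(n - p)]
    r <- rle(m)
    ends_rel <- cumsum(r$lengths)
    starts_rel <- ends_rel - r$lengths + 1L
    hit <- which(r$values & r$lengths >= p)
    for (h in hit) {
      start <- starts_rel[h]           # = first matched position - p
      span <- r$lengths[h] + p
      end <- start + span - 1L
      tchars <- s[start:end]
      q <- minimal_period(tchars, upto = p)
      if (q != p) next  # reported at its own minimal period (if in range)
      out <- c(out, list(tibble(
        start = start, end = end, period = q,
        unit = chars_to_seq(tchars[seq_len(q)]),
        copies = span / q, span = span)))
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), period = integer(),
                  unit = character(), copies = double(), span = integer()))
  }
  bind_rows(out) |> distinct() |> arrange(.data$start, .data$period)
}

cyclic_rotations <- function(unit) {
  k <- nchar(unit)
  vapply(seq_len(k) - 1L, function(r) {
    paste0(substr(unit, r + 1, k), substr(unit, 1, r))
  }, "")
}

units_match <- function(u1, u2) {
  nchar(u1) == nchar(u2) && u2 %in% cyclic_rotations(u1)
}

#' Compare tandem-repeat catalogs between an accession and the reference
#'
#' Projects accession loci to reference coordinates through the accession's
#' known edit list (deletion intervals on the reference), then matches loci
#' whose units are identical up to cyclic rotation and whose projected
#' starts agree within \code{tolerance}. Unmatched accession loci are
#' gained; unmatched reference loci are lost; reference loci inside a
#' deleted interval are lost with \code{in_deletion = TRUE}.
#'
#' @param accession_loci,reference_loci Locus tibbles from
#'   \code{\link{scan_trs}}.
#' @param deletions Tibble of deleted reference intervals (\code{start},
#'   \code{end}) carried by the accession, or NULL for identity projection.
#' @param tolerance Maximum projected-start discrepancy in bp (default 50).
#' @return Object of class \code{tr_comparison}: list with \code{gained},
#'   \code{lost} (with \code{in_deletion} flag), \code{shared} (matched
#'   pairs) and \code{summary} (one-row tibble of counts).
#' @export
compare_trs <- function(accession_loci, reference_loci, deletions = NULL,
                        tolerance = 50) {
  map <- edited_to_ref_map(deletions)
  acc <- accession_loci |>
    mutate(proj_start = project_to_ref(.data$start, map))
  ref <- reference_loci
  in_del <- rep(FALSE, nrow(ref))
  if (!is.null(deletions) && nrow(deletions) > 0) {
    for (i in seq_len(nrow(deletions))) {
      in_del <- in_del | (ref$start >= deletions$start[i] &
                            ref$end <= deletions$end[i])
    }
  }
  used_ref <- rep(FALSE, nrow(ref))
  matched_acc <- rep(FALSE, nrow(acc))
  shared <- list()
  for (i in seq_len(nrow(acc))) {
    cand <- which(!used_ref & !in_del &
                    abs(ref$start - acc$proj_start[i]) <= tolerance &
                    ref$period == acc$period[i])
    cand <- cand[vapply(cand, function(j) units_match(acc$unit[i], ref$unit[j]),
                        TRUE)]
    if (length(cand) > 0) {
      j <- cand[which.min(abs(ref$start[cand] - acc$proj_start[i]))]
      used_ref[j] <- TRUE
      matched_acc[i] <- TRUE
      shared <- c(shared, list(tibble(
        acc_start = acc$start[i], ref_start = ref$start[j],
        period = acc$period[i], unit = acc$unit[i])))
    }
  }
  gained <- acc[!matched_acc, setdiff(names(acc), "proj_start")]
  lost <- ref[!used_ref, ] |> mutate(in_deletion = in_del[!used_ref])
  shared_tbl <- if (length(shared)) bind_rows(shared) else
    tibble(acc_start = integer(), ref_start = integer(),
           period = integer(), unit = character())
  structure(list(
    gained = gained, lost = lost, shared = shared_tbl,
    summary = tibble(n_gained = nrow(gained), n_lost = nrow(lost),
                     n_shared = nrow(shared_tbl))
  ), class = "tr_comparison")
}

#' @export
print.tr_comparison <- function(x, ...) {
  cat("<tr_comparison> gained:", x$summary$n_gained,
      " lost:", x$summary$n_lost, " shared:", x$summary$n_shared, "\n")
  invisible(x)
}

#' @export
glance.tr_comparison <- function(x, ...) x$summary

#' Write tandem-repeat loci as BED (0-based half-open)
#'
#' @param loci Locus tibble from \code{\link{scan_trs}}.
#' @param path Output path.
#' @param chrom Chromosome/locus name.
#' @export
write_trs_bed <- function(loci, path, chrom = "locus") {
  bed <- loci |>
    mutate(chrom = chrom, bed_start = .data$start - 1L, bed_end = .data$end,
           name = paste0(.data$unit, "x", round(.data$copies, 2))) |>
    select("chrom", "bed_start", "bed_end", "name")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
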