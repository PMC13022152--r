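# Paired-end read simulation with realignment to reference coordinates.
#
# Pairs are placed uniformly on the (possibly deletion-carrying) accession
# sequence with truncated-normal template lengths and forward-reverse
# orientation. Records are then expressed in REFERENCE coordinates: a read
# overlapping a deletion junction would be split/clipped by a real aligner
# and is dropped; a pair whose reads flank a deletion survives with its
# template length inflated by the deletion length -- exactly the signal the
# deletion detector consumes.

# mapping from accession (edited) coordinates to reference coordinates given
# reference-space deletions
edited_to_ref_map <- function(deletions) {
  if (is.null(deletions) || nrow(deletions) == 0) {
    return(list(junctions = numeric(0), shifts = numeric(0)))
  }
  d <- arrange(deletions, .data$start)
  len <- d$end - d$start + 1L
  cum <- cumsum(len)
  # last edited position before deletion i
  junctions <- d$start - c(0, head(cum, -1)) - 1L
  list(junctions = junctions, shifts = cum)
}

project_to_ref <- function(pos, map) {
  if (length(map$junctions) == 0) return(pos)
  i <- findInterval(pos - 0.5, map$junctions)
  pos + c(0, map$shifts)[i + 1L]
}

#' Simulate read pairs over an accession sequence
#'
#' @param sequence Character scalar accession sequence.
#' @param config A \code{\link{sim_config}} (insert model, read length,
#'   coverage).
#' @param deletions Tibble of true deleted intervals in reference coordinates
#'   (\code{start}, \code{end}), or NULL for a deletion-free accession.
#' @param accession Accession id recorded in the output.
#' @param seed RNG seed (default: derived from the config seed).
#' @return Tibble with columns \code{accession}, \code{chrom},
#'   \code{left_pos}, \code{right_pos} (1-based leftmost positions of the two
#'   reads in reference coordinates), \code{orientation} ("FR"),
#'   \code{template_length}.
#' @examples
#' ref <- make_reference(sim_config(seed = 7))
#' pairs <- simulate_read_pairs(ref$sequence, ref$config, accession = "wt")
#' mean(pairs$template_length)
#' @export
simulate_read_pairs <- function(sequence, config, deletions = NULL,
                                accession = "acc",
                                seed = derive_seed(config$seed, accession)) {
  assert_that(config$coverage > 0, "coverage must be positive")
  L <- nchar(sequence)
  assert_that(L >= config$insert_mean,
              "sequence shorter than the mean insert size")
  rl <- config$read_length
  n_pairs <- max(1L, round(config$coverage * L / (2 * rl)))
  with_seed(seed, {
    tlen <- round(rnorm(n_pairs, config$insert_mean, config$insert_sd))
    # truncate so both reads fit inside the template
    lo <- 2 * rl
    while (any(bad <- tlen < lo | tlen > L)) {
      tlen[bad] <- round(rnorm(sum(bad), config$insert_mean, config$insert_sd))
    }
    left_e <- floor(runif(n_pairs, 1, L - tlen + 1 + 1))
    right_e <- left_e + tlen - rl

    map <- edited_to_ref_map(deletions)
    if (length(map$junctions) > 0) {
      crosses <- function(st) {
        out <- rep(FALSE, length(st))
        for (j in map$junctions) out <- out | (st <= j & st + rl - 1L > j)
        out
      }
      keep <- !crosses(left_e) & !crosses(right_e)
      tlen <- tlen[keep]; left_e <- left_e[keep]; right_e <- right_e[keep]
    }
    left_r <- project_to_ref(left_e, map)
    right_r <- project_to_ref(right_e, map)

    tibble(accession = accession, chrom = "locus",
           left_pos = as.integer(left_r), right_pos = as.integer(right_r),
           orientation = "FR",
           template_length = as.integer(right_r - left_r + rl))
  })
}

#' Read or write the pairs TSV dialect
#'
#' Columns: accession, chrom, left_pos, right_pos, orientation,
#' template_length (1-based leftmost positions).
#'
#' @param path File path.
#' @return \code{read_pairs_tsv} returns the pairs tibble.
#' @export
read_pairs_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    accession = "c", chrom = "c", left_pos = "i",
                    right_pos = "i", orientation = "c", template_length = "i"))
}

#' @rdname read_pairs_tsv
#' @param pairs Pairs tibble.
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Read pairs from a SAM file
#'
#' Extracts properly paired, forward-strand, leftmost mates (FLAG bits) and
#' their TLEN fields into the pairs tibble dialect.
#'
#' @param path SAM file path.
#' @param read_length Read length used to reconstruct the mate's leftmost
#'   position from TLEN.
#' @return Pairs tibble as in \code{\link{read_pairs_tsv}}.
#' @export
read_pairs_sam <- function(path, read_length = 150L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(accession = character(), chrom = character(),
                  left_pos = integer(), right_pos = integer(),
                  orientation = character(), template_length = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 1L)
  # paired, mapped, mate mapped, read forward, mate reverse, leftmost (TLEN>0)
  tlen <- vapply(f, function(x) as.integer(x[9]), 1L)
  keep <- bitwAnd(flag, 1L) > 0 & bitwAnd(flag, 4L) == 0 &
    bitwAnd(flag, 8L) == 0 & bitwAnd(flag, 16L) == 0 &
    bitwAnd(flag, 32L) > 0 & tlen > 0
  f <- f[keep]; tlen <- tlen[keep]
  pos <- vapply(f, function(x) as.integer(x[4]), 1L)
  tibble(
    accession = vapply(f, function(x) sub("/[12]$", "", x[1]), ""),
    chrom = vapply(f, function(x) x[3], ""),
    left_pos = pos,
    right_pos = pos + tlen - read_length,
    orientation = "FR",
    template_length = tlen
  )
}
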