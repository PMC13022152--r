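#' Simulation configuration for the synthetic SD1 locus
#'
#' Bundles every tunable of the synthetic-data generator: locus geometry, the
#' three-exon/two-intron gene model, the paired-end insert-size model, the
#' population mutation parameter for neutral coalescent samples, and the
#' haplotype-dependent plant-height model.
#'
#' Defaults place the gene at locus positions 10,001..12,743 so that the
#' published chromosome-1 coordinates of the haplotype catalogue map onto the
#' locus through the single offset \code{\link{sd1_coord_offset}}, with every
#' diagnostic SNP landing at the codon and phase implied by its amino-acid
#' change.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @param locus_length Locus length in bp.
#' @param exon_intervals List of three 1-based inclusive exon intervals
#'   (sorted, non-overlapping, within the locus; total length a multiple of 3).
#' @param promoter_flank Promoter length in bp immediately upstream of exon 1.
#' @param insert_mean,insert_sd Mean and standard deviation (bp) of the
#'   truncated-normal template-length model.
#' @param read_length Read length in bp.
#' @param coverage Haploid fold-coverage of simulated pairs.
#' @param theta Per-locus population mutation parameter for neutral samples.
#' @param n_samples Default sample count for neutral samples.
#' @param height_means Named numeric vector, haplotype type id -> mean plant
#'   height (cm) at heading.
#' @param height_sd Within-group height standard deviation (cm).
#' @param coord_offset Chromosome-1 to locus coordinate offset.
#' @return A list of class \code{sim_config}.
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$locus_length
#' @export
sim_config <- function(seed = 1L,
                       locus_length = 25000L,
                       exon_intervals = list(c(10001L, 10450L),
                                             c(10553L, 10952L),
                                             c(12424L, 12743L)),
                       promoter_flank = 1000L,
                       insert_mean = 400,
                       insert_sd = 30,
                       read_length = 150L,
                       coverage = 30,
                       theta = 5,
                       n_samples = 20L,
                       height_means = c(`1` = 150, `2` = 110, `3` = 60,
                                        `4` = 60, `5` = 60, `6` = 85,
                                        `7` = 85, `8` = 90, `9` = 90,
                                        `10` = 90, `11` = 150, `12` = 85),
                       height_sd = 8,
                       coord_offset = sd1_coord_offset()) {
  ex <- lapply(exon_intervals, as.integer)
  assert_that(length(ex) >= 1 && all(vapply(ex, length, 1L) == 2),
              "exon_intervals must be a list of (start, end) pairs")
  starts <- vapply(ex, `[`, 1L, 1)
  ends <- vapply(ex, `[`, 1L, 2)
  assert_that(all(starts <= ends), "exon start must not exceed exon end")
  assert_that(all(diff(starts) > 0) && all(ends[-length(ends)] < starts[-1]),
              "exon intervals must be sorted and non-overlapping")
  assert_that(starts[1] > promoter_flank && ends[length(ends)] <= locus_length,
              "exon layout (with promoter flank) does not fit in the locus")
  cds_len <- sum(ends - starts + 1L)
  assert_that(cds_len %% 3L == 0L, "total exon (CDS) length must be a multiple of 3")
  assert_that(insert_mean > 2 * read_length,
              "insert_mean must exceed twice the read length")
  assert_that(coverage > 0, "coverage must be positive")
  assert_that(theta >= 0, "theta must be non-negative")
  structure(list(
    seed = as.integer(seed),
    locus_length = as.integer(locus_length),
    gene_start = starts[1],
    gene_end = ends[length(ends)],
    exon_intervals = ex,
    promoter_flank = as.integer(promoter_flank),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    read_length = as.integer(read_length),
    coverage = coverage,
    theta = theta,
    n_samples = as.integer(n_samples),
    height_means = height_means,
    height_sd = height_sd,
    coord_offset = as.integer(coord_offset)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  locus:", x$locus_length, "bp; gene", x$gene_start, "-", x$gene_end,
      "(", length(x$exon_intervals), "exons )\n")
  cat("  inserts: N(", x$insert_mean, ",", x$insert_sd,
      ") reads:", x$read_length, "bp at", x$coverage, "x\n")
  cat("  theta:", x$theta, " seed:", x$seed, "\n")
  invisible(x)
}
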