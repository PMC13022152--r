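# Reference locus construction.
#
# The locus is random sequence except where biology pins it down: the CDS is
# built from non-stop codons with ATG start and TAA stop, canonical GT/AG
# dinucleotides are planted at intron boundaries, and the codons containing
# the catalogue's diagnostic sites are fixed so that each published
# amino-acid change corresponds to a single-nucleotide change at the
# published coordinate.

# codons planted at diagnostic positions (keyed by chromosome-1 coordinate):
# the codon shown is the wild-type (GR) state; `phase` is the position of the
# diagnostic base within the codon and is cross-checked against the gene
# model at build time.
diagnostic_codons <- function() {
  tibble(
    chr1_pos = c(38382746, 38382764, 38383221, 38383286, 38383363,
                 38384938, 38385057, 38385064, 38385083),
    codon = c("GGT", "GGA", "GCC", "CCA", "CTC", "TAC", "CGA", "TAC", "GAC"),
    phase = c(2L, 2L, 3L, 2L, 1L, 3L, 2L, 3L, 1L)
  )
}

# genomic positions of CDS bases in transcription order
cds_position_map <- function(exon_intervals) {
  unlist(lapply(exon_intervals, function(iv) seq.int(iv[1], iv[2])))
}

#' Build the gene model table
#'
#' @param config A \code{\link{sim_config}}.
#' @return Tibble with columns \code{feature} (promoter, exon, intron),
#'   \code{rank}, \code{start}, \code{end}, \code{strand}.
#' @export
gene_model_from_config <- function(config) {
  ex <- config$exon_intervals
  starts <- vapply(ex, `[`, 1L, 1)
  ends <- vapply(ex, `[`, 1L, 2)
  rows <- list(tibble(feature = "promoter", rank = 1L,
                      start = starts[1] - config$promoter_flank,
                      end = starts[1] - 1L))
  for (i in seq_along(ex)) {
    rows <- c(rows, list(tibble(feature = "exon", rank = i,
                                start = starts[i], end = ends[i])))
    if (i < length(ex)) {
      rows <- c(rows, list(tibble(feature = "intron", rank = i,
                                  start = ends[i] + 1L, end = starts[i + 1] - 1L)))
    }
  }
  bind_rows(rows) |> mutate(strand = "+") |> arrange(.data$start)
}

#' Generate the reference locus and gene model
#'
#' Produces a random locus of \code{config$locus_length} bp carrying a
#' three-exon gene whose concatenated CDS starts with ATG, ends with a stop
#' codon, contains no internal stop, and carries the wild-type (GR)
#' diagnostic codons at the catalogue positions. Intron boundaries get
#' canonical GT/AG dinucleotides. Deterministic for a fixed
#' \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{sd1_reference}: \code{sequence} (character
#'   scalar), \code{gene_model} (tibble), \code{config}.
#' @examples
#' ref <- make_reference(sim_config(seed = 7))
#' nchar(ref$sequence)
#' @export
make_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "T")
  codons61 <- {
    all3 <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
    cs <- paste0(all3[, 1], all3[, 2], all3[, 3])
    setdiff(cs, c("TAA", "TAG", "TGA"))
  }
  with_seed(config$seed, {
    s <- sample(bases, config$locus_length, replace = TRUE)

    cds_map <- cds_position_map(config$exon_intervals)
    n_codon <- length(cds_map) / 3L
    codons <- sample(codons61, n_codon, replace = TRUE)
    codons[1] <- "ATG"
    codons[n_codon] <- "TAA"

    # plant diagnostic codons where the catalogue positions fall inside the CDS
    diag <- diagnostic_codons() |>
      mutate(locus_pos = .data$chr1_pos - config$coord_offset,
             cds_pos = match(.data$locus_pos, cds_map)) |>
      dplyr::filter(!is.na(.data$cds_pos))
    if (nrow(diag) > 0) {
      # only plant where the layout puts the site at its expected codon
      # phase (always true for the default layout; custom layouts keep a
      # valid gene but need not reproduce the catalogue's codon geometry)
      in_frame <- (diag$cds_pos - 1L) %% 3L + 1L == diag$phase
      diag <- diag[in_frame, , drop = FALSE]
      codons[ceiling(diag$cds_pos / 3)] <- diag$codon
    }

    s[cds_map] <- seq_to_chars(chars_to_seq(codons))

    # canonical splice dinucleotides
    gm <- gene_model_from_config(config)
    introns <- dplyr::filter(gm, .data$feature == "intron")
    for (i in seq_len(nrow(introns))) {
      s[introns$start[i] + 0:1] <- c("G", "T")
      s[introns$end[i] - 1:0] <- c("A", "G")
    }

    structure(list(sequence = chars_to_seq(s), gene_model = gm,
                   config = config),
              class = "sd1_reference")
  })
}

#' @export
print.sd1_reference <- function(x, ...) {
  cat("<sd1_reference> ", nchar(x$sequence), " bp, gene ",
      x$config$gene_start, "-", x$config$gene_end, "\n", sep = "")
  invisible(x)
}

#' Extract and translate the CDS of a reference or edited sequence
#'
#' @param sequence Character scalar locus sequence.
#' @param gene_model Gene model tibble (exon rows define the CDS).
#' @return Character scalar CDS sequence.
#' @export
extract_cds <- function(sequence, gene_model) {
  ex <- dplyr::filter(gene_model, .data$feature == "exon") |> arrange(.data$start)
  chars <- seq_to_chars(sequence)
  chars_to_seq(chars[cds_position_map(
    lapply(seq_len(nrow(ex)), function(i) c(ex$start[i], ex$end[i])))])
}
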