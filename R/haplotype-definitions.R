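#' The twelve SD1 haplotype definitions
#'
#' Machine-readable encoding of the published SD1 haplotype catalogue: the
#' wild-type combination G100/R340 (type 1, \emph{GR}), the partially
#' functional E100/Q340 (type 2, \emph{EQ}) and E100/R340 (type 11, \emph{ER})
#' combinations, seven point loss-of-function alleles (missense, premature
#' stop, or a 2-bp frameshift indel), and the two long deletions: the 1,279-bp
#' deletion of type 6 and the 383-bp \emph{DGWG} deletion of type 7 whose use
#' in IR8 drove the Green Revolution.
#'
#' Positions are 1-based Nipponbare chromosome-1 coordinates. They are mapped
#' onto the synthetic locus by subtracting a single offset
#' (\code{\link{sd1_coord_offset}}), so the published coordinates remain
#' quotable while all arithmetic happens on the 25-kb locus.
#'
#' Alternate nucleotides at diagnostic SNP sites are derived from the stated
#' amino-acid changes via the genetic code on the locus CDS (the publication
#' prints the coordinates and residue changes, not the alleles).
#'
#' The historical record is ambiguous on whether the type-9 Aijiao-Nante
#' frameshift is a 2-bp insertion or deletion; the narrative descriptions say
#' deletion, the tabulated catalogue says insertion. The default encodes a
#' deletion; set \code{indel_as = "insertion"} for the alternative.
#'
#' @param indel_as "deletion" (default) or "insertion" for the type-9 2-bp
#'   frameshift indel.
#' @return A tibble with one row per haplotype: \code{type_id},
#'   \code{allele_name}, \code{class} (one of \code{combo}, \code{point_snp},
#'   \code{indel}, \code{long_deletion}), \code{precedence} (1 = structural,
#'   2 = point LOF, 3 = residue-100/340 combination), \code{pos}/\code{end}
#'   (chromosome-1 coordinates), \code{ref}/\code{alt} nucleotides for SNPs,
#'   \code{aa_detail}, and the expected \code{res100}/\code{res340} states for
#'   combination types.
#' @examples
#' sd1_haplotypes()
#' @export
sd1_haplotypes <- function(indel_as = c("deletion", "insertion")) {
  indel_as <- match.arg(indel_as)
  defs <- tibble(
    type_id = 1:12,
    allele_name = c("GR", "EQ", "Jikkoku", "Calrose76", "Reimei", "new_allele",
                    "DGWG", "9311", "Aijiao-Nante", "Zhayeqing8", "ER", "bm"),
    class = c("combo", "combo", "point_snp", "point_snp", "point_snp",
              "long_deletion", "long_deletion", "point_snp", "indel",
              "point_snp", "combo", "point_snp"),
    precedence = c(3L, 3L, 2L, 2L, 2L, 1L, 1L, 2L, 2L, 2L, 3L, 2L),
    pos = c(NA, NA, 38382746, 38383363, 38385083, 38381879, 38382762,
            38385064, 38382846, 38383286, NA, 38384938),
    end = c(NA, NA, NA, NA, NA, 38383157, 38383144, NA, 38382847, NA, NA, NA),
    ref = c(NA, NA, "G", "C", "G", NA, NA, "C", NA, "C", NA, "C"),
    alt = c(NA, NA, "T", "T", "C", NA, NA, "A", NA, "T", NA, "A"),
    aa_detail = c("Gly100/Arg340", "Glu100/Gln340", "Gly94Val", "Leu266Phe",
                  "Asp349His", "1279-bp deletion", "383-bp deletion",
                  "Tyr342*", "Arg130fs", "Pro240Leu", "Glu100/Arg340",
                  "Tyr300*"),
    res100 = c("G", "E", NA, NA, NA, NA, NA, NA, NA, NA, "E", NA),
    res340 = c("R", "Q", NA, NA, NA, NA, NA, NA, NA, NA, "R", NA),
    indel_kind = c(NA, NA, NA, NA, NA, NA, NA, NA, indel_as, NA, NA, NA)
  )
  defs
}

#' Coordinate offset between chromosome 1 and the synthetic locus
#'
#' Synthetic locus position = chromosome-1 position minus this offset. With
#' the default, the SD1 gene body (chr1 38,382,466..38,385,208) maps to locus
#' positions 10,001..12,743 inside the default 25-kb locus, and the published
#' minus-10-kb to plus-10-kb analysis window maps to positions 1..22,743.
#'
#' @return Integer offset (default 38,372,465).
#' @export
sd1_coord_offset <- function() 38372465L

#' Diagnostic residue-100/340 SNP sites
#'
#' The two functional-nucleotide-polymorphism sites that distinguish the GR,
#' EQ and ER combinations: chromosome-1 positions 38,382,764 (codon 100) and
#' 38,385,057 (codon 340). On the wild-type (GR) reference both carry G; the
#' G-to-A change yields Glu100 and Gln340 respectively.
#'
#' @return Named integer vector with elements \code{res100} and \code{res340}.
#' @export
sd1_diagnostic_sites <- function() {
  c(res100 = 38382764L, res340 = 38385057L)
}

#' Long-deletion geometry of the haplotype catalogue
#'
#' Lengths and pairwise 3'-end distances of the defined long deletions.
#' Length is \code{end - start + 1} (1-based inclusive); the 3'-end breakpoint
#' is \code{end + 1}, the first retained base after the deletion; the pairwise
#' distance is the absolute difference of breakpoints (invariant to using
#' \code{end} consistently instead).
#'
#' @param definitions A haplotype definition table from
#'   \code{\link{sd1_haplotypes}}.
#' @return A list with \code{lengths}: tibble of \code{type_id},
#'   \code{start}, \code{end}, \code{length}, \code{three_prime_end}; and
#'   \code{three_prime_distances}: tibble of \code{type_a}, \code{type_b},
#'   \code{distance} for every unordered pair.
#' @examples
#' geo <- deletion_geometry(sd1_haplotypes())
#' geo$lengths
#' geo$three_prime_distances
#' @export
deletion_geometry <- function(definitions = sd1_haplotypes()) {
  dels <- dplyr::filter(definitions, .data$class == "long_deletion")
  assert_that(nrow(dels) > 0, "no long-deletion haplotypes in the definition table")
  lengths <- dels |>
    mutate(length = .data$end - .data$pos + 1,
           three_prime_end = .data$end + 1) |>
    select("type_id", start = "pos", "end", "length", "three_prime_end")
  pairs <- if (nrow(lengths) >= 2) {
    idx <- utils::combn(seq_len(nrow(lengths)), 2)
    tibble(
      type_a = lengths$type_id[idx[1, ]],
      type_b = lengths$type_id[idx[2, ]],
      distance = abs(lengths$three_prime_end[idx[1, ]] -
                       lengths$three_prime_end[idx[2, ]])
    )
  } else {
    tibble(type_a = integer(), type_b = integer(), distance = numeric())
  }
  list(lengths = lengths, three_prime_distances = pairs)
}

#' Read or write a haplotype definition table as TSV
#'
#' @param path File path.
#' @return \code{read_haplotype_definitions} returns the definition tibble.
#' @export
read_haplotype_definitions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    type_id = "i", allele_name = "c", class = "c",
                    precedence = "i", pos = "d", end = "d", ref = "c",
                    alt = "c", aa_detail = "c", res100 = "c", res340 = "c",
                    indel_kind = "c"))
}

#' @rdname read_haplotype_definitions
#' @param definitions Definition tibble.
#' @export
write_haplotype_definitions <- function(definitions, path) {
  readr::write_tsv(definitions, path)
  invisible(path)
}
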