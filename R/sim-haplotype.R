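#' Apply a haplotype definition to the reference locus
#'
#' Edits the reference sequence to carry one catalogue haplotype: diagnostic
#' SNPs for the residue-100/340 combinations and point alleles, the 2-bp
#' frameshift indel, or one of the two long deletions. SNPs preserve length;
#' a deletion shortens the sequence by exactly the interval length. Emitted
#' truth records are VCF-style (left-anchored indels) in locus coordinates.
#'
#' @param reference An \code{sd1_reference} from \code{\link{make_reference}}.
#' @param haplotype Integer type id (1..12) or a single-row slice of the
#'   definition table.
#' @param definitions Haplotype definition table.
#' @return List of class \code{sd1_accession_seq}: \code{sequence} (edited),
#'   \code{type_id}, \code{edits} (tibble: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{kind}), \code{deletions} (tibble of true
#'   deleted intervals \code{start}, \code{end} in locus coordinates).
#' @examples
#' ref <- make_reference(sim_config(seed = 7))
#' acc <- apply_haplotype(ref, 7)
#' nchar(ref$sequence) - nchar(acc$sequence)  # 383
#' @export
apply_haplotype <- function(reference, haplotype, definitions = sd1_haplotypes()) {
  stopifnot(inherits(reference, "sd1_reference"))
  def <- if (is.numeric(haplotype)) {
    dplyr::filter(definitions, .data$type_id == haplotype)
  } else haplotype
  assert_that(nrow(def) == 1, "haplotype must identify exactly one definition row")
  off <- reference$config$coord_offset
  chars <- seq_to_chars(reference$sequence)
  L <- length(chars)
  sites <- sd1_diagnostic_sites() - off

  snp_edit <- function(pos, ref, alt) {
    assert_that(pos >= 1 && pos <= L, "edit position outside locus")
    assert_that(chars[pos] == ref,
                paste0("reference mismatch at locus position ", pos,
                       ": expected ", ref, ", found ", chars[pos]))
    tibble(chrom = "locus", pos = as.integer(pos), ref = ref, alt = alt,
           kind = "snp")
  }

  edits <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), kind = character())
  deletions <- tibble(start = integer(), end = integer())

  if (def$class == "combo") {
    if (!is.na(def$res100) && def$res100 == "E") {
      edits <- bind_rows(edits, snp_edit(sites[["res100"]], "G", "A"))
    }
    if (!is.na(def$res340) && def$res340 == "Q") {
      edits <- bind_rows(edits, snp_edit(sites[["res340"]], "G", "A"))
    }
  } else if (def$class == "point_snp") {
    edits <- bind_rows(edits, snp_edit(def$pos - off, def$ref, def$alt))
  } else if (def$class == "indel") {
    s <- as.integer(def$pos - off); e <- as.integer(def$end - off)
    assert_that(s >= 2 && e <= L && s <= e, "indel interval outside locus")
    if (identical(def$indel_kind, "insertion")) {
      ins <- chars_to_seq(chars[s:e])
      edits <- bind_rows(edits, tibble(
        chrom = "locus", pos = e, ref = chars[e],
        alt = paste0(chars[e], ins), kind = "ins"))
    } else {
      edits <- bind_rows(edits, tibble(
        chrom = "locus", pos = s - 1L,
        ref = chars_to_seq(chars[(s - 1L):e]), alt = chars[s - 1L],
        kind = "del"))
      deletions <- bind_rows(deletions, tibble(start = s, end = e))
    }
  } else if (def$class == "long_deletion") {
    s <- as.integer(def$pos - off); e <- as.integer(def$end - off)
    assert_that(s >= 2 && e <= L && s <= e, "deletion interval outside locus")
    edits <- bind_rows(edits, tibble(
      chrom = "locus", pos = s - 1L,
      ref = chars_to_seq(chars[(s - 1L):e]), alt = chars[s - 1L],
      kind = "del"))
    deletions <- bind_rows(deletions, tibble(start = s, end = e))
  } else {
    abort(paste0("unknown haplotype class: ", def$class))
  }

  # overlapping edits are a definition error
  if (nrow(edits) > 1) {
    iv <- edits |> mutate(s = .data$pos, e = .data$pos + nchar(.data$ref) - 1L) |>
      arrange(.data$s)
    assert_that(all(iv$e[-nrow(iv)] < iv$s[-1]), "overlapping edits in definition")
  }

  out <- chars
  # apply right-to-left so positions stay valid
  ord <- order(edits$pos, decreasing = TRUE)
  for (i in ord) {
    p <- edits$pos[i]; r <- edits$ref[i]; a <- edits$alt[i]
    stopifnot(chars_to_seq(out[p:(p + nchar(r) - 1L)]) == r)
    out <- c(out[seq_len(p - 1L)], seq_to_chars(a),
             if (p + nchar(r) <= length(out)) out[(p + nchar(r)):length(out)])
  }

  structure(list(sequence = chars_to_seq(out),
                 type_id = def$type_id,
                 allele_name = def$allele_name,
                 edits = edits,
                 deletions = deletions),
            class = "sd1_accession_seq")
}
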