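# Minimal variant-effect annotator: classifies variants by location within
# the gene model (promoter, exons, introns, splice sites) and predicted
# impact on the protein (synonymous / missense / stop gained / frameshift /
# in-frame indel), in the style of the usual ANN-type annotators but for a
# single transcript.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

aa3 <- function(aa1) unname(AA3[aa1])

#' Translate a CDS with the standard genetic code
#'
#' @param cds Character scalar over A/C/G/T, length divisible by 3. The empty
#'   string translates to the empty string.
#' @return Single-letter amino-acid string with any trailing stop dropped;
#'   attribute \code{internal_stop} flags a premature termination codon.
#' @examples
#' translate_cds("ATGGGAAGATAA")  # "MGR"
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) == 0) {
    return(structure("", internal_stop = FALSE))
  }
  assert_that(nchar(cds) %% 3 == 0, "CDS length must be divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  trailing <- endsWith(aa, "*")
  if (trailing) aa <- substr(aa, 1, nchar(aa) - 1)
  structure(aa, internal_stop = grepl("*", aa, fixed = TRUE))
}

codon_of <- function(cds_chars, codon_i) {
  chars_to_seq(cds_chars[(3 * codon_i - 2):(3 * codon_i)])
}

translate_codon <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

feature_at <- function(gene_model, pos) {
  hit <- dplyr::filter(gene_model, .data$start <= pos, .data$end >= pos)
  if (nrow(hit) == 0) NULL else hit[1, ]
}

# 2 intronic bp flanking each exon (the canonical GT/AG positions)
in_splice_site <- function(gene_model, pos) {
  introns <- dplyr::filter(gene_model, .data$feature == "intron")
  any(pos >= introns$start & pos <= introns$start + 1L) ||
    any(pos >= introns$end - 1L & pos <= introns$end)
}

#' Annotate a variant against the gene model
#'
#' Classifies a single variant (SNP or indel/deletion, VCF-style
#' left-anchored alleles) by the features it touches and its predicted
#' protein impact. A CDS SNP gets its codon recomputed and is labelled
#' synonymous / missense / stop_gained with a "Gly100Glu"-style detail; a
#' CDS indel whose length change is not a multiple of 3 is a frameshift
#' ("Arg130fs", first affected codon); a deletion spanning several features
#' yields one row per feature class touched (promoter_deletion,
#' exonic_deletion, intronic, splice_site). Variants outside the modelled
#' region are upstream/downstream, not errors.
#'
#' @param pos 1-based position (locus coordinates).
#' @param ref,alt Reference and alternate alleles.
#' @param gene_model Gene model tibble (see
#'   \code{\link{gene_model_from_config}}).
#' @param sequence Reference locus sequence (needed for codon recomputation).
#' @return Tibble with columns \code{class} and \code{detail} (one row per
#'   class for spanning deletions).
#' @examples
#' ref <- make_reference(sim_config(seed = 7))
#' annotate_variant(38382764 - sd1_coord_offset(), "G", "A",
#'                  ref$gene_model, ref$sequence)
#' @export
annotate_variant <- function(pos, ref, alt, gene_model, sequence) {
  exons <- dplyr::filter(gene_model, .data$feature == "exon") |>
    arrange(.data$start)
  gene_start <- min(exons$start)
  gene_end <- max(exons$end)
  promoter <- dplyr::filter(gene_model, .data$feature == "promoter")
  cds_map <- cds_position_map(
    lapply(seq_len(nrow(exons)), function(i) c(exons$start[i], exons$end[i])))
  chars <- seq_to_chars(sequence)

  if (nchar(ref) == 1 && nchar(alt) == 1) {
    # SNP
    if (in_splice_site(gene_model, pos)) {
      return(tibble(class = "splice_site", detail = ""))
    }
    cds_i <- match(pos, cds_map)
    if (!is.na(cds_i)) {
      codon_i <- ceiling(cds_i / 3)
      phase <- (cds_i - 1L) %% 3L + 1L
      cds_chars <- chars[cds_map]
      ref_codon <- codon_of(cds_chars, codon_i)
      alt_chars <- seq_to_chars(ref_codon)
      alt_chars[phase] <- alt
      alt_codon <- chars_to_seq(alt_chars)
      ref_aa <- translate_codon(ref_codon)
      alt_aa <- translate_codon(alt_codon)
      cls <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gained"
      else "missense"
      detail <- if (cls == "synonymous") {
        paste0(aa3(ref_aa), codon_i, aa3(ref_aa))
      } else if (cls == "stop_gained") {
        paste0(aa3(ref_aa), codon_i, "*")
      } else {
        paste0(aa3(ref_aa), codon_i, aa3(alt_aa))
      }
      return(tibble(class = cls, detail = detail))
    }
    f <- feature_at(gene_model, pos)
    if (!is.null(f) && f$feature == "intron") {
      return(tibble(class = "intronic", detail = ""))
    }
    if (!is.null(f) && f$feature == "promoter") {
      return(tibble(class = "upstream", detail = "promoter"))
    }
    return(tibble(class = if (pos < gene_start) "upstream" else "downstream",
                  detail = ""))
  }

  # indel: affected reference interval beyond the anchor base
  ref_len <- nchar(ref); alt_len <- nchar(alt)
  net <- alt_len - ref_len
  if (ref_len > alt_len) {
    del_start <- pos + alt_len
    del_end <- pos + ref_len - 1L
  } else {
    del_start <- pos + 1L   # insertion point
    del_end <- pos
  }

  # long deletions spanning features -> one class per feature touched
  if (ref_len > alt_len) {
    span_classes <- list()
    if (nrow(promoter) > 0 &&
        interval_overlap(del_start, del_end, promoter$start, promoter$end) > 0) {
      span_classes <- c(span_classes,
                        list(tibble(class = "promoter_deletion", detail = "")))
    }
    ex_hit <- any(interval_overlap(del_start, del_end, exons$start, exons$end) > 0)
    introns <- dplyr::filter(gene_model, .data$feature == "intron")
    int_hit <- nrow(introns) > 0 &&
      any(interval_overlap(del_start, del_end, introns$start, introns$end) > 0)
    multi_feature <- (length(span_classes) > 0) + ex_hit + int_hit > 1
    if (multi_feature) {
      if (ex_hit) span_classes <- c(span_classes,
                                    list(tibble(class = "exonic_deletion", detail = "")))
      if (int_hit) span_classes <- c(span_classes,
                                     list(tibble(class = "intronic", detail = "")))
      return(bind_rows(span_classes))
    }
    if (length(span_classes) == 1 && !ex_hit && !int_hit) {
      return(span_classes[[1]])
    }
  }

  # short indel within one feature
  cds_hit <- cds_map[cds_map >= del_start & cds_map <= del_end]
  if (ref_len > alt_len && length(cds_hit) == 0) {
    f <- feature_at(gene_model, del_start)
    if (!is.null(f) && f$feature == "intron") {
      if (in_splice_site(gene_model, del_start) ||
          in_splice_site(gene_model, del_end)) {
        return(tibble(class = "splice_site", detail = ""))
      }
      return(tibble(class = "intronic", detail = ""))
    }
    if (!is.null(f) && f$feature == "promoter") {
      return(tibble(class = "promoter_deletion", detail = ""))
    }
    return(tibble(class = if (del_start < gene_start) "upstream" else "downstream",
                  detail = ""))
  }
  if (ref_len < alt_len) {
    ins_in_cds <- !is.na(match(pos, cds_map)) && !is.na(match(pos + 1L, cds_map))
    if (!ins_in_cds) {
      f <- feature_at(gene_model, pos)
      cls <- if (is.null(f)) {
        if (pos < gene_start) "upstream" else "downstream"
      } else switch(f$feature, intron = "intronic", promoter = "upstream",
                    exon = "intronic")
      return(tibble(class = cls, detail = ""))
    }
  }

  # coding indel
  first_cds <- if (ref_len > alt_len) match(cds_hit[1], cds_map)
  else match(pos, cds_map) + 1L
  codon_i <- ceiling(first_cds / 3)
  cds_chars <- chars[cds_map]
  ref_aa <- translate_codon(codon_of(cds_chars, codon_i))
  if (abs(net) %% 3 != 0) {
    return(tibble(class = "frameshift",
                  detail = paste0(aa3(ref_aa), codon_i, "fs")))
  }
  tibble(class = "inframe_indel", detail = paste0(aa3(ref_aa), codon_i))
}

#' Annotate a table of variants
#'
#' Vectorised \code{\link{annotate_variant}} over the distinct sites of a
#' genotype-call or truth-edit table.
#'
#' @param variants Tibble with \code{pos}, \code{ref}, \code{alt} (extra
#'   columns are carried through; multi-allelic ALT lists are split).
#' @param gene_model,sequence As in \code{\link{annotate_variant}}.
#' @return Input rows joined with \code{class} and \code{detail} (rows
#'   duplicate where a deletion spans several feature classes).
#' @export
annotate_variants <- function(variants, gene_model, sequence) {
  sites <- variants |> distinct(.data$pos, .data$ref, .data$alt)
  ann <- purrr::pmap(list(sites$pos, sites$ref, sites$alt), function(p, r, a) {
    a1 <- strsplit(a, ",", fixed = TRUE)[[1]][1]
    annotate_variant(p, r, a1, gene_model, sequence) |>
      mutate(pos = p, ref = r, alt = a)
  }) |> bind_rows()
  left_join(variants, ann, by = c("pos", "ref", "alt"),
            relationship = "many-to-many")
}
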