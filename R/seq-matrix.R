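#' Aligned sequence matrix
#'
#' A light container for aligned haplotype sequences: a character matrix
#' (rows = samples, columns = sites) over A/C/G/T plus "-" (alignment gap),
#' "N" (missing) and IUPAC ambiguity codes (heterozygous sites from VCF
#' conversion), with 1-based reference positions per column.
#'
#' @param x Character matrix (samples x sites) with rownames.
#' @param positions Integer vector of 1-based site positions (default
#'   1..ncol).
#' @return Object of class \code{seq_matrix}.
#' @export
seq_matrix <- function(x, positions = seq_len(ncol(x))) {
  stopifnot(is.matrix(x), is.character(x))
  assert_that(length(positions) == ncol(x),
              "positions must have one entry per column")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  structure(list(states = toupper(x), positions = as.integer(positions)),
            class = "seq_matrix")
}

#' @export
print.seq_matrix <- function(x, ...) {
  cat("<seq_matrix> ", nrow(x$states), " sequences x ", ncol(x$states),
      " sites\n", sep = "")
  invisible(x)
}

#' @export
dim.seq_matrix <- function(x) dim(x$states)

#' Subset a seq_matrix to sites within a positional window
#'
#' @param m A \code{\link{seq_matrix}}.
#' @param from,to 1-based inclusive bounds.
#' @return A \code{seq_matrix} with the retained columns.
#' @export
subset_sites <- function(m, from, to) {
  keep <- m$positions >= from & m$positions <= to
  seq_matrix(m$states[, keep, drop = FALSE], m$positions[keep])
}

#' Convert full-length sequences to a seq_matrix
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return A \code{seq_matrix} over every position.
#' @export
seq_matrix_from_strings <- function(seqs) {
  lens <- nchar(seqs)
  assert_that(length(unique(lens)) == 1, "sequences must be aligned (equal length)")
  mat <- do.call(rbind, lapply(seqs, seq_to_chars))
  rownames(mat) <- names(seqs) %||% paste0("s", seq_along(seqs))
  seq_matrix(mat)
}

#' Read/write FASTA alignments as seq_matrix
#'
#' @param path FASTA path.
#' @return \code{read_fasta_matrix} returns a \code{seq_matrix}.
#' @export
read_fasta_matrix <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seq_matrix_from_strings(setNames(as.character(ss), names(ss)))
}

#' @rdname read_fasta_matrix
#' @param m A \code{seq_matrix}.
#' @export
write_fasta_matrix <- function(m, path) {
  seqs <- apply(m$states, 1, chars_to_seq)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(seqs, rownames(m$states))), path)
  invisible(path)
}

#' Write a seq_matrix in relaxed PHYLIP format
#'
#' @param m A \code{seq_matrix}.
#' @param path Output path.
#' @export
write_phylip <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m$states), ncol(m$states)), con)
  writeLines(paste(rownames(m$states),
                   apply(m$states, 1, chars_to_seq)), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path PHYLIP path.
#' @return A \code{seq_matrix}.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  nm <- vapply(body, `[`, "", 1)
  sq <- vapply(body, function(x) paste(x[-1], collapse = ""), "")
  assert_that(length(nm) == hdr[1] && all(nchar(sq) == hdr[2]),
              "PHYLIP header does not match body")
  seq_matrix_from_strings(setNames(sq, nm))
}
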