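# internal helpers shared across modules

`%||%` <- rlang::`%||%`

# run `code` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# deterministic sub-seed for a named stage, kept well below 2^31
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 131L + sum(utf8ToInt(salt)) * 7L) %% 2000000011L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# character string -> character vector of single bases, and back
seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

# 1-based inclusive interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- interval_overlap(s1, e1, s2, e2)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

# harmonic number a1(n) = sum_{i=1}^{n-1} 1/i (Watterson denominator)
harmonic_a1 <- function(n) {
  if (n < 2) return(NA_real_)
  sum(1 / seq_len(n - 1))
}

is_het <- function(gt) {
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    x <- x[x != "."]
    length(x) == 2 && x[1] != x[2]
  }, logical(1))
}

is_hom_alt <- function(gt) {
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    x <- x[x != "."]
    length(x) >= 1 && all(x == x[1]) && x[1] != "0"
  }, logical(1))
}
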