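# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_reference <- function() {
  fixture("reference", function() make_reference(sim_config(seed = 7)))
}

small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(sim_config(seed = 11), n_per_type = 2, n_het = 2)
  })
}

# brute-force diversity oracle: explicit loops over columns and pairs
oracle_diversity <- function(states) {
  valid <- c("A", "C", "G", "T")
  keep <- logical(ncol(states))
  for (j in seq_len(ncol(states))) keep[j] <- all(states[, j] %in% valid)
  x <- states[, keep, drop = FALSE]
  n <- nrow(x); L <- ncol(x)
  if (L == 0) return(list(S = NA, eta = NA, k = NA, pi = NA, L_used = 0))
  S <- 0L; eta <- 0L
  for (j in seq_len(L)) {
    u <- length(unique(x[, j]))
    if (u > 1) S <- S + 1L
    eta <- eta + u - 1L
  }
  total <- 0L; npairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(x[i, ] != x[j, ])
      npairs <- npairs + 1L
    }
  }
  k <- total / npairs
  a1 <- sum(1 / seq_len(n - 1))
  list(S = S, eta = eta, k = k, pi = k / L, L_used = L,
       theta_per_seq = eta / a1, theta_w_site = eta / a1 / L)
}

# brute-force exact tandem-repeat oracle: tests every (start, period) run
oracle_scan_trs <- function(sequence, min_period = 8L, max_period = 10L) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  found <- list()
  for (p in min_period:max_period) {
    start <- 1L
    while (start + 2 * p - 1 <= n) {
      # extend the run of s[i] == s[i - p] starting at `start`
      end <- start + p - 1L
      while (end + 1L <= n && s[end + 1L] == s[end + 1L - p]) end <- end + 1L
      span <- end - start + 1L
      if (span >= 2 * p) {
        # maximal left? if extendable left, skip (will be found earlier)
        left_ext <- start > 1L && s[start - 1L] == s[start - 1L + p]
        if (!left_ext) {
          t <- s[start:end]
          q <- p
          for (cand in 1:(p - 1)) {
            if (all(t[(cand + 1):span] == t[seq_len(span - cand)])) {
              q <- cand; break
            }
          }
          if (q == p) {
            found <- c(found, list(data.frame(
              start = start, end = end, period = p,
              unit = paste(t[1:p], collapse = ""),
              copies = span / p, span = span)))
          }
        }
        start <- start + 1L
      } else {
        start <- start + 1L
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      unit = character(), copies = double(), span = integer()))
  }
  out <- unique(do.call(rbind, found))
  out[order(out$start, out$period), , drop = FALSE]
}

# random additive tree -> patristic distance matrix (oracle for NJ recovery)
random_additive_case <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- cophenetic(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# plant a repeat unit into a random background sequence
plant_repeat <- function(len, unit, copies, at, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  rep_seq <- strsplit(strrep(unit, ceiling(copies)), "")[[1]]
  rep_seq <- rep_seq[seq_len(round(copies * nchar(unit)))]
  s[at:(at + length(rep_seq) - 1L)] <- rep_seq
  paste(s, collapse = "")
}
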