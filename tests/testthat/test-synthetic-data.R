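# synthetic-data generator: reference construction, haplotype editing,
# read-pair simulation, coalescent sampler, phenotypes

test_that("reference locus satisfies its construction constraints", {
  ref <- default_reference()
  expect_equal(nchar(ref$sequence), 25000)
  cds <- extract_cds(ref$sequence, ref$gene_model)
  expect_equal(nchar(cds) %% 3, 0)
  aa <- translate_cds(cds)
  expect_false(attr(aa, "internal_stop"))
  expect_equal(substr(as.character(aa), 1, 1), "M")
  # same config + seed -> identical bytes
  ref2 <- make_reference(sim_config(seed = 7))
  expect_identical(ref$sequence, ref2$sequence)
  # different seed -> different sequence
  ref3 <- make_reference(sim_config(seed = 8))
  expect_false(identical(ref$sequence, ref3$sequence))
})

test_that("CDS length is a multiple of 3 across random valid layouts", {
  for (seed in 1:20) {
    set.seed(seed)
    e1 <- c(10001L, 10001L + 3L * sample(100:200, 1) - 1L)
    gap1 <- sample(80:200, 1)
    e2s <- e1[2] + gap1
    e2 <- c(e2s, e2s + 3L * sample(100:200, 1) - 1L)
    gap2 <- sample(80:200, 1)
    e3s <- e2[2] + gap2
    e3 <- c(e3s, e3s + 3L * sample(50:150, 1) - 1L)
    cfg <- sim_config(seed = seed, exon_intervals = list(e1, e2, e3))
    ref <- make_reference(cfg)
    cds <- extract_cds(ref$sequence, ref$gene_model)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- translate_cds(cds)
    expect_false(attr(aa, "internal_stop"))
  }
})

test_that("invalid exon layouts are rejected", {
  expect_error(sim_config(exon_intervals = list(c(100L, 50L))), "start")
  expect_error(sim_config(exon_intervals = list(c(10001L, 10450L),
                                                c(10300L, 10600L),
                                                c(12424L, 12743L))),
               "non-overlapping")
  expect_error(sim_config(exon_intervals = list(c(10001L, 10451L),
                                                c(10553L, 10952L),
                                                c(12424L, 12743L))),
               "multiple of 3")
  expect_error(sim_config(insert_mean = 250, read_length = 150), "twice")
})

test_that("haplotype edits change sequence length exactly as defined", {
  ref <- default_reference()
  a7 <- apply_haplotype(ref, 7)
  expect_equal(nchar(ref$sequence) - nchar(a7$sequence), 383)
  a6 <- apply_haplotype(ref, 6)
  expect_equal(nchar(ref$sequence) - nchar(a6$sequence), 1279)
  a1 <- apply_haplotype(ref, 1)
  expect_identical(a1$sequence, ref$sequence)
  # SNP haplotypes preserve length; the 2-bp indel removes 2 bp
  for (t in c(2:5, 8, 10:12)) {
    expect_equal(nchar(apply_haplotype(ref, t)$sequence), nchar(ref$sequence))
  }
  expect_equal(nchar(ref$sequence) - nchar(apply_haplotype(ref, 9)$sequence), 2)
})

test_that("total length change equals total defined deletion length", {
  ref <- default_reference()
  total_diff <- 0; total_def <- 0
  for (t in 1:12) {
    a <- apply_haplotype(ref, t)
    total_diff <- total_diff + (nchar(ref$sequence) - nchar(a$sequence))
    if (nrow(a$deletions) > 0) {
      total_def <- total_def + sum(a$deletions$end - a$deletions$start + 1)
    }
  }
  expect_equal(total_diff, total_def)
})

test_that("truth edits round-trip through the VCF writer and reader", {
  sim <- small_cohort()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$calls, path)
  back <- read_vcf(path)
  orig <- dplyr::arrange(sim$calls, pos, sample)
  got <- dplyr::arrange(back, pos, sample)
  expect_equal(nrow(got), nrow(orig))
  key <- c("chrom", "pos", "ref", "sample", "gt")
  expect_equal(got[key], orig[key])
  expect_equal(got$depth, orig$depth)
})

test_that("simulated template lengths match the insert model", {
  cfg <- sim_config(seed = 3)
  ref <- default_reference()
  pairs <- simulate_read_pairs(ref$sequence, cfg, accession = "wt", seed = 5)
  N <- nrow(pairs)
  expect_lt(abs(mean(pairs$template_length) - 400), 3 * 30 / sqrt(N))
  expect_true(all(pairs$orientation == "FR"))
  expect_true(all(pairs$right_pos > pairs$left_pos))
})

test_that("pairs spanning a deletion have inflated template lengths", {
  cfg <- sim_config(seed = 3)
  ref <- default_reference()
  a7 <- apply_haplotype(ref, 7)
  pairs <- simulate_read_pairs(a7$sequence, cfg, deletions = a7$deletions,
                               accession = "t7", seed = 6)
  s <- a7$deletions$start; e <- a7$deletions$end
  spanning <- pairs$left_pos + cfg$read_length - 1 < s & pairs$right_pos > e
  expect_gt(sum(spanning), 10)
  m_span <- mean(pairs$template_length[spanning])
  expect_lt(abs(m_span - (400 + 383)), 3 * 30 / sqrt(sum(spanning)) + 5)
  # non-spanning pairs unaffected
  m_conc <- mean(pairs$template_length[!spanning])
  expect_lt(abs(m_conc - 400), 5)
})

test_that("degenerate read-simulation inputs error", {
  cfg <- sim_config(seed = 1)
  ref <- default_reference()
  cfg_bad <- cfg; cfg_bad$coverage <- 0
  expect_error(simulate_read_pairs(ref$sequence, cfg_bad), "coverage")
  expect_error(simulate_read_pairs(strrep("A", 300), cfg), "shorter")
})

test_that("neutral sampler matches Watterson's expectation", {
  # theta = 0: no segregating sites
  m0 <- simulate_neutral_sample(8, 0, seed = 1)
  expect_equal(ncol(m0$states), 0)
  # E[S] = theta * a1(n); check over replicates with 3-SE tolerance
  set.seed(42)
  reps <- 400
  S <- replicate(reps, ncol(simulate_neutral_sample(10, 5)$states))
  expected <- 5 * sum(1 / (1:9))
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - expected), 3 * se)
  # n = 2: E[pairwise differences] = theta
  set.seed(43)
  k2 <- replicate(400, {
    m <- simulate_neutral_sample(2, 2)
    if (ncol(m$states) == 0) 0 else sum(m$states[1, ] != m$states[2, ])
  })
  expect_lt(abs(mean(k2) - 2), 3 * sd(k2) / sqrt(400))
})

test_that("phenotypes follow the configured group means", {
  cfg <- sim_config(seed = 2)
  truth <- tibble::tibble(accession = paste0("a", 1:60),
                          type_id = rep(c(1L, 7L), each = 30))
  ph <- simulate_phenotypes(truth, cfg, seed = 9)
  expect_equal(nrow(ph), 60)
  means <- tapply(ph$height_cm, ph$type_id, mean)
  expect_lt(abs(means[["1"]] - 150), 3 * 8 / sqrt(30))
  expect_lt(abs(means[["7"]] - 85), 3 * 8 / sqrt(30))
  # zero noise puts every accession exactly at its mean
  cfg0 <- cfg; cfg0$height_sd <- 0
  ph0 <- simulate_phenotypes(truth, cfg0, seed = 9)
  expect_true(all(ph0$height_cm %in% c(150, 85)))
  # determinism
  expect_identical(ph, simulate_phenotypes(truth, cfg, seed = 9))
  # missing group mean errors
  expect_error(simulate_phenotypes(tibble::tibble(accession = "x", type_id = 99L),
                                   cfg), "height mean")
})

test_that("cohort simulation is deterministic and writes byte-identical files", {
  sim1 <- simulate_cohort(sim_config(seed = 21), n_per_type = 1, types = c(1, 7))
  sim2 <- simulate_cohort(sim_config(seed = 21), n_per_type = 1, types = c(1, 7))
  expect_identical(sim1$calls, sim2$calls)
  expect_identical(sim1$pairs, sim2$pairs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(sim1, d1); write_cohort(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
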