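# haplotype assignment, precedence, frequency tables, deletion geometry

test_that("deletion geometry matches the catalogue", {
  geo <- deletion_geometry(sd1_haplotypes())
  len7 <- geo$lengths$length[geo$lengths$type_id == 7]
  len6 <- geo$lengths$length[geo$lengths$type_id == 6]
  expect_equal(len7, 383)
  expect_equal(len6, 1279)
  d <- geo$three_prime_distances
  expect_equal(d$distance[d$type_a == 6 & d$type_b == 7], 13)
  # 3'-end breakpoints land at the published chromosome-1 positions
  expect_equal(geo$lengths$three_prime_end[geo$lengths$type_id == 7], 38383145)
  expect_equal(geo$lengths$three_prime_end[geo$lengths$type_id == 6], 38383158)
  # invariant to using `end` consistently instead of `end + 1`
  ends <- geo$lengths$end
  expect_equal(abs(diff(ends)), d$distance)
  expect_error(deletion_geometry(dplyr::filter(sd1_haplotypes(),
                                               class == "combo")),
               "no long-deletion")
})

classify_simple <- function(variants, dels = NULL) {
  classify_accession(variants, dels, accession = "acc")
}

hom_call <- function(pos_chr1, alt, ref = "G") {
  tibble::tibble(chrom = "locus", pos = pos_chr1 - sd1_coord_offset(),
                 ref = ref, alt = alt, sample = "acc", gt = "1/1",
                 depth = 30, alt_fraction = 1, allele = alt)
}

test_that("combination types resolve from residue-100/340 states", {
  empty <- hom_call(38382764, "A")[0, ]
  expect_equal(classify_simple(empty)$label, "1")   # reference identity
  eq <- dplyr::bind_rows(hom_call(38382764, "A"), hom_call(38385057, "A"))
  expect_equal(classify_simple(eq)$label, "2")
  er <- hom_call(38382764, "A")
  expect_equal(classify_simple(er)$label, "11")
  gq <- hom_call(38385057, "A")
  expect_equal(classify_simple(gq)$label, "GQ_unobserved")
})

test_that("point LOF diagnostics take precedence over 100/340 states", {
  # stop-gained at residue 342 plus readable EQ states -> type 8
  v <- dplyr::bind_rows(hom_call(38385064, "A", ref = "C"),
                        hom_call(38382764, "A"), hom_call(38385057, "A"))
  expect_equal(classify_simple(v)$label, "8")
  # every point type classifies from its own diagnostic
  defs <- sd1_haplotypes()
  for (t in c(3, 4, 5, 8, 10, 12)) {
    d <- defs[defs$type_id == t, ]
    expect_equal(classify_simple(hom_call(d$pos, d$alt, ref = d$ref))$label,
                 as.character(t))
  }
})

test_that("structural calls dominate and conflicts are errors", {
  v7 <- dplyr::bind_rows(hom_call(38382764, "A"))
  del7 <- tibble::tibble(start = 38382762L - sd1_coord_offset(),
                         end = 38383144L - sd1_coord_offset(),
                         support = 10L)
  expect_equal(classify_simple(v7, del7)$label, "7")
  del6 <- tibble::tibble(start = 38381879L - sd1_coord_offset(),
                         end = 38383157L - sd1_coord_offset(),
                         support = 10L)
  both <- dplyr::bind_rows(del7, del6)
  expect_error(classify_simple(v7, both), "multiple structural")
  # a call overlapping below the reciprocal threshold does not match
  weak <- tibble::tibble(start = del7$start - 400L, end = del7$end + 400L,
                         support = 10L)
  expect_equal(classify_simple(v7[0, ], weak)$label, "1")
})

test_that("heterozygous deciding sites give the heterozygous label", {
  het <- tibble::tibble(chrom = "locus",
                        pos = 38382764L - sd1_coord_offset(), ref = "G",
                        alt = "A", sample = "acc", gt = "0/1", depth = 30,
                        alt_fraction = 0.5, allele = "A")
  expect_equal(classify_simple(het)$label, "heterozygous")
  defs <- sd1_haplotypes()
  d <- defs[defs$type_id == 8, ]
  het_lof <- dplyr::mutate(hom_call(d$pos, d$alt, ref = d$ref), gt = "0/1",
                           alt_fraction = 0.5)
  expect_equal(classify_simple(het_lof)$label, "heterozygous")
})

test_that("classification is invariant to variant row order", {
  v <- dplyr::bind_rows(hom_call(38385064, "A", ref = "C"),
                        hom_call(38382764, "A"), hom_call(38385057, "A"))
  perm <- v[c(3, 1, 2), ]
  expect_equal(classify_simple(v)$label, classify_simple(perm)$label)
})

test_that("a noiseless synthetic cohort is recovered perfectly", {
  sim <- small_cohort()
  hc <- classify_cohort(sim$calls, sim$pairs)
  joined <- dplyr::left_join(sim$truth, hc, by = "accession")
  expect_equal(joined$label.y, joined$label.x)
  expect_equal(sum(joined$label.y == "heterozygous"), 2)
})

test_that("frequency tables count per subpopulation with exact truth", {
  calls <- tibble::tibble(
    accession = paste0("a", 1:10), type_id = 1L, label = "1",
    zygosity = "homozygous", evidence = "")
  meta <- tibble::tibble(accession = paste0("a", 1:10),
                         subpopulation = "indica", category = "landrace")
  tab <- tabulate_frequencies(calls, meta)
  expect_equal(tab$n, 10)
  expect_equal(tab$pct, 100)
  # heterozygous calls excluded from numerator and denominator
  calls2 <- dplyr::bind_rows(
    calls, tibble::tibble(accession = "a11", type_id = NA_integer_,
                          label = "heterozygous", zygosity = "heterozygous",
                          evidence = ""))
  meta2 <- dplyr::bind_rows(meta, tibble::tibble(
    accession = "a11", subpopulation = "indica", category = "landrace"))
  tab2 <- tabulate_frequencies(calls2, meta2)
  expect_equal(sum(tab2$n), 10)
  tab2h <- tabulate_frequencies(calls2, meta2, homozygous_only = FALSE)
  expect_equal(sum(tab2h$n), 11)
  # missing metadata: excluded with a warning, listed in the report
  expect_warning(tab3 <- tabulate_frequencies(calls2, meta), "without metadata")
  expect_equal(attr(tab3, "excluded"), "a11")
})

test_that("frequency marginals match a counting oracle on a synthetic cohort", {
  sim <- small_cohort()
  hc <- classify_cohort(sim$calls, sim$pairs)
  tab <- tabulate_frequencies(hc, sim$metadata)
  truth_counts <- dplyr::count(
    dplyr::filter(dplyr::left_join(sim$truth, sim$metadata, by = "accession"),
                  label != "heterozygous"),
    label, subpopulation)
  joined <- dplyr::full_join(tab, truth_counts,
                             by = c("label", "subpopulation"))
  expect_equal(joined$n.x, joined$n.y)
  # per-group percentages sum to 100 (up to rounding)
  sums <- dplyr::summarise(dplyr::group_by(tab, subpopulation),
                           s = sum(pct))$s
  expect_true(all(abs(sums - 100) < 0.3))
})
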