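test_that("exhaustive enumeration covers 3 SNVs per coding nucleotide", {
  g <- toy_genome()
  tab <- synth_ea_table(g, seed = 5)
  bg <- enumerate_background(g, tab)
  expect_equal(bg$n_enumerated, 3 * g$coding_length_total)
  # per-gene opportunity counts: 15-nt CDS -> 45 possible SNVs
  expect_equal(unname(bg$opportunities), c(45L, 45L))
  expect_equal(sum(bg$opportunities), 3 * g$coding_length_total)
  # pool size equals reachable missense with an EA entry
  for (lt in names(bg$pools)) {
    n_expect <- sum(bg$enum$locus_tag == lt & bg$enum$effect == "missense" &
                      !is.na(bg$enum$ea))
    expect_length(bg$pools[[lt]], n_expect)
  }
  expect_equal(length(bg$genome_pool), sum(lengths(bg$pools)))
})

test_that("exhaustive pools are deterministic and invariant to feature order", {
  tab_for <- function(g) synth_ea_table(g, seed = 5)
  g1 <- toy_genome(feature_order = c("A", "B"))
  g2 <- toy_genome(feature_order = c("B", "A"))
  b1 <- enumerate_background(g1, tab_for(g1))
  b2 <- enumerate_background(g2, tab_for(g2))
  expect_identical(b1$pools, b2$pools)
  expect_identical(b1$pools, enumerate_background(g1, tab_for(g1))$pools)
})

test_that("sampled backgrounds are seeded and converge to the exhaustive pool", {
  g <- toy_genome()
  tab <- synth_ea_table(g, seed = 5)
  s1 <- sample_background(g, tab, n_mutations = 500, seed = 42)
  s2 <- sample_background(g, tab, n_mutations = 500, seed = 42)
  expect_identical(s1$pools, s2$pools)
  expect_equal(s1$mode, "sampled")

  one <- sample_background(g, tab, n_mutations = 1, seed = 7)
  expect_lte(length(one$genome_pool), 1)

  # total-variation distance between sampled and exhaustive per-gene pool
  # compositions below 0.05 at n = 1e5
  ex <- enumerate_background(g, tab)
  big <- sample_background(g, tab, n_mutations = 1e5, seed = 8)
  for (lt in names(ex$pools)) {
    p <- table(factor(big$pools[[lt]], levels = sort(unique(ex$pools[[lt]]))))
    q <- table(factor(ex$pools[[lt]], levels = sort(unique(ex$pools[[lt]]))))
    tv <- 0.5 * sum(abs(p / sum(p) - q / sum(q)))
    expect_lt(tv, 0.05)
  }
})

test_that("custom backgrounds reuse the ingestion path", {
  g <- toy_genome()
  tab <- synth_ea_table(g, seed = 5)
  v <- data.frame(contig = "TOY", pos = c(14L, 50L, 47L),
                  strain = "obs", stringsAsFactors = FALSE)
  v$ref <- substring(g$contigs[[1]], v$pos, v$pos)
  v$alt <- c("A", "C", "G")
  vcf <- tempfile(fileext = ".vcf")
  gd <- tempfile(fileext = ".gd")
  write_vcf(v, g, vcf)
  write_gd(v, g, gd)

  bg_vcf <- load_custom_background(vcf, "vcf", g, tab)
  bg_gd <- load_custom_background(gd, "gd", g, tab)
  expect_identical(bg_vcf$pools, bg_gd$pools)

  # a custom background identical to the observed set gives D+ = 0, p = 1
  eff <- annotate_variants(v, g, tab)
  obs <- eff$ea[eff$effect == "missense" & !is.na(eff$ea)]
  for (lt in unique(eff$locus_tag[eff$effect == "missense"])) {
    pool <- bg_vcf$pools[[lt]]
    o <- sort(eff$ea[eff$effect == "missense" & eff$locus_tag == lt])
    ks <- ea_ks(o, pool)
    expect_equal(ks$stat, 0)
    expect_equal(ks$p, 1)
  }

  # intergenic-only custom background is an error (statistics undefined)
  vi <- data.frame(contig = "TOY", pos = 5L, ref = "C", alt = "T",
                   strain = "obs")
  vcf2 <- tempfile(fileext = ".vcf")
  write_vcf(vi, g, vcf2)
  expect_error(load_custom_background(vcf2, "vcf", g, tab),
               "no scored missense")
})
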