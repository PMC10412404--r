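write_test_ea <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("locus_tag\tposition\tref_aa\talt_aa\tea", rows), path)
  path
}

test_that("EA table load/lookup round-trips and rejects bad rows", {
  g <- toy_genome()
  tab <- load_ea_table(write_test_ea(c(
    "tgA\t2\tA\tV\t73.5",
    "tgA\t2\tA\tD\t91.25",
    "tgB\t3\tD\tG\t12",
    "tgA\t3\tQ\tH\t101"      # out of range -> rejected
  )), genome = g)
  expect_equal(unname(tab$report["rejected_range"]), 1L)

  hit <- lookup_ea(tab, "tgA", "A2V")
  expect_equal(hit$ea, 73.5)
  expect_equal(hit$status, "ok")
  # absent entries are missing, never zero
  expect_true(is.na(lookup_ea(tab, "tgA", "A2W")$ea))
  expect_equal(lookup_ea(tab, "tgA", "A2W")$status, "missing")
  # reference-residue mismatch is distinct from missing
  expect_equal(lookup_ea(tab, "tgA", "G2V")$status, "ref_mismatch")
  # stop-gain policy
  expect_true(is.na(lookup_ea(tab, "tgA", "Q3*")$ea))
  expect_equal(lookup_ea(tab, "tgA", "Q3*", stop_policy = "max")$ea, 100)
})

test_that("rows contradicting the protein sequence are rejected; conflicting duplicates error", {
  g <- toy_genome()
  tab <- load_ea_table(write_test_ea(c(
    "tgA\t2\tA\tV\t50",
    "tgA\t2\tG\tW\t50",      # protein has A at 2, not G
    "tgZ\t1\tM\tK\t50"       # unknown gene
  )), genome = g)
  expect_equal(nrow(tab$data), 1)
  expect_equal(unname(tab$report["rejected_ref_mismatch"]), 2L)

  expect_error(
    load_ea_table(write_test_ea(c("tgA\t2\tA\tV\t50", "tgA\t2\tA\tV\t60")), g),
    "conflicting EA"
  )
})

test_that("a 0-1 scaled table is rescaled to 0-100 with a warning", {
  f <- write_test_ea(c("tgA\t2\tA\tV\t0.4", "tgA\t2\tA\tD\t0.9"))
  expect_warning(tab <- load_ea_table(f), "rescaling")
  expect_equal(sort(tab$data$ea), c(40, 90))
})

test_that("synthetic EA tables are deterministic under seed", {
  g <- toy_genome()
  t1 <- synth_ea_table(g, seed = 5)
  t2 <- synth_ea_table(g, seed = 5)
  t3 <- synth_ea_table(g, seed = 6)
  expect_identical(t1$data, t2$data)
  expect_false(identical(t1$data$ea, t3$data$ea))
})

test_that("synthetic EA entries are exactly the single-nucleotide-reachable missense set", {
  g <- toy_genome()
  tab <- synth_ea_table(g, seed = 5)
  bg <- enumerate_background(g, tab)
  reach <- unique(bg$enum[bg$enum$effect == "missense",
                          c("locus_tag", "codon_index", "alt_aa")])
  have <- unique(tab$data[, c("locus_tag", "position", "alt_aa")])
  key_r <- paste(reach$locus_tag, reach$codon_index, reach$alt_aa)
  key_h <- paste(have$locus_tag, have$position, have$alt_aa)
  expect_setequal(key_h, key_r)
})

test_that("Beta(1,1) synthetic scores have mean about 50 at large entry counts", {
  g <- make_synthetic_genome(30, c(300L, 600L), seed = 11)
  tab <- synth_ea_table(g, seed = 12, shape1 = 1, shape2 = 1)
  expect_gt(nrow(tab$data), 1e4)
  expect_lt(abs(mean(tab$data$ea) - 50), 2)
})

test_that("EA assigned during annotation equals a direct lookup on the same key", {
  g <- toy_genome()
  tab <- synth_ea_table(g, seed = 5)
  v <- data.frame(contig = "TOY", pos = c(14L, 11L, 50L, 47L),
                  strain = "s1", stringsAsFactors = FALSE)
  v$ref <- substring(g$contigs[[1]], v$pos, v$pos)
  v$alt <- c("A", "A", "C", "G")
  e <- annotate_variants(v, g, tab)
  mis <- e[e$effect == "missense", ]
  expect_gt(nrow(mis), 0)
  direct <- lookup_ea(tab, mis$locus_tag, mis$sub)
  expect_equal(mis$ea, direct$ea)
})

test_that("residue track tables load into per-gene vectors", {
  g <- toy_genome()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("locus_tag\tposition\tscore",
               "tgA\t1\t85.2", "tgA\t4\t10", "tgB\t2\t55"), f)
  tr <- load_residue_track(f, g)
  expect_equal(tr$tgA, c(85.2, NA, NA, 10))
  expect_equal(tr$tgB, c(NA, 55, NA, NA))
})
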