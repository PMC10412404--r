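write_test_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=TOY,length=60>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows
  ), path)
  path
}

test_that("VCF reading keeps biallelic SNVs and counts every skip reason", {
  rows <- c(
    "TOY\t14\t.\tC\tA\t.\tPASS\t.",
    "TOY\t16\t.\tC\tT\t.\t.\t.",
    "TOY\t20\t.\tGT\tG\t.\tPASS\t.",     # deletion
    "TOY\t22\t.\tG\tA,T\t.\tPASS\t.",    # multi-allelic
    "TOY\t25\t.\tA\tG\t.\tq10\t.",       # filtered
    "TOY\t30\t.\tA\t<DEL>\t.\tPASS\t."   # symbolic
  )
  v <- read_vcf(write_test_vcf(rows), strain = "s1")
  expect_equal(nrow(v), 2)
  expect_equal(v$pos, c(14L, 16L))
  expect_equal(v$ref, c("C", "C"))
  expect_equal(v$alt, c("A", "T"))
  expect_equal(unique(v$strain), "s1")
  rep <- attr(v, "report")
  expect_equal(unname(rep["skipped_indel"]), 1L)
  expect_equal(unname(rep["skipped_multiallelic"]), 1L)
  expect_equal(unname(rep["skipped_filter"]), 1L)
  expect_equal(unname(rep["skipped_symbolic"]), 1L)
  # counts conserve: accepted + skipped(by reason) = total data lines
  expect_equal(nrow(v) + sum(rep), length(rows))

  # multi-allelic splitting and filter retention are opt-in
  v2 <- read_vcf(write_test_vcf(rows), strain = "s1",
                 split_multiallelic = TRUE, keep_filtered = TRUE)
  expect_equal(nrow(v2), 5)
  expect_equal(sum(v2$pos == 22), 2)
})

test_that("a VCF without a header is a hard error", {
  bad <- tempfile(fileext = ".vcf")
  writeLines("TOY\t14\t.\tC\tA\t.\tPASS\t.", bad)
  expect_error(read_vcf(bad), "header")
})

test_that("GenomeDiff reading converts SNP entries and skips everything else", {
  g <- toy_genome()
  gd <- tempfile(fileext = ".gd")
  writeLines(c(
    "#=GENOME_DIFF\t1.0",
    "SNP\t1\t23\tTOY\t14\tA",
    "DEL\t2\t24\tTOY\t20\t1",
    "RA\t23\t.\tTOY\t14\t0\tC\tA",
    "SNP\t3\t25\tTOY\t999\tA",   # beyond contig
    "SNP\t4\t26\tTOY\t15\tT"     # alt equals reference base
  ), gd)
  v <- read_gd(gd, g, strain = "s1")
  expect_equal(nrow(v), 1)
  # reference base read from the genome
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "A")
  rep <- attr(v, "report")
  expect_equal(unname(rep["skipped_other_type"]), 1L)
  expect_equal(unname(rep["skipped_evidence"]), 1L)
  expect_equal(unname(rep["rejected_bad_position"]), 1L)
  expect_equal(unname(rep["rejected_bad_base"]), 1L)
})

test_that("substitution lists are validated and malformed lines reported", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "recA\tA123V",
    "ftsZ\tQ47*\ts2",
    "geneX\t123AV",
    "geneY\tA12A"
  ), f)
  s <- read_substitutions(f, strain = "s1")
  expect_equal(nrow(s), 2)
  expect_equal(s$gene, c("recA", "ftsZ"))
  expect_equal(s$alt_aa, c("V", "*"))
  expect_equal(s$strain, c("s1", "s2"))
  expect_equal(attr(s, "report")$rejected_lines, c(4L, 5L))
})

test_that("annotation assigns the expected effect classes on the toy genome", {
  g <- toy_genome()
  v <- data.frame(
    contig = "TOY",
    pos = c(14L, 16L, 18L, 12L, 5L, 50L),
    ref = c("C", "C", "A", "G", "C", "A"),
    alt = c("A", "T", "G", "A", "T", "C"),
    strain = "s1", stringsAsFactors = FALSE
  )
  e <- annotate_variants(v, g)
  by_pos <- function(p) e[!is.na(e$pos) & e$pos == p, ]
  # codon 2 GCT -> GAT: missense A2D
  expect_equal(by_pos(14)$sub, "A2D")
  expect_equal(by_pos(14)$effect, "missense")
  # codon 3 CAA -> TAA: nonsense
  expect_equal(by_pos(16)$sub, "Q3*")
  expect_equal(by_pos(16)$effect, "nonsense")
  # codon 3 third position CAA -> CAG: synonymous
  expect_equal(by_pos(18)$effect, "synonymous")
  # start codon ATG -> ATA: start-loss
  expect_equal(by_pos(12)$effect, "start-loss")
  # intergenic retained for accounting only
  expect_equal(by_pos(5)$effect, "intergenic")
  expect_true(is.na(by_pos(5)$locus_tag))
  # minus-strand gene: genomic A>C at 50 is coding T>G in codon 2 (GTT->GGT)
  expect_equal(by_pos(50)$locus_tag, "tgB")
  expect_equal(by_pos(50)$sub, "V2G")

  # reference mismatches are rejected and counted
  bad <- data.frame(contig = "TOY", pos = 14L, ref = "G", alt = "A",
                    strain = "s1")
  e2 <- annotate_variants(bad, g)
  expect_equal(nrow(e2), 0)
  expect_equal(unname(attr(e2, "report")["rejected_ref_mismatch"]), 1L)
})

test_that("pooling collapses duplicates within a strain but keeps recurrence across strains", {
  r <- data.frame(contig = "TOY", pos = 14L, ref = "C", alt = "A",
                  strain = "s1", stringsAsFactors = FALSE)
  r2 <- r; r2$strain <- "s2"
  pooled <- pool_variants(rbind(r, r), rbind(r2))
  expect_equal(nrow(pooled), 2)
  expect_setequal(pooled$strain, c("s1", "s2"))
})

test_that("the same mutation set as VCF and GD yields identical variant tables", {
  g <- toy_genome()
  v <- data.frame(contig = "TOY", pos = c(14L, 16L, 50L),
                  ref = c("C", "C", "A"), alt = c("A", "T", "C"),
                  strain = "x", stringsAsFactors = FALSE)
  vcf <- tempfile(fileext = ".vcf"); gd <- tempfile(fileext = ".gd")
  write_vcf(v, g, vcf)
  write_gd(v, g, gd)
  a <- read_vcf(vcf, strain = "x")
  b <- read_gd(gd, g, strain = "x")
  expect_equal(a[, c("contig", "pos", "ref", "alt", "strain")],
               b[, c("contig", "pos", "ref", "alt", "strain")],
               ignore_attr = TRUE)
})
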