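test_that("GenBank loading preserves genes on both strands and translates them", {
  g <- toy_genome()
  expect_s3_class(g, "ref_genome")
  expect_equal(nrow(g$genes), 2)
  expect_equal(g$genes$strand, c("+", "-"))
  expect_equal(g$genes$protein_seq, c("MAQC", "MVDR"))
  expect_equal(g$genes$gene_name, c("alpha", "beta"))
  expect_equal(g$coding_length_total, 30)
  expect_equal(g$genes$cds_length, g$genes$end - g$genes$start + 1L)
  expect_equal(g$genes$protein_length, g$genes$cds_length / 3 - 1)
})

test_that("unusable CDS features are skipped with reasons; no usable CDS is an error", {
  extra <- c(
    "     CDS             join(10..12,16..24)",
    '                     /locus_tag="tgJoin"',
    "     CDS             25..39",  # no locus_tag, and pad translation is broken anyway
    "     CDS             10..23",  # length not divisible by 3
    '                     /locus_tag="tgFrame"'
  )
  g <- toy_genome(extra_features = extra)
  expect_equal(nrow(g$genes), 2)
  expect_equal(unname(g$report[["compound_location"]]), 1)
  expect_equal(unname(g$report[["length_not_multiple_of_3"]]), 1)
  expect_equal(unname(g$report[["missing_locus_tag"]]), 1)

  no_cds <- tempfile(fileext = ".gbk")
  lines <- toy_genbank_lines()
  writeLines(lines[!grepl("CDS|locus_tag|/gene", lines)], no_cds)
  expect_error(load_genbank(no_cds), "no usable CDS")
  expect_error(load_genbank(tempfile()), "not found")
})

test_that("codon translation follows the bacterial table", {
  expect_equal(translate_codon(c("ATG", "TAA", "GTG", "TGA", "TAG")),
               c("M", "*", "V", "*", "*"))
  # ambiguous bases are untranslatable, never an error
  expect_equal(translate_codon(c("ANA", "NNN", "AT")),
               c(NA_character_, NA_character_, NA_character_))
})

test_that("codon_at maps boundary and interior positions on both strands", {
  g <- toy_genome()
  # plus strand: first base of the start codon
  expect_equal(codon_at(g, "tgA", 10),
               data.frame(codon_index = 1L, offset_in_codon = 0L, codon = "ATG"))
  # minus strand: gene end is the first base of the start codon
  expect_equal(codon_at(g, "tgB", 54),
               data.frame(codon_index = 1L, offset_in_codon = 0L, codon = "ATG"))
  # interior position, hand-indexed: pos 15 is codon 2 offset 2 (GCT)
  expect_equal(codon_at(g, "tgA", 15),
               data.frame(codon_index = 2L, offset_in_codon = 2L, codon = "GCT"))
  expect_error(codon_at(g, "tgA", 30), "outside gene")
  expect_error(codon_at(g, "nope", 10), "unknown locus_tag")
})

test_that("codon_at visits each (codon_index, offset) exactly once across a gene", {
  g <- toy_genome()
  for (lt in g$genes$locus_tag) {
    row <- g$genes[g$genes$locus_tag == lt, ]
    m <- codon_at(g, lt, row$start:row$end)
    key <- paste(m$codon_index, m$offset_in_codon)
    expect_equal(sort(key), sort(paste(rep(1:(row$cds_length / 3), each = 3), 0:2)))
    # translating codons 1..L reproduces the protein followed by a stop
    codons <- m$codon[m$offset_in_codon == 0][order(m$codon_index[m$offset_in_codon == 0])]
    expect_equal(paste(translate_codon(codons), collapse = ""),
                 paste0(row$protein_seq, "*"))
  }
})

test_that("GFF3+FASTA loading matches the GenBank reader", {
  contig <- toy_contig()
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">TOY synthetic", contig), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "TOY\ttest\tCDS\t10\t24\t.\t+\t0\tID=cdsA;locus_tag=tgA;gene=alpha",
    "TOY\ttest\tCDS\t40\t54\t.\t-\t0\tID=cdsB;locus_tag=tgB;gene=beta"
  ), gff)
  g1 <- toy_genome()
  g2 <- load_gff3(gff, fa)
  expect_equal(g2$genes[names(g2$genes) != "contig"],
               g1$genes[names(g1$genes) != "contig"])
  expect_equal(unname(g2$contigs), unname(g1$contigs))
})

test_that("annotation is strand-symmetric under genome reverse complement", {
  g <- toy_genome()
  g_rc <- load_genbank(write_mirrored_toy_genbank())
  L <- nchar(g$contigs[[1]])
  variants <- data.frame(
    contig = "TOY",
    pos = c(14L, 16L, 18L, 50L, 43L),   # hits in both genes
    stringsAsFactors = FALSE
  )
  variants$ref <- substring(g$contigs[[1]], variants$pos, variants$pos)
  variants$alt <- c("A", "T", "G", "C", "C")
  variants$strain <- "s1"
  mirrored <- data.frame(
    contig = "TOYRC",
    pos = L - variants$pos + 1L,
    ref = unname(c(A = "T", C = "G", G = "C", T = "A")[variants$ref]),
    alt = unname(c(A = "T", C = "G", G = "C", T = "A")[variants$alt]),
    strain = "s1", stringsAsFactors = FALSE
  )
  e1 <- annotate_variants(variants, g)
  e2 <- annotate_variants(mirrored, g_rc)
  cols <- c("locus_tag", "codon_index", "ref_aa", "alt_aa", "sub", "effect")
  o1 <- order(e1$locus_tag, e1$codon_index, e1$alt_aa)
  o2 <- order(e2$locus_tag, e2$codon_index, e2$alt_aa)
  expect_equal(e1[o1, cols], e2[o2, cols], ignore_attr = TRUE)
})
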