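options(eadriver.verbose = FALSE)

# ---- hand-crafted toy genome ----------------------------------------------
# contig (60 nt):
#   1..9    C pad
#   10..24  gene tgA, + strand:  ATG GCT CAA TGT TAA  -> protein MAQC
#   25..39  A pad
#   40..54  gene tgB, - strand, coding ATG GTT GAT CGA TAA -> protein MVDR
#   55..60  G pad
TOY_GENE_A <- "ATGGCTCAATGTTAA"
TOY_GENE_B <- "ATGGTTGATCGATAA"

toy_contig <- function() {
  rc_b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(TOY_GENE_B)))
  paste0(strrep("C", 9), TOY_GENE_A, strrep("A", 15), rc_b, strrep("G", 6))
}

toy_genbank_lines <- function(contig = toy_contig(), contig_id = "TOY",
                              extra_features = character(0),
                              feature_order = c("A", "B")) {
  feats <- list(
    A = c("     CDS             10..24",
          '                     /locus_tag="tgA"',
          '                     /gene="alpha"'),
    B = c("     CDS             complement(40..54)",
          '                     /locus_tag="tgB"',
          '                     /gene="beta"')
  )
  c(
    sprintf("LOCUS       %s              %d bp    DNA     circular BCT 01-JAN-2024",
            contig_id, nchar(contig)),
    "DEFINITION  toy fixture.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(contig)),
    unlist(feats[feature_order], use.names = FALSE),
    extra_features,
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(contig)),
    "//"
  )
}

write_toy_genbank <- function(path = tempfile(fileext = ".gbk"), ...) {
  writeLines(toy_genbank_lines(...), path)
  path
}

toy_genome <- function(...) load_genbank(write_toy_genbank(...))

# mirror image of the toy genome: reverse-complemented contig, flipped
# coordinates and strands (for the strand-symmetry property)
write_mirrored_toy_genbank <- function(path = tempfile(fileext = ".gbk")) {
  contig <- toy_contig()
  L <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  lines <- c(
    sprintf("LOCUS       TOYRC              %d bp    DNA     circular BCT 01-JAN-2024", L),
    "DEFINITION  mirrored toy fixture.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    sprintf("     CDS             complement(%d..%d)", L - 24 + 1, L - 10 + 1),
    '                     /locus_tag="tgA"',
    sprintf("     CDS             %d..%d", L - 54 + 1, L - 40 + 1),
    '                     /locus_tag="tgB"',
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(rc)),
    "//"
  )
  writeLines(lines, path)
  path
}

# ---- independent oracles ---------------------------------------------------

# brute-force sweep of F_bg - F_obs over all pooled points
bf_ks_stat <- function(obs, bg) {
  pts <- c(obs, bg)
  max(vapply(pts, function(t) mean(bg <= t) - mean(obs <= t), 1.0), 0)
}

# exact binomial upper tail P(X >= n) by direct summation
bf_binom_tail <- function(n, N, p) {
  if (n <= 0) return(1)
  if (n > N) return(0)
  k <- n:N
  sum(exp(lchoose(N, k) + k * log(p) + (N - k) * log1p(-p)))
}

# Benjamini-Hochberg step-up, written out directly
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# ---- shared heavy fixture for acceptance-scale checks ----------------------
.fx_cache <- new.env(parent = emptyenv())

calibration_fixture <- function() {
  if (is.null(.fx_cache$cal)) {
    g <- make_synthetic_genome(50, c(300L, 900L), seed = 101)
    ea <- synth_ea_table(g, seed = 102)
    .fx_cache$cal <- list(genome = g, ea = ea,
                          bg = enumerate_background(g, ea))
  }
  .fx_cache$cal
}

# small effects table builder for structure/track tests
make_effects <- function(locus_tag, codon_index, ref_aa, alt_aa, ea,
                         strain = "s1",
                         effect = ifelse(alt_aa == "*", "nonsense", "missense")) {
  n <- length(codon_index)
  data.frame(
    strain = rep_len(strain, n), contig = rep_len(NA_character_, n),
    pos = rep_len(NA_integer_, n), ref = rep_len(NA_character_, n),
    alt = rep_len(NA_character_, n),
    locus_tag = rep_len(locus_tag, n), gene_name = rep_len("", n),
    codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
    sub = paste0(ref_aa, codon_index, alt_aa),
    effect = rep_len(effect, n), ea = ea,
    stringsAsFactors = FALSE
  )
}
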