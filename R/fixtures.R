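#' Specification for a synthetic ALE fixture
#'
#' Defines the study conditions emulated by [make_fixture()]: a toy
#' bacterial genome, a synthetic EA table, and evolved-strain mutation
#' sets with optional seeded driver genes.
#'
#' @param n_genes Number of genes in the toy genome.
#' @param gene_length_range Min/max CDS length in nt (rounded to
#'   multiples of 3, inclusive of start and stop codons).
#' @param n_strains Number of evolved strains (replicate ALE lineages).
#' @param neutral_per_strain Neutral mutations per strain, drawn uniformly
#'   over all possible coding SNVs.
#' @param drivers Data frame with columns `locus_tag`, `extra_mutations`,
#'   `ea_bias` — each driver gene receives that many extra distinct
#'   missense mutations; with probability `ea_bias` a mutation is drawn
#'   from the top EA quartile of the gene's possible missense changes,
#'   otherwise from the bottom quartile (`ea_bias = 1` means top quartile
#'   only; `ea_bias = 0` yields a high-count low-impact decoy).
#' @param ea_shape1,ea_shape2 Beta shapes for the synthetic EA table.
#' @param seed Integer master seed; all stages derive from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 50L, gene_length_range = c(300L, 900L),
                         n_strains = 5L, neutral_per_strain = 20L,
                         drivers = NULL, ea_shape1 = 2, ea_shape2 = 2,
                         seed = 1L) {
  if (is.null(drivers)) {
    drivers <- data.frame(locus_tag = character(0),
                          extra_mutations = integer(0),
                          ea_bias = numeric(0))
  }
  stopifnot(n_genes >= 1, n_strains >= 1, neutral_per_strain >= 0,
            all(drivers$extra_mutations >= 0),
            all(drivers$ea_bias >= 0 & drivers$ea_bias <= 1))
  structure(
    list(n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         n_strains = as.integer(n_strains),
         neutral_per_strain = as.integer(neutral_per_strain),
         drivers = drivers, ea_shape1 = ea_shape1, ea_shape2 = ea_shape2,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# sense codons of translation table 11 (no stops)
sense_codons <- function() {
  gc <- genetic_code_11()
  names(gc)[gc != "*"]
}

#' Generate a synthetic bacterial genome
#'
#' One contig carrying `n_genes` random CDSs (ATG start, TAA stop, random
#' sense codons in between, no internal stops), random strands, separated
#' by short random intergenic spacers. Deterministic under `seed`.
#'
#' @inheritParams fixture_spec
#' @param seed Integer seed.
#' @param contig Contig identifier.
#' @return A [ref_genome].
#' @export
make_synthetic_genome <- function(n_genes = 50L,
                                  gene_length_range = c(300L, 900L),
                                  seed = 1L, contig = "SYNCTG01") {
  withr::with_seed(as.integer(seed), {
    sense <- sense_codons()
    sense <- sense[!sense %in% START_CODONS]  # avoid alt-start codon-1 edge cases
    n_codons_range <- pmax(gene_length_range %/% 3L, 4L)
    lens <- sample(seq(n_codons_range[1], n_codons_range[2]), n_genes,
                   replace = TRUE)
    cds <- vapply(lens, function(nc) {
      paste0("ATG", paste(sample(sense, nc - 2L, replace = TRUE),
                          collapse = ""), "TAA")
    }, "")
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    spacers <- vapply(seq_len(n_genes + 1L), function(i) {
      paste(sample(DNA_BASES, sample(15:30, 1), replace = TRUE),
            collapse = "")
    }, "")
    pieces <- character(0)
    starts <- integer(n_genes)
    ends <- integer(n_genes)
    at <- 0L
    for (i in seq_len(n_genes)) {
      pieces <- c(pieces, spacers[i])
      at <- at + nchar(spacers[i])
      starts[i] <- at + 1L
      genomic <- if (strands[i] == "+") cds[i] else revcomp(cds[i])
      pieces <- c(pieces, genomic)
      at <- at + nchar(genomic)
      ends[i] <- at
    }
    pieces <- c(pieces, spacers[n_genes + 1L])
    contigs <- stats::setNames(paste(pieces, collapse = ""), contig)
    cds_df <- data.frame(
      locus_tag = sprintf("GENE_%03d", seq_len(n_genes)),
      gene_name = sprintf("syg%03d", seq_len(n_genes)),
      contig = contig, start = starts, end = ends, strand = strands,
      stringsAsFactors = FALSE
    )
    new_ref_genome(contigs, cds_df, source = "synthetic")
  })
}

#' Write a genome as a GenBank flat file
#'
#' Emits one GenBank record per contig with `source` and `CDS` features
#' (locus_tag and gene qualifiers) and the full ORIGIN sequence.
#'
#' @param genome A [ref_genome].
#' @param path Output path.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(genome$contigs)) {
    seq <- genome$contigs[[ctg]]
    n <- nchar(seq)
    writeLines(sprintf(
      "LOCUS       %-16s %d bp    DNA     circular BCT 01-JAN-2024", ctg, n),
      con)
    writeLines("DEFINITION  synthetic fixture genome.", con)
    writeLines(sprintf("ACCESSION   %s", ctg), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    g <- genome$genes[genome$genes$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i], g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', g$locus_tag[i]), con)
      if (nzchar(g$gene_name[i])) {
        writeLines(sprintf('                     /gene="%s"', g$gene_name[i]), con)
      }
    }
    writeLines("ORIGIN", con)
    s <- tolower(seq)
    starts <- seq(1, n, by = 60)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59, n))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write variants as a minimal VCF 4.2 file
#' @param variants Variant data frame (`contig`, `pos`, `ref`, `alt`).
#' @param genome A [ref_genome] (for contig header lines).
#' @param path Output path.
#' @export
write_vcf <- function(variants, genome, path) {
  v <- variants[order(variants$contig, variants$pos, variants$alt), ,
                drop = FALSE]
  v <- unique(v[, c("contig", "pos", "ref", "alt")])
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=eadriver-fixture",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$contigs),
            nchar(genome$contigs)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", v$contig, v$pos, v$ref, v$alt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write variants as a breseq GenomeDiff file
#' @inheritParams write_vcf
#' @export
write_gd <- function(variants, genome, path) {
  v <- variants[order(variants$contig, variants$pos, variants$alt), ,
                drop = FALSE]
  v <- unique(v[, c("contig", "pos", "ref", "alt")])
  lines <- c(
    "#=GENOME_DIFF\t1.0",
    if (nrow(v)) sprintf("SNP\t%d\t%d\t%s\t%d\t%s", seq_len(nrow(v)),
                         seq_len(nrow(v)) + nrow(v), v$contig, v$pos, v$alt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write effects as an amino-acid substitution list
#'
#' Three-column tab-delimited file (gene, substitution, strain) holding
#' the amino-acid-representable subset (missense and nonsense) of an
#' effects table.
#'
#' @param effects Effects data frame.
#' @param path Output path.
#' @export
write_substitutions <- function(effects, path) {
  e <- effects[effects$effect %in% c("missense", "nonsense") &
                 !is.na(effects$locus_tag), , drop = FALSE]
  e <- e[order(e$strain, e$locus_tag, e$codon_index, e$alt_aa,
               method = "radix"), , drop = FALSE]
  lines <- c("# gene\tsubstitution\tstrain",
             sprintf("%s\t%s\t%s", e$locus_tag, e$sub, e$strain))
  writeLines(lines, path)
  invisible(path)
}

# Draw evolved-strain mutations in memory from an exhaustive background
# enumeration: per strain `neutral_per_strain` uniform coding SNVs, plus
# per driver gene `extra_mutations` distinct missense SNVs drawn from the
# top (prob. ea_bias) or bottom EA quartile of that gene's missense pool.
# Returns rows of background$enum plus a `strain` column. Runs in the
# current RNG stream.
draw_strain_mutations <- function(background, n_strains, neutral_per_strain,
                                  drivers = NULL,
                                  aa_representable_only = FALSE) {
  enum <- background$enum
  stopifnot(!is.null(enum))
  strains <- sprintf("strain_%02d", seq_len(n_strains))
  cand <- seq_len(nrow(enum))
  if (aa_representable_only) {
    cand <- cand[enum$effect %in% c("missense", "nonsense")]
  }
  picks <- list()
  for (s in strains) {
    idx <- if (neutral_per_strain > 0)
      sample(cand, neutral_per_strain, replace = TRUE) else integer(0)
    if (length(idx)) {
      rows <- enum[idx, , drop = FALSE]
      rows$strain <- s
      picks[[length(picks) + 1L]] <- rows
    }
  }
  if (!is.null(drivers) && nrow(drivers) > 0) {
    for (i in seq_len(nrow(drivers))) {
      lt <- drivers$locus_tag[i]
      k <- drivers$extra_mutations[i]
      if (k == 0) next
      gi <- which(enum$locus_tag == lt & enum$effect == "missense" &
                    !is.na(enum$ea))
      if (length(gi) == 0) {
        stop_noisy("driver gene ", lt, " has no scored missense SNV")
      }
      ea <- enum$ea[gi]
      hi <- gi[ea >= quantile(ea, 0.75)]
      lo <- gi[ea <= quantile(ea, 0.25)]
      from_top <- stats::runif(k) < drivers$ea_bias[i]
      pick_stratum <- function(pool, m) {
        if (m == 0) return(integer(0))
        if (length(pool) < m) {
          stop_noisy("driver gene ", lt, ": stratum has only ", length(pool),
                     " candidate SNVs, need ", m)
        }
        sample(pool, m, replace = FALSE)
      }
      idx <- c(pick_stratum(hi, sum(from_top)),
               pick_stratum(lo, sum(!from_top)))
      rows <- enum[idx, , drop = FALSE]
      rows$strain <- sample(strains, length(idx), replace = TRUE)
      picks[[length(picks) + 1L]] <- rows
    }
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic fixture on disk
#'
#' Builds a toy genome, a synthetic EA table, and per-strain mutation sets
#' with optional seeded drivers, and writes: a GenBank file, the EA table,
#' one VCF and one GenomeDiff file per strain (the same mutation set in
#' both formats), a pooled substitution list, and a driver truth table.
#' Byte-identical outputs under the same [fixture_spec()] seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param aa_representable_only Restrict neutral mutations to missense and
#'   nonsense SNVs so the identical set is expressible in all three input
#'   formats (used for format-equivalence checks).
#' @return List with `genome`, `ea_table`, `background`, `mutations`
#'   (drawn enumeration rows + strain), `truth` (the driver table) and
#'   `paths` (named vector of written files).
#' @export
make_fixture <- function(spec, dir, aa_representable_only = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_synthetic_genome(spec$n_genes, spec$gene_length_range,
                                  seed = spec$seed)
  if (nrow(spec$drivers) &&
      !all(spec$drivers$locus_tag %in% genome$genes$locus_tag)) {
    missing <- setdiff(spec$drivers$locus_tag, genome$genes$locus_tag)
    stop_noisy("driver gene(s) not in genome: ", paste(missing, collapse = ", "))
  }
  ea <- synth_ea_table(genome, seed = spec$seed + 1L,
                       shape1 = spec$ea_shape1, shape2 = spec$ea_shape2)
  background <- enumerate_background(genome, ea)
  muts <- withr::with_seed(spec$seed + 2L, draw_strain_mutations(
    background, spec$n_strains, spec$neutral_per_strain, spec$drivers,
    aa_representable_only = aa_representable_only))
  muts$sub <- paste0(muts$ref_aa, muts$codon_index, muts$alt_aa)

  paths <- c(genbank = file.path(dir, "genome.gbk"),
             ea_table = file.path(dir, "ea_table.tsv"),
             substitutions = file.path(dir, "substitutions.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genbank(genome, paths[["genbank"]])
  write_ea_table(ea, paths[["ea_table"]])
  write_substitutions(muts, paths[["substitutions"]])
  write.table(spec$drivers, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (s in unique(muts$strain)) {
    sv <- muts[muts$strain == s, , drop = FALSE]
    vp <- file.path(dir, paste0(s, ".vcf"))
    gp <- file.path(dir, paste0(s, ".gd"))
    write_vcf(sv, genome, vp)
    write_gd(sv, genome, gp)
    paths[paste0(s, ".vcf")] <- vp
    paths[paste0(s, ".gd")] <- gp
  }
  list(genome = genome, ea_table = ea, background = background,
       mutations = muts, truth = spec$drivers, paths = paths)
}
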