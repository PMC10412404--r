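# Enumerate all single-nucleotide changes of one gene's CDS.
# `g` is one row of genome$genes. Returns a data frame with one row per
# (CDS position x 3 alternate bases): coding-strand and genomic
# coordinates, codon arithmetic, residues, and effect class.
enumerate_cds_snvs <- function(g) {
  L <- g$cds_length
  refb <- strsplit(g$cds_seq, "")[[1]]
  OTHER <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  cds_pos <- rep(seq_len(L), each = 3L)
  alt <- unlist(OTHER[refb], use.names = FALSE)
  ref <- refb[cds_pos]
  ci <- (cds_pos - 1L) %/% 3L + 1L
  off <- (cds_pos - 1L) %% 3L
  codon <- substr(rep(g$cds_seq, length(ci)), (ci - 1L) * 3L + 1L, ci * 3L)
  mut <- mutate_codon(codon, off + 1L, alt)
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(mut)
  if (g$strand == "+") {
    gpos <- g$start + cds_pos - 1L
    gref <- ref
    galt <- alt
  } else {
    gpos <- g$end - cds_pos + 1L
    gref <- comp_base(ref)
    galt <- comp_base(alt)
  }
  data.frame(
    locus_tag = g$locus_tag, contig = g$contig,
    pos = gpos, ref = gref, alt = galt,
    cds_pos = cds_pos, codon_index = ci,
    ref_aa = ref_aa, alt_aa = alt_aa,
    effect = classify_effect(ci, codon, mut, ref_aa, alt_aa),
    stringsAsFactors = FALSE
  )
}

new_background <- function(mode, enum_scored, genome, seed = NA_integer_,
                           keep_enumeration = TRUE) {
  is_pool <- enum_scored$effect == "missense" & !is.na(enum_scored$ea)
  pools <- split(enum_scored$ea[is_pool], enum_scored$locus_tag[is_pool])
  # genes with zero scored missense still get an (empty) pool slot
  all_genes <- genome$genes$locus_tag
  pools <- c(pools, stats::setNames(
    rep(list(numeric(0)), sum(!all_genes %in% names(pools))),
    all_genes[!all_genes %in% names(pools)]
  ))
  pools <- pools[order(names(pools))]
  structure(
    list(
      mode = mode,
      pools = pools,
      genome_pool = unlist(pools, use.names = FALSE),
      opportunities = stats::setNames(3L * genome$genes$cds_length,
                                      genome$genes$locus_tag),
      coding_length_total = genome$coding_length_total,
      n_enumerated = nrow(enum_scored),
      seed = seed,
      enum = if (keep_enumeration) enum_scored else NULL
    ),
    class = "ea_background"
  )
}

#' @export
print.ea_background <- function(x, ...) {
  cat(sprintf(
    "<ea_background> mode=%s, %d gene pools, %d scored missense values, %d enumerated SNVs\n",
    x$mode, length(x$pools), length(x$genome_pool), x$n_enumerated
  ))
  invisible(x)
}

#' Exhaustive mutation background
#'
#' Enumerates every possible coding SNV of the genome (3 alternate bases
#' per coding position; a position inside two overlapping genes is
#' enumerated once per gene) and pools the EA scores of all reachable
#' missense substitutions per gene. This is the deterministic,
#' exact limit of randomly simulating mutations in the reference genome
#' and is the default background for the driver statistics.
#'
#' @param genome A [ref_genome].
#' @param ea_table An [ea_table].
#' @param nonsense_ea `"exclude"` (default) or `"max"`; must match the
#'   policy used when annotating the observed variants.
#' @param keep_enumeration Keep the full per-SNV table in the object
#'   (needed by [sample_background()] reuse and the fixture machinery).
#' @return An `ea_background` with `mode = "exhaustive"`.
#' @export
enumerate_background <- function(genome, ea_table,
                                 nonsense_ea = c("exclude", "max"),
                                 keep_enumeration = TRUE) {
  nonsense_ea <- match.arg(nonsense_ea)
  ord <- order(genome$genes$locus_tag, method = "radix")
  enum <- do.call(rbind, lapply(ord, function(i)
    enumerate_cds_snvs(genome$genes[i, ])))
  enum <- assign_ea(enum, ea_table, nonsense_ea)
  new_background("exhaustive", enum, genome,
                 keep_enumeration = keep_enumeration)
}

#' Randomly sampled mutation background
#'
#' Draws `n_mutations` SNVs uniformly over (genomic position x 3 alternate
#' bases) with replacement across the whole genome, annotates them, and
#' pools the missense EA scores per gene exactly as for observed data.
#' Deterministic under `seed`. Intergenic draws contribute to no pool.
#'
#' @inheritParams enumerate_background
#' @param n_mutations Number of simulated mutations (default 100,000).
#' @param seed Integer seed.
#' @return An `ea_background` with `mode = "sampled"`.
#' @export
sample_background <- function(genome, ea_table, n_mutations = 1e5, seed = 1L,
                              nonsense_ea = c("exclude", "max")) {
  nonsense_ea <- match.arg(nonsense_ea)
  stopifnot(n_mutations >= 1)
  bg <- enumerate_background(genome, ea_table, nonsense_ea = nonsense_ea)
  enum <- bg$enum
  site_key <- paste(enum$contig, enum$pos, enum$alt, sep = "|")
  row_by_site <- split(seq_len(nrow(enum)), site_key)

  glen <- nchar(genome$contigs)
  total <- sum(glen)
  drawn <- withr::with_seed(as.integer(seed), {
    gidx <- sample.int(total, n_mutations, replace = TRUE)
    ctg <- rep(names(glen), glen)[gidx]
    pos <- gidx - rep(cumsum(c(0, glen[-length(glen)])), glen)[gidx]
    ref <- substr(genome$contigs[ctg], pos, pos)
    alt_i <- sample.int(3L, n_mutations, replace = TRUE)
    OTHER <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"),
                  N = c(NA, NA, NA))
    alt <- mapply(function(r, i) OTHER[[r]][i], ref, alt_i, USE.NAMES = FALSE)
    paste(ctg, pos, alt, sep = "|")
  })
  rows <- unlist(row_by_site[drawn], use.names = FALSE)
  sampled <- enum[rows, , drop = FALSE]
  out <- new_background("sampled", sampled, genome, seed = as.integer(seed))
  out$n_drawn <- n_mutations
  out
}

#' Custom mutation background
#'
#' Builds the background pools from a user-supplied mutation set (VCF,
#' GenomeDiff, or substitution list), processed through exactly the same
#' ingestion and annotation path as observed data.
#'
#' @param path Path to the background file.
#' @param format One of `"vcf"`, `"gd"`, `"substitutions"`.
#' @inheritParams enumerate_background
#' @return An `ea_background` with `mode = "custom"`.
#' @export
load_custom_background <- function(path, format = c("vcf", "gd", "substitutions"),
                                   genome, ea_table,
                                   nonsense_ea = c("exclude", "max")) {
  format <- match.arg(format)
  nonsense_ea <- match.arg(nonsense_ea)
  effects <- switch(format,
    vcf = annotate_variants(read_vcf(path, strain = "background"),
                            genome, ea_table, nonsense_ea),
    gd = annotate_variants(read_gd(path, genome, strain = "background"),
                           genome, ea_table, nonsense_ea),
    substitutions = effects_from_substitutions(
      read_substitutions(path, strain = "background"),
      genome, ea_table, nonsense_ea)
  )
  usable <- effects[effects$effect == "missense" & !is.na(effects$ea), ,
                    drop = FALSE]
  if (nrow(usable) == 0) {
    stop_noisy("custom background ", path,
               " contains no scored missense mutation; statistics undefined")
  }
  new_background("custom", effects, genome)
}

#' Summarize a background per gene
#'
#' @param background An `ea_background`.
#' @return Data frame with `locus_tag`, `opportunities` (possible coding
#'   SNVs), `pool_size` (scored missense in the pool) and `pool_mean_ea`.
#' @export
background_summary <- function(background) {
  lt <- names(background$pools)
  data.frame(
    locus_tag = lt,
    opportunities = unname(background$opportunities[lt]),
    pool_size = vapply(background$pools, length, 1L),
    pool_mean_ea = vapply(background$pools, function(p)
      if (length(p)) mean(p) else NA_real_, 1.0),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
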