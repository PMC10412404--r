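# Classify a codon change. All arguments are parallel vectors:
# codon_index, reference codon, mutated codon (both coding-strand),
# and their translations. Start-codon handling: a change at codon 1 that
# leaves a valid start codon (ATG/GTG/TTG) is classified by its translated
# residues; a change that destroys the start codon is "start-loss".
classify_effect <- function(codon_index, ref_codon, alt_codon, ref_aa, alt_aa) {
  eff <- ifelse(is.na(ref_aa) | is.na(alt_aa), "untranslatable",
         ifelse(ref_aa == "*" & alt_aa == "*", "synonymous",
         ifelse(ref_aa == "*", "stop-loss",
         ifelse(alt_aa == "*", "nonsense",
         ifelse(ref_aa == alt_aa, "synonymous", "missense")))))
  startloss <- codon_index == 1L & ref_codon %in% START_CODONS &
    !(alt_codon %in% START_CODONS)
  eff[startloss] <- "start-loss"
  eff
}

EFFECT_COLS <- c("strain", "contig", "pos", "ref", "alt", "locus_tag",
                 "gene_name", "codon_index", "ref_aa", "alt_aa", "sub",
                 "effect", "ea")

empty_effects <- function() {
  data.frame(strain = character(0), contig = character(0), pos = integer(0),
             ref = character(0), alt = character(0), locus_tag = character(0),
             gene_name = character(0), codon_index = integer(0),
             ref_aa = character(0), alt_aa = character(0), sub = character(0),
             effect = character(0), ea = numeric(0),
             stringsAsFactors = FALSE)
}

#' Annotate genomic SNVs with their protein-level consequences
#'
#' Maps each variant to every gene containing it (one row per containing
#' gene — overlapping genes each receive the variant, since the driver
#' statistics are per-gene) and computes the codon index and reference/
#' alternate residues on the coding strand. Variants whose stated reference
#' base disagrees with the genome are rejected and counted; variants in no
#' CDS are kept with effect `"intergenic"` for accounting only.
#'
#' When `ea_table` is supplied, each missense row is assigned its EA score
#' (`NA`, counted, when the table has no entry). Nonsense rows get EA 100
#' when `nonsense_ea = "max"` (premature stops treated as maximally
#' disruptive) and `NA` under the default `"exclude"`.
#'
#' @param variants Variant data frame (`contig`, `pos`, `ref`, `alt`,
#'   `strain`), e.g. from [read_vcf()], [read_gd()] or [pool_variants()].
#' @param genome A [ref_genome].
#' @param ea_table Optional [ea_table] of EA scores.
#' @param nonsense_ea `"exclude"` (default) or `"max"`.
#' @return Data frame of protein effects with a `"report"` attribute
#'   (rejection counts).
#' @export
annotate_variants <- function(variants, genome, ea_table = NULL,
                              nonsense_ea = c("exclude", "max")) {
  nonsense_ea <- match.arg(nonsense_ea)
  v <- as.data.frame(variants)
  report <- c(rejected_ref_mismatch = 0L, rejected_unknown_contig = 0L)
  if (nrow(v) == 0) {
    out <- empty_effects()
    attr(out, "report") <- report
    return(out)
  }
  v$ref <- toupper(v$ref)
  v$alt <- toupper(v$alt)
  known <- v$contig %in% names(genome$contigs)
  report["rejected_unknown_contig"] <- sum(!known)
  v <- v[known, , drop = FALSE]
  genome_base <- substr(genome$contigs[v$contig], v$pos, v$pos)
  ok <- genome_base == v$ref
  report["rejected_ref_mismatch"] <- sum(!ok)
  v <- v[ok, , drop = FALSE]
  if (nrow(v) == 0) {
    out <- empty_effects()
    attr(out, "report") <- report
    return(out)
  }

  genes <- genome$genes
  pieces <- list()
  hit_any <- rep(FALSE, nrow(v))
  for (ctg in unique(v$contig)) {
    vi <- which(v$contig == ctg)
    gi <- which(genes$contig == ctg)
    if (length(gi) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(v$pos[vi], v$pos[vi]),
      IRanges::IRanges(genes$start[gi], genes$end[gi])
    )
    if (length(ov) == 0) next
    qi <- vi[S4Vectors::queryHits(ov)]
    si <- gi[S4Vectors::subjectHits(ov)]
    hit_any[qi] <- TRUE
    g <- genes[si, , drop = FALSE]
    pos <- v$pos[qi]
    o <- ifelse(g$strand == "+", pos - g$start, g$end - pos)
    ci <- o %/% 3L + 1L
    off <- o %% 3L
    codon <- substr(g$cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
    alt_c <- ifelse(g$strand == "+", v$alt[qi], comp_base(v$alt[qi]))
    mut <- mutate_codon(codon, off + 1L, alt_c)
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(mut)
    pieces[[length(pieces) + 1L]] <- data.frame(
      strain = v$strain[qi], contig = ctg, pos = pos,
      ref = v$ref[qi], alt = v$alt[qi],
      locus_tag = g$locus_tag, gene_name = g$gene_name,
      codon_index = ci, ref_aa = ref_aa, alt_aa = alt_aa,
      effect = classify_effect(ci, codon, mut, ref_aa, alt_aa),
      stringsAsFactors = FALSE
    )
  }
  inter <- v[!hit_any, , drop = FALSE]
  if (nrow(inter) > 0) {
    pieces[[length(pieces) + 1L]] <- data.frame(
      strain = inter$strain, contig = inter$contig, pos = inter$pos,
      ref = inter$ref, alt = inter$alt,
      locus_tag = NA_character_, gene_name = NA_character_,
      codon_index = NA_integer_, ref_aa = NA_character_,
      alt_aa = NA_character_, effect = "intergenic",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  out$sub <- ifelse(is.na(out$codon_index), NA_character_,
                    paste0(out$ref_aa, out$codon_index, out$alt_aa))
  out <- out[order(out$strain, out$contig, out$pos, out$alt,
                   out$locus_tag, method = "radix"), , drop = FALSE]
  out <- assign_ea(out, ea_table, nonsense_ea)
  out <- out[, EFFECT_COLS]
  rownames(out) <- NULL
  attr(out, "report") <- report
  report_skips(as.list(report), "annotate_variants")
  out
}

# attach EA scores to an effects table (missense from the table; nonsense
# per policy); records how many scored-eligible rows lacked an entry
assign_ea <- function(effects, ea_table, nonsense_ea = "exclude") {
  effects$ea <- NA_real_
  if (!is.null(ea_table)) {
    mi <- which(effects$effect == "missense")
    if (length(mi)) {
      key <- ea_key(effects$locus_tag[mi], effects$codon_index[mi],
                    effects$alt_aa[mi])
      effects$ea[mi] <- unname(ea_table$scores[key])
      n_missing <- sum(is.na(effects$ea[mi]))
      if (n_missing > 0) {
        ea_msg(sprintf(
          "assign_ea: %d missense mutation(s) without an EA entry (kept in frequency counts, dropped from EA statistics)",
          n_missing))
      }
    }
  }
  if (nonsense_ea == "max") {
    effects$ea[effects$effect == "nonsense"] <- 100
  }
  effects
}

#' Build protein effects directly from an amino-acid substitution list
#'
#' The substitution-list input bypasses genome annotation. The gene field
#' is resolved first as a locus tag, then as a unique gene name; an
#' ambiguous gene name is an error. Rows whose reference residue disagrees
#' with the protein sequence, or whose position exceeds the protein length,
#' are rejected and counted.
#'
#' @param subs Data frame from [read_substitutions()].
#' @param genome A [ref_genome].
#' @inheritParams annotate_variants
#' @return Effects data frame as [annotate_variants()] (genomic columns `NA`).
#' @export
effects_from_substitutions <- function(subs, genome, ea_table = NULL,
                                       nonsense_ea = c("exclude", "max")) {
  nonsense_ea <- match.arg(nonsense_ea)
  report <- c(rejected_unknown_gene = 0L, rejected_ref_mismatch = 0L,
              rejected_bad_position = 0L)
  genes <- genome$genes
  s <- as.data.frame(subs)
  if (nrow(s) == 0) {
    out <- empty_effects()
    attr(out, "report") <- report
    return(out)
  }
  li <- match(s$gene, genes$locus_tag)
  unresolved <- which(is.na(li))
  for (i in unresolved) {
    hits <- which(genes$gene_name == s$gene[i] & genes$gene_name != "")
    if (length(hits) > 1) {
      stop_noisy("ambiguous gene name '", s$gene[i], "' matches ",
                 length(hits), " locus tags")
    }
    if (length(hits) == 1) li[i] <- hits
  }
  report["rejected_unknown_gene"] <- sum(is.na(li))
  keep <- !is.na(li)
  s <- s[keep, , drop = FALSE]
  li <- li[keep]
  g <- genes[li, , drop = FALSE]
  ok_pos <- s$position >= 1 & s$position <= g$protein_length + 1L
  report["rejected_bad_position"] <- sum(!ok_pos)
  s <- s[ok_pos, , drop = FALSE]
  g <- g[ok_pos, , drop = FALSE]
  prot_stop <- paste0(g$protein_seq, "*")
  ref_here <- substr(prot_stop, s$position, s$position)
  ok_ref <- ref_here == s$ref_aa
  report["rejected_ref_mismatch"] <- sum(!ok_ref)
  s <- s[ok_ref, , drop = FALSE]
  g <- g[ok_ref, , drop = FALSE]
  eff <- ifelse(s$ref_aa == "*" & s$alt_aa != "*", "stop-loss",
         ifelse(s$alt_aa == "*", "nonsense",
         ifelse(s$ref_aa == s$alt_aa, "synonymous", "missense")))
  out <- data.frame(
    strain = s$strain, contig = NA_character_, pos = NA_integer_,
    ref = NA_character_, alt = NA_character_,
    locus_tag = g$locus_tag, gene_name = g$gene_name,
    codon_index = s$position, ref_aa = s$ref_aa, alt_aa = s$alt_aa,
    sub = s$sub, effect = eff, stringsAsFactors = FALSE
  )
  out <- out[order(out$strain, out$locus_tag, out$codon_index, out$alt_aa,
                   method = "radix"), , drop = FALSE]
  out <- assign_ea(out, ea_table, nonsense_ea)
  out <- out[, EFFECT_COLS]
  rownames(out) <- NULL
  attr(out, "report") <- report
  report_skips(as.list(report), "effects_from_substitutions")
  out
}
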