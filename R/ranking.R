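#' Ranking configuration
#'
#' @param n_mc Monte-Carlo replicates for the EA-sum null (>= 100).
#' @param min_mut Minimum scored missense mutations a gene needs to enter
#'   the EA tests (genes below get p = 1 and no q-value).
#' @param seed Optional integer seed making the Monte-Carlo nulls
#'   reproducible.
#' @param background_scope `"per_gene"` (default): each gene's observed EA
#'   values are compared against that gene's own background pool;
#'   `"genome_wide"`: against the pooled background of all genes.
#' @param count_synonymous Include synonymous mutations in the frequency
#'   counts (default `FALSE`: nonsynonymous only).
#' @param collapse_recurrent Collapse identical substitutions recurring in
#'   different strains to a single count (default `FALSE`: recurrence
#'   across replicate lineages is retained as frequency signal; duplicates
#'   within one strain are always collapsed).
#' @param nonsense_ea `"exclude"` or `"max"` — see [annotate_variants()].
#' @param top_n Default list length for [venn_overlap()].
#' @return A `ranking_config` list.
#' @export
ranking_config <- function(n_mc = 10000L, min_mut = 1L, seed = NULL,
                           background_scope = c("per_gene", "genome_wide"),
                           count_synonymous = FALSE,
                           collapse_recurrent = FALSE,
                           nonsense_ea = c("exclude", "max"),
                           top_n = 20L) {
  background_scope <- match.arg(background_scope)
  nonsense_ea <- match.arg(nonsense_ea)
  stopifnot(n_mc >= 100, min_mut >= 1)
  structure(
    list(n_mc = as.integer(n_mc), min_mut = as.integer(min_mut),
         seed = seed, background_scope = background_scope,
         count_synonymous = isTRUE(count_synonymous),
         collapse_recurrent = isTRUE(collapse_recurrent),
         nonsense_ea = nonsense_ea, top_n = as.integer(top_n)),
    class = "ranking_config"
  )
}

#' One-sided two-sample Kolmogorov-Smirnov shift test on EA scores
#'
#' Computes `D+ = sup_x [F_bg(x) - F_obs(x)]`, the one-sided two-sample
#' Kolmogorov-Smirnov statistic sensitive to the observed EA distribution
#' being shifted toward HIGH impact relative to the background, with the
#' asymptotic one-sided p-value `exp(-2 D^2 nm/(n+m))` (floored at machine
#' precision, capped at 1).
#'
#' @param obs Numeric vector of observed EA scores (non-empty).
#' @param bg Numeric vector: the background EA pool (non-empty).
#' @return List with `stat` (D+, in \[0,1\]) and `p`.
#' @export
ea_ks <- function(obs, bg) {
  n <- length(obs)
  m <- length(bg)
  if (n == 0 || m == 0) stop_noisy("ea_ks: empty sample or background pool")
  so <- sort(obs)
  sb <- sort(bg)
  pts <- c(so, sb)
  d <- max(findInterval(pts, sb) / m - findInterval(pts, so) / n, 0)
  p <- exp(-2 * d^2 * n * m / (n + m))
  list(stat = d, p = min(1, max(p, .Machine$double.xmin)))
}

#' Monte-Carlo EA-sum burden test
#'
#' `sumEA` is the total EA of the gene's observed (scored missense)
#' mutations. The null holds the observed count `n` fixed and draws `n`
#' EA values with replacement from the background pool `n_mc` times; the
#' p-value is the add-one empirical upper tail
#' `(1 + #\{null sums >= sumEA\}) / (1 + n_mc)` (so p = 0 is impossible).
#'
#' @inheritParams ea_ks
#' @param n_mc Number of Monte-Carlo null draws.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return List with `sum_ea` and `p`.
#' @export
ea_sum_test <- function(obs, bg, n_mc = 10000L, seed = NULL) {
  n <- length(obs)
  if (n == 0) stop_noisy("ea_sum_test: empty observed sample")
  if (length(bg) == 0) stop_noisy("ea_sum_test: empty background pool")
  s <- sum(sort(obs))
  null_sums <- with_opt_seed(seed, {
    draws <- sample(bg, n * n_mc, replace = TRUE)
    if (n == 1) draws else .colSums(draws, n, n_mc)
  })
  p <- (1 + sum(null_sums >= s)) / (1 + n_mc)
  list(sum_ea = s, p = p)
}

#' Exact binomial mutation-frequency test
#'
#' Upper-tail exact binomial test of the gene's mutation count against its
#' share of the coding genome: `X ~ Binomial(N_total, L_gene / L_coding)`,
#' `p = P(X >= n_gene)`.
#'
#' @param n_mut Observed mutation count in the gene.
#' @param cds_length Gene CDS length (nt).
#' @param n_total Total counted mutations across all genes.
#' @param coding_length_total Total coding length (nt).
#' @return Upper-tail p-value.
#' @export
frequency_test <- function(n_mut, cds_length, n_total, coding_length_total) {
  stopifnot(n_total >= 1)
  pbinom(n_mut - 1, n_total, cds_length / coding_length_total,
         lower.tail = FALSE)
}

# deduplicate counted effects: always within strain at the amino-acid
# level; optionally across strains
dedup_effects <- function(effects, collapse_recurrent = FALSE) {
  key <- paste(effects$locus_tag, effects$codon_index, effects$ref_aa,
               effects$alt_aa, effects$effect, sep = "|")
  if (!collapse_recurrent) key <- paste(effects$strain, key, sep = "|")
  effects[!duplicated(key), , drop = FALSE]
}

#' Rank genes as phenotype drivers
#'
#' Computes the three per-gene driver statistics from annotated effects
#' and a mutation background: the one-sided EA distribution-shift test
#' ([ea_ks()]), the Monte-Carlo EA burden test ([ea_sum_test()]), and the
#' exact binomial frequency test ([frequency_test()]); then applies
#' Benjamini-Hochberg correction within each method and assigns ranks
#' (ascending p; ties broken by descending sumEA for the EA methods,
#' descending count for frequency, then locus tag).
#'
#' Counted mutations default to nonsynonymous coding changes (missense,
#' nonsense, start-loss, stop-loss), pooled over strains after collapsing
#' duplicates within each strain. EA statistics use the scored missense
#' subset. Genes whose background pool is empty are excluded and reported.
#'
#' @param effects Effects data frame from [annotate_variants()] or
#'   [effects_from_substitutions()].
#' @param background An `ea_background` (see [enumerate_background()]).
#' @param genome A [ref_genome].
#' @param config A [ranking_config()].
#' @return A `gene_results` data frame, one row per gene: `locus_tag`,
#'   `gene_name`, `cds_length`, `n_mut`, `n_missense_scored`, `sum_ea`,
#'   `ks_stat`, `p_ks`, `p_sum`, `p_freq`, `q_ks`, `q_sum`, `q_freq`,
#'   `rank_ks`, `rank_sum`, `rank_freq`; attribute `"excluded"` lists
#'   genes with empty background pools.
#' @export
rank_drivers <- function(effects, background, genome,
                         config = ranking_config()) {
  stopifnot(inherits(config, "ranking_config"))
  counted_classes <- c("missense", "nonsense", "start-loss", "stop-loss")
  if (config$count_synonymous) counted_classes <- c(counted_classes, "synonymous")
  eff <- effects[effects$effect %in% counted_classes & !is.na(effects$locus_tag), ,
                 drop = FALSE]
  eff <- dedup_effects(eff, config$collapse_recurrent)

  genes <- genome$genes[order(genome$genes$locus_tag, method = "radix"), ,
                        drop = FALSE]
  pools <- background$pools
  pool_len <- vapply(pools, length, 1L)
  excluded <- genes$locus_tag[pool_len[genes$locus_tag] == 0]
  if (length(excluded)) {
    ea_msg("rank_drivers: excluding ", length(excluded),
           " gene(s) with empty background EA pool")
  }
  genes <- genes[!genes$locus_tag %in% excluded, , drop = FALSE]

  n_total <- nrow(eff)
  if (n_total < 1) stop_noisy("rank_drivers: no counted mutations")

  scored <- eff[eff$effect %in% c("missense",
                                  if (config$nonsense_ea == "max") "nonsense") &
                  !is.na(eff$ea), , drop = FALSE]
  obs_by_gene <- split(scored$ea, scored$locus_tag)

  G <- nrow(genes)
  res <- data.frame(
    locus_tag = genes$locus_tag, gene_name = genes$gene_name,
    cds_length = genes$cds_length,
    n_mut = 0L, n_missense_scored = 0L, sum_ea = 0,
    ks_stat = NA_real_, p_ks = 1, p_sum = 1, p_freq = 1,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab <- table(eff$locus_tag)
  res$n_mut <- as.integer(ifelse(is.na(tab[res$locus_tag]), 0L,
                                 tab[res$locus_tag]))
  res$p_freq <- frequency_test(res$n_mut, res$cds_length, n_total,
                               background$coding_length_total)

  do_gene <- function() {
    for (i in seq_len(G)) {
      lt <- res$locus_tag[i]
      obs <- sort(obs_by_gene[[lt]] %||% numeric(0))
      res$n_missense_scored[i] <- length(obs)
      res$sum_ea[i] <- sum(obs)
      if (length(obs) >= config$min_mut) {
        pool <- if (config$background_scope == "per_gene") pools[[lt]] else
          background$genome_pool
        ks <- ea_ks(obs, pool)
        res$ks_stat[i] <- ks$stat
        res$p_ks[i] <- ks$p
        res$p_sum[i] <- ea_sum_test(obs, pool, n_mc = config$n_mc)$p
      }
    }
    res
  }
  res <- with_opt_seed(config$seed, do_gene())

  tested <- res$n_missense_scored >= config$min_mut
  res$q_ks <- res$q_sum <- NA_real_
  res$q_ks[tested] <- p.adjust(res$p_ks[tested], method = "BH")
  res$q_sum[tested] <- p.adjust(res$p_sum[tested], method = "BH")
  res$q_freq <- p.adjust(res$p_freq, method = "BH")

  res$rank_ks <- rank_order(res$p_ks, -res$sum_ea, res$locus_tag)
  res$rank_sum <- rank_order(res$p_sum, -res$sum_ea, res$locus_tag)
  res$rank_freq <- rank_order(res$p_freq, -res$n_mut, res$locus_tag)
  class(res) <- c("gene_results", "data.frame")
  attr(res, "excluded") <- excluded
  attr(res, "n_total_mut") <- n_total
  res
}

# 1-based rank following order(primary, tiebreak1, tiebreak2)
rank_order <- function(p, tie1, tie2) {
  o <- order(p, tie1, tie2, method = "radix")
  r <- integer(length(p))
  r[o] <- seq_along(o)
  r
}

#' Order a results table by one method's ranking
#'
#' @param results A `gene_results` data frame from [rank_drivers()].
#' @param method `"ks"`, `"sum"`, or `"freq"`.
#' @return The table ordered by that method's rank.
#' @export
rank_genes <- function(results, method = c("ks", "sum", "freq")) {
  method <- match.arg(method)
  results[order(results[[paste0("rank_", method)]]), , drop = FALSE]
}

#' Top-ranked genes under one method
#' @inheritParams rank_genes
#' @param n List length.
#' @return Character vector of locus tags, best first.
#' @export
top_genes <- function(results, method = c("ks", "sum", "freq"), n = 20L) {
  method <- match.arg(method)
  n <- min(n, nrow(results))
  head(rank_genes(results, method)$locus_tag, n)
}

#' Write a gene results table
#' @param results A `gene_results` data frame.
#' @param path Output path (tab-delimited).
#' @export
write_gene_results <- function(results, path) {
  out <- as.data.frame(results)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
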