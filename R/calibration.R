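#' Null calibration of the three driver tests
#'
#' Simulates evolved strains whose mutations are drawn from the background
#' itself (no drivers), ranks genes on each replicate, and reports the
#' empirical rejection rate of each test at level `alpha`. Because all
#' three tests are discrete and one-sided they should be conservative:
#' rejection at or below `alpha`, never meaningfully above.
#'
#' @param genome A [ref_genome].
#' @param background An exhaustive `ea_background` (with enumeration kept).
#' @param n_reps Number of null replicates.
#' @param n_strains,neutral_per_strain Strain design per replicate.
#' @param alpha Nominal test level.
#' @param n_mc Monte-Carlo replicates for the EA-sum null per gene.
#' @param seed Integer seed.
#' @return List with per-test rejection rates and counts: elements `ks`,
#'   `sum`, `freq`, each `list(rejections, n, rate)`.
#' @export
simulate_null_calibration <- function(genome, background, n_reps = 1000L,
                                      n_strains = 5L, neutral_per_strain = 20L,
                                      alpha = 0.05, n_mc = 499L, seed = 1L) {
  cfg <- ranking_config(n_mc = n_mc)
  rej <- c(ks = 0L, sum = 0L, freq = 0L)
  tot <- c(ks = 0L, sum = 0L, freq = 0L)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      rows <- draw_strain_mutations(background, n_strains, neutral_per_strain)
      res <- rank_drivers(rows, background, genome, cfg)
      tested <- res$n_missense_scored >= cfg$min_mut
      rej["ks"] <- rej["ks"] + sum(res$p_ks[tested] <= alpha)
      rej["sum"] <- rej["sum"] + sum(res$p_sum[tested] <= alpha)
      rej["freq"] <- rej["freq"] + sum(res$p_freq <= alpha)
      tot["ks"] <- tot["ks"] + sum(tested)
      tot["sum"] <- tot["sum"] + sum(tested)
      tot["freq"] <- tot["freq"] + nrow(res)
    }
  })
  out <- lapply(c(ks = "ks", sum = "sum", freq = "freq"), function(m) {
    list(rejections = unname(rej[m]), n = unname(tot[m]),
         rate = unname(rej[m] / tot[m]))
  })
  out$alpha <- alpha
  out
}

#' Driver-recovery power simulation
#'
#' Repeatedly seeds driver genes with extra high-impact mutations on top
#' of neutral strain mutations, ranks genes, and measures how often (a)
#' every seeded driver lands in the EA_sum and EA_KS top-`top_k` lists and
#' (b) a low-impact high-count decoy gene ranks strictly better under the
#' frequency method than under EA_sum — the design premise that weighting
#' mutations by functional impact separates drivers from merely
#' mutation-prone genes.
#'
#' @inheritParams simulate_null_calibration
#' @param drivers Driver table as in [fixture_spec()] (high `ea_bias`).
#' @param decoy Optional one-row driver table with `ea_bias` 0 (the
#'   low-impact decoy).
#' @param top_k List length defining recovery.
#' @return List with `recovery_sum`, `recovery_ks`, `decoy_freq_better`
#'   (rates over replicates) and `n_reps`.
#' @export
simulate_driver_recovery <- function(genome, background, drivers,
                                     decoy = NULL, n_reps = 100L,
                                     n_strains = 5L, neutral_per_strain = 20L,
                                     top_k = 2L * nrow(drivers),
                                     n_mc = 999L, seed = 1L) {
  cfg <- ranking_config(n_mc = n_mc)
  all_drivers <- rbind(drivers, decoy)
  hit_sum <- hit_ks <- decoy_better <- logical(n_reps)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      rows <- draw_strain_mutations(background, n_strains, neutral_per_strain,
                                    drivers = all_drivers)
      res <- rank_drivers(rows, background, genome, cfg)
      hit_sum[r] <- all(drivers$locus_tag %in% top_genes(res, "sum", top_k))
      hit_ks[r] <- all(drivers$locus_tag %in% top_genes(res, "ks", top_k))
      if (!is.null(decoy)) {
        i <- match(decoy$locus_tag[1], res$locus_tag)
        decoy_better[r] <- res$rank_freq[i] < res$rank_sum[i]
      }
    }
  })
  list(recovery_sum = mean(hit_sum), recovery_ks = mean(hit_ks),
       decoy_freq_better = if (is.null(decoy)) NA_real_ else mean(decoy_better),
       n_reps = n_reps)
}
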