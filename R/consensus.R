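#' Overlap of the three methods' top gene lists
#'
#' Exact set algebra over the top-`n` lists of the EA_KS, EA_sum and
#' frequency rankings: the seven disjoint Venn regions, plus the consensus
#' set of genes appearing in at least two lists (genes ranked highly by
#' several methods are the strongest driver candidates).
#'
#' @param results A `gene_results` data frame from [rank_drivers()], or
#'   `NULL` when the three lists are given directly.
#' @param n List length (clamped, with a warning, to the number of genes).
#' @param top_ks,top_sum,top_freq Optional explicit character vectors
#'   overriding the lists extracted from `results`.
#' @return An `overlap_report` list: `n`, `top` (the three ordered lists),
#'   `regions` (named list of the 7 disjoint region memberships),
#'   `region_sizes`, and `consensus`.
#' @export
venn_overlap <- function(results = NULL, n = 20L,
                         top_ks = NULL, top_sum = NULL, top_freq = NULL) {
  if (is.null(top_ks)) {
    stopifnot(!is.null(results))
    if (n > nrow(results)) {
      warning("n = ", n, " exceeds the ", nrow(results),
              " tested genes; clamping", call. = FALSE)
      n <- nrow(results)
    }
    top_ks <- top_genes(results, "ks", n)
    top_sum <- top_genes(results, "sum", n)
    top_freq <- top_genes(results, "freq", n)
  }
  a <- unique(top_ks); b <- unique(top_sum); c <- unique(top_freq)
  u <- sort(unique(c(a, b, c)))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  regions <- list(
    ks_only    = u[ina & !inb & !inc],
    sum_only   = u[!ina & inb & !inc],
    freq_only  = u[!ina & !inb & inc],
    ks_sum     = u[ina & inb & !inc],
    ks_freq    = u[ina & !inb & inc],
    sum_freq   = u[!ina & inb & inc],
    all_three  = u[ina & inb & inc]
  )
  structure(
    list(
      n = n,
      top = list(ks = top_ks, sum = top_sum, freq = top_freq),
      regions = regions,
      region_sizes = vapply(regions, length, 1L),
      consensus = u[(ina + inb + inc) >= 2]
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> top-%d lists; union %d; consensus (>=2 methods) %d\n",
              x$n, sum(x$region_sizes), length(x$consensus)))
  for (nm in names(x$region_sizes)) {
    cat(sprintf("  %-9s %d\n", nm, x$region_sizes[[nm]]))
  }
  invisible(x)
}

#' Write an overlap report
#'
#' Writes the report as JSON plus a tab-delimited membership table
#' (gene, in_ks, in_sum, in_freq, region).
#'
#' @param report An `overlap_report`.
#' @param json_path,tsv_path Output paths (`NULL` to skip either).
#' @export
write_overlap_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n = report$n, top = report$top, regions = report$regions,
           region_sizes = as.list(report$region_sizes),
           consensus = report$consensus),
      json_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  if (!is.null(tsv_path)) {
    u <- sort(unique(unlist(report$top)))
    region_of <- rep(NA_character_, length(u))
    for (nm in names(report$regions)) {
      region_of[u %in% report$regions[[nm]]] <- nm
    }
    df <- data.frame(
      gene = u,
      in_ks = as.integer(u %in% report$top$ks),
      in_sum = as.integer(u %in% report$top$sum),
      in_freq = as.integer(u %in% report$top$freq),
      region = region_of
    )
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Export a gene list as a STRING enrichment query payload
#'
#' Writes the newline-delimited identifier list that would be submitted to
#' the STRING protein-protein-interaction enrichment service, preceded by
#' a comment line carrying the taxon identifier. The network call itself
#' is deliberately not made (reproducibility; service version drift) — the
#' payload can be pasted into the STRING web interface.
#'
#' @param genes Non-empty character vector of gene identifiers.
#' @param path Output path.
#' @param taxon NCBI taxon identifier (e.g. 511145 for E. coli K-12
#'   MG1655).
#' @export
export_string_query <- function(genes, path, taxon = 511145) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop_noisy("export_string_query: empty gene set")
  writeLines(c(sprintf("# species=%s", taxon), sort(genes)), path)
  invisible(path)
}
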