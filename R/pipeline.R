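#' Run the full driver analysis
#'
#' Convenience wrapper chaining ingestion, annotation, background
#' construction and ranking. Exactly one of `variants` (genomic SNVs) or
#' `substitutions` (amino-acid substitution records) must be supplied.
#'
#' @param genome A [ref_genome].
#' @param ea_table An [ea_table].
#' @param variants Pooled variant data frame (see [pool_variants()]).
#' @param substitutions Data frame from [read_substitutions()].
#' @param background An `ea_background`, or `NULL` to enumerate the
#'   exhaustive background.
#' @param config A [ranking_config()].
#' @return List with `results` ([rank_drivers()] table), `effects`,
#'   `background`, and `config`.
#' @export
run_driver_analysis <- function(genome, ea_table, variants = NULL,
                                substitutions = NULL, background = NULL,
                                config = ranking_config()) {
  if (is.null(variants) == is.null(substitutions)) {
    stop_noisy("supply exactly one of `variants` or `substitutions`")
  }
  effects <- if (!is.null(variants)) {
    annotate_variants(variants, genome, ea_table,
                      nonsense_ea = config$nonsense_ea)
  } else {
    effects_from_substitutions(substitutions, genome, ea_table,
                               nonsense_ea = config$nonsense_ea)
  }
  if (is.null(background)) {
    background <- enumerate_background(genome, ea_table,
                                       nonsense_ea = config$nonsense_ea)
  }
  results <- rank_drivers(effects, background, genome, config)
  list(results = results, effects = effects, background = background,
       config = config)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version, and MD5 hashes of the
#' input files so a run can be reproduced and compared.
#'
#' @param path Output JSON path.
#' @param config A [ranking_config()].
#' @param files Named character vector of input file paths to hash.
#' @param extra Optional named list appended verbatim.
#' @export
write_manifest <- function(path, config, files = character(0), extra = list()) {
  manifest <- c(
    list(
      package = "eadriver",
      version = as.character(utils::packageVersion("eadriver")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      input_md5 = as.list(tools::md5sum(files[file.exists(files)]))
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
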