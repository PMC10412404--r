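ea_key <- function(locus_tag, position, alt_aa) {
  paste(locus_tag, position, alt_aa, sep = "|")
}

#' EA score table
#'
#' An `ea_table` holds Evolutionary Action (EA) scores for missense
#' substitutions: one value on the 0-100 scale per (gene, residue
#' position, alternate residue). Higher EA means a more functionally
#' disruptive substitution. Internally a long data frame plus a keyed
#' numeric vector for O(1) lookup.
#'
#' @name ea_table
NULL

new_ea_table <- function(df, genome = NULL, source = "memory") {
  report <- c(rejected_range = 0L, rejected_ref_mismatch = 0L,
              rejected_bad_row = 0L)
  df$locus_tag <- as.character(df$locus_tag)
  df$position <- as.integer(df$position)
  df$ref_aa <- toupper(as.character(df$ref_aa))
  df$alt_aa <- toupper(as.character(df$alt_aa))
  df$ea <- as.numeric(df$ea)

  bad <- is.na(df$position) | df$position < 1 | is.na(df$ea) |
    !df$ref_aa %in% AA_ONE_LETTER | !df$alt_aa %in% c(AA_ONE_LETTER, "*") |
    df$ref_aa == df$alt_aa
  report["rejected_bad_row"] <- sum(bad)
  df <- df[!bad, , drop = FALSE]

  if (nrow(df) > 0 && all(df$ea <= 1)) {
    warning("all EA values are <= 1; rescaling from [0,1] to the 0-100 scale",
            call. = FALSE)
    df$ea <- df$ea * 100
  }
  out_of_range <- df$ea < 0 | df$ea > 100
  report["rejected_range"] <- sum(out_of_range)
  df <- df[!out_of_range, , drop = FALSE]

  if (!is.null(genome)) {
    gi <- match(df$locus_tag, genome$genes$locus_tag)
    prot <- paste0(genome$genes$protein_seq[gi], "*")
    ref_here <- substr(prot, df$position, df$position)
    ok <- !is.na(gi) & ref_here == df$ref_aa
    report["rejected_ref_mismatch"] <- sum(!ok)
    df <- df[ok, , drop = FALSE]
  }

  df <- unique(df[, c("locus_tag", "position", "ref_aa", "alt_aa", "ea")])
  key <- ea_key(df$locus_tag, df$position, df$alt_aa)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_noisy("conflicting EA values for ", length(dup),
               " substitution key(s), e.g. ", dup[1])
  }
  protein_length <- if (!is.null(genome)) {
    stats::setNames(genome$genes$protein_length, genome$genes$locus_tag)
  } else {
    tapply(df$position, df$locus_tag, max)
  }
  report_skips(as.list(report), paste0("load_ea_table ", source))
  structure(
    list(
      data = df,
      scores = stats::setNames(df$ea, key),
      ref_res = stats::setNames(df$ref_aa, paste(df$locus_tag, df$position, sep = "|")),
      protein_length = protein_length,
      report = report
    ),
    class = "ea_table"
  )
}

#' @export
print.ea_table <- function(x, ...) {
  cat(sprintf("<ea_table> %d substitutions across %d gene(s)\n",
              nrow(x$data), length(unique(x$data$locus_tag))))
  invisible(x)
}

#' Load an EA score table
#'
#' Reads a tab-delimited table with header columns `locus_tag`,
#' `position`, `ref_aa`, `alt_aa`, `ea` (EA on the 0-100 scale; a table
#' entirely on a 0-1 scale is rescaled with a warning). Rows with EA
#' outside the scale, invalid residues, or (when `genome` is supplied) a
#' reference residue disagreeing with the protein sequence are rejected
#' and counted. Duplicate keys with conflicting EA are an error.
#'
#' @param path Path to the table (plain or gzipped).
#' @param genome Optional [ref_genome] for reference-residue validation.
#' @return An [ea_table].
#' @export
load_ea_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_noisy("EA table not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("locus_tag", "position", "ref_aa", "alt_aa", "ea")
  if (!all(need %in% names(df))) {
    stop_noisy("EA table ", path, " must have columns: ",
               paste(need, collapse = ", "))
  }
  new_ea_table(df[, need], genome = genome, source = path)
}

#' Write an EA table to disk
#' @param table An [ea_table].
#' @param path Output path.
#' @export
write_ea_table <- function(table, path) {
  write.table(table$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quick EA lookup for substitutions
#'
#' Looks up EA scores for substitutions in `refAA<pos>altAA` form.
#' Absent entries return status `"missing"` with `NA` (never 0). A
#' reference residue that contradicts the table's record for that position
#' returns status `"ref_mismatch"`, distinct from missing. Stop-gain
#' substitutions (`alt = *`) are governed by `stop_policy`: `"exclude"`
#' (default, `NA`) or `"max"` (EA 100, the maximally disruptive score).
#'
#' @param table An [ea_table].
#' @param gene Character vector of locus tags (recycled).
#' @param substitution Character vector like `"A123V"`, `"Q47*"`.
#' @param stop_policy `"exclude"` or `"max"`.
#' @return Data frame with columns `gene`, `sub`, `position`, `ref_aa`,
#'   `alt_aa`, `ea`, `status`.
#' @export
lookup_ea <- function(table, gene, substitution,
                      stop_policy = c("exclude", "max")) {
  stop_policy <- match.arg(stop_policy)
  n <- max(length(gene), length(substitution))
  gene <- rep_len(as.character(gene), n)
  substitution <- rep_len(toupper(substitution), n)
  p <- parse_substitution(substitution)
  ea <- rep(NA_real_, n)
  status <- rep("missing", n)
  status[!p$ok] <- "malformed"

  idx <- which(p$ok)
  if (length(idx)) {
    ref_known <- unname(table$ref_res[paste(gene[idx], p$position[idx], sep = "|")])
    mismatch <- !is.na(ref_known) & ref_known != p$ref_aa[idx]
    status[idx][mismatch] <- "ref_mismatch"

    is_stop <- p$alt_aa[idx] == "*"
    if (stop_policy == "max") {
      ea[idx][is_stop & !mismatch] <- 100
      status[idx][is_stop & !mismatch] <- "stop_scored"
    } else {
      status[idx][is_stop & !mismatch] <- "stop_excluded"
    }
    reg <- idx[!is_stop & !mismatch]
    if (length(reg)) {
      val <- unname(table$scores[ea_key(gene[reg], p$position[reg], p$alt_aa[reg])])
      ea[reg] <- val
      status[reg][!is.na(val)] <- "ok"
    }
  }
  data.frame(gene = gene, sub = substitution, position = p$position,
             ref_aa = p$ref_aa, alt_aa = p$alt_aa, ea = ea, status = status,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic EA table for a genome
#'
#' For every gene and every residue position, each alternate residue
#' reachable by a single nucleotide change from the reference codon
#' receives an EA score drawn from `100 * Beta(shape1, shape2)`
#' (`reachable_only = FALSE` scores all 19 alternates instead).
#' Deterministic under `seed`.
#'
#' @param genome A [ref_genome].
#' @param seed Integer seed.
#' @param shape1,shape2 Beta shape parameters (default 2, 2: a broad
#'   unimodal impact spectrum centred at 50).
#' @param reachable_only Restrict to single-nucleotide-reachable
#'   substitutions (default), mirroring what an SNV screen can observe.
#' @return An [ea_table].
#' @export
synth_ea_table <- function(genome, seed = 1L, shape1 = 2, shape2 = 2,
                           reachable_only = TRUE) {
  rows <- lapply(seq_len(nrow(genome$genes)), function(i) {
    g <- genome$genes[i, ]
    if (reachable_only) {
      enum <- enumerate_cds_snvs(g)
      mis <- enum[enum$effect == "missense", c("codon_index", "ref_aa", "alt_aa")]
      mis <- unique(mis)
    } else {
      prot <- strsplit(g$protein_seq, "")[[1]]
      mis <- expand.grid(codon_index = seq_along(prot),
                         alt_aa = AA_ONE_LETTER, stringsAsFactors = FALSE)
      mis$ref_aa <- prot[mis$codon_index]
      mis <- mis[mis$ref_aa != mis$alt_aa, c("codon_index", "ref_aa", "alt_aa")]
    }
    if (nrow(mis) == 0) return(NULL)
    data.frame(locus_tag = g$locus_tag, position = mis$codon_index,
               ref_aa = mis$ref_aa, alt_aa = mis$alt_aa,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$locus_tag, df$position, df$alt_aa, method = "radix"), ]
  df$ea <- withr::with_seed(as.integer(seed),
                            100 * rbeta(nrow(df), shape1, shape2))
  new_ea_table(df, genome = genome, source = "synthetic")
}

#' Load a per-residue score track table
#'
#' Tab-delimited with header columns `locus_tag`, `position`, `score`
#' (e.g. Evolutionary Trace ranks or AlphaFold pLDDT values). Returns one
#' numeric vector per gene, `NA` at positions without an entry.
#'
#' @param path Path to the table.
#' @param genome A [ref_genome] giving protein lengths.
#' @return Named list of numeric vectors (one per locus tag).
#' @export
load_residue_track <- function(path, genome) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("locus_tag", "position", "score")
  if (!all(need %in% names(df))) {
    stop_noisy("track table ", path, " must have columns: ",
               paste(need, collapse = ", "))
  }
  out <- list()
  for (lt in unique(df$locus_tag)) {
    i <- match(lt, genome$genes$locus_tag)
    if (is.na(i)) next
    len <- genome$genes$protein_length[i]
    v <- rep(NA_real_, len)
    sub <- df[df$locus_tag == lt & df$position >= 1 & df$position <= len, ]
    v[sub$position] <- sub$score
    out[[lt]] <- v
  }
  out
}
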