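#' Read SNVs from a VCF file
#'
#' Parses a VCF 4.x file into a variant table. Only biallelic single
#' nucleotide variants are kept; indels, MNVs, and symbolic alleles are
#' skipped and counted. Multi-allelic rows are skipped by default, or split
#' into one record per alternate base with `split_multiallelic = TRUE`
#' (only when every alternate is a single base). Rows whose FILTER is
#' neither `PASS` nor `.` are skipped unless `keep_filtered = TRUE`.
#' Genotype columns are ignored: each retained site is attributed to
#' `strain` (one evolved clone per file, the usual ALE design).
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param strain Strain label attached to every record; defaults to the
#'   file name without extension.
#' @param keep_filtered Keep rows with non-PASS FILTER values.
#' @param split_multiallelic Split multi-allelic SNV rows instead of
#'   skipping them.
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`, `strain`
#'   and a `"report"` attribute of skip counts.
#' @export
read_vcf <- function(path, strain = NULL, keep_filtered = FALSE,
                     split_multiallelic = FALSE) {
  if (!file.exists(path)) stop_noisy("VCF file not found: ", path)
  first <- read_text_lines(path)[1]
  if (is.na(first) || !startsWith(first, "##fileformat=VCF")) {
    stop_noisy("missing or garbled VCF header in ", path)
  }
  strain <- strain %||% sub("\\.(vcf|vcf\\.gz)$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  report <- c(skipped_filter = 0L, skipped_symbolic = 0L,
              skipped_multiallelic = 0L, skipped_indel = 0L)
  if (nrow(fix) == 0) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      strain = character(0))
    attr(out, "report") <- report
    return(out)
  }
  fix$REF <- toupper(fix$REF)
  fix$ALT <- toupper(fix$ALT %||% "")
  filt <- fix$FILTER
  ok_filter <- keep_filtered | is.na(filt) | filt %in% c("PASS", ".")
  report["skipped_filter"] <- sum(!ok_filter)
  fix <- fix[ok_filter, , drop = FALSE]

  symbolic <- grepl("[][<>*]", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  report["skipped_symbolic"] <- sum(symbolic)
  fix <- fix[!symbolic, , drop = FALSE]

  multi <- grepl(",", fix$ALT)
  rows <- list()
  if (any(multi)) {
    mfix <- fix[multi, , drop = FALSE]
    if (split_multiallelic) {
      for (i in seq_len(nrow(mfix))) {
        alts <- strsplit(mfix$ALT[i], ",")[[1]]
        if (nchar(mfix$REF[i]) == 1 && all(nchar(alts) == 1) &&
            all(alts %in% DNA_BASES)) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = mfix$CHROM[i], pos = as.integer(mfix$POS[i]),
            ref = mfix$REF[i], alt = alts, stringsAsFactors = FALSE
          )
        } else {
          report["skipped_indel"] <- report["skipped_indel"] + 1L
        }
      }
    } else {
      report["skipped_multiallelic"] <- sum(multi)
    }
  }
  fix <- fix[!multi, , drop = FALSE]
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES & fix$REF != fix$ALT
  report["skipped_indel"] <- report["skipped_indel"] + sum(!snv)
  fix <- fix[snv, , drop = FALSE]
  rows[[length(rows) + 1L]] <- data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  out$strain <- rep(strain, nrow(out))
  rownames(out) <- NULL
  attr(out, "report") <- report
  report_skips(as.list(report), paste0("read_vcf ", basename(path)))
  out
}

#' Read SNVs from a breseq GenomeDiff file
#'
#' Converts `SNP` mutation entries (columns: type, id, parent-ids, seq-id,
#' position, new base) of a GenomeDiff (GD) file into variant records. The
#' reference base is taken from the genome at the stated position. All
#' other entry types (INS, DEL, MOB, AMP, CON, SUB and the evidence lines
#' RA/MC/JC/UN, ...) are skipped and counted by type.
#'
#' @param path Path to a GD file (plain or gzipped).
#' @param genome A [ref_genome], used to fill in the reference base.
#' @param strain Strain label; defaults to the file name without extension.
#' @return As [read_vcf()].
#' @export
read_gd <- function(path, genome, strain = NULL) {
  if (!file.exists(path)) stop_noisy("GenomeDiff file not found: ", path)
  strain <- strain %||% sub("\\.(gd|gd\\.gz)$", "", basename(path))
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  report <- c(skipped_other_type = 0L, skipped_evidence = 0L,
              rejected_bad_position = 0L, rejected_bad_base = 0L)
  rows <- list()
  mutation_types <- c("SNP", "SUB", "DEL", "INS", "MOB", "AMP", "CON", "INV")
  for (line in lines) {
    f <- strsplit(line, "\t")[[1]]
    type <- f[1]
    if (type != "SNP") {
      if (type %in% mutation_types) {
        report["skipped_other_type"] <- report["skipped_other_type"] + 1L
      } else {
        report["skipped_evidence"] <- report["skipped_evidence"] + 1L
      }
      next
    }
    contig <- f[4]
    pos <- suppressWarnings(as.integer(f[5]))
    alt <- toupper(f[6])
    if (is.na(pos) || !contig %in% names(genome$contigs) ||
        pos < 1 || pos > nchar(genome$contigs[[contig]])) {
      report["rejected_bad_position"] <- report["rejected_bad_position"] + 1L
      next
    }
    ref <- substr(genome$contigs[[contig]], pos, pos)
    if (!alt %in% DNA_BASES || alt == ref) {
      report["rejected_bad_base"] <- report["rejected_bad_base"] + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  out$strain <- rep(strain, nrow(out))
  rownames(out) <- NULL
  attr(out, "report") <- report
  report_skips(as.list(report), paste0("read_gd ", basename(path)))
  out
}

SUB_PATTERN <- "^([ACDEFGHIKLMNPQRSTVWY*])([0-9]+)([ACDEFGHIKLMNPQRSTVWY*])$"

parse_substitution <- function(sub) {
  m <- regmatches(sub, regexec(SUB_PATTERN, sub))
  ok <- lengths(m) == 4
  data.frame(
    ok = ok,
    ref_aa = vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_, ""),
    position = vapply(m, function(x) if (length(x) == 4) as.integer(x[3]) else NA_integer_, 1L),
    alt_aa = vapply(m, function(x) if (length(x) == 4) x[4] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Read an amino-acid substitution list
#'
#' Tab-delimited file with two or three columns: gene (locus tag or gene
#' name), substitution in `refAA<pos>altAA` form (e.g. `A123V`, stop as
#' `*`), and an optional strain label. Lines starting with `#` are
#' comments. Malformed lines are rejected and their line numbers recorded
#' in the load report.
#'
#' @param path Path to the file (plain or gzipped).
#' @param strain Default strain label for two-column rows.
#' @return Data frame with columns `gene`, `sub`, `ref_aa`, `position`,
#'   `alt_aa`, `strain`, and a `"report"` attribute.
#' @export
read_substitutions <- function(path, strain = "substitutions") {
  if (!file.exists(path)) stop_noisy("substitution file not found: ", path)
  lines <- read_text_lines(path)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- list()
  bad_lines <- integer(0)
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 2 || length(f) > 3) {
      bad_lines <- c(bad_lines, i)
      next
    }
    p <- parse_substitution(toupper(trimws(f[2])))
    if (!p$ok || p$position < 1 || p$ref_aa == p$alt_aa) {
      bad_lines <- c(bad_lines, i)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = trimws(f[1]), sub = toupper(trimws(f[2])),
      ref_aa = p$ref_aa, position = p$position, alt_aa = p$alt_aa,
      strain = if (length(f) == 3) trimws(f[3]) else strain,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), sub = character(0),
               ref_aa = character(0), position = integer(0),
               alt_aa = character(0), strain = character(0))
  rownames(out) <- NULL
  report <- list(rejected_lines = bad_lines)
  attr(out, "report") <- report
  if (length(bad_lines)) {
    ea_msg(sprintf("read_substitutions %s: rejected %d malformed line(s): %s",
                   basename(path), length(bad_lines),
                   paste(bad_lines, collapse = ",")))
  }
  out
}

#' Pool variant tables from several strains
#'
#' Binds per-strain variant tables into one observed set. Duplicate
#' identical rows within one strain are collapsed; the same variant seen in
#' different strains is retained once per strain (recurrence across
#' replicate ALE lineages is frequency signal).
#'
#' @param ... Variant data frames from [read_vcf()] / [read_gd()].
#' @return Pooled variant data frame.
#' @export
pool_variants <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    x <- as.data.frame(x)[, c("contig", "pos", "ref", "alt", "strain")]
    x
  }))
  out <- unique(out)
  rownames(out) <- NULL
  out
}
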