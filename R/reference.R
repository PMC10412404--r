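#' Reference genome container
#'
#' A `ref_genome` is a list with elements
#' \describe{
#'   \item{contigs}{named character vector of uppercase nucleotide sequences}
#'   \item{genes}{data frame of gene models: `locus_tag`, `gene_name`,
#'     `contig`, `start`, `end` (1-based inclusive), `strand` (`+`/`-`),
#'     `cds_length` (nt), `cds_seq` (coding-strand CDS sequence),
#'     `protein_seq` (without the trailing stop), `protein_length`}
#'   \item{coding_length_total}{sum of `cds_length` over all retained genes}
#'   \item{report}{named counts of CDS features skipped at load time}
#' }
#'
#' Coordinates are 1-based inclusive throughout (the GenBank/VCF convention).
#' A variant falling inside several overlapping genes is annotated once per
#' containing gene, since all driver statistics are per-gene.
#'
#' @name ref_genome
NULL

new_ref_genome <- function(contigs, cds_df, report = list(), source = "memory") {
  built <- build_gene_models(contigs, cds_df)
  report <- utils::modifyList(as.list(report), as.list(built$report))
  genes <- built$genes
  if (nrow(genes) == 0) {
    stop_noisy("no usable CDS features in ", source)
  }
  report_skips(report, paste0("load ", source))
  structure(
    list(
      contigs = contigs,
      genes = genes,
      coding_length_total = sum(genes$cds_length),
      report = report
    ),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf(
    "<ref_genome> %d contig(s), %d gene(s), %d coding nt\n",
    length(x$contigs), nrow(x$genes), x$coding_length_total
  ))
  invisible(x)
}

# Validate candidate CDS rows (locus_tag, gene_name, contig, start, end,
# strand) against the contig sequences; extract coding-strand sequence and
# protein; drop broken frames with per-reason counts.
build_gene_models <- function(contigs, cds_df) {
  report <- c(
    missing_locus_tag = 0L, out_of_range = 0L, length_not_multiple_of_3 = 0L,
    ambiguous_bases = 0L, internal_stop = 0L, no_terminal_stop = 0L,
    duplicate_locus_tag = 0L
  )
  keep <- rep(TRUE, nrow(cds_df))
  cds_df$locus_tag <- as.character(cds_df$locus_tag)
  cds_df$gene_name <- as.character(cds_df$gene_name %||% "")
  cds_df$gene_name[is.na(cds_df$gene_name)] <- ""

  bad <- is.na(cds_df$locus_tag) | cds_df$locus_tag == ""
  report["missing_locus_tag"] <- sum(bad)
  keep <- keep & !bad

  clen <- nchar(contigs)[cds_df$contig]
  bad <- is.na(clen) | cds_df$start < 1 | cds_df$end > clen |
    cds_df$start > cds_df$end
  bad[is.na(bad)] <- TRUE
  report["out_of_range"] <- sum(bad & keep)
  keep <- keep & !bad

  len <- cds_df$end - cds_df$start + 1L
  bad <- len %% 3L != 0L
  report["length_not_multiple_of_3"] <- sum(bad & keep, na.rm = TRUE)
  keep <- keep & !bad

  df <- cds_df[keep, , drop = FALSE]
  if (nrow(df) > 0) {
    seqs <- substr(contigs[df$contig], df$start, df$end)
    neg <- df$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    ok_seq <- grepl("^[ACGT]+$", seqs)
    report["ambiguous_bases"] <- sum(!ok_seq)
    df <- df[ok_seq, , drop = FALSE]
    seqs <- seqs[ok_seq]
    if (nrow(df) > 0) {
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(seqs),
        genetic.code = genetic_code_11(), no.init.codon = TRUE
      ))
      n <- nchar(prot)
      has_term <- substr(prot, n, n) == "*"
      body <- substr(prot, 1, n - 1)
      internal <- grepl("\\*", body)
      report["internal_stop"] <- sum(internal)
      report["no_terminal_stop"] <- sum(!has_term & !internal)
      ok <- has_term & !internal
      df <- df[ok, , drop = FALSE]
      df$cds_seq <- seqs[ok]
      df$protein_seq <- body[ok]
    }
  }
  if (nrow(df) > 0) {
    dup <- duplicated(df$locus_tag)
    report["duplicate_locus_tag"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    df$cds_length <- df$end - df$start + 1L
    df$protein_length <- df$cds_length %/% 3L - 1L
    rownames(df) <- df$locus_tag
    df <- df[, c("locus_tag", "gene_name", "contig", "start", "end", "strand",
                 "cds_length", "cds_seq", "protein_seq", "protein_length")]
  } else {
    df$cds_seq <- character(0)
    df$protein_seq <- character(0)
    df$cds_length <- integer(0)
    df$protein_length <- integer(0)
  }
  list(genes = df, report = report)
}

#' Load an annotated genome from a GenBank flat file
#'
#' Reads sequence and CDS features (with `/locus_tag`) from a GenBank flat
#' file, possibly with several records (contigs). CDS features with compound
#' (`join(...)`) or fuzzy locations, without a locus tag, with a length not
#' divisible by three, or whose translation has internal stops or lacks a
#' terminal stop codon are skipped and counted in the load report
#' (pseudogenes and broken frames have no defined per-residue EA positions).
#'
#' @param path Path to a GenBank flat file (may be gzipped).
#' @return A [ref_genome] object.
#' @seealso [load_gff3()] for the GFF3+FASTA dialect.
#' @export
load_genbank <- function(path) {
  if (!file.exists(path)) stop_noisy("GenBank file not found: ", path)
  lines <- read_text_lines(path)
  rec_id <- cumsum(grepl("^LOCUS", lines))
  if (max(rec_id) == 0) stop_noisy("not a GenBank flat file (no LOCUS line): ", path)
  records <- split(lines, rec_id)
  records <- records[names(records) != "0"]

  contigs <- character(0)
  cds_rows <- list()
  report <- c(compound_location = 0L, fuzzy_location = 0L, unparsed_location = 0L)

  for (rl in records) {
    contig_id <- strsplit(trimws(rl[1]), "\\s+")[[1]][2]
    origin_i <- grep("^ORIGIN", rl)[1]
    feat_i <- grep("^FEATURES", rl)[1]
    if (is.na(origin_i)) stop_noisy("GenBank record ", contig_id, " has no ORIGIN section: ", path)
    end_i <- grep("^//", rl)[1]
    if (is.na(end_i)) end_i <- length(rl) + 1L
    seq <- toupper(paste(gsub("[^A-Za-z]", "", rl[(origin_i + 1):(end_i - 1)]),
                         collapse = ""))
    if (nchar(seq) == 0) stop_noisy("empty sequence for record ", contig_id, " in ", path)
    contigs[contig_id] <- seq

    if (is.na(feat_i)) next
    flines <- rl[(feat_i + 1):(origin_i - 1)]
    feats <- parse_genbank_features(flines)
    for (ft in feats) {
      if (ft$key != "CDS") next
      loc <- parse_genbank_location(ft$location)
      if (!loc$ok) {
        report[loc$reason] <- report[loc$reason] + 1L
        next
      }
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        locus_tag = ft$qualifiers[["locus_tag"]] %||% NA_character_,
        gene_name = ft$qualifiers[["gene"]] %||% "",
        contig = contig_id, start = loc$start, end = loc$end,
        strand = loc$strand, stringsAsFactors = FALSE
      )
    }
  }
  cds_df <- if (length(cds_rows)) do.call(rbind, cds_rows) else
    data.frame(locus_tag = character(0), gene_name = character(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  new_ref_genome(contigs, cds_df, report = report, source = path)
}

# Split a FEATURES block into features: key, location string, qualifiers.
parse_genbank_features <- function(flines) {
  feats <- list()
  cur <- NULL
  in_location <- FALSE
  for (line in flines) {
    if (!nzchar(trimws(line))) next
    indent <- nchar(line) - nchar(sub("^ +", "", line))
    body <- trimws(line)
    if (indent < 21 && indent >= 1) {  # new feature key line
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      parts <- strsplit(body, "\\s+")[[1]]
      cur <- list(key = parts[1],
                  location = paste(parts[-1], collapse = ""),
                  qualifiers = list())
      in_location <- TRUE
    } else if (!is.null(cur)) {
      if (startsWith(body, "/")) {
        in_location <- FALSE
        m <- regmatches(body, regexec('^/([A-Za-z_0-9]+)=?"?([^"]*)"?$', body))[[1]]
        if (length(m) == 3) cur$qualifiers[[m[2]]] <- m[3]
      } else if (in_location) {
        cur$location <- paste0(cur$location, body)
      }
      # qualifier continuation lines are ignored (locus_tag/gene fit one line)
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

parse_genbank_location <- function(loc) {
  l <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", l)) {
    strand <- "-"
    l <- sub("^complement\\((.*)\\)$", "\\1", l)
  }
  if (grepl("join\\(|order\\(", l)) return(list(ok = FALSE, reason = "compound_location"))
  if (grepl("[<>]", l)) return(list(ok = FALSE, reason = "fuzzy_location"))
  m <- regmatches(l, regexec("^(\\d+)\\.\\.(\\d+)$", l))[[1]]
  if (length(m) != 3) return(list(ok = FALSE, reason = "unparsed_location"))
  list(ok = TRUE, start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Load an annotated genome from GFF3 + FASTA
#'
#' Second reader dialect with the same post-conditions as [load_genbank()]:
#' CDS features are taken from the GFF3, sequences from the FASTA. A CDS
#' split over several GFF3 rows (a compound location) is skipped and
#' reported. The locus tag is taken from the `locus_tag` attribute, falling
#' back to `ID`.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to the genome FASTA.
#' @return A [ref_genome] object.
#' @export
load_gff3 <- function(gff_path, fasta_path) {
  if (!file.exists(gff_path)) stop_noisy("GFF3 file not found: ", gff_path)
  if (!file.exists(fasta_path)) stop_noisy("FASTA file not found: ", fasta_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  contigs <- toupper(as.character(dna))

  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop_noisy("no CDS features in ", gff_path)
  mc <- S4Vectors::mcols(gr)
  locus <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag) else NA
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA
  locus <- ifelse(is.na(locus) | locus == "", id, locus)
  gene <- if ("gene" %in% names(mc)) as.character(mc$gene) else ""
  cds_df <- data.frame(
    locus_tag = locus,
    gene_name = ifelse(is.na(gene), "", gene),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  report <- c(compound_location = 0L, no_strand = 0L)
  multi <- cds_df$locus_tag %in% cds_df$locus_tag[duplicated(cds_df$locus_tag)]
  report["compound_location"] <- length(unique(cds_df$locus_tag[multi]))
  cds_df <- cds_df[!multi, , drop = FALSE]
  bad_strand <- !cds_df$strand %in% c("+", "-")
  report["no_strand"] <- sum(bad_strand)
  cds_df <- cds_df[!bad_strand, , drop = FALSE]
  new_ref_genome(contigs, cds_df, report = report, source = gff_path)
}

gene_row <- function(genome, locus_tag) {
  i <- match(locus_tag, genome$genes$locus_tag)
  if (is.na(i)) stop_noisy("unknown locus_tag: ", locus_tag)
  genome$genes[i, , drop = FALSE]
}

#' Codon coordinates of a genomic position within a gene
#'
#' Maps a 1-based genomic position inside a gene to its codon index (1 =
#' start codon), offset within the codon (0/1/2 along the coding strand),
#' and the codon sequence oriented to the coding strand (for minus-strand
#' genes this is the reverse complement of the genomic triplet).
#'
#' @param genome A [ref_genome].
#' @param locus_tag Gene identifier.
#' @param genomic_pos Integer vector of 1-based genomic positions.
#' @return Data frame with columns `codon_index`, `offset_in_codon`, `codon`.
#' @export
codon_at <- function(genome, locus_tag, genomic_pos) {
  g <- gene_row(genome, locus_tag)
  if (any(genomic_pos < g$start | genomic_pos > g$end)) {
    bad <- genomic_pos[genomic_pos < g$start | genomic_pos > g$end][1]
    stop_noisy(sprintf("position %d outside gene %s (%d..%d)",
                       bad, locus_tag, g$start, g$end))
  }
  o <- if (g$strand == "+") genomic_pos - g$start else g$end - genomic_pos
  ci <- o %/% 3L + 1L
  data.frame(
    codon_index = ci,
    offset_in_codon = o %% 3L,
    codon = substr(rep(g$cds_seq, length(ci)), (ci - 1L) * 3L + 1L, ci * 3L),
    stringsAsFactors = FALSE
  )
}
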