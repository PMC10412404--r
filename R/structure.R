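#' Per-residue mutation-burden tracks for one gene
#'
#' Projects annotated effects onto residue positions: `sum_ea[i]` is the
#' total EA of scored missense substitutions at residue `i` and
#' `unique_mutations[i]` the number of distinct amino-acid substitutions
#' (missense or nonsense) observed there. By default each distinct
#' substitution contributes once regardless of how many strains carry it
#' (`per_occurrence = TRUE` instead counts each strain occurrence).
#'
#' @param effects Effects data frame (see [annotate_variants()]).
#' @param locus_tag Gene to project.
#' @param genome A [ref_genome] (gives the protein length).
#' @param per_occurrence Pool EA per strain occurrence instead of once
#'   per distinct substitution.
#' @return List with numeric vectors `sum_ea` and `unique_mutations`,
#'   both of length `protein_length`.
#' @export
residue_tracks_from_effects <- function(effects, locus_tag, genome,
                                        per_occurrence = FALSE) {
  g <- gene_row(genome, locus_tag)
  len <- g$protein_length
  e <- effects[!is.na(effects$locus_tag) & effects$locus_tag == locus_tag &
                 effects$effect %in% c("missense", "nonsense") &
                 !is.na(effects$codon_index) & effects$codon_index <= len, ,
               drop = FALSE]
  sum_ea <- rep(0, len)
  uniq <- rep(0L, len)
  if (nrow(e) > 0) {
    distinct <- unique(e[, c("codon_index", "ref_aa", "alt_aa", "effect", "ea")])
    cnt <- table(factor(distinct$codon_index, levels = seq_len(len)))
    uniq <- as.integer(cnt)
    pooled <- if (per_occurrence) {
      e[!duplicated(paste(e$strain, e$codon_index, e$alt_aa)), , drop = FALSE]
    } else {
      distinct
    }
    scored <- pooled[pooled$effect == "missense" & !is.na(pooled$ea), ,
                     drop = FALSE]
    if (nrow(scored) > 0) {
      s <- tapply(scored$ea, factor(scored$codon_index, levels = seq_len(len)),
                  sum)
      s[is.na(s)] <- 0
      sum_ea <- as.numeric(s)
    }
  }
  list(sum_ea = sum_ea, unique_mutations = uniq)
}

TRACK_NA_FLAG <- -1

#' Write a per-residue track into a PDB B-factor column
#'
#' Writes `track` values into the B-factor column of a single-chain PDB
#' (AlphaFold-style numbering from 1), clamped to \[0, 999.99\] at the
#' 2-decimal fixed-format precision; residues without a defined value are
#' flagged as `-1.00`. A companion PyMOL command script applies a
#' blue-white-red spectrum over the defined range and colors flagged
#' residues grey, reproducing the track as a structure coloring.
#'
#' @param pdb_path Input PDB file.
#' @param track Numeric vector, one value per residue (`NA` = undefined).
#' @param out_path Output PDB path.
#' @param pml_path Optional output path for the PyMOL `.pml` script.
#' @param track_name Label used inside the PyMOL script.
#' @return `out_path`, invisibly.
#' @export
write_colored_pdb <- function(pdb_path, track, out_path, pml_path = NULL,
                              track_name = "track") {
  pdb <- bio3d::read.pdb(pdb_path)
  atom <- pdb$atom
  resnos <- unique(atom$resno[atom$type == "ATOM"])
  if (length(resnos) != length(track)) {
    stop_noisy(sprintf(
      "residue count mismatch: PDB %s has %d residues, track has %d values",
      basename(pdb_path), length(resnos), length(track)))
  }
  vals <- pmin(pmax(round(as.numeric(track), 2), 0), 999.99)
  vals[is.na(track)] <- TRACK_NA_FLAG
  b <- vals[match(atom$resno, resnos)]
  b[atom$type != "ATOM"] <- 0
  bio3d::write.pdb(pdb, file = out_path, b = b)

  if (!is.null(pml_path)) {
    defined <- vals[!is.na(track)]
    lines <- c(
      sprintf("# PyMOL coloring script: %s", track_name),
      sprintf("load %s, colored", basename(out_path)),
      "hide everything",
      "show cartoon",
      "select undefined_res, b < -0.5",
      "color grey50, undefined_res"
    )
    if (length(defined) > 0) {
      lines <- c(lines, sprintf(
        "spectrum b, blue_white_red, not undefined_res, minimum=%.2f, maximum=%.2f",
        min(defined), max(defined)))
    }
    lines <- c(lines, "deselect")
    writeLines(lines, pml_path)
  }
  invisible(out_path)
}

#' Read a per-residue track back from a PDB B-factor column
#'
#' Inverse of [write_colored_pdb()]: returns one value per residue (the
#' first ATOM record of each), converting the `-1.00` undefined flag back
#' to `NA`.
#'
#' @param pdb_path PDB file written by [write_colored_pdb()].
#' @param na_flag Flag value marking undefined residues.
#' @return Numeric vector, one value per residue.
#' @export
read_track_from_pdb <- function(pdb_path, na_flag = TRACK_NA_FLAG) {
  pdb <- bio3d::read.pdb(pdb_path)
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  first <- atom[!duplicated(atom$resno), , drop = FALSE]
  v <- first$b
  v[v == na_flag] <- NA_real_
  v
}

#' Write a synthetic single-chain C-alpha PDB
#'
#' Generates a minimal alpha-carbon-only structure (a noisy helix-like
#' trace) with residues numbered from 1, for exercising the structure
#' coloring export without any downloaded model. Clearly synthetic: all
#' residues are alanine.
#'
#' @param n_res Number of residues.
#' @param path Output path.
#' @param seed Integer seed for the coordinate jitter.
#' @return `path`, invisibly.
#' @export
make_synthetic_pdb <- function(n_res, path, seed = 1L) {
  stopifnot(n_res >= 1)
  xyz <- withr::with_seed(as.integer(seed), {
    t <- seq_len(n_res)
    cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t) +
      matrix(stats::runif(3 * n_res, -0.1, 0.1), ncol = 3)
  })
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = as.numeric(t(xyz)),
    resno = seq_len(n_res), resid = rep("ALA", n_res),
    elety = rep("CA", n_res), chain = rep("A", n_res),
    b = rep(0, n_res)
  )
  invisible(path)
}
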