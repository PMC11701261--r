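#' Synthetic locus specification
#'
#' Describes a toy genome fragment with planted features, used to exercise
#' the whole pipeline without external data: gene promoters, ATAC
#' enhancers, an acetylated (open) block around the gene, repressed
#' H3K27me3/H3K9me3 domains, and a convergent CTCF pair with RAD21
#' co-peaks and oriented binding motifs.
#'
#' The default locus is a 100 kbp fragment with one gene: promoter at
#' 50-51 kbp (also accessible), strong enhancers at 40 and 65 kbp, a weak
#' distal ATAC site at 93 kbp, an H3K27ac block over 45-56 kbp, an
#' H3K27me3 domain at 5-15 kbp, an H3K9me3 domain at 85-95 kbp, and a
#' convergent CTCF pair (forward at 30 kbp, backward at 75 kbp) at maximal
#' score (activation probability 1).
#'
#' @param chrom chromosome name.
#' @param length_kbp fragment length.
#' @param genes data.frame `(gene, promoter_start, promoter_end)`.
#' @param atac data.frame `(start, end, strength)` of accessible sites
#'   (promoters are added automatically).
#' @param h3k27ac,h3k27me3,h3k9me3 data.frames `(start, end)`.
#' @param ctcf data.frame `(start, end, orientation, score)` with
#'   orientation `"forward"`, `"backward"` or `"bidirectional"`.
#' @param seed integer seed echoed into the files for provenance.
#' @return an object of class `synthetic_locus`.
#' @export
synthetic_locus <- function(chrom = "chrS", length_kbp = 100,
                            genes = data.frame(gene = "G1",
                                               promoter_start = 50000,
                                               promoter_end = 51000),
                            atac = data.frame(
                              start = c(40000, 65000, 93000),
                              end = c(41000, 66000, 94000),
                              strength = c(10, 10, 2)),
                            h3k27ac = data.frame(start = 45000, end = 56000),
                            h3k27me3 = data.frame(start = 5000, end = 15000),
                            h3k9me3 = data.frame(start = 85000, end = 95000),
                            ctcf = data.frame(
                              start = c(30000, 75000),
                              end = c(30400, 75400),
                              orientation = c("forward", "backward"),
                              score = c(20, 20)),
                            seed = 1) {
  end_bp <- length_kbp * 1000
  feats <- rbind(atac[, c("start", "end")], h3k27ac, h3k27me3, h3k9me3,
                 ctcf[, c("start", "end")],
                 data.frame(start = genes$promoter_start,
                            end = genes$promoter_end))
  if (any(feats$start < 0 | feats$end > end_bp))
    stop("synthetic features must lie within the fragment")
  if (!all(ctcf$orientation %in% c("forward", "backward", "bidirectional")))
    stop("bad CTCF orientation in synthetic locus")
  structure(list(chrom = chrom, length_kbp = length_kbp, genes = genes,
                 atac = atac, h3k27ac = h3k27ac, h3k27me3 = h3k27me3,
                 h3k9me3 = h3k9me3, ctcf = ctcf, seed = seed),
            class = "synthetic_locus")
}

#' Write a synthetic locus as peak/motif/promoter files
#'
#' Produces the full input stack consumed by the annotation module: ATAC
#' and CTCF narrowPeak files, BED files for the histone marks and RAD21
#' (RAD21 peaks mirror the CTCF peaks, satisfying the co-occupancy rule),
#' a promoter BED with gene names, and a motif-hit TSV with one oriented
#' motif per CTCF peak. Byte-identical under the same spec.
#'
#' @param spec a [synthetic_locus()].
#' @param dir output directory.
#' @return named list of file paths plus the [genome_fragment()].
#' @export
synth_epigenome <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- spec$chrom
  np_line <- function(start, end, name, signal)
    sprintf("%s\t%d\t%d\t%s\t%d\t.\t%g\t-1\t-1\t%d", ch, start, end, name,
            pmin(1000L, as.integer(round(signal * 10))), signal,
            as.integer((end - start) / 2))
  paths <- list()

  atac <- rbind(spec$atac,
                data.frame(start = spec$genes$promoter_start,
                           end = spec$genes$promoter_end, strength = 10))
  atac <- atac[order(atac$start), , drop = FALSE]
  paths$atac <- file.path(dir, "atac.narrowPeak")
  writeLines(np_line(atac$start, atac$end,
                     sprintf("atac_%d", seq_len(nrow(atac))), atac$strength),
             paths$atac)

  for (m in c("h3k27ac", "h3k27me3", "h3k9me3")) {
    d <- spec[[m]]
    paths[[m]] <- file.path(dir, paste0(m, ".bed"))
    writeLines(if (nrow(d)) sprintf("%s\t%d\t%d", ch, d$start, d$end)
               else character(), paths[[m]])
  }

  ct <- spec$ctcf
  ct$name <- sprintf("ctcf_%d", seq_len(nrow(ct)))
  paths$ctcf <- file.path(dir, "ctcf.narrowPeak")
  writeLines(np_line(ct$start, ct$end, ct$name, ct$score), paths$ctcf)
  paths$rad21 <- file.path(dir, "rad21.bed")
  writeLines(sprintf("%s\t%d\t%d", ch, ct$start, ct$end), paths$rad21)

  # one 19 bp motif per CTCF peak at the peak centre; bidirectional sites
  # get equal-scoring motifs on both strands
  motif <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
    mid <- floor((ct$start[i] + ct$end[i]) / 2)
    strands <- switch(ct$orientation[i], forward = "+", backward = "-",
                      bidirectional = c("+", "-"))
    data.frame(chrom = ch, start = mid - 9, end = mid + 10, strand = strands,
               score = 15, peak_id = ct$name[i], stringsAsFactors = FALSE)
  }))
  paths$motifs <- file.path(dir, "motifs.tsv")
  utils::write.table(motif, paths$motifs, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths$promoters <- file.path(dir, "promoters.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", ch, spec$genes$promoter_start,
                     spec$genes$promoter_end, spec$genes$gene),
             paths$promoters)

  fragment <- genome_fragment(ch, 0, spec$length_kbp * 1000)
  jsonlite::write_json(list(chrom = ch, length_kbp = spec$length_kbp,
                            seed = spec$seed, files = paths),
                       file.path(dir, "locus.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  c(paths, list(fragment = fragment))
}

#' Annotate a synthetic (or real) locus directory
#'
#' Chains peak parsing, mark annotation, CTCF boundary calling and promoter
#' assignment for the file set produced by [synth_epigenome()].
#'
#' @param files named list of paths (as from [synth_epigenome()]); must
#'   contain `atac`, `h3k27ac`, `h3k27me3`, `h3k9me3`, `ctcf`, `rad21`,
#'   `motifs`, `promoters`.
#' @param fragment the [genome_fragment()].
#' @return an annotated bead track.
#' @export
annotate_locus <- function(files, fragment) {
  peaks <- list(atac = parse_peak_file(files$atac, "narrowPeak"),
                h3k27ac = parse_peak_file(files$h3k27ac, "bed"),
                h3k27me3 = parse_peak_file(files$h3k27me3, "bed"),
                h3k9me3 = parse_peak_file(files$h3k9me3, "bed"))
  track <- annotate_marks(fragment, peaks)
  motif <- utils::read.table(files$motifs, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  track <- call_ctcf_beads(track, parse_peak_file(files$ctcf, "narrowPeak"),
                           parse_peak_file(files$rad21, "bed"), motif)
  prom <- utils::read.table(files$promoters, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "gene"),
                            stringsAsFactors = FALSE)
  annotate_promoters(track, prom)
}

#' Deterministic toy structure ensemble from a contact plan
#'
#' Builds explicit coordinate sets (no dynamics) realizing a prescribed
#' contact plan between a promoter bead and candidate beads, so partner
#' frequencies and network catalogs are known exactly by construction.
#' Non-candidate beads sit on a straight line with 5 sigma spacing (no
#' incidental contacts); planned in-contact candidates are placed 2 sigma
#' from the promoter in distinct directions, others 10 sigma away.
#'
#' @param n_beads chain length.
#' @param promoter_bead 0-based promoter bead.
#' @param contact_matrix logical matrix (n_structures x n_candidates) whose
#'   column names are the 0-based candidate bead indices; `TRUE` means the
#'   candidate contacts the promoter in that structure.
#' @param track optional bead track attached to the ensemble.
#' @return a `structure_ensemble` (no periodic box).
#' @export
toy_ensemble <- function(n_beads, promoter_bead, contact_matrix,
                         track = NULL) {
  if (is.null(colnames(contact_matrix)))
    stop("contact_matrix must have candidate bead indices as colnames")
  cand <- as.integer(colnames(contact_matrix))
  if (anyNA(cand)) stop("contact_matrix must have candidate bead indices as colnames")
  if (any(cand < 0 | cand >= n_beads) || promoter_bead >= n_beads)
    stop("bead index outside the chain")
  if (promoter_bead %in% cand)
    stop("unrealizable plan: the promoter cannot be its own candidate")
  base <- cbind(5 * (0:(n_beads - 1)), 0, 0)
  p0 <- base[promoter_bead + 1, ]
  # distinct contact directions in the yz plane
  ang <- 2 * pi * seq_along(cand) / (length(cand) + 1)
  frames <- lapply(seq_len(nrow(contact_matrix)), function(s) {
    p <- base
    for (k in seq_along(cand)) {
      p[cand[k] + 1, ] <- if (contact_matrix[s, k])
        p0 + 2 * c(0, cos(ang[k]), sin(ang[k]))
      else
        p0 + 10 * c(1, cos(ang[k]), sin(ang[k]))
    }
    p
  })
  structure_ensemble(frames, track = track, box = NULL)
}

# element symbols encode the dominant bead class for viewers
.bead_elements <- function(n, track = NULL) {
  el <- rep("C", n)
  if (!is.null(track)) {
    el[track$h3k9me3] <- "S"
    el[track$h3k27me3] <- "P"
    el[track$h3k27ac] <- "O"
    el[track$atac] <- "N"
    el[track$promoter] <- "F"
  }
  el
}

#' Export a structure as XYZ or CIF
#'
#' One pseudo-atom per bead. XYZ round-trips numerically (1e-6); the
#' mmCIF carries the bead index as the sequence id, the genomic offset
#' (kbp) as the B factor, and the mark class in the residue name, and
#' parses in standard structure viewers.
#'
#' @param structure n x 3 coordinate matrix (sigma).
#' @param path output file.
#' @param format `"xyz"` or `"cif"`.
#' @param track optional bead track for mark classes.
#' @return the path, invisibly.
#' @export
export_structure <- function(structure, path, format = c("xyz", "cif"),
                             track = NULL) {
  format <- match.arg(format)
  n <- nrow(structure)
  el <- .bead_elements(n, track)
  if (format == "xyz") {
    lines <- c(as.character(n), "chromatin beads (coordinates in sigma)",
               sprintf("%s %.6f %.6f %.6f", el, structure[, 1],
                       structure[, 2], structure[, 3]))
    writeLines(lines, path)
  } else {
    comp <- c(C = "CHR", N = "ATA", O = "ACE", P = "PME", S = "HME", F = "PRO")
    lines <- c("data_chromatin_structure", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
               "_atom_site.auth_asym_id", "_atom_site.pdbx_PDB_model_num",
               sprintf(
                 "ATOM %d %s CA . %s A 1 %d ? %.4f %.4f %.4f 1.00 %.2f %d A 1",
                 seq_len(n), el, comp[el], seq_len(n), structure[, 1],
                 structure[, 2], structure[, 3], seq_len(n) - 1, seq_len(n)),
               "#")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an XYZ structure written by [export_structure()]
#' @param path file path.
#' @return n x 3 coordinate matrix.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  dimnames(m) <- NULL
  m
}
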