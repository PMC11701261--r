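#' Promoter-candidate contact frequencies across an ensemble
#'
#' For each candidate bead, the fraction of structures in which its
#' minimum-image centre-to-centre distance to the promoter bead is strictly
#' below the contact threshold (3.5 sigma by default).
#'
#' @param ensemble a `structure_ensemble`.
#' @param promoter_bead 0-based promoter bead index.
#' @param candidate_beads 0-based candidate (ATAC) bead indices.
#' @param threshold contact distance threshold in sigma (strict `<`).
#' @return named numeric vector of frequencies in `[0, 1]` (names are the
#'   candidate bead indices).
#' @export
contact_frequency <- function(ensemble, promoter_bead, candidate_beads,
                              threshold = 3.5) {
  if (!length(ensemble$frames)) stop("empty ensemble")
  box <- ensemble$box
  hits <- vapply(ensemble$frames, function(p) {
    d <- sweep(p[candidate_beads + 1, , drop = FALSE], 2, p[promoter_bead + 1, ])
    if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    sqrt(rowSums(d * d)) < threshold
  }, logical(length(candidate_beads)))
  hits <- matrix(hits, nrow = length(candidate_beads))
  stats::setNames(rowMeans(hits), candidate_beads)
}

#' Call ATAC partners of a promoter
#'
#' Candidates in contact with the promoter in at least `threshold` of the
#' structures (inclusive, so a frequency of exactly 10% qualifies).
#'
#' @param frequencies output of [contact_frequency()].
#' @param threshold partner frequency threshold (default 0.10).
#' @return integer vector of partner bead indices (0-based).
#' @export
call_partners <- function(frequencies, threshold = 0.10) {
  as.integer(names(frequencies)[frequencies >= threshold])
}

#' Call influential nodes of a promoter
#'
#' Partners in contact with the promoter in at least `threshold` of the
#' structures (inclusive); these very frequent contacts are the
#' hypothesized key regulators.
#'
#' @param frequencies output of [contact_frequency()].
#' @param threshold influential frequency threshold (default 0.50).
#' @return integer vector of influential bead indices (0-based).
#' @export
call_influential <- function(frequencies, threshold = 0.50) {
  call_partners(frequencies, threshold)
}

#' Genomic extent of a topos
#'
#' The contiguous genomic region encompassing the promoter and all its
#' partners: `[min bead, max bead]` over the union, converted to bp. With
#' no partners the topos degenerates to the promoter bead's own interval.
#'
#' @param promoter_bead 0-based promoter bead.
#' @param partners 0-based partner beads (possibly empty).
#' @param fragment a [genome_fragment()].
#' @return list with `start`, `end` (bp, 0-based half-open), `size_kbp` and
#'   the bead range.
#' @export
topos_extent <- function(promoter_bead, partners, fragment) {
  beads <- c(promoter_bead, partners)
  b0 <- min(beads); b1 <- max(beads)
  iv0 <- interval_of(fragment, b0)
  iv1 <- interval_of(fragment, b1)
  list(start = iv0$start, end = iv1$end,
       size_kbp = (iv1$end - iv0$start) / 1000,
       bead_min = b0, bead_max = b1)
}

#' Catalog the interaction networks of a topos
#'
#' For each structure, the subset of partners simultaneously in contact
#' with the promoter is that structure's interaction network; networks are
#' cataloged with their occurrence fractions over the ensemble. The empty
#' subset is a valid network. The number of distinct networks N is bounded
#' by `min(2^q, n_structures)` for q partners.
#'
#' @param ensemble a `structure_ensemble`.
#' @param promoter_bead 0-based promoter bead.
#' @param partners 0-based partner beads.
#' @param threshold contact threshold in sigma (strict `<`).
#' @param include_empty count structures with no partner contact as the
#'   empty network (default `TRUE`).
#' @return an object of class `network_catalog`: data.frame with `network`
#'   (comma-separated sorted partner beads, `""` for the empty subset),
#'   `count` and `fraction`; attributes `q` and `n_structures`.
#' @export
enumerate_networks <- function(ensemble, promoter_bead, partners,
                               threshold = 3.5, include_empty = TRUE) {
  if (!length(ensemble$frames)) stop("empty ensemble")
  box <- ensemble$box
  partners <- sort(partners)
  keys <- vapply(ensemble$frames, function(p) {
    if (!length(partners)) return("")
    d <- sweep(p[partners + 1, , drop = FALSE], 2, p[promoter_bead + 1, ])
    if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    paste(partners[sqrt(rowSums(d * d)) < threshold], collapse = ",")
  }, character(1))
  if (!include_empty) keys <- keys[keys != ""]
  tab <- table(keys)
  cat_df <- data.frame(network = names(tab), count = as.integer(tab),
                       fraction = as.integer(tab) / sum(tab),
                       stringsAsFactors = FALSE)
  cat_df <- cat_df[order(-cat_df$count), , drop = FALSE]
  rownames(cat_df) <- NULL
  structure(cat_df, q = length(partners), n_structures = length(keys),
            class = c("network_catalog", "data.frame"))
}

#' Structural diversity of a topos
#'
#' Shannon entropy of the network occurrence distribution normalized by the
#' number of partners plus one:
#' \deqn{H = \frac{S}{q+1} = \frac{1}{q+1}\sum_{i=1}^{N} -n_i \ln n_i.}
#' The +1 keeps H well-defined for promoters with no partners (q = 0,
#' single empty network, H = 0). Since the maximum S is ln N and N is at
#' most 2^q, S scales like q ln 2, which the normalization removes.
#'
#' @param catalog a `network_catalog` (or data.frame with a `fraction`
#'   column).
#' @param q number of partners; defaults to the catalog's `q` attribute.
#' @return H (dimensionless).
#' @export
diversity_score <- function(catalog, q = attr(catalog, "q")) {
  ni <- catalog$fraction
  if (abs(sum(ni) - 1) > 1e-9) stop("network fractions must sum to 1")
  if (is.null(q)) stop("q (number of partners) required")
  s <- sum(-ni * log(ni))
  s / (q + 1)
}

#' Full per-promoter topos report
#'
#' Assembles contact frequencies over the fragment's ATAC beads, the
#' partner and influential sets, the topos extent, the network catalog and
#' the diversity score for one promoter.
#'
#' @param ensemble a `structure_ensemble` whose track carries ATAC flags.
#' @param promoter_bead 0-based promoter bead (must be on the fragment).
#' @param gene gene label.
#' @param contact_threshold contact distance in sigma.
#' @param partner_threshold,influential_threshold frequency thresholds.
#' @return an object of class `topos_report`.
#' @export
topos_report <- function(ensemble, promoter_bead, gene = NA_character_,
                         contact_threshold = 3.5, partner_threshold = 0.10,
                         influential_threshold = 0.50) {
  track <- ensemble$track
  if (is.null(track)) stop("ensemble carries no bead track")
  fragment <- attr(track, "fragment")
  candidates <- setdiff(track$bead[track$atac], promoter_bead)
  freq <- contact_frequency(ensemble, promoter_bead, candidates,
                            contact_threshold)
  partners <- call_partners(freq, partner_threshold)
  influential <- call_influential(freq, influential_threshold)
  catalog <- enumerate_networks(ensemble, promoter_bead, partners,
                                contact_threshold)
  structure(list(gene = gene, promoter_bead = promoter_bead,
                 frequencies = freq, partners = partners,
                 influential = influential, q = length(partners),
                 extent = topos_extent(promoter_bead, partners, fragment),
                 catalog = catalog,
                 diversity = diversity_score(catalog, length(partners)),
                 thresholds = c(contact = contact_threshold,
                                partner = partner_threshold,
                                influential = influential_threshold)),
            class = "topos_report")
}

#' @export
print.topos_report <- function(x, ...) {
  cat(sprintf("topos report for %s (promoter bead %d):\n", x$gene,
              x$promoter_bead))
  cat(sprintf("  q = %d partner(s), %d influential node(s)\n", x$q,
              length(x$influential)))
  cat(sprintf("  extent %.0f kbp; N = %d network(s); diversity H = %.4f\n",
              x$extent$size_kbp, nrow(x$catalog), x$diversity))
  invisible(x)
}

#' Correlation of diversity with the influential-node share
#'
#' Spearman correlation between the diversity H and the percentage of
#' partners that are influential, over reports with at least one
#' influential node and not all partners influential, overall and within
#' partner-count bins.
#'
#' @param reports list of [topos_report()]s (>= 10 qualifying).
#' @param bins partner-count bin breaks for the per-bin correlations.
#' @return list with `overall` (rho, p, n, plus a `degenerate` flag when
#'   the correlation is undefined), `by_bin` data.frame, and the filtered
#'   input table.
#' @export
diversity_vs_influential <- function(reports, bins = c(0, 2, 5, 10, Inf)) {
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(gene = r$gene, q = r$q, n_influential = length(r$influential),
               H = r$diversity, stringsAsFactors = FALSE)))
  tab <- tab[tab$n_influential >= 1 & tab$n_influential < tab$q, , drop = FALSE]
  if (nrow(tab) < 10)
    stop("fewer than 10 qualifying reports (>=1 influential, not all influential)")
  tab$pct_influential <- 100 * tab$n_influential / tab$q
  overall <- .spearman_or_degenerate(tab$H, tab$pct_influential)
  tab$bin <- cut(tab$q, breaks = bins)
  by_bin <- do.call(rbind, lapply(split(tab, tab$bin, drop = TRUE), function(d) {
    s <- .spearman_or_degenerate(d$H, d$pct_influential)
    data.frame(bin = as.character(d$bin[1]), n = nrow(d), rho = s$rho,
               p = s$p, degenerate = s$degenerate)
  }))
  rownames(by_bin) <- NULL
  list(overall = c(overall, n = nrow(tab)), by_bin = by_bin, table = tab)
}

.spearman_or_degenerate <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Export topos reports as JSON + genome-wide TSV + BED extents
#'
#' Writes one JSON per promoter, a summary TSV (gene, q, influential count,
#' extent, N, H) and a BED file of topos extents.
#'
#' @param reports list of [topos_report()]s.
#' @param fragment the [genome_fragment()].
#' @param dir output directory.
#' @return invisibly, the summary TSV path.
#' @export
export_topos_reports <- function(reports, fragment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- do.call(rbind, lapply(reports, function(r) {
    jsonlite::write_json(
      list(gene = r$gene, promoter_bead = r$promoter_bead,
           partners = r$partners, influential = r$influential, q = r$q,
           extent = r$extent, diversity = r$diversity,
           networks = as.data.frame(r$catalog),
           thresholds = as.list(r$thresholds)),
      file.path(dir, sprintf("topos_%s.json", r$gene)),
      auto_unbox = TRUE, digits = NA)
    data.frame(gene = r$gene, q = r$q, n_influential = length(r$influential),
               extent_kbp = r$extent$size_kbp, n_networks = nrow(r$catalog),
               H = r$diversity)
  }))
  tsv <- file.path(dir, "topos_summary.tsv")
  utils::write.table(summ, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- vapply(reports, function(r)
    sprintf("%s\t%d\t%d\t%s", fragment$chrom, as.integer(r$extent$start),
            as.integer(r$extent$end), r$gene), character(1))
  writeLines(bed, file.path(dir, "topos_extents.bed"))
  invisible(tsv)
}
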