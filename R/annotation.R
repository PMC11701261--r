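#' Genome fragment to simulate
#'
#' A contiguous fragment of one chromosome, discretized on a fixed 1 kbp bead
#' grid. Coordinates are 0-based half-open (BED convention) throughout; bead
#' `i` (0-based) covers `[start + 1000*i, start + 1000*(i+1)) ∩ [start, end)`.
#'
#' @param chrom chromosome name.
#' @param start,end fragment limits in bp (0-based half-open).
#' @return an object of class `genome_fragment`.
#' @export
genome_fragment <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1, end > start)
  n_beads <- as.integer(ceiling((end - start) / 1000))
  if (n_beads < 10) stop("fragment too small: need at least 10 beads (10 kbp)")
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), n_beads = n_beads),
            class = "genome_fragment")
}

#' @export
print.genome_fragment <- function(x, ...) {
  cat(sprintf("genome fragment %s:%d-%d (%d beads of 1 kbp)\n",
              x$chrom, x$start, x$end, x$n_beads))
  invisible(x)
}

#' Bead index of a genomic coordinate
#' @param fragment a [genome_fragment()].
#' @param bp position(s) in bp within the fragment.
#' @return 0-based bead index (vectorized).
#' @export
bead_of <- function(fragment, bp) {
  if (any(bp < fragment$start | bp >= fragment$end))
    stop("coordinate outside the fragment")
  as.integer(floor((bp - fragment$start) / 1000))
}

#' Genomic interval covered by a bead
#' @param fragment a [genome_fragment()].
#' @param bead 0-based bead index (vectorized).
#' @return data.frame with 0-based half-open `start`, `end` columns.
#' @export
interval_of <- function(fragment, bead) {
  if (any(bead < 0 | bead >= fragment$n_beads)) stop("bead index out of range")
  data.frame(start = fragment$start + 1000 * bead,
             end = pmin(fragment$start + 1000 * (bead + 1), fragment$end))
}

#' Parse a peak interval file (BED or narrowPeak)
#'
#' Reads BED3+/BED6 or ENCODE 10-column narrowPeak. Records are returned
#' sorted by (chrom, start); for narrowPeak the `signalValue` column is used
#' as the peak score. Comment, `track` and `browser` lines are skipped.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `score`,
#'   `strand` (and narrowPeak extras when present).
#' @export
parse_peak_file <- function(path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (dialect == "narrowPeak") 10L else 3L
  bad <- which(nf < minf)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields",
                 dialect, idx[bad[1]], path, minf))
  get <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_,
                            character(1))
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: bad interval coordinates",
                 dialect, idx[bad[1]], path))
  if (dialect == "narrowPeak") {
    score <- suppressWarnings(as.numeric(get(7)))  # signalValue
    if (anyNA(score))
      stop(sprintf("malformed narrowPeak line %d in %s: bad signalValue",
                   idx[which(is.na(score))[1]], path))
    out <- data.frame(chrom = chrom, start = start, end = end, score = score,
                      strand = get(6), name = get(4),
                      pValue = suppressWarnings(as.numeric(get(8))),
                      qValue = suppressWarnings(as.numeric(get(9))),
                      peak = suppressWarnings(as.numeric(get(10))),
                      stringsAsFactors = FALSE)
  } else {
    score <- suppressWarnings(as.numeric(get(5)))
    score[is.na(score)] <- 0
    strand <- get(6); strand[is.na(strand)] <- "."
    out <- data.frame(chrom = chrom, start = start, end = end, score = score,
                      strand = strand, stringsAsFactors = FALSE)
  }
  if (any(out$score < 0)) stop("negative peak score in ", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# beads (0-based) overlapping >= 1 bp of each peak; via IRanges on the bead grid
.overlapping_beads <- function(fragment, peaks) {
  if (!nrow(peaks)) return(integer())
  peaks <- peaks[peaks$chrom == fragment$chrom &
                 peaks$end > fragment$start & peaks$start < fragment$end, ,
                 drop = FALSE]
  if (!nrow(peaks)) return(integer())
  grid <- interval_of(fragment, 0:(fragment$n_beads - 1))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(peaks$start + 1, peaks$end),        # 0-based half-open -> 1-based closed
    IRanges::IRanges(grid$start + 1, grid$end))
  sort(unique(S4Vectors::subjectHits(hits) - 1L))
}

#' Annotate chromatin marks on a fragment's beads
#'
#' A bead carries a mark iff its 1 kbp interval overlaps at least 1 bp of a
#' peak of the corresponding assay. The H3K27ac flag additionally controls
#' where crumple springs are omitted downstream.
#'
#' @param fragment a [genome_fragment()].
#' @param peaks_by_assay named list of peak data.frames (from
#'   [parse_peak_file()]); names must be among
#'   `"atac"`, `"h3k27ac"`, `"h3k27me3"`, `"h3k9me3"`.
#' @return an object of class `bead_track`: data.frame with 0-based `bead`
#'   and one logical column per mark, plus a `promoter` flag column and
#'   attributes `fragment`, `ctcf` (filled by [call_ctcf_beads()] /
#'   [annotate_promoters()]).
#' @export
annotate_marks <- function(fragment, peaks_by_assay = list()) {
  known <- chromatin_marks()
  if (length(peaks_by_assay) && !all(names(peaks_by_assay) %in% known))
    stop("unknown assay label: ",
         paste(setdiff(names(peaks_by_assay), known), collapse = ", "))
  n <- fragment$n_beads
  track <- data.frame(bead = 0:(n - 1))
  for (m in known) {
    flag <- logical(n)
    if (m %in% names(peaks_by_assay)) {
      b <- .overlapping_beads(fragment, peaks_by_assay[[m]])
      flag[b + 1] <- TRUE
    }
    track[[m]] <- flag
  }
  track$promoter <- FALSE
  structure(track, fragment = fragment,
            ctcf = data.frame(bead = integer(), orientation = character(),
                              prob = numeric(), stringsAsFactors = FALSE),
            promoters = data.frame(gene = character(), bead = integer(),
                                   stringsAsFactors = FALSE),
            class = c("bead_track", "data.frame"))
}

#' @export
print.bead_track <- function(x, ...) {
  fr <- attr(x, "fragment")
  cat(sprintf("bead track for %s:%d-%d (%d beads)\n", fr$chrom, fr$start,
              fr$end, fr$n_beads))
  for (m in chromatin_marks())
    cat(sprintf("  %-9s %d beads\n", m, sum(x[[m]])))
  cat(sprintf("  promoters %d; CTCF beads %d\n", sum(x$promoter),
              length(unique(attr(x, "ctcf")$bead))))
  invisible(x)
}

#' Call CTCF boundary beads with orientation and activation probability
#'
#' A bead becomes a CTCF boundary candidate iff it overlaps a CTCF peak that
#' (a) overlaps a RAD21 peak (cohesin co-occupancy) and (b) contains at
#' least one binding-motif hit. Orientation comes from the best-scoring
#' motif; when the best hits on opposite strands score within
#' `tie_fraction` of the larger the site is bidirectional. Each peak's
#' activation probability is linearly proportional to its score,
#' `p = min(1, score / max score)` over the qualifying peaks of the
#' fragment. When several peaks share a bead, all activation outcomes are
#' enumerated (each peak independently active with its own probability;
#' simultaneously active opposite orientations combine to bidirectional) and
#' the resulting outcome distribution is stored.
#'
#' @param track a [annotate_marks()] bead track (returned updated).
#' @param ctcf_peaks,rad21_peaks peak data.frames.
#' @param motif_hits data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`), `score`, `peak_id` (row index into `ctcf_peaks`
#'   after sorting, or matching a `name` column).
#' @param tie_fraction bidirectional tie window as a fraction of the larger
#'   motif score (default 0.10).
#' @return the track with its `ctcf` attribute set: data.frame
#'   `(bead, orientation, prob)` with per-bead outcome probabilities summing
#'   to <= 1 (the remainder is the inactive outcome).
#' @export
call_ctcf_beads <- function(track, ctcf_peaks, rad21_peaks, motif_hits,
                            tie_fraction = 0.10) {
  fragment <- attr(track, "fragment")
  pk <- ctcf_peaks[ctcf_peaks$chrom == fragment$chrom &
                   ctcf_peaks$end > fragment$start &
                   ctcf_peaks$start < fragment$end, , drop = FALSE]
  if (!nrow(pk)) { attr(track, "ctcf") <- .empty_ctcf(); return(track) }
  pk$peak_id <- if ("name" %in% names(pk) && !anyNA(pk$name)) pk$name else
    sprintf("ctcf_peak_%d", seq_len(nrow(pk)))

  # (a) RAD21 co-occupancy
  has_rad21 <- rep(FALSE, nrow(pk))
  if (nrow(rad21_peaks)) {
    r <- rad21_peaks[rad21_peaks$chrom == fragment$chrom, , drop = FALSE]
    if (nrow(r)) {
      hits <- IRanges::findOverlaps(IRanges::IRanges(pk$start + 1, pk$end),
                                    IRanges::IRanges(r$start + 1, r$end))
      has_rad21[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }

  # (b) motif support + orientation per peak
  orient <- rep(NA_character_, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    mh <- motif_hits[motif_hits$peak_id == pk$peak_id[i], , drop = FALSE]
    if (!nrow(mh)) next
    inside <- mh$start >= pk$start[i] & mh$end <= pk$end[i]
    if (any(!inside)) {
      warning(sprintf("motif hit outside its peak %s; skipped", pk$peak_id[i]))
      mh <- mh[inside, , drop = FALSE]
    }
    if (!nrow(mh)) next
    best_fwd <- suppressWarnings(max(mh$score[mh$strand == "+"], -Inf))
    best_bwd <- suppressWarnings(max(mh$score[mh$strand == "-"], -Inf))
    top <- max(best_fwd, best_bwd)
    if (!is.finite(top)) next
    if (is.finite(best_fwd) && is.finite(best_bwd) &&
        abs(best_fwd - best_bwd) < tie_fraction * top) {
      orient[i] <- "bidirectional"
    } else {
      orient[i] <- if (best_fwd >= best_bwd) "forward" else "backward"
    }
  }

  ok <- has_rad21 & !is.na(orient)
  pk <- pk[ok, , drop = FALSE]; orient <- orient[ok]
  if (!nrow(pk)) { attr(track, "ctcf") <- .empty_ctcf(); return(track) }
  pk$prob <- pmin(1, pk$score / max(pk$score))
  pk$orientation <- orient

  out <- list()
  for (i in seq_len(nrow(pk))) {
    beads <- .overlapping_beads(fragment, pk[i, , drop = FALSE])
    for (b in beads)
      out[[length(out) + 1]] <- data.frame(bead = b,
                                           orientation = pk$orientation[i],
                                           prob = pk$prob[i])
  }
  per_peak <- do.call(rbind, out)
  # enumerate outcomes per bead over its peaks
  res <- lapply(split(per_peak, per_peak$bead), .enumerate_ctcf_outcomes)
  ctcf <- do.call(rbind, res)
  rownames(ctcf) <- NULL
  attr(track, "ctcf") <- ctcf
  track
}

.empty_ctcf <- function() data.frame(bead = integer(), orientation = character(),
                                     prob = numeric(), stringsAsFactors = FALSE)

# All 2^k activation patterns of the peaks in one bead; active orientations
# union to bidirectional when mixed. Returns non-inactive outcomes only.
.enumerate_ctcf_outcomes <- function(peaks) {
  k <- nrow(peaks)
  acc <- c(forward = 0, backward = 0, bidirectional = 0)
  for (pattern in 0:(2^k - 1)) {
    on <- bitwAnd(pattern, 2^(seq_len(k) - 1)) > 0
    p <- prod(ifelse(on, peaks$prob, 1 - peaks$prob))
    if (!any(on) || p == 0) next
    ors <- unique(peaks$orientation[on])
    label <- if ("bidirectional" %in% ors || length(setdiff(ors, "bidirectional")) > 1)
      "bidirectional" else ors
    acc[label] <- acc[label] + p
  }
  acc <- acc[acc > 0]
  data.frame(bead = peaks$bead[1], orientation = names(acc), prob = as.numeric(acc),
             stringsAsFactors = FALSE)
}

#' Sample a per-run CTCF boundary activation
#'
#' Each CTCF bead independently samples one outcome from its orientation
#' distribution (the remainder being inactive), mimicking cell-to-cell
#' variability in CTCF binding.
#'
#' @param track a bead track with CTCF records.
#' @param seed integer seed (deterministic boundary set under a fixed seed).
#' @return data.frame `(bead, orientation)` of active boundaries.
#' @export
sample_ctcf_activation <- function(track, seed = NULL) {
  ctcf <- attr(track, "ctcf")
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(ctcf))
    return(data.frame(bead = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  res <- lapply(split(ctcf, ctcf$bead), function(d) {
    stopifnot(sum(d$prob) <= 1 + 1e-9)
    u <- stats::runif(1)
    cum <- cumsum(d$prob)
    hit <- which(u < cum)
    if (!length(hit)) return(NULL)  # inactive this run
    data.frame(bead = d$bead[1], orientation = d$orientation[hit[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(bead = integer(), orientation = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign promoter beads
#'
#' One promoter bead per gene: the bead containing the midpoint of the
#' provided promoter interval. Genes whose promoter lies outside the
#' fragment are dropped with a warning.
#'
#' @param track a bead track.
#' @param promoter_intervals data.frame with columns `chrom`, `start`,
#'   `end`, `gene`.
#' @return the track, with the `promoter` flag set and a `promoters`
#'   attribute data.frame `(gene, bead)`.
#' @export
annotate_promoters <- function(track, promoter_intervals) {
  fragment <- attr(track, "fragment")
  pr <- promoter_intervals
  if (anyDuplicated(pr$gene))
    stop("duplicate gene id in promoter intervals: ",
         pr$gene[duplicated(pr$gene)][1])
  mid <- floor((pr$start + pr$end) / 2)
  inside <- pr$chrom == fragment$chrom & mid >= fragment$start & mid < fragment$end
  if (any(!inside))
    warning(sum(!inside), " promoter(s) outside the fragment dropped: ",
            paste(pr$gene[!inside], collapse = ", "))
  pr <- pr[inside, , drop = FALSE]; mid <- mid[inside]
  beads <- if (nrow(pr)) bead_of(fragment, mid) else integer()
  track$promoter[beads + 1] <- TRUE
  attr(track, "promoters") <- data.frame(gene = pr$gene, bead = beads,
                                         stringsAsFactors = FALSE)
  track
}

#' Export a bead track as per-mark BED files
#'
#' Writes one BED file per mark (bead intervals carrying the flag) plus a
#' JSON sidecar with annotation provenance. Re-annotating from these files
#' reproduces the track exactly.
#'
#' @param track a bead track.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written file paths.
#' @export
export_track_bed <- function(track, dir, prefix = "track") {
  fragment <- attr(track, "fragment")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (m in chromatin_marks()) {
    beads <- track$bead[track[[m]]]
    iv <- if (length(beads)) interval_of(fragment, beads) else
      data.frame(start = numeric(), end = numeric())
    p <- file.path(dir, sprintf("%s_%s.bed", prefix, m))
    writeLines(if (nrow(iv))
      sprintf("%s\t%d\t%d", fragment$chrom, as.integer(iv$start),
              as.integer(iv$end)) else character(), p)
    paths[m] <- p
  }
  sidecar <- file.path(dir, sprintf("%s_provenance.json", prefix))
  jsonlite::write_json(list(fragment = unclass(fragment),
                            overlap_rule = ">=1bp",
                            coordinates = "0-based half-open",
                            files = as.list(paths)),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  paths["provenance"] <- sidecar
  invisible(paths)
}
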