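#' Contact map container
#'
#' A symmetric binned read-count (or balanced) matrix with resolution and
#' normalization metadata.
#'
#' @param counts symmetric non-negative matrix.
#' @param bin_kbp bin size in kbp.
#' @param fragment optional [genome_fragment()].
#' @param total_reads total read count represented.
#' @param normalization `"raw"` or `"ICE"`.
#' @param mask logical vector of masked (zero-marginal) bins, or `NULL`.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(counts, bin_kbp = 1, fragment = NULL,
                        total_reads = sum(counts) / 2 + sum(diag(counts)) / 2,
                        normalization = "raw", mask = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  if (any(counts < 0)) stop("contact map counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-9 * max(1, max(counts)))
    stop("contact map must be symmetric")
  structure(list(counts = counts, bin_kbp = bin_kbp, fragment = fragment,
                 total_reads = total_reads, normalization = normalization,
                 mask = mask),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact map: %d x %d bins at %g kbp, %s, ~%.3g reads\n",
              nrow(x$counts), ncol(x$counts), x$bin_kbp, x$normalization,
              x$total_reads))
  invisible(x)
}

#' Sample in-silico sequencing reads from a structure ensemble
#'
#' Emulates the crosslinking step of Hi-C/Micro-C: repeatedly pick a
#' structure and a uniformly random bead pair (i, j), compute their
#' minimum-image separation r, and accept the pair as a read with
#' probability \eqn{p = \exp(-r/r_t)}. Accepted reads are accumulated
#' symmetrically into a 1 kbp (= 1 bead) matrix. Self-pairs are excluded;
#' adjacent pairs are retained. The distance threshold `rt` defaults to
#' 3.5 sigma (Hi-C-like); 1.5 sigma gives a Micro-C-like map.
#'
#' @param ensemble a `structure_ensemble`.
#' @param n_reads target number of accepted reads.
#' @param rt crosslinking distance threshold in sigma.
#' @param seed RNG seed.
#' @return a raw [contact_map()] at 1 kbp resolution; its
#'   `acceptance_rate` attribute records accepted/attempted trials.
#' @export
sample_reads <- function(ensemble, n_reads, rt = 3.5, seed = NULL) {
  if (!length(ensemble$frames)) stop("empty ensemble")
  stopifnot(rt > 0, n_reads >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ensemble$frames[[1]])
  box <- ensemble$box
  counts <- matrix(0, n, n)
  accepted <- 0; attempted <- 0; accepted_raw <- 0
  batch <- max(10000, min(5e5, ceiling(n_reads * 3)))
  while (accepted < n_reads) {
    s <- sample.int(length(ensemble$frames), batch, replace = TRUE)
    i <- sample.int(n, batch, replace = TRUE)
    j <- sample.int(n, batch, replace = TRUE)
    ok <- i != j
    s <- s[ok]; i <- i[ok]; j <- j[ok]
    attempted <- attempted + length(i)
    d <- vapply(seq_along(i), function(k) {
      dv <- ensemble$frames[[s[k]]][i[k], ] - ensemble$frames[[s[k]]][j[k], ]
      if (!is.null(box)) dv <- dv - box * round(dv / box)
      sqrt(sum(dv * dv))
    }, numeric(1))
    acc <- stats::runif(length(d)) < exp(-d / rt)
    i <- i[acc]; j <- j[acc]
    accepted_raw <- accepted_raw + length(i)
    accepted_now <- length(i)
    if (accepted + accepted_now > n_reads) {
      keep <- seq_len(n_reads - accepted)
      i <- i[keep]; j <- j[keep]
      accepted_now <- length(i)
    }
    for (k in seq_along(i)) {
      counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
      counts[j[k], i[k]] <- counts[j[k], i[k]] + 1
    }
    accepted <- accepted + accepted_now
  }
  m <- contact_map(counts, bin_kbp = 1,
                   fragment = if (!is.null(ensemble$track))
                     attr(ensemble$track, "fragment") else NULL,
                   total_reads = accepted)
  attr(m, "acceptance_rate") <- accepted_raw / attempted
  m
}

#' Re-bin a contact map to a coarser resolution
#'
#' Block-sum aggregation; total reads are conserved exactly. The target bin
#' size must be a multiple of the source bin size.
#'
#' @param map a [contact_map()].
#' @param target_kbp target bin size in kbp.
#' @return a re-binned [contact_map()].
#' @export
bin_map <- function(map, target_kbp) {
  f <- target_kbp / map$bin_kbp
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target bin size must be a positive multiple of the source bin size")
  f <- as.integer(round(f))
  if (f == 1L) return(map)
  n <- nrow(map$counts)
  groups <- (seq_len(n) - 1L) %/% f
  agg <- rowsum(t(rowsum(map$counts, groups)), groups)
  contact_map(as.matrix(agg), bin_kbp = target_kbp, fragment = map$fragment,
              total_reads = map$total_reads,
              normalization = map$normalization)
}

#' Iterative correction (ICE) balancing of a contact map
#'
#' Iteratively divides rows and columns by their marginals until all
#' non-masked marginals are equal (coefficient of variation below `tol`).
#' Bins with zero marginal are masked before balancing and reported in the
#' result.
#'
#' @param map a raw [contact_map()].
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the marginal coefficient of
#'   variation.
#' @return the balanced [contact_map()] (normalization `"ICE"`), with
#'   masked bins recorded in `$mask`.
#' @export
ice_normalize <- function(map, max_iter = 200, tol = 1e-8) {
  w <- map$counts
  mask <- rowSums(w) == 0
  active <- !mask
  for (iter in seq_len(max_iter)) {
    s <- rowSums(w[active, active, drop = FALSE])
    s <- s / mean(s)
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0
    if (cv < tol) {
      out <- contact_map(w, bin_kbp = map$bin_kbp, fragment = map$fragment,
                         total_reads = map$total_reads, normalization = "ICE",
                         mask = mask)
      return(out)
    }
    w[active, active] <- w[active, active, drop = FALSE] / outer(s, s)
  }
  stop(sprintf("ICE did not converge in %d iterations (residual CV %.3g)",
               max_iter, cv))
}

# upper-triangle values of jointly unmasked bins, optionally excluding a
# near-diagonal band |i-j| < band (in bins)
.map_pair_values <- function(a, b, band = 0) {
  stopifnot(all(dim(a$counts) == dim(b$counts)), a$bin_kbp == b$bin_kbp)
  n <- nrow(a$counts)
  keep_bin <- rep(TRUE, n)
  if (!is.null(a$mask)) keep_bin <- keep_bin & !a$mask
  if (!is.null(b$mask)) keep_bin <- keep_bin & !b$mask
  idx <- which(upper.tri(a$counts), arr.ind = TRUE)
  sel <- keep_bin[idx[, 1]] & keep_bin[idx[, 2]] &
    (idx[, 2] - idx[, 1]) >= band
  cbind(a$counts[idx[sel, , drop = FALSE]], b$counts[idx[sel, , drop = FALSE]])
}

#' Pearson correlation between two contact maps
#'
#' Correlates the vectorized upper triangles of jointly non-masked bins,
#' optionally excluding a near-diagonal band.
#'
#' @param map_a,map_b [contact_map()]s with identical shape and binning.
#' @param band exclude pairs with bin distance |i-j| below this (bins;
#'   default 0 = none).
#' @return list with `r`, `p` and `n` (number of paired bins).
#' @export
map_correlation <- function(map_a, map_b, band = 0) {
  v <- .map_pair_values(map_a, map_b, band)
  if (nrow(v) < 3) stop("fewer than 3 paired bins")
  ct <- stats::cor.test(v[, 1], v[, 2], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(v))
}

#' Directionality score profile of a contact map
#'
#' For each bin i, sums the contacts to bins within a genomic window on the
#' left of i and subtracts the contacts within the same window on the
#' right: \deqn{D(i) = \sum_{j=i-u}^{i-l} c_{ij} - \sum_{j=i+l}^{i+u} c_{ij}}
#' with the lower threshold l = 20 kbp (to avoid near-diagonal artifacts)
#' and upper threshold u = 500 kbp. Because both sides aggregate up to the
#' same genomic distance the strong distance dependence of contact
#' frequency cancels. Windows truncated by the fragment edge are flagged.
#'
#' @param map a [contact_map()].
#' @param lower,upper window thresholds in kbp.
#' @return numeric vector `D` with a logical `edge` attribute flagging bins
#'   whose window was truncated.
#' @export
directionality_score <- function(map, lower = 20, upper = 500) {
  stopifnot(upper > lower, lower >= map$bin_kbp)
  n <- nrow(map$counts)
  lb <- as.integer(round(lower / map$bin_kbp))
  ub <- as.integer(round(upper / map$bin_kbp))
  if (n * map$bin_kbp < 2 * lower)
    stop("fragment shorter than twice the lower threshold")
  d <- numeric(n)
  edge <- logical(n)
  for (i in seq_len(n)) {
    lo_l <- max(1, i - ub); hi_l <- i - lb
    lo_r <- i + lb; hi_r <- min(n, i + ub)
    left <- if (hi_l >= lo_l) sum(map$counts[i, lo_l:hi_l]) else 0
    right <- if (hi_r >= lo_r) sum(map$counts[i, lo_r:hi_r]) else 0
    d[i] <- left - right
    edge[i] <- (i - ub < 1) || (i + ub > n)
  }
  attr(d, "edge") <- edge
  d
}

#' Pearson correlation of directionality-score profiles
#'
#' The D profiles of the two maps are computed with identical windows and
#' correlated over bins whose windows are untruncated in both maps.
#'
#' @inheritParams map_correlation
#' @param lower,upper window thresholds in kbp.
#' @return list with `r`, `p` and `n`.
#' @export
directionality_correlation <- function(map_a, map_b, lower = 20, upper = 500) {
  da <- directionality_score(map_a, lower, upper)
  db <- directionality_score(map_b, lower, upper)
  keep <- !(attr(da, "edge") | attr(db, "edge"))
  if (!is.null(map_a$mask)) keep <- keep & !map_a$mask
  if (!is.null(map_b$mask)) keep <- keep & !map_b$mask
  if (sum(keep) < 3) stop("fewer than 3 untruncated bins")
  ct <- stats::cor.test(da[keep], db[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Write / read a contact map as dense TSV
#'
#' The header line carries the bin size, normalization and total reads so a
#' round trip preserves the metadata.
#'
#' @param map a [contact_map()].
#' @param path file path.
#' @return `write_contact_map`: the path, invisibly. `read_contact_map`:
#'   the [contact_map()].
#' @export
write_contact_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_kbp=%g normalization=%s total_reads=%g",
                     map$bin_kbp, map$normalization, map$total_reads), con)
  utils::write.table(map$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  header <- readLines(path, n = 1)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  counts <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(counts) <- NULL
  contact_map(counts, bin_kbp = as.numeric(meta[["bin_kbp"]]),
              total_reads = as.numeric(meta[["total_reads"]]),
              normalization = meta[["normalization"]])
}
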