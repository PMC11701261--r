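#' Two-colour FISH probe pair
#'
#' Two non-overlapping genomic intervals on the fragment; the position of a
#' probe in a structure is the centre of mass of the beads it covers.
#'
#' @param fragment a [genome_fragment()].
#' @param interval_a,interval_b numeric length-2 vectors `(start, end)` in
#'   bp (0-based half-open).
#' @param label optional label.
#' @return an object of class `probe_pair` with the derived bead lists.
#' @export
probe_pair <- function(fragment, interval_a, interval_b, label = "probe_pair") {
  mk <- function(iv) {
    if (iv[1] < fragment$start || iv[2] > fragment$end || iv[2] <= iv[1])
      stop("probe interval outside the fragment")
    bead_of(fragment, seq(iv[1], iv[2] - 1, by = 1000))
  }
  beads_a <- unique(mk(interval_a))
  beads_b <- unique(mk(interval_b))
  if (interval_a[2] > interval_b[1] && interval_b[2] > interval_a[1])
    stop("probe intervals must not overlap")
  structure(list(beads_a = beads_a, beads_b = beads_b, label = label,
                 interval_a = interval_a, interval_b = interval_b),
            class = "probe_pair")
}

#' Probe separation in one structure
#'
#' Euclidean distance between the centres of mass of the two probes' beads,
#' computed on unwrapped coordinates (the trajectory never folds positions
#' into the box, so probes straddling a box face do not produce spurious
#' centres).
#'
#' @param structure an n x 3 coordinate matrix (sigma).
#' @param pair a [probe_pair()].
#' @return distance in sigma.
#' @export
probe_separation <- function(structure, pair) {
  if (max(pair$beads_a, pair$beads_b) >= nrow(structure))
    stop("probe beads outside the structure")
  com_a <- colMeans(structure[pair$beads_a + 1, , drop = FALSE])
  com_b <- colMeans(structure[pair$beads_b + 1, , drop = FALSE])
  sqrt(sum((com_a - com_b)^2))
}

#' Probe separation distribution across an ensemble
#'
#' One centre-of-mass separation per structure, in sigma.
#'
#' @param ensemble a `structure_ensemble`.
#' @param pair a [probe_pair()].
#' @return numeric vector, one value per structure.
#' @export
separation_distribution <- function(ensemble, pair) {
  if (!length(ensemble$frames)) stop("empty ensemble")
  vapply(ensemble$frames, probe_separation, numeric(1), pair = pair)
}

#' Fit the physical bead size to an experimental FISH distribution
#'
#' Finds the value of sigma (in nm) that minimizes the two-sample
#' Kolmogorov-Smirnov distance between the simulated separations (in sigma)
#' rescaled by sigma and the experimental separations (in nm). The search
#' is a 0.5 nm grid over `bracket` followed by golden-section refinement.
#'
#' @param sim_sigma simulated separations in sigma (>= 10 values).
#' @param exp_nm experimental separations in nm (>= 10 values).
#' @param bracket search bracket in nm.
#' @return list with `sigma_nm`, `ks_stat`, `p` (two-sample KS p value at
#'   the optimum) and the sample sizes.
#' @export
fit_sigma_nm <- function(sim_sigma, exp_nm, bracket = c(10, 50)) {
  if (length(sim_sigma) < 10 || length(exp_nm) < 10)
    stop("need at least 10 values in each sample")
  if (stats::sd(exp_nm) == 0)
    stop("degenerate (zero-variance) experimental sample")
  ks_at <- function(s)
    suppressWarnings(stats::ks.test(sim_sigma * s, exp_nm)$statistic)
  grid <- seq(bracket[1], bracket[2], by = 0.5)
  stat <- vapply(grid, ks_at, numeric(1))
  best <- grid[which.min(stat)]
  lo <- max(bracket[1], best - 0.5)
  hi <- min(bracket[2], best + 0.5)
  opt <- stats::optimize(ks_at, c(lo, hi))
  sigma <- if (opt$objective <= min(stat)) opt$minimum else best
  kt <- suppressWarnings(stats::ks.test(sim_sigma * sigma, exp_nm))
  list(sigma_nm = sigma, ks_stat = unname(kt$statistic), p = kt$p.value,
       n_sim = length(sim_sigma), n_exp = length(exp_nm))
}

#' Median-centred separations normalized by the local bead size
#'
#' `(x - median(x)) / sigma` per value, so the output has median 0 and its
#' spread is expressed in units of the locally fitted bead size.
#'
#' @param x separations (any consistent unit).
#' @param sigma the fitted bead size in the same unit per sigma.
#' @return normalized values.
#' @export
normalized_separation <- function(x, sigma) {
  stopifnot(sigma > 0)
  (x - stats::median(x)) / sigma
}

#' Read an experimental FISH distance sample
#'
#' Accepts a single-column numeric text file, or a TSV whose first column
#' is a label and second column the distance in nm.
#'
#' @param path file path.
#' @return numeric vector of distances in nm.
#' @export
read_fish_distances <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  col <- if (ncol(tab) == 1) tab[[1]] else tab[[2]]
  x <- suppressWarnings(as.numeric(col))
  if (anyNA(x)) stop("non-numeric distance values in ", path)
  x
}
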