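# Inter-mutational distances and exact piecewise-constant fitting (Potts
# filter) used to call clustered rearrangements.

#' Inter-mutational distances of sorted breakpoints on one chromosome
#'
#' The inter-mutational distance (IMD) of a breakpoint is the distance to the
#' breakpoint immediately preceding it on the same chromosome. The first
#' breakpoint, which has no predecessor, takes the distance to its successor
#' so that it can join a cluster at the chromosome edge. A chromosome with a
#' single breakpoint contributes no defined IMD.
#'
#' @param positions Numeric vector of breakpoint positions (bp), sorted
#'   ascending.
#' @return Numeric vector the same length as \code{positions}: for n >= 2,
#'   \code{imd[1] == imd[2]} and \code{imd[i] == positions[i] -
#'   positions[i-1]} for i >= 2; for n == 1, \code{NA}.
#' @export
#' @examples
#' compute_imd(c(100, 300, 1300))  # 200 200 1000
compute_imd <- function(positions) {
  n <- length(positions)
  stopifnot(n >= 1, !is.unsorted(positions))
  if (n == 1) return(NA_real_)
  d <- diff(positions)
  c(d[1], d)
}

#' Exact piecewise-constant fit of an ordered series
#'
#' Partitions an ordered numeric series into contiguous segments minimizing
#' the penalized least-squares objective
#' \deqn{\sum_{s} \sum_{i \in s} (x_i - \bar{x}_s)^2 + \gamma \, k}
#' where the sum runs over the \eqn{k} segments and \eqn{\bar{x}_s} is the
#' segment mean. The global minimizer is found by dynamic programming over
#' cut points in O(n^2); ties are broken toward fewer segments. This is the
#' Potts-filter formulation used for rainfall-plot segmentation of
#' log-transformed inter-mutational distances.
#'
#' @param values Ordered numeric series (here, \code{log10(imd + 1)}).
#' @param gamma Positive penalty per segment.
#' @return A list of class \code{pcf_segmentation} with elements
#'   \code{starts} and \code{ends} (1-based segment index bounds),
#'   \code{means} (segment means of \code{values}), \code{objective}, and
#'   \code{gamma}.
#' @export
#' @examples
#' fit <- pcf_segment(c(0, 0, 0, 5, 5, 5), gamma = 0.5)
#' fit$starts  # 1 4
pcf_segment <- function(values, gamma) {
  n <- length(values)
  stopifnot(n >= 1, is.numeric(gamma), gamma > 0, all(is.finite(values)))
  # within-segment SSE via prefix sums: sse(i..j) = S2 - S^2/m
  cs  <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  sse <- function(i, j) {
    m <- j - i + 1
    s <- cs[j + 1] - cs[i]
    max(0, (cs2[j + 1] - cs2[i]) - s * s / m)
  }
  best  <- numeric(n + 1)   # best[j+1] = min objective for prefix of length j
  nseg  <- integer(n + 1)
  cut   <- integer(n + 1)   # start index of the last segment
  best[1] <- 0
  for (j in seq_len(n)) {
    b <- Inf; bs <- 0L; bc <- 0L
    for (i in seq_len(j)) {
      cand <- best[i] + sse(i, j) + gamma
      cseg <- nseg[i] + 1L
      if (cand < b - 1e-12 ||
          (abs(cand - b) <= 1e-12 && cseg < bs)) {
        b <- cand; bs <- cseg; bc <- i
      }
    }
    best[j + 1] <- b; nseg[j + 1] <- bs; cut[j + 1] <- bc
  }
  starts <- integer(0)
  j <- n
  while (j > 0) {
    starts <- c(cut[j + 1], starts)
    j <- cut[j + 1] - 1L
  }
  ends <- c(starts[-1] - 1L, n)
  means <- mapply(function(i, j) mean(values[i:j]), starts, ends)
  structure(list(starts = starts, ends = ends, means = means,
                 objective = best[n + 1], gamma = gamma),
            class = "pcf_segmentation")
}

#' @export
print.pcf_segmentation <- function(x, ...) {
  cat("Piecewise-constant fit:", length(x$starts), "segment(s), objective",
      format(x$objective, digits = 6), "(gamma =", x$gamma, ")\n")
  invisible(x)
}

# one sample's breakpoint table: both mates of every SV contribute a
# breakpoint to their own chromosome
.breakpoint_table <- function(records) {
  data.frame(
    record = rep(seq_len(nrow(records)), 2),
    chromosome = c(records$chrom1, records$chrom2),
    position = c(records$pos1, records$pos2),
    stringsAsFactors = FALSE
  )
}

#' Annotate structural variants as clustered or non-clustered
#'
#' Per sample, breakpoints are collected per chromosome (both mates of every
#' SV contribute one each), sorted, and their inter-mutational distances
#' (IMDs) computed. Each chromosome's \code{log10(imd + 1)} series is
#' segmented with [pcf_segment()]; a segment is clustered when its mean raw
#' IMD is at most the sample mean IMD (over all chromosomes jointly) divided
#' by \code{cluster_factor} AND it contains at least \code{min_cluster_bp}
#' breakpoints. An SV is clustered when either of its breakpoints lies in a
#' clustered segment.
#'
#' @inheritParams build_sv_matrix
#' @return Logical vector, one flag per row of \code{records}.
#' @export
annotate_clustered <- function(records, gamma = 25, cluster_factor = 10,
                               min_cluster_bp = 10) {
  stopifnot(nrow(records) > 0, gamma > 0, cluster_factor > 0,
            min_cluster_bp >= 1)
  clustered <- logical(nrow(records))
  for (s in unique(records$sample)) {
    rows <- which(records$sample == s)
    bp <- .breakpoint_table(records[rows, , drop = FALSE])
    bp$record <- rows[bp$record]

    # IMDs per chromosome, in sorted-position order
    per_chrom <- split(seq_len(nrow(bp)), bp$chromosome)
    imds <- vector("list", length(per_chrom))
    orders <- vector("list", length(per_chrom))
    for (k in seq_along(per_chrom)) {
      idx <- per_chrom[[k]]
      o <- idx[order(bp$position[idx])]
      orders[[k]] <- o
      imds[[k]] <- compute_imd(bp$position[o])
    }
    all_imd <- unlist(imds)
    all_imd <- all_imd[is.finite(all_imd)]
    if (length(all_imd) == 0) next  # < 2 breakpoints on every chromosome
    sample_mean_imd <- mean(all_imd)

    bp_clustered <- logical(nrow(bp))
    for (k in seq_along(per_chrom)) {
      o <- orders[[k]]
      imd <- imds[[k]]
      if (length(o) < 2) next
      fit <- pcf_segment(log10(imd + 1), gamma = gamma)
      for (g in seq_along(fit$starts)) {
        seg <- fit$starts[g]:fit$ends[g]
        if (length(seg) >= min_cluster_bp &&
            mean(imd[seg]) <= sample_mean_imd / cluster_factor) {
          bp_clustered[o[seg]] <- TRUE
        }
      }
    }
    hit <- unique(bp$record[bp_clustered])
    clustered[hit] <- TRUE
  }
  clustered
}
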