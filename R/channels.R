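# Canonical channel schemas for the 48-channel copy-number classification and
# the 32-channel structural-variant classification.

.CN_SIZE_BINS  <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
.CN_SIZE_EDGES <- c(0, 1e5, 1e6, 1e7, 4e7, Inf)
.HD_SIZE_BINS  <- c("0-100kb", "100kb-1Mb", ">1Mb")
.HD_SIZE_EDGES <- c(0, 1e5, 1e6, Inf)
.TCN_CLASSES   <- c("0", "1", "2", "3-4", "5-8", "9+")

.SV_SIZE_BINS  <- c("0-10kb", "10-100kb", "100kb-1Mb", "1Mb-10Mb", ">10Mb")
.SV_SIZE_EDGES <- c(0, 1e4, 1e5, 1e6, 1e7, Inf)
.SV_TYPES      <- c("del", "tds", "inv", "trans")

.CHROMS <- c(as.character(1:22), "X", "Y")

#' Canonical CNV channel labels
#'
#' The 48-channel copy-number schema partitions allele-specific segments by
#' heterozygosity state (homozygous deletion, loss of heterozygosity,
#' heterozygous), total copy number class, and segment size. Labels have the
#' form \code{"TCN:state:sizebin"}, e.g. \code{"2:LOH:>40Mb"} for copy-neutral
#' LOH of a segment larger than 40 Mb.
#'
#' Channel order is fixed: the homozygous-deletion block (3 channels), then
#' the LOH block (25 channels), then the heterozygous block (20 channels),
#' each ordered by total-copy-number class and then size bin.
#'
#' @return Character vector of the 48 canonical channel labels, in order.
#' @export
#' @examples
#' head(cnv48_channels())
cnv48_channels <- function() {
  homdel <- paste("0", "homdel", .HD_SIZE_BINS, sep = ":")
  loh <- as.vector(t(outer(c("1", "2", "3-4", "5-8", "9+"),
                           .CN_SIZE_BINS,
                           function(t, s) paste(t, "LOH", s, sep = ":"))))
  het <- as.vector(t(outer(c("2", "3-4", "5-8", "9+"),
                           .CN_SIZE_BINS,
                           function(t, s) paste(t, "het", s, sep = ":"))))
  c(homdel, loh, het)
}

#' Canonical SV channel labels
#'
#' The 32-channel structural-variant schema partitions rearrangements by
#' clustered status, event type (deletion, tandem duplication, inversion,
#' translocation), and size. Translocations are not size-binned. Labels have
#' the form \code{"clustered_del_0-10kb"} or \code{"non-clustered_trans"}.
#'
#' Channel order is fixed: the clustered block then the non-clustered block;
#' within each, deletions, tandem duplications and inversions by ascending
#' size bin, then translocations.
#'
#' @return Character vector of the 32 canonical channel labels, in order.
#' @export
#' @examples
#' sv32_channels()
sv32_channels <- function() {
  one_block <- function(prefix) {
    binned <- as.vector(t(outer(c("del", "tds", "inv"), .SV_SIZE_BINS,
                                function(ty, s) paste(prefix, ty, s, sep = "_"))))
    c(binned, paste(prefix, "trans", sep = "_"))
  }
  c(one_block("clustered"), one_block("non-clustered"))
}

#' Normalize a pair of allele copy numbers
#'
#' Rounds each allele copy number to the nearest integer (ties round half away
#' from zero, so 2.5 becomes 3) and orders the pair so that the major allele
#' comes first. Copy-number callers that fit fractional states (e.g. PURPLE,
#' Battenberg) are brought onto the integer grid the schema is defined on.
#'
#' @param cn_a,cn_b Non-negative finite allele copy numbers (possibly
#'   fractional, in either order).
#' @return Integer vector \code{c(major, minor)} with \code{major >= minor}.
#' @export
#' @examples
#' normalize_alleles(0.6, 2.4)  # c(2, 1)
#' normalize_alleles(2.5, 0)    # c(3, 0)
normalize_alleles <- function(cn_a, cn_b) {
  if (!is.numeric(cn_a) || !is.numeric(cn_b) ||
      !is.finite(cn_a) || !is.finite(cn_b) || cn_a < 0 || cn_b < 0) {
    stop("allele copy numbers must be finite and non-negative", call. = FALSE)
  }
  # round() rounds half to even; the schema rounds half away from zero
  r <- function(x) as.integer(floor(x + 0.5))
  a <- r(cn_a); b <- r(cn_b)
  c(max(a, b), min(a, b))
}

.tcn_class <- function(tcn) {
  if (tcn == 0) "0"
  else if (tcn == 1) "1"
  else if (tcn == 2) "2"
  else if (tcn <= 4) "3-4"
  else if (tcn <= 8) "5-8"
  else "9+"
}

# left-open, right-closed bins: size in (edge[i], edge[i+1]] -> bins[i]
.size_bin <- function(size, edges, bins) {
  bins[findInterval(size, edges, left.open = TRUE)]
}

#' Classify one copy-number segment into its CNV48 channel
#'
#' Determines the heterozygosity state from the allele pair (\code{homdel} if
#' both alleles are lost, \code{LOH} if only the minor allele is lost,
#' \code{het} otherwise), the total-copy-number class from
#' \code{major_cn + minor_cn}, and the size bin from the segment length
#' \code{end - start + 1} (1-based inclusive coordinates; bins are left-open,
#' right-closed).
#'
#' @param major_cn,minor_cn Integer allele copy numbers with
#'   \code{major_cn >= minor_cn >= 0} (see [normalize_alleles()]).
#' @param start,end 1-based inclusive segment coordinates (bp).
#' @return The channel label, one of [cnv48_channels()].
#' @export
#' @examples
#' classify_cnv_segment(1, 1, 1, 50000)       # "2:het:0-100kb"
#' classify_cnv_segment(2, 0, 1, 6e7)         # "2:LOH:>40Mb" (copy-neutral LOH)
classify_cnv_segment <- function(major_cn, minor_cn, start, end) {
  stopifnot(major_cn >= minor_cn, minor_cn >= 0, end > start)
  size <- end - start + 1
  if (major_cn == 0) {
    state <- "homdel"
    bin <- .size_bin(size, .HD_SIZE_EDGES, .HD_SIZE_BINS)
  } else {
    state <- if (minor_cn == 0) "LOH" else "het"
    bin <- .size_bin(size, .CN_SIZE_EDGES, .CN_SIZE_BINS)
  }
  paste(.tcn_class(major_cn + minor_cn), state, bin, sep = ":")
}

#' Classify one structural variant into its SV32 channel
#'
#' @param svtype One of \code{"del"}, \code{"tds"}, \code{"inv"},
#'   \code{"trans"}.
#' @param size Event size in bp (\code{|pos2 - pos1|}); ignored for
#'   translocations, which are not size-binned.
#' @param clustered Logical clustered flag (see [annotate_clustered()]).
#' @return The channel label, one of [sv32_channels()].
#' @export
#' @examples
#' classify_sv("del", 5000, FALSE)   # "non-clustered_del_0-10kb"
#' classify_sv("trans", NA, TRUE)    # "clustered_trans"
classify_sv <- function(svtype, size = NA, clustered = FALSE) {
  stopifnot(svtype %in% .SV_TYPES, is.logical(clustered))
  prefix <- if (clustered) "clustered" else "non-clustered"
  if (svtype == "trans") return(paste(prefix, "trans", sep = "_"))
  stopifnot(is.finite(size), size > 0)
  bin <- .size_bin(size, .SV_SIZE_EDGES, .SV_SIZE_BINS)
  paste(prefix, svtype, bin, sep = "_")
}

#' Infer the SV class from chromosomes and strand orientations
#'
#' Follows the standard paired-end convention: mates on different chromosomes
#' are translocations; on the same chromosome, \code{+/+} is a deletion,
#' \code{-/-} a tandem duplication, and \code{+/-} or \code{-/+} an inversion.
#'
#' @param chrom1,chrom2 Chromosome labels of the two mates.
#' @param strand1,strand2 Strands, \code{"+"} or \code{"-"}.
#' @return One of \code{"del"}, \code{"tds"}, \code{"inv"}, \code{"trans"}.
#' @export
#' @examples
#' infer_svclass("2", "2", "+", "+")  # "del"
#' infer_svclass("1", "X", "-", "-")  # "trans"
infer_svclass <- function(chrom1, chrom2, strand1, strand2) {
  if (chrom1 != chrom2) return("trans")
  stopifnot(strand1 %in% c("+", "-"), strand2 %in% c("+", "-"))
  if (strand1 == "+" && strand2 == "+") "del"
  else if (strand1 == "-" && strand2 == "-") "tds"
  else "inv"
}

# strip a leading "chr" and validate against the human chromosome set;
# returns NA for labels outside 1-22/X/Y
.norm_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  ifelse(x %in% .CHROMS, x, NA_character_)
}
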