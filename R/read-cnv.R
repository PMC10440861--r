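# Readers for allele-specific copy-number segmentation tables.

# Per-dialect column mappings. FACETS reports total (tcn.em) and minor
# (lcn.em) copy number, so major = tcn.em - lcn.em. Battenberg rows carry
# subclonal states in extra columns; only the clonal state (nMaj1_A/nMin1_A)
# is used.
.CNV_DIALECTS <- list(
  GENERIC    = list(sample = "sample", chrom = "chrom", start = "start",
                    end = "end", a = "major_cn", b = "minor_cn"),
  ASCAT      = list(sample = "sample", chrom = "chr", start = "startpos",
                    end = "endpos", a = "nMajor", b = "nMinor"),
  ABSOLUTE   = list(sample = "sample", chrom = "Chromosome", start = "Start",
                    end = "End", a = "Modal_HSCN_1", b = "Modal_HSCN_2"),
  SEQUENZA   = list(sample = "sample", chrom = "chromosome", start = "start.pos",
                    end = "end.pos", a = "A", b = "B"),
  FACETS     = list(sample = "sample", chrom = "chrom", start = "start",
                    end = "end", a = "tcn.em", b = "lcn.em"),
  BATTENBERG = list(sample = "sample", chrom = "chr", start = "startpos",
                    end = "endpos", a = "nMaj1_A", b = "nMin1_A"),
  PURPLE     = list(sample = "sample", chrom = "chromosome", start = "start",
                    end = "end", a = "majorAlleleCopyNumber",
                    b = "minorAlleleCopyNumber")
)

#' Read an allele-specific copy-number segmentation file
#'
#' Reads a tab-separated segmentation table in one of the supported caller
#' dialects and returns validated segments with alleles normalized to ordered
#' integers. Rows failing validation (non-positive length, chromosome outside
#' 1-22/X/Y, missing or negative copy numbers) are skipped with a warning.
#'
#' Supported dialects and their column mappings:
#' \describe{
#'   \item{generic}{sample, chrom, start, end, major_cn, minor_cn}
#'   \item{ascat}{sample, chr, startpos, endpos, nMajor, nMinor}
#'   \item{absolute}{sample, Chromosome, Start, End, Modal_HSCN_1, Modal_HSCN_2}
#'   \item{sequenza}{sample, chromosome, start.pos, end.pos, A, B}
#'   \item{facets}{sample, chrom, start, end, tcn.em, lcn.em (major = tcn.em - lcn.em)}
#'   \item{battenberg}{sample, chr, startpos, endpos, nMaj1_A, nMin1_A (clonal state)}
#'   \item{purple}{sample, chromosome, start, end, majorAlleleCopyNumber,
#'     minorAlleleCopyNumber}
#' }
#' All tables are interpreted as 1-based inclusive coordinates. Fractional
#' copy numbers are rounded half away from zero.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Dialect name (case-insensitive), one of
#'   \code{"generic"}, \code{"ascat"}, \code{"absolute"}, \code{"sequenza"},
#'   \code{"facets"}, \code{"battenberg"}, \code{"purple"}.
#' @param sample Optional sample name used when the file has no sample column.
#' @return A data.frame of segments with columns \code{sample},
#'   \code{chromosome}, \code{start}, \code{end}, \code{major_cn},
#'   \code{minor_cn}, plus an attribute \code{n_skipped} with the number of
#'   rows dropped by validation.
#' @export
read_segmentation <- function(path, dialect = "generic", sample = NULL) {
  dialect <- toupper(dialect)
  if (!dialect %in% names(.CNV_DIALECTS)) {
    stop("unknown dialect '", dialect, "'; supported: ",
         paste(tolower(names(.CNV_DIALECTS)), collapse = ", "), call. = FALSE)
  }
  map <- .CNV_DIALECTS[[dialect]]
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)

  needed <- unlist(map[c("chrom", "start", "end", "a", "b")])
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("dialect ", tolower(dialect), ": missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (map$sample %in% names(df)) {
    sample_ids <- as.character(df[[map$sample]])
  } else if (!is.null(sample)) {
    sample_ids <- rep(sample, nrow(df))
  } else {
    stop("dialect ", tolower(dialect), ": missing mandatory column(s): ",
         map$sample, " (or supply `sample`)", call. = FALSE)
  }

  n <- nrow(df)
  chrom <- .norm_chrom(df[[map$chrom]])
  start <- suppressWarnings(as.numeric(df[[map$start]]))
  end   <- suppressWarnings(as.numeric(df[[map$end]]))
  cn_a  <- suppressWarnings(as.numeric(df[[map$a]]))
  cn_b  <- suppressWarnings(as.numeric(df[[map$b]]))
  if (dialect == "FACETS") cn_a <- cn_a - cn_b  # tcn.em - lcn.em = major

  ok <- !is.na(chrom) & is.finite(start) & is.finite(end) & end > start &
    is.finite(cn_a) & is.finite(cn_b) & cn_a >= 0 & cn_b >= 0
  ok[is.na(ok)] <- FALSE
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " of ", n, " row(s) failed validation and were skipped",
            call. = FALSE)
  }
  if (sum(ok) == 0) {
    stop("no valid segments in ", path, call. = FALSE)
  }

  idx <- which(ok)
  norm <- vapply(idx, function(i) normalize_alleles(cn_a[i], cn_b[i]),
                 integer(2))
  out <- data.frame(
    sample = sample_ids[idx],
    chromosome = chrom[idx],
    start = start[idx],
    end = end[idx],
    major_cn = norm[1, ],
    minor_cn = norm[2, ],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build the 48-channel copy-number count matrix
#'
#' Classifies each segment with [classify_cnv_segment()] and tabulates counts
#' per channel and sample. Every canonical channel appears as a row even when
#' its count is zero for all samples.
#'
#' @param segments Data.frame of segments as returned by
#'   [read_segmentation()] (columns \code{sample}, \code{chromosome},
#'   \code{start}, \code{end}, \code{major_cn}, \code{minor_cn}).
#' @param samples Optional character vector fixing the column set and order;
#'   defaults to the samples present, in order of first appearance. Samples
#'   listed here but absent from \code{segments} get all-zero columns.
#' @return A \code{channel_matrix} (48 x n_samples integer matrix).
#' @export
build_cnv_matrix <- function(segments, samples = NULL) {
  stopifnot(nrow(segments) > 0)
  labels <- mapply(classify_cnv_segment,
                   segments$major_cn, segments$minor_cn,
                   segments$start, segments$end)
  if (is.null(samples)) samples <- unique(segments$sample)
  channel_matrix_from_events(labels, segments$sample, schema = "CN48",
                             samples = samples)
}
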