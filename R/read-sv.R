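# BEDPE reader for structural variants.

.SVCLASS_SYNONYMS <- c(
  del = "del", deletion = "del", dup = "tds", tds = "tds",
  "tandem-duplication" = "tds", tandem_duplication = "tds",
  "tandem-dup" = "tds", inv = "inv", inversion = "inv",
  tra = "trans", trans = "trans", translocation = "trans", bnd = "trans"
)

#' Read structural variants from a BEDPE file
#'
#' Reads a tab-separated BEDPE file (header required) with the six mandatory
#' columns \code{chrom1, start1, end1, chrom2, start2, end2}, optional
#' \code{strand1}/\code{strand2}, optional \code{svclass}, and optional
#' \code{sample}. Starts are converted from BEDPE's 0-based half-open
#' convention to 1-based, and each mate's breakpoint is collapsed to the
#' midpoint of its interval, \code{floor((start + end) / 2)}.
#'
#' The SV class is taken from \code{svclass} when present (common synonyms
#' such as \code{DEL}, \code{DUP}, \code{inversion}, \code{TRA}, \code{BND}
#' are accepted); otherwise it is inferred from the strand columns via
#' [infer_svclass()]. Records with an unknown class token, or lacking both a
#' class and a complete strand pair, are skipped with a warning; a file
#' providing neither an \code{svclass} column nor both strand columns is a
#' fatal error.
#'
#' @param path Path to the BEDPE file.
#' @param sample Optional sample name used when the file has no sample column.
#' @return A data.frame with one row per SV: \code{sample}, \code{chrom1},
#'   \code{pos1}, \code{chrom2}, \code{pos2}, \code{svclass}, \code{size}
#'   (\code{abs(pos2 - pos1)} for intra-chromosomal records, \code{NA} for
#'   translocations), plus attribute \code{n_skipped}.
#' @export
read_bedpe <- function(path, sample = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("BEDPE: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_class   <- "svclass" %in% names(df)
  has_strands <- all(c("strand1", "strand2") %in% names(df))
  if (!has_class && !has_strands) {
    stop("BEDPE: neither an svclass column nor both strand1 and strand2 ",
         "columns are present", call. = FALSE)
  }
  if ("sample" %in% names(df)) {
    sample_ids <- as.character(df$sample)
  } else if (!is.null(sample)) {
    sample_ids <- rep(sample, nrow(df))
  } else {
    sample_ids <- rep("sample1", nrow(df))
  }

  chrom1 <- .norm_chrom(df$chrom1)
  chrom2 <- .norm_chrom(df$chrom2)
  # BEDPE starts are 0-based half-open; +1 makes them 1-based inclusive
  pos1 <- floor((as.numeric(df$start1) + 1 + as.numeric(df$end1)) / 2)
  pos2 <- floor((as.numeric(df$start2) + 1 + as.numeric(df$end2)) / 2)

  n <- nrow(df)
  svclass <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cls <- NA_character_
    if (has_class && !is.na(df$svclass[i]) && nzchar(df$svclass[i])) {
      tok <- tolower(trimws(df$svclass[i]))
      if (tok %in% names(.SVCLASS_SYNONYMS)) cls <- .SVCLASS_SYNONYMS[[tok]]
    } else if (has_strands &&
               !is.na(df$strand1[i]) && df$strand1[i] %in% c("+", "-") &&
               !is.na(df$strand2[i]) && df$strand2[i] %in% c("+", "-") &&
               !is.na(chrom1[i]) && !is.na(chrom2[i])) {
      cls <- infer_svclass(chrom1[i], chrom2[i], df$strand1[i], df$strand2[i])
    }
    svclass[i] <- cls
  }

  intra <- !is.na(chrom1) & !is.na(chrom2) & chrom1 == chrom2
  size <- ifelse(intra, abs(pos2 - pos1), NA_real_)
  # intra-chromosomal records need a positive size for binning; pre-assigned
  # translocations may join distant loci of one chromosome and are exempt
  ok <- !is.na(chrom1) & !is.na(chrom2) & !is.na(svclass) &
    is.finite(pos1) & is.finite(pos2) &
    (!intra | svclass == "trans" | size > 0)
  ok[is.na(ok)] <- FALSE

  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " of ", n, " BEDPE record(s) failed validation and ",
            "were skipped", call. = FALSE)
  }
  if (sum(ok) == 0) stop("no valid SV records in ", path, call. = FALSE)

  idx <- which(ok)
  out <- data.frame(
    sample = sample_ids[idx],
    chrom1 = chrom1[idx], pos1 = pos1[idx],
    chrom2 = chrom2[idx], pos2 = pos2[idx],
    svclass = svclass[idx],
    size = size[idx],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build the 32-channel structural-variant count matrix
#'
#' Annotates each record's clustered status per sample with
#' [annotate_clustered()], classifies every record with [classify_sv()], and
#' tabulates counts per channel and sample.
#'
#' @param records Data.frame of SV records as returned by [read_bedpe()].
#' @param samples Optional character vector fixing the column set and order.
#' @param gamma PCF penalty per segment on the log10 inter-mutational
#'   distance scale (default 25).
#' @param cluster_factor A segment is clustered when its mean IMD is at most
#'   the sample mean IMD divided by this factor (default 10).
#' @param min_cluster_bp Minimum number of breakpoints a segment must contain
#'   to be eligible for the clustered annotation (default 10).
#' @return A \code{channel_matrix} (32 x n_samples integer matrix).
#' @export
build_sv_matrix <- function(records, samples = NULL, gamma = 25,
                            cluster_factor = 10, min_cluster_bp = 10) {
  stopifnot(nrow(records) > 0)
  clustered <- annotate_clustered(records, gamma = gamma,
                                  cluster_factor = cluster_factor,
                                  min_cluster_bp = min_cluster_bp)
  labels <- mapply(classify_sv, records$svclass, records$size, clustered)
  if (is.null(samples)) samples <- unique(records$sample)
  channel_matrix_from_events(labels, records$sample, schema = "SV32",
                             samples = samples)
}
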