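# The channel x sample count matrix container and its TSV dialect.

.schema_channels <- function(schema) {
  switch(schema,
         CN48 = cnv48_channels(),
         SV32 = sv32_channels(),
         stop("unknown schema '", schema, "'", call. = FALSE))
}

#' Construct a channel matrix from classified events
#'
#' @param labels Character vector of channel labels, one per event.
#' @param sample_ids Character vector of sample identifiers, one per event.
#' @param schema \code{"CN48"} or \code{"SV32"}.
#' @param samples Optional column set/order; defaults to samples present in
#'   order of first appearance.
#' @return An integer matrix of class \code{channel_matrix} with canonical
#'   channel rownames, sample colnames, and a \code{schema} attribute.
#' @export
channel_matrix_from_events <- function(labels, sample_ids, schema,
                                       samples = NULL) {
  channels <- .schema_channels(schema)
  bad <- setdiff(unique(labels), channels)
  if (length(bad) > 0) {
    stop("label(s) outside the ", schema, " schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples)) samples <- unique(sample_ids)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  tab <- table(factor(labels, levels = channels),
               factor(sample_ids, levels = samples))
  m <- matrix(as.integer(tab), nrow = length(channels),
              dimnames = list(channels, samples))
  structure(m, schema = schema, class = c("channel_matrix", "matrix", "array"))
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(attr(x, "schema"), "channel matrix:", nrow(x), "channels x", ncol(x),
      "sample(s),", sum(x), "event(s) total\n")
  nz <- x[rowSums(x) > 0, , drop = FALSE]
  if (nrow(nz) > 0) {
    print(unclass(nz))
  } else {
    cat("(all counts zero)\n")
  }
  invisible(x)
}

#' Write a channel matrix as TSV
#'
#' Writes the matrix in the standard mutational-matrix dialect: a
#' tab-separated file whose first column, headed \code{MutationType}, holds
#' the channel labels in canonical order, followed by one integer column per
#' sample. The output is deterministic.
#'
#' @param matrix A \code{channel_matrix}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "channel_matrix"))
  df <- data.frame(MutationType = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("MutationType", colnames(matrix))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write matrix to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a channel matrix from TSV
#'
#' Reads a matrix written by [write_matrix()]. The schema (CN48 or SV32) is
#' auto-detected from the channel labels; rows may appear in any order and
#' are re-sorted to canonical order. A label outside both schemas is a fatal
#' error naming the offending label.
#'
#' @param path Path to the TSV file.
#' @return A \code{channel_matrix}.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "MutationType") {
    stop("matrix file must have a first column 'MutationType'", call. = FALSE)
  }
  labels <- as.character(df$MutationType)
  schema <- if (all(labels %in% cnv48_channels())) "CN48"
  else if (all(labels %in% sv32_channels())) "SV32"
  else {
    bad <- labels[!(labels %in% c(cnv48_channels(), sv32_channels()))]
    stop("unknown channel label(s): ", paste(utils::head(bad, 5),
                                             collapse = ", "), call. = FALSE)
  }
  channels <- .schema_channels(schema)
  if (length(labels) != length(channels) || anyDuplicated(labels)) {
    stop("expected the ", length(channels), " canonical ", schema,
         " channels exactly once each", call. = FALSE)
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("matrix cells must be non-negative integers", call. = FALSE)
  }
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(labels, colnames(counts)))
  m <- m[channels, , drop = FALSE]  # canonical row order
  structure(m, schema = schema, class = c("channel_matrix", "matrix", "array"))
}
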