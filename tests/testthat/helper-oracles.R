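# Independent oracles and small input builders used across test files.

# Exhaustive piecewise-constant-fit oracle: minimum penalized least-squares
# objective over all 2^(n-1) segmentations of the series. Independent of the
# dynamic-programming implementation under test.
exhaustive_pcf_objective <- function(values, gamma) {
  n <- length(values)
  if (n == 1) return(gamma)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)  # boundary after index i
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    obj <- gamma * length(starts)
    for (k in seq_along(starts)) {
      seg <- values[starts[k]:ends[k]]
      obj <- obj + sum((seg - mean(seg))^2)
    }
    if (obj < best) best <- obj
  }
  best
}

# one CNV profile used for cross-dialect agreement tests
reference_cnv_profile <- function() {
  data.frame(
    sample = rep(c("T1", "T2"), c(5, 4)),
    chromosome = c("1", "2", "3", "X", "5", "1", "7", "9", "12"),
    start = c(10001, 5e6, 1e6, 2e6, 1e7, 20001, 3e6, 1e6, 5e6),
    end = c(60000, 5e6 + 2e5, 1e6 + 5e6, 2e6 + 2e7, 6e7, 120000,
            3e6 + 8e5, 1e6 + 3e6, 5e6 + 5e7),
    major_cn = c(1, 2, 0, 3, 9, 2, 1, 5, 2),
    minor_cn = c(1, 0, 0, 2, 4, 2, 0, 3, 2),
    stringsAsFactors = FALSE
  )
}

# write a CNV profile in any supported caller dialect
write_dialect_file <- function(seg, dialect, path) {
  d <- switch(toupper(dialect),
    GENERIC = data.frame(sample = seg$sample, chrom = seg$chromosome,
                         start = seg$start, end = seg$end,
                         major_cn = seg$major_cn, minor_cn = seg$minor_cn),
    ASCAT = data.frame(sample = seg$sample, chr = seg$chromosome,
                       startpos = seg$start, endpos = seg$end,
                       nMajor = seg$major_cn, nMinor = seg$minor_cn),
    ABSOLUTE = data.frame(sample = seg$sample, Chromosome = seg$chromosome,
                          Start = seg$start, End = seg$end,
                          Modal_HSCN_1 = seg$major_cn,
                          Modal_HSCN_2 = seg$minor_cn),
    SEQUENZA = setNames(data.frame(seg$sample, seg$chromosome, seg$start,
                                   seg$end, seg$major_cn, seg$minor_cn),
                        c("sample", "chromosome", "start.pos", "end.pos",
                          "A", "B")),
    FACETS = setNames(data.frame(seg$sample, seg$chromosome, seg$start,
                                 seg$end, seg$major_cn + seg$minor_cn,
                                 seg$minor_cn),
                      c("sample", "chrom", "start", "end", "tcn.em",
                        "lcn.em")),
    BATTENBERG = data.frame(sample = seg$sample, chr = seg$chromosome,
                            startpos = seg$start, endpos = seg$end,
                            nMaj1_A = seg$major_cn, nMin1_A = seg$minor_cn),
    PURPLE = data.frame(sample = seg$sample, chromosome = seg$chromosome,
                        start = seg$start, end = seg$end,
                        majorAlleleCopyNumber = seg$major_cn,
                        minorAlleleCopyNumber = seg$minor_cn),
    stop("unknown dialect"))
  write.table(format(d, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

# write SV records as a BEDPE file (single-base mate intervals around each
# 1-based breakpoint)
write_bedpe_file <- function(rec, path, strands = TRUE, svclass = TRUE,
                             sample_col = TRUE) {
  d <- data.frame(chrom1 = rec$chrom1, start1 = rec$pos1 - 1,
                  end1 = rec$pos1, chrom2 = rec$chrom2,
                  start2 = rec$pos2 - 1, end2 = rec$pos2)
  if (strands) { d$strand1 <- rec$strand1; d$strand2 <- rec$strand2 }
  if (svclass) d$svclass <- rec$svclass
  if (sample_col) d$sample <- rec$sample
  write.table(format(d, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

# a single-sample SV set with a k-breakpoint tight cluster (1 kb apart,
# one chromosome, built from translocations so the cluster holds exactly k
# breakpoints) plus paired background breakpoints 10 Mb apart elsewhere
tight_cluster_records <- function(k, sample = "S") {
  cl <- data.frame(
    sample = sample,
    chrom1 = "1", pos1 = 1e6 + (seq_len(k) - 1) * 1000,
    chrom2 = "9", pos2 = 1e6 + (seq_len(k) - 1) * 3e6,
    strand1 = "+", strand2 = "-", svclass = "trans",
    stringsAsFactors = FALSE
  )
  bg <- data.frame(
    sample = sample,
    chrom1 = "2", pos1 = 1e6 + (0:4) * 2e7,
    chrom2 = "2", pos2 = 1e6 + (0:4) * 2e7 + 1e7,
    strand1 = "+", strand2 = "+", svclass = "del",
    stringsAsFactors = FALSE
  )
  rbind(cl, bg)
}
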