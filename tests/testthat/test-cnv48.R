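test_that("allele normalization rounds half away from zero and orders the pair", {
  expect_identical(normalize_alleles(1, 1), c(1L, 1L))
  expect_identical(normalize_alleles(0.6, 2.4), c(2L, 1L))
  expect_identical(normalize_alleles(2.5, 0), c(3L, 0L))
  expect_identical(normalize_alleles(1.5, 0.5), c(2L, 1L))
  # idempotent on integers
  for (a in 0:6) for (b in 0:a) {
    expect_identical(normalize_alleles(a, b), c(a, b))
  }
  expect_error(normalize_alleles(-1, 0), "non-negative")
  expect_error(normalize_alleles(NA_real_, 1), "finite")
  expect_error(normalize_alleles(Inf, 1), "finite")
})

test_that("segment classification follows the printed schema rules", {
  expect_identical(classify_cnv_segment(1, 1, 1, 50000), "2:het:0-100kb")
  expect_identical(classify_cnv_segment(0, 0, 1, 500000), "0:homdel:100kb-1Mb")
  expect_identical(classify_cnv_segment(9, 3, 1, 2e6), "9+:het:1Mb-10Mb")
  expect_identical(classify_cnv_segment(2, 0, 1, 6e7), "2:LOH:>40Mb")
  expect_identical(classify_cnv_segment(1, 0, 1, 1e5), "1:LOH:0-100kb")
  expect_identical(classify_cnv_segment(0, 0, 1, 5e6), "0:homdel:>1Mb")
})

test_that("size bins are left-open right-closed at every boundary", {
  # length = end - start + 1; start = 1 makes length = end
  expect_match(classify_cnv_segment(1, 1, 1, 1e5), "0-100kb$")
  expect_match(classify_cnv_segment(1, 1, 1, 1e5 + 1), "100kb-1Mb$")
  expect_match(classify_cnv_segment(1, 1, 1, 1e6), "100kb-1Mb$")
  expect_match(classify_cnv_segment(1, 1, 1, 1e6 + 1), "1Mb-10Mb$")
  expect_match(classify_cnv_segment(1, 1, 1, 1e7), "1Mb-10Mb$")
  expect_match(classify_cnv_segment(1, 1, 1, 1e7 + 1), "10Mb-40Mb$")
  expect_match(classify_cnv_segment(1, 1, 1, 4e7), "10Mb-40Mb$")
  expect_match(classify_cnv_segment(1, 1, 1, 4e7 + 1), ">40Mb$")
  expect_match(classify_cnv_segment(0, 0, 1, 1e6), "100kb-1Mb$")
  expect_match(classify_cnv_segment(0, 0, 1, 1e6 + 1), ">1Mb$")
})

test_that("classification partitions the allele grid into the 48 channels", {
  sizes <- c(10, 1e5, 1e5 + 1, 1e6, 1e6 + 1, 1e7, 1e7 + 1, 4e7, 4e7 + 1, 1e9)
  seen <- character(0)
  for (major in 0:12) for (minor in 0:major) for (size in sizes) {
    lab <- classify_cnv_segment(major, minor, 1, size)
    expect_true(lab %in% cnv48_channels())
    seen <- c(seen, lab)
  }
  expect_setequal(unique(seen), cnv48_channels())  # all 48 reachable
})

test_that("the canonical channel set is the 3 + 25 + 20 decomposition", {
  ch <- cnv48_channels()
  expect_length(ch, 48)
  expect_false(anyDuplicated(ch) > 0)
  state <- vapply(strsplit(ch, ":"), `[`, "", 2)
  expect_identical(as.integer(table(state)[c("homdel", "LOH", "het")]),
                   c(3L, 25L, 20L))
  # homdel <=> TCN class 0; het excludes TCN 0 and 1
  tcn <- vapply(strsplit(ch, ":"), `[`, "", 1)
  expect_true(all((state == "homdel") == (tcn == "0")))
  expect_false(any(state == "het" & tcn %in% c("0", "1")))
})

test_that("the generic reader validates rows and normalizes alleles", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "S1\tchr1\t100\t50000\t1\t1",
               "S1\t2\t5000\t4000\t2\t1",      # end <= start
               "S1\tGL000205\t1\t100\t2\t1",   # non-canonical chromosome
               "S1\t3\t1\t2000\tNA\t1",        # missing allele
               "S1\t4\t1000\t900000\t0.6\t2.4"), f)
  expect_warning(seg <- read_segmentation(f, "generic"), "3 of 5")
  expect_equal(nrow(seg), 2)
  expect_identical(seg$chromosome, c("1", "4"))
  expect_identical(seg$major_cn, c(1L, 2L))
  expect_identical(seg$minor_cn, c(1L, 1L))
  expect_identical(attr(seg, "n_skipped"), 3L)
})

test_that("missing mandatory columns and empty files are fatal", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn", "S1\t1\t1\t100\t1"), f)
  expect_error(read_segmentation(f, "generic"), "minor_cn")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "S1\t1\t500\t400\t1\t1"), f)
  expect_error(suppressWarnings(read_segmentation(f, "generic")),
               "no valid segments")
})

test_that("all six caller dialects agree with the generic reading", {
  seg <- reference_cnv_profile()
  dialects <- c("generic", "ascat", "absolute", "sequenza", "facets",
                "battenberg", "purple")
  mats <- lapply(dialects, function(d) {
    f <- write_dialect_file(seg, d, tempfile(fileext = ".tsv"))
    build_cnv_matrix(read_segmentation(f, d))
  })
  for (i in 2:length(mats)) expect_identical(mats[[i]], mats[[1]])
})

test_that("the CNV matrix conserves counts and honors a supplied sample list", {
  seg <- reference_cnv_profile()
  m <- build_cnv_matrix(seg)
  expect_identical(dim(m), c(48L, 2L))
  expect_identical(rownames(m), cnv48_channels())
  expect_identical(as.integer(colSums(m)),
                   as.integer(table(seg$sample)[colnames(m)]))
  expect_identical(sum(m), nrow(seg))
  # sample present in the list but absent from the data gets a zero column
  m2 <- build_cnv_matrix(seg, samples = c("T1", "T2", "EMPTY"))
  expect_identical(unname(m2[, "EMPTY"]), rep(0L, 48))
  # three identical segments of one sample land in one cell
  one <- data.frame(sample = "A", chromosome = "1",
                    start = c(1, 1e6, 2e6), end = c(50000, 1e6 + 49999, 2e6 + 49999),
                    major_cn = 1L, minor_cn = 1L)
  m3 <- build_cnv_matrix(one)
  expect_identical(unname(m3["2:het:0-100kb", "A"]), 3L)
  expect_identical(sum(m3), 3L)
})
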