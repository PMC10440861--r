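test_that("strand conventions map to the canonical SV classes", {
  expect_identical(infer_svclass("2", "2", "+", "+"), "del")
  expect_identical(infer_svclass("2", "2", "-", "-"), "tds")
  expect_identical(infer_svclass("3", "3", "+", "-"), "inv")
  expect_identical(infer_svclass("3", "3", "-", "+"), "inv")
  expect_identical(infer_svclass("1", "X", "-", "-"), "trans")
})

test_that("SV classification partitions into the 32 channels, all reachable", {
  ch <- sv32_channels()
  expect_length(ch, 32)
  expect_false(anyDuplicated(ch) > 0)
  sizes <- c(1, 1e4, 1e4 + 1, 1e5, 1e5 + 1, 1e6, 1e6 + 1, 1e7, 1e7 + 1, 1e9)
  seen <- character(0)
  for (ty in c("del", "tds", "inv")) for (s in sizes) for (cl in c(TRUE, FALSE)) {
    lab <- classify_sv(ty, s, cl)
    expect_true(lab %in% ch)
    seen <- c(seen, lab)
  }
  seen <- c(seen, classify_sv("trans", NA, TRUE), classify_sv("trans", NA, FALSE))
  expect_setequal(unique(seen), ch)
  # spot checks forced by the schema
  expect_identical(classify_sv("del", 5000, FALSE), "non-clustered_del_0-10kb")
  expect_identical(classify_sv("trans", NA, TRUE), "clustered_trans")
  expect_identical(classify_sv("inv", 1.5e7, TRUE), "clustered_inv_>10Mb")
})

test_that("the BEDPE reader converts coordinates, infers classes, and validates", {
  f <- tempfile(fileext = ".bedpe")
  writeLines(c(
    "chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tstrand1\tstrand2\tsvclass",
    "chr1\t999\t1000\tchr5\t5999\t6000\t+\t-\t",      # strands: cross-chrom -> trans
    "2\t99\t100\t2\t10099\t10100\t\t\tdeletion",      # svclass synonym
    "3\t0\t100\t3\t50000\t50100\t+\t+\t",             # midpoint positions
    "4\t0\t100\t4\t5000\t5100\t\t\tweird",            # unknown token -> skip
    "5\t0\t100\t5\t5000\t5100\t+\t\t"                 # no strand2, no class -> skip
  ), f)
  expect_warning(rec <- read_bedpe(f, sample = "S"), "2 of 5")
  expect_equal(nrow(rec), 3)
  expect_identical(rec$svclass, c("trans", "del", "del"))
  expect_identical(rec$chrom1[1], "1")  # "chr" prefix stripped
  # row 3: mate intervals (0,100] and (50000,50100] -> midpoints 50 and 50050
  expect_identical(rec$pos1[3], 50)
  expect_identical(rec$pos2[3], 50050)
  expect_identical(rec$size[3], 50000)
  expect_true(is.na(rec$size[1]))  # translocations carry no size
})

test_that("a BEDPE without both strands and svclass is fatal", {
  f <- tempfile(fileext = ".bedpe")
  writeLines(c("chrom1\tstart1\tend1\tchrom2\tstart2\tend2",
               "1\t0\t100\t1\t5000\t5100"), f)
  expect_error(read_bedpe(f), "svclass.*strand1|strand")
  writeLines(c("chrom1\tstart1\tend1\tchrom2\tend2",
               "1\t0\t100\t1\t5100"), f)
  expect_error(read_bedpe(f), "start2")
})

test_that("the SV matrix conserves counts across channels and samples", {
  rec <- data.frame(
    sample = rep(c("A", "B"), c(4, 3)),
    chrom1 = c("1", "2", "3", "1", "4", "5", "6"),
    pos1 = c(1e6, 2e6, 3e6, 4e6, 1e6, 2e6, 3e6),
    chrom2 = c("1", "2", "3", "9", "4", "5", "7"),
    pos2 = c(1e6 + 5e3, 2e6 + 5e4, 3e6 + 5e5, 8e6, 1e6 + 2e7, 2e6 + 5e6, 9e6),
    svclass = c("del", "tds", "inv", "trans", "del", "inv", "trans"),
    stringsAsFactors = FALSE
  )
  rec$size <- ifelse(rec$chrom1 == rec$chrom2, abs(rec$pos2 - rec$pos1), NA)
  m <- build_sv_matrix(rec)
  expect_identical(dim(m), c(32L, 2L))
  expect_identical(rownames(m), sv32_channels())
  expect_identical(as.integer(colSums(m)), c(4L, 3L))
  expect_identical(sum(m), nrow(rec))
  # all sparse: nothing can be clustered
  expect_true(all(m[startsWith(rownames(m), "clustered"), ] == 0L))
})

test_that("identical BEDPE inputs produce byte-identical matrix files", {
  sv <- generate_sv_fixture("mixed", 20, 3, dir = tempfile())
  out1 <- tempfile(); out2 <- tempfile()
  write_matrix(build_sv_matrix(read_bedpe(sv$file)), out1)
  write_matrix(build_sv_matrix(read_bedpe(sv$file)), out2)
  expect_identical(readLines(out1), readLines(out2))
})
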