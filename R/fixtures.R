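# Seeded generators of synthetic segmentation and BEDPE files with known
# ground-truth channel assignments. Coordinates respect real human (GRCh38)
# chromosome lengths so profiles and rainfall plots look plausible.

.CHROM_LENGTHS <- c(
  "1" = 248956422, "2" = 242193529, "3" = 198295559, "4" = 190214555,
  "5" = 181538259, "6" = 170805979, "7" = 159345973, "8" = 145138636,
  "9" = 138394717, "10" = 133797422, "11" = 135086622, "12" = 133275309,
  "13" = 114364328, "14" = 107043718, "15" = 101991189, "16" = 90338345,
  "17" = 83257441, "18" = 80373285, "19" = 58617616, "20" = 64444167,
  "21" = 46709983, "22" = 50818468, "X" = 156040895, "Y" = 57227415
)

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.CNV_SCENARIOS <- c("focal_amp", "loh_heavy", "wgd", "mixed")
.SV_SCENARIOS <- c("chromothripsis", "dispersed", "mixed")

# channel -> plausible (major, minor) pair and a length inside the size bin
.realize_cnv_channel <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  tcn_class <- parts[1]; state <- parts[2]; bin <- parts[3]
  tcn <- switch(tcn_class,
                "0" = 0L, "1" = 1L, "2" = 2L,
                "3-4" = sample(3:4, 1), "5-8" = sample(5:8, 1),
                "9+" = sample(9:12, 1))
  if (state == "homdel") {
    major <- 0L; minor <- 0L
  } else if (state == "LOH") {
    major <- tcn; minor <- 0L
  } else {
    minor <- sample.int(tcn %/% 2, 1)
    major <- tcn - minor
  }
  len <- switch(bin,
                "0-100kb"   = sample(1000:100000, 1),
                "100kb-1Mb" = sample(100001:1000000, 1),
                "1Mb-10Mb"  = sample(1000001:10000000, 1),
                "10Mb-40Mb" = sample(10000001:40000000, 1),
                ">40Mb"     = sample(40000001:120000000, 1),
                ">1Mb"      = sample(1000001:10000000, 1))
  list(major = major, minor = minor, len = len)
}

.cnv_channel_weights <- function(scenario) {
  channels <- cnv48_channels()
  w <- rep(0, length(channels))
  names(w) <- channels
  focal <- as.vector(outer(c("5-8", "9+"),
                           c("0-100kb", "100kb-1Mb", "1Mb-10Mb"),
                           function(t, s) paste(t, "het", s, sep = ":")))
  loh1 <- paste("1", "LOH", .CN_SIZE_BINS, sep = ":")
  wgd <- paste("3-4", "het", c("10Mb-40Mb", ">40Mb"), sep = ":")
  switch(scenario,
         focal_amp = { w[focal] <- 0.60 / length(focal)
                       w[setdiff(channels, focal)] <-
                         0.40 / (48 - length(focal)) },
         loh_heavy = { w[loh1] <- 0.70 / length(loh1)
                       w[setdiff(channels, loh1)] <-
                         0.30 / (48 - length(loh1)) },
         wgd = { w[wgd] <- 0.70 / length(wgd)
                 w[setdiff(channels, wgd)] <- 0.30 / (48 - length(wgd)) },
         mixed = { w[] <- 1 / 48 })
  w
}

#' Generate a synthetic copy-number segmentation fixture
#'
#' Emits a generic-dialect segmentation file whose segments realize a
#' scenario-specific mixture of the 48 channels, together with a ground-truth
#' table recording the intended channel of every segment. Classifying the
#' emitted file reproduces the ground-truth channel counts exactly.
#'
#' Scenarios emulate archetypal tumor profiles: \code{focal_amp} draws 60\%
#' of events from high-copy (TCN 5-8 and 9+) heterozygous channels with
#' sizes up to 10 Mb (the focal-amplification / ecDNA pattern);
#' \code{loh_heavy} draws 70\% from TCN = 1 LOH channels (extensive allelic
#' loss); \code{wgd} draws 70\% from TCN 3-4 heterozygous channels larger
#' than 10 Mb (whole-genome duplication); \code{mixed} is uniform over all 48
#' channels.
#'
#' Segments are placed without overlap on chromosomes 1-22, largest first on
#' the chromosome with the most remaining room. Identical
#' (scenario, n_events, seed) calls produce byte-identical files.
#'
#' @param scenario One of \code{"focal_amp"}, \code{"loh_heavy"},
#'   \code{"wgd"}, \code{"mixed"}.
#' @param n_events Number of segments to emit.
#' @param seed Integer seed; fixes the fixture completely.
#' @param sample_id Sample name written to the file.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix; defaults to the scenario name.
#' @return A list with \code{file} (segmentation TSV), \code{truth_file}
#'   (TSV: record_id, intended_channel), \code{meta_file} (scenario,
#'   n_events, seed sidecar), \code{truth} (data.frame), and \code{counts}
#'   (named integer vector over the 48 canonical channels).
#' @export
generate_cnv_fixture <- function(scenario, n_events = 20, seed = 1,
                                 sample_id = "sample1", dir = tempdir(),
                                 prefix = scenario) {
  scenario <- match.arg(scenario, .CNV_SCENARIOS)
  stopifnot(n_events >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- .cnv_channel_weights(scenario)

  .with_seed(seed, {
    labels <- sample(names(w), n_events, replace = TRUE, prob = w)
    real <- lapply(labels, .realize_cnv_channel)
    lens <- vapply(real, `[[`, 0, "len")

    # place largest-first on the autosome with the most remaining room
    cursor <- setNames(rep(10001, 22), as.character(1:22))
    limit <- .CHROM_LENGTHS[as.character(1:22)]
    ord <- order(lens, decreasing = TRUE)
    chrom <- character(n_events); start <- numeric(n_events)
    for (i in ord) {
      room <- limit - cursor
      k <- which.max(room)
      if (room[k] < lens[i] + 10000) {
        stop("n_events exceeds placeable capacity for scenario ", scenario,
             call. = FALSE)
      }
      chrom[i] <- names(cursor)[k]
      start[i] <- cursor[k]
      cursor[k] <- cursor[k] + lens[i] + 10000  # gap keeps segments disjoint
    }
  })

  seg <- data.frame(
    sample = sample_id, chrom = chrom,
    start = as.integer(start), end = as.integer(start + lens - 1),
    major_cn = vapply(real, `[[`, 0L, "major"),
    minor_cn = vapply(real, `[[`, 0L, "minor"),
    stringsAsFactors = FALSE
  )
  file <- file.path(dir, paste0(prefix, ".segments.tsv"))
  utils::write.table(seg, file, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- data.frame(record_id = seq_len(n_events),
                      intended_channel = labels, stringsAsFactors = FALSE)
  truth_file <- file.path(dir, paste0(prefix, ".truth.tsv"))
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_file <- .write_fixture_meta(dir, prefix, scenario, n_events, seed)

  counts <- table(factor(labels, levels = cnv48_channels()))
  list(file = file, truth_file = truth_file, meta_file = meta_file,
       truth = truth,
       counts = setNames(as.integer(counts), names(counts)))
}

.write_fixture_meta <- function(dir, prefix, scenario, n_events, seed) {
  meta_file <- file.path(dir, paste0(prefix, ".meta.tsv"))
  utils::write.table(
    data.frame(scenario = scenario, n_events = n_events, seed = seed),
    meta_file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_file
}

# strand pair consistent with each intra-chromosomal class
.SV_STRANDS <- list(del = c("+", "+"), tds = c("-", "-"), inv = c("+", "-"),
                    trans = c("+", "-"))

#' Generate a synthetic structural-variant fixture
#'
#' Emits a BEDPE file plus a ground-truth table recording each record's
#' intended channel (including the intended clustered flag). Running the full
#' pipeline (read, cluster annotation, classification) on the emitted file
#' reproduces the ground truth exactly; the generator's geometry guarantees
#' the clustering threshold inequalities hold with a wide margin.
#'
#' Scenarios: \code{chromothripsis} places 6 intra-chromosomal events whose
#' 12 breakpoints sit 1 kb apart inside a single 1 Mb window of one
#' chromosome (these are the clustered records) plus widely spaced background
#' events (at least 5 Mb apart) on other chromosomes; \code{dispersed} places
#' events of all types and size bins round-robin across chromosomes, at most
#' four events per chromosome, so no chromosome can reach the ten-breakpoint
#' clustering minimum; \code{mixed} is the chromothripsis cluster plus
#' dispersed-style background.
#'
#' @inheritParams generate_cnv_fixture
#' @param scenario One of \code{"chromothripsis"}, \code{"dispersed"},
#'   \code{"mixed"}.
#' @param n_events Number of SV records; chromothripsis/mixed need at least 8
#'   (6 clustered + 2 background).
#' @return A list with \code{file} (BEDPE), \code{truth_file},
#'   \code{meta_file}, \code{truth} (data.frame: record_id,
#'   intended_channel, intended_clustered), and \code{counts} (named integer
#'   vector over the 32 canonical channels).
#' @export
generate_sv_fixture <- function(scenario, n_events = 20, seed = 1,
                                sample_id = "sample1", dir = tempdir(),
                                prefix = scenario) {
  scenario <- match.arg(scenario, .SV_SCENARIOS)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cluster_chrom <- "5"
  n_cluster <- if (scenario == "dispersed") 0L else 6L
  if (scenario != "dispersed" && n_events < n_cluster + 2) {
    stop("scenario ", scenario, " needs n_events >= ", n_cluster + 2,
         call. = FALSE)
  }
  n_bg <- n_events - n_cluster
  bg_chroms <- setdiff(as.character(1:22), cluster_chrom)
  # background capacity: <= 4 events (8 breakpoints) per chromosome keeps
  # every background chromosome below the 10-breakpoint clustering minimum
  if (n_bg > 4 * length(bg_chroms)) {
    stop("n_events exceeds placeable capacity for scenario ", scenario,
         call. = FALSE)
  }

  rec <- .with_seed(seed, {
    out <- list()
    if (n_cluster > 0) {
      # 12 breakpoints, 1 kb apart, inside one window: sizes 1 kb (0-10kb bin)
      base <- 5e6
      types <- rep(c("del", "tds", "inv"), length.out = n_cluster)
      for (j in seq_len(n_cluster)) {
        p1 <- base + (2 * (j - 1)) * 1000
        out[[length(out) + 1]] <- list(
          chrom1 = cluster_chrom, pos1 = p1,
          chrom2 = cluster_chrom, pos2 = p1 + 1000,
          svclass = types[j], clustered = TRUE)
      }
    }
    if (n_bg > 0) {
      if (scenario == "chromothripsis") {
        # only large, widely spaced intra events: every background IMD is
        # >= 5 Mb, thousands of times the 1 kb cluster spacing
        sizes <- c(5e6, 2e7)
        types <- c("del", "tds", "inv")
        spacing <- 3e7
      } else {
        sizes <- c(5e3, 5e4, 5e5, 5e6, 2e7)
        types <- c("del", "tds", "inv", "trans")
        spacing <- 3e7
      }
      cursor <- setNames(rep(1e6, length(bg_chroms)), bg_chroms)
      nev <- setNames(rep(0L, length(bg_chroms)), bg_chroms)
      ci <- 0L
      for (j in seq_len(n_bg)) {
        tries <- 0L
        repeat {
          ci <- (ci %% length(bg_chroms)) + 1L
          ch <- bg_chroms[ci]
          if (nev[ch] < 4 &&
              cursor[ch] + spacing < .CHROM_LENGTHS[[ch]]) break
          tries <- tries + 1L
          if (tries > length(bg_chroms)) {
            stop("n_events exceeds placeable capacity for scenario ",
                 scenario, call. = FALSE)
          }
        }
        ty <- sample(types, 1)
        ch2 <- bg_chroms[(ci %% length(bg_chroms)) + 1L]
        if (ty == "trans" && nev[ch2] >= 4) ty <- "inv"  # mate chromosome full
        if (ty == "trans") {
          # mate on the following background chromosome; offset by j so
          # repeated translocation mates never coincide
          out[[length(out) + 1]] <- list(
            chrom1 = ch, pos1 = cursor[ch],
            chrom2 = ch2, pos2 = .CHROM_LENGTHS[[ch2]] - 2e6 - j * 1e5,
            svclass = "trans", clustered = FALSE)
          nev[ch2] <- nev[ch2] + 1L
        } else {
          sz <- sample(sizes, 1)
          out[[length(out) + 1]] <- list(
            chrom1 = ch, pos1 = cursor[ch],
            chrom2 = ch, pos2 = cursor[ch] + sz,
            svclass = ty, clustered = FALSE)
        }
        cursor[ch] <- cursor[ch] + spacing
        nev[ch] <- nev[ch] + 1L
      }
    }
    out
  })

  df <- do.call(rbind, lapply(rec, as.data.frame, stringsAsFactors = FALSE))
  strands <- t(vapply(df$svclass, function(cl) .SV_STRANDS[[cl]],
                      character(2)))
  bedpe <- data.frame(
    chrom1 = df$chrom1,
    start1 = as.integer(df$pos1 - 1), end1 = as.integer(df$pos1),
    chrom2 = df$chrom2,
    start2 = as.integer(df$pos2 - 1), end2 = as.integer(df$pos2),
    strand1 = strands[, 1], strand2 = strands[, 2],
    svclass = df$svclass, sample = sample_id,
    stringsAsFactors = FALSE
  )
  file <- file.path(dir, paste0(prefix, ".bedpe"))
  utils::write.table(bedpe, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  size <- ifelse(df$chrom1 == df$chrom2, abs(df$pos2 - df$pos1), NA)
  labels <- mapply(classify_sv, df$svclass, size, df$clustered)
  truth <- data.frame(record_id = seq_len(nrow(df)),
                      intended_channel = unname(labels),
                      intended_clustered = df$clustered,
                      stringsAsFactors = FALSE)
  truth_file <- file.path(dir, paste0(prefix, ".truth.tsv"))
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_file <- .write_fixture_meta(dir, prefix, scenario, n_events, seed)

  counts <- table(factor(labels, levels = sv32_channels()))
  list(file = file, truth_file = truth_file, meta_file = meta_file,
       truth = truth,
       counts = setNames(as.integer(counts), names(counts)))
}
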