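# Demultiplexing, UMI extraction, adapter trimming, paired-end merging,
# quality filtering.

test_that("demultiplexing assigns within one mismatch and rejects ambiguity", {
  bc <- tibble::tibble(sample = c("s1", "s2"), barcode = c("AAAAAA", "TTTTTT"))
  reads <- make_reads(rep("ACGT", 4))
  idx <- c("AAAAAA",      # exact
           "AAAAAT",      # one mismatch from s1, five from s2
           "AAATTT",      # three from both: unassigned
           "TTTTTA")      # one mismatch from s2
  out <- demultiplex(reads, bc, index = idx)
  expect_identical(out$sample, c("s1", "s1", NA, "s2"))
  cnt <- attr(out, "demux_counts")
  expect_equal(unname(cnt["assigned"] + cnt["unassigned"]), nrow(reads))
})

test_that("indices within distance 1 of two barcodes stay unassigned", {
  # enumerate all 1-neighbours of two distance-2 barcodes; any index near both
  # must be ambiguous
  bc <- tibble::tibble(sample = c("s1", "s2"), barcode = c("AACC", "AAGC"))
  expect_warning(out <- demultiplex(make_reads("ACGT"), bc, index = "AATC"),
                 "distance")
  # AATC is distance 1 from both AACC and AAGC
  expect_true(is.na(out$sample))
})

test_that("demultiplex validates index length", {
  bc <- tibble::tibble(sample = "s1", barcode = "AAAA")
  expect_error(demultiplex(make_reads("ACGT"), bc, index = "AAAAAA"), "length")
})

test_that("UMI extraction trims prefixes, parses headers, discards N-UMIs", {
  r <- make_reads(strrep("ACGT", 10), qual = strrep("I", 40))
  out <- extract_umi(r, umi_scheme("read_prefix", 8))
  expect_equal(nchar(out$bases), 32)
  expect_equal(nchar(out$qual), 32)
  expect_identical(out$umi, "ACGTACGT")

  rh <- tibble::tibble(read_id = "m1.1:ACGTACGTACGT", bases = "AAAA", qual = "IIII")
  out2 <- extract_umi(rh, umi_scheme("header"))
  expect_identical(out2$umi, "ACGTACGTACGT")
  expect_identical(out2$bases, "AAAA")

  rn <- make_reads(c("NNNNACGTACGT", "ACGTACGTACGT"))
  out3 <- extract_umi(rn, umi_scheme("read_prefix", 4))
  expect_equal(nrow(out3), 1)
  expect_equal(nrow(attr(out3, "umi_discarded")), 1)
})

test_that("simulated molecules receive distinct extracted UMIs", {
  cfg <- scenario_config("uditas_aav", seed = 9, n_molecules = 1000,
                         mixture = c(wild_type = 1), false_priming_fraction = 0,
                         error_rate = 0, q20_fraction = 0)
  mols <- simulate_molecules(cfg)
  sq <- amplify_and_sequence(mols, cfg)
  reads <- extract_umi(sq$r2, umi_scheme("header"))
  expect_equal(length(unique(reads$umi)), 1000)
})

test_that("3' adapter trimming matches a brute-force overlap oracle", {
  adapter <- "AGATCGGAAGAGC"
  set.seed(10)
  core <- random_dna(30)
  # full adapter appended
  out <- trim_adapter_3p(make_reads(paste0(core, adapter)), adapter)
  expect_identical(out$bases, core)
  # 5-base adapter prefix at the end
  out5 <- trim_adapter_3p(make_reads(paste0(core, substr(adapter, 1, 5))), adapter)
  expect_identical(out5$bases, core)
  # no adapter: unchanged (allow rare chance suffix match of >= 3)
  clean <- paste0(core, "TTTT")
  out0 <- trim_adapter_3p(make_reads(clean), adapter)
  expect_identical(out0$bases, clean)
  # brute-force oracle over random reads
  for (i in 1:30) {
    read <- random_dna(25)
    got <- trim_adapter_3p(make_reads(read), adapter)$bases
    best <- 0
    for (o in 3:min(25, nchar(adapter))) {
      mm <- sum(utf8ToInt(substr(read, 25 - o + 1, 25)) !=
                  utf8ToInt(substr(adapter, 1, o)))
      if (mm <= floor(o * 0.1)) best <- o
    }
    expect_identical(got, substr(read, 1, 25 - best))
  }
})

test_that("pair merging obeys overlap arithmetic and the higher-quality rule", {
  set.seed(11)
  frag <- random_dna(200)
  r1 <- make_reads(substr(frag, 1, 150))
  r2 <- make_reads(revcomp(substr(frag, 51, 200)))
  m <- merge_pairs(r1, r2)
  expect_identical(m$bases, frag)
  expect_equal(m$overlap_len, 100)
  expect_equal(nchar(m$bases), 150 + 150 - m$overlap_len)

  # disagreeing column: Q38 "A" beats Q12 "G"; column quality is the max
  b1 <- paste0(substr(frag, 1, 150))
  substr(b1, 100, 100) <- "A"
  b2 <- substr(frag, 51, 200)
  substr(b2, 50, 50) <- "G"
  q1 <- strrep(phred_encode(38), 150)
  q2 <- strrep(phred_encode(12), 150)
  m2 <- merge_pairs(tibble::tibble(read_id = "p", bases = b1, qual = q1),
                    tibble::tibble(read_id = "p", bases = revcomp(b2), qual = q2))
  expect_identical(substr(m2$bases, 100, 100), "A")
  expect_equal(phred_decode(m2$qual)[100], 38)
})

test_that("merging is symmetric under mate swap", {
  set.seed(12)
  for (i in 1:10) {
    frag <- random_dna(180)
    r1 <- make_reads(substr(frag, 1, 150))
    r2 <- make_reads(revcomp(substr(frag, 31, 180)))
    m12 <- merge_pairs(r1, r2)
    m21 <- merge_pairs(r2, r1)
    expect_identical(m21$bases, revcomp(m12$bases))
  }
})

test_that("merge recovers true fragments from simulated error-bearing pairs", {
  set.seed(13)
  n <- 400
  frags <- vapply(1:n, function(i) random_dna(180), character(1))
  add_err <- function(x) {
    k <- rbinom(1, nchar(x), 0.001)
    if (k > 0) for (p in sample.int(nchar(x), k))
      substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
    x
  }
  b1 <- vapply(substr(frags, 1, 150), add_err, character(1), USE.NAMES = FALSE)
  b2 <- vapply(revcomp(substr(frags, 31, 180)), add_err, character(1), USE.NAMES = FALSE)
  m <- merge_pairs(make_reads(b1), make_reads(b2))
  ok <- m$overlap_len == 120
  expect_gte(mean(ok), 0.99)
})

test_that("quality filter applies the exact mean-30 / min-24 boundaries", {
  mk <- function(q) tibble::tibble(read_id = "x", bases = strrep("A", length(q)),
                                   qual = phred_encode(q))
  keep <- function(q) nrow(quality_filter(mk(q))) == 1
  expect_true(keep(rep(30, 10)))          # mean exactly 30: kept
  expect_false(keep(rep(29, 10)))         # mean 29: removed
  expect_false(keep(c(23, rep(40, 9))))   # one base below 24: removed
  expect_true(keep(c(24, rep(40, 9))))    # min exactly 24: kept
  expect_false(keep(c(28, 30)))           # mean 29
  expect_true(keep(c(24, 36)))            # mean 30, min 24
  expect_false(keep(integer(0)))          # empty read: discarded
})

test_that("quality decisions depend only on qualities, not bases", {
  set.seed(14)
  for (i in 1:20) {
    q <- sample(20:40, 30, replace = TRUE)
    b1 <- random_dna(30); b2 <- random_dna(30)
    d1 <- nrow(quality_filter(tibble::tibble(read_id = "x", bases = b1,
                                             qual = phred_encode(q))))
    d2 <- nrow(quality_filter(tibble::tibble(read_id = "x", bases = b2,
                                             qual = phred_encode(q))))
    expect_equal(d1, d2)
  }
})

test_that("FASTQ round-trips through write and read", {
  set.seed(15)
  r <- make_reads(c(random_dna(40), random_dna(35)),
                  qual = c(strrep("I", 40), paste0(strrep("5", 35))))
  f <- tempfile(fileext = ".fastq")
  write_fastq(r, f)
  back <- read_fastq(f)
  expect_identical(back$read_id, r$read_id)
  expect_identical(back$bases, r$bases)
  expect_identical(back$qual, r$qual)
})
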