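toy_barcodes <- data.frame(
  sample = c("S1", "S2", "S3"),
  barcode = c("ACGTAC", "TTTTTT", "GAGAGAGA"),
  population = c("P1", "P1", "P2"),
  stringsAsFactors = FALSE
)

test_that("exact barcode matches are assigned and stripped", {
  reads <- c(paste0("ACGTAC", strrep("A", 100)),
             paste0("TTTTTT", strrep("C", 100)))
  d <- demultiplex(reads, toy_barcodes)
  expect_equal(d$reads$S1, strrep("A", 100))
  expect_equal(d$reads$S2, strrep("C", 100))
  expect_length(d$unassigned, 0)
  expect_equal(d$tally$n_assigned + d$tally$n_unassigned, d$tally$n_input)
})

test_that("single-mismatch prefixes assign when unambiguous (Hamming-1 enumeration)", {
  ## every Hamming-1 neighbour of S1's barcode must land in S1: no other
  ## barcode is within distance 1 of any of them
  bc <- toy_barcodes$barcode[1]
  tail100 <- strrep("G", 100)
  neighbours <- character(0)
  for (p in 1:6) for (b in c("A", "C", "G", "T")) {
    if (substr(bc, p, p) != b) {
      mut <- bc
      substr(mut, p, p) <- b
      neighbours <- c(neighbours, mut)
    }
  }
  d <- demultiplex(paste0(neighbours, tail100), toy_barcodes)
  expect_equal(d$tally$n_assigned, length(neighbours))
  expect_length(d$reads$S1, length(neighbours))
  expect_true(all(d$reads$S1 == tail100))
})

test_that("reads two mismatches from every barcode stay unassigned", {
  read <- paste0("ACGGGC", strrep("T", 100)) # 2 from S1, >2 from others
  d <- demultiplex(read, toy_barcodes)
  expect_equal(d$tally$n_unassigned, 1L)
  expect_equal(d$unassigned, read)
})

test_that("ties at the minimal distance are unassigned, even across lengths", {
  amb <- data.frame(sample = c("A", "B"),
                    barcode = c("AAAAA", "AAAAAT"),
                    population = c("P1", "P1"), stringsAsFactors = FALSE)
  ## prefix AAAAA matches A exactly and B's 6-mer at distance <= 1
  read <- paste0("AAAAAT", strrep("G", 100))
  d <- demultiplex(read, amb, max_mismatch = 1)
  expect_equal(d$tally$n_unassigned, 1L)
})

test_that("strict demultiplexing is a subset of one-mismatch demultiplexing", {
  set.seed(20)
  reads <- vapply(1:300, function(i) {
    bc <- sample(toy_barcodes$barcode, 1)
    if (runif(1) < 0.5) { # inject one error somewhere in the prefix
      p <- sample(nchar(bc), 1)
      substr(bc, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    paste0(bc, paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""))
  }, character(1))
  d0 <- demultiplex(reads, toy_barcodes, max_mismatch = 0)
  d1 <- demultiplex(reads, toy_barcodes, max_mismatch = 1)
  for (s in toy_barcodes$sample) {
    expect_true(all(d0$reads[[s]] %in% d1$reads[[s]]))
  }
  expect_gte(d1$tally$n_assigned, d0$tally$n_assigned)
})

test_that("trimming truncates long reads and discards short ones", {
  r126 <- paste(sample(c("A", "C", "G", "T"), 126, TRUE), collapse = "")
  r100 <- strrep("A", 100)
  r80 <- strrep("C", 80)
  tr <- trim_reads(c(r126, r100, r80), 100)
  expect_equal(tr$n_discarded, 1L)
  expect_equal(tr$reads, c(substr(r126, 1, 100), r100))
})

test_that("tag counting collapses, aggregates per population and conserves reads", {
  s1 <- rep(strrep("A", 100), 3)
  s2 <- c(rep(strrep("A", 100), 5), strrep("G", 100))
  s3 <- rep(strrep("T", 100), 2)
  tab <- count_tags(list(S1 = s1, S2 = s2, S3 = s3), toy_barcodes)
  a_id <- tab$tags$tag_id[tab$tags$seq == strrep("A", 100)]
  expect_equal(tab$counts$count[tab$counts$tag_id == a_id &
                                  tab$counts$sample == "S1"], 3L)
  pc <- population_counts(tab)
  expect_equal(pc$count[pc$tag_id == a_id & pc$population == "P1"], 8L)
  expect_equal(total_reads(tab), length(s1) + length(s2) + length(s3))
  ## permutation invariance to read order
  tab2 <- count_tags(list(S1 = rev(s1), S2 = sample(s2), S3 = s3),
                     toy_barcodes)
  expect_identical(tab, tab2)
  ## unknown samples are a data error
  expect_error(count_tags(list(SX = s1), toy_barcodes), "absent")
})

test_that("tags round-trip through FASTQ", {
  tab <- count_tags(list(S1 = c(rep(strrep("A", 100), 2), strrep("G", 100))),
                    toy_barcodes)
  fq <- tempfile(fileext = ".fastq")
  tags_to_fastq(tab, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_setequal(as.character(back), tab$tags$seq)
  expect_match(names(back)[1], "count=")
  ## empty table gives an empty FASTQ
  empty <- count_tags(list(S1 = character(0)), toy_barcodes)
  fq2 <- tempfile(fileext = ".fastq")
  tags_to_fastq(empty, fq2)
  expect_length(Biostrings::readDNAStringSet(fq2, format = "fastq"), 0)
})

test_that("barcode tables are validated", {
  expect_error(read_barcode_table(data.frame(sample = "a", barcode = "ACG",
                                             population = "p")), "5-10")
  expect_error(read_barcode_table(data.frame(sample = c("a", "b"),
                                             barcode = c("ACGTA", "ACGTA"),
                                             population = "p")), "unique")
  expect_error(read_barcode_table(data.frame(sample = "a",
                                             barcode = "ACGTN",
                                             population = "p")), "alphabet")
})
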