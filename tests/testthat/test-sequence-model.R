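test_that("load_genome parses FASTA + GFF3 and preserves gene counts", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  withr::with_seed(1, writeLines(c(">chr1", random_dna(3000)), fa))
  writeLines(c(
    "##gff-version 3",
    "chr1\tsim\tgene\t201\t700\t.\t+\t.\tID=gA",
    "chr1\tsim\tgene\t720\t1300\t.\t+\t.\tID=gB",
    "chr1\tsim\tgene\t1500\t2100\t.\t-\t.\tID=gC",
    "chr1\tsim\tgene\t2400\t2900\t.\t-\t.\tID=gD"), gff)
  b <- load_genome(fa, gff)
  expect_s3_class(b, "genome_bundle")
  expect_equal(nrow(b$genes), 4)
  expect_equal(b$genes$gene_id, c("gA", "gB", "gC", "gD"))  # coordinate order
  expect_true(all(b$genes$start <= b$genes$end))
})

test_that("load_genome rejects malformed annotations with informative errors", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  withr::with_seed(2, writeLines(c(">chr1", random_dna(1000)), fa))
  tsv <- file.path(dir, "genes.tsv")

  writeLines(c("gene_id\tstart\tend\tstrand", "gX\t500\t400\t+"), tsv)
  expect_error(load_genome(fa, tsv), "end < start")

  writeLines(c("gene_id\tstart\tend\tstrand\treplicon",
               "gX\t100\t200\t+\tchr2"), tsv)
  expect_error(load_genome(fa, tsv), "chr2")
})

test_that("assemble_tus honors an explicit TU table and validates coverage", {
  b <- tiny_bundle()
  tt <- tibble::tibble(tu_id = c("TU1", "TU2", "TU3"),
                       gene_ids = c("gA,gB", "gC", "gD"))
  tus <- assemble_tus(b$genes, tt)
  expect_equal(nrow(tus), 3)
  expect_equal(tus$gene_ids[[1]], c("gA", "gB"))
  expect_equal(tus$strand, c("+", "-", "-"))

  expect_error(assemble_tus(b$genes, tibble::tibble(
    tu_id = c("T1", "T2"), gene_ids = c("gA,gB,gA", "gC,gD"))), "more than once")
  expect_error(assemble_tus(b$genes, tibble::tibble(
    tu_id = "T1", gene_ids = "gA,gB,gZ,gC,gD")), "unknown")
  expect_error(assemble_tus(b$genes, tibble::tibble(
    tu_id = "T1", gene_ids = "gA,gB")), "does not cover")
})

test_that("fallback TU heuristic merges same-strand genes within the gap", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), genome_id = "t", replicon_id = "chr",
    start = c(100L, 420L), end = c(400L, 900L), strand = "+")
  tus <- assemble_tus(genes, gap_threshold = 50)  # gap = 19
  expect_equal(nrow(tus), 1)
  expect_equal(tus$gene_ids[[1]], c("g1", "g2"))

  genes$strand <- c("+", "-")
  tus2 <- assemble_tus(genes, gap_threshold = 50)
  expect_equal(nrow(tus2), 2)

  genes$strand <- c("+", "+")
  tus3 <- assemble_tus(genes, gap_threshold = 18)  # gap 19 > 18
  expect_equal(nrow(tus3), 2)

  # minus-strand TU lists genes 5'->3' on the coding strand
  genes$strand <- c("-", "-")
  tus4 <- assemble_tus(genes, gap_threshold = 50)
  expect_equal(tus4$gene_ids[[1]], c("g2", "g1"))
})

test_that("extract_upstream applies the cap and coding extension on both strands", {
  seq_chr <- withr::with_seed(3, random_dna(3000))
  genes <- tibble::tibble(
    gene_id = c("up", "g1"), replicon_id = "chr",
    start = c(1L, 2001L), end = c(1000L, 2500L), strand = "+")
  b <- genome_bundle("t", c(chr = seq_chr), genes)
  tus <- assemble_tus(b$genes, tibble::tibble(tu_id = c("TUup", "TU1"),
                                              gene_ids = c("up", "g1")))
  r <- extract_upstream(tus, b)
  r1 <- r[r$tu_id == "TU1", ]
  # 1000 bp inter-TU truncated to the immediate upstream 800, + 40 coding
  expect_equal(r1$length, 840L)
  expect_equal(r1$intertu_length, 800L)
  expect_equal(c(r1$start, r1$end), c(1201L, 2040L))
  expect_equal(r1$sequence, substr(seq_chr, 1201, 2040))

  # minus strand: gene 500-900, next gene body starts at 1401 -> 500 bp
  genes2 <- tibble::tibble(
    gene_id = c("g1", "down"), replicon_id = "chr",
    start = c(500L, 1401L), end = c(900L, 2000L), strand = c("-", "+"))
  b2 <- genome_bundle("t2", c(chr = seq_chr), genes2)
  tus2 <- assemble_tus(b2$genes, tibble::tibble(tu_id = c("TU1", "TUd"),
                                                gene_ids = c("g1", "down")))
  r2 <- extract_upstream(tus2, b2)
  r21 <- r2[r2$tu_id == "TU1", ]
  expect_equal(r21$length, 540L)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(r21$sequence,
               paste0(rc(substr(seq_chr, 901, 1400)),
                      rc(substr(seq_chr, 861, 900))))

  # zero upstream: gene starting at position 1
  genes3 <- tibble::tibble(gene_id = "g1", replicon_id = "chr",
                           start = 1L, end = 600L, strand = "+")
  b3 <- genome_bundle("t3", c(chr = seq_chr), genes3)
  tus3 <- assemble_tus(b3$genes)
  r3 <- extract_upstream(tus3, b3)
  expect_equal(r3$length, 40L)
  expect_true(r3$flagged)
})

test_that("upstream regions never exceed cap + coding extension", {
  sim <- simulate_genomes(simulation_config(n_genomes = 1, n_tus = 60,
                                            seed = 11))
  r <- sim$bundles$G1$regions
  expect_true(all(r$length <= 800 + 40))
  expect_true(all(nchar(r$sequence) == r$length))
})

test_that("compute_background counts inter-TU bases with pseudocounts", {
  reg <- function(s) tibble::tibble(genome_id = "t", kind = "interTU",
                                    sequence = s, intertu_length = nchar(s))
  q1 <- compute_background(reg("ACGT"))
  expect_equal(unname(q1[c("A", "C", "G", "T")]), rep(0.25, 4))
  q2 <- compute_background(reg("AAAA"))
  expect_equal(unname(q2["A"]), 5 / 8)
  expect_equal(unname(q2["C"]), 1 / 8)
  expect_error(compute_background(reg("NNNN")), "informative")
  expect_error(compute_background(reg("ACGT")[0, ]), "no inter-TU")
  # sums to 1 tightly
  q3 <- compute_background(reg(withr::with_seed(4, random_dna(5000, gc = 0.6))))
  expect_lt(abs(sum(q3) - 1), 1e-12)
})

test_that("BED round-trip preserves intervals and strands", {
  sim <- simulate_genomes(simulation_config(n_genomes = 1, n_tus = 30,
                                            seed = 12))
  r <- sim$bundles$G1$regions
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(r, path)
  back <- read_regions_bed(path)
  back <- back[match(r$region_id, back$region_id), ]
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)
  expect_equal(back$strand, r$strand)
})
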