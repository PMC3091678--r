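test_that("window scores match their closed forms", {
  p1 <- build_profile("AGTACTAATGTTCT", uniform_q)
  expect_equal(score_window(p1, "AGTACTAATGTTCT", uniform_q),
               14 * log(1.6), tolerance = 1e-12)
  # one mismatching position swaps one log(1.6) for log(0.8)
  expect_equal(score_window(p1, "AGTACTAATGTACT", uniform_q),
               13 * log(1.6) + log(0.8), tolerance = 1e-12)
  expect_error(score_window(p1, "AGTACTAATGTNCT", uniform_q), "non-ACGT")
})

test_that("an uninformative column contributes nothing", {
  # 4 sites covering all bases at position 1: that column is uniform,
  # I_1 = 0, so the base read there cannot move the score
  sites <- c("AACA", "CACA", "GACA", "TACA")
  p <- build_profile(sites, uniform_q)
  expect_equal(p$I[1], 0, tolerance = 1e-12)
  s_a <- score_window(p, "AACA", uniform_q)
  s_t <- score_window(p, "TACA", uniform_q)
  expect_equal(s_a, s_t, tolerance = 1e-12)
})

test_that("best_site recovers planted windows and honors strandedness", {
  p <- build_profile("AGTACTAATGTTCT", uniform_q)
  withr::local_seed(7)
  flank <- random_dna(50)
  flank2 <- random_dna(50)
  region <- paste0(flank, "AGTACTAATGTTCT", flank2)
  hit <- best_site(region, p, uniform_q)
  expect_equal(hit$offset, 50)
  expect_equal(hit$site, "AGTACTAATGTTCT")

  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hit_rc <- best_site(rc(region), p, uniform_q)
  expect_equal(hit_rc$s_M, hit$s_M)
  expect_equal(hit_rc$strand_of_window, "-")
  expect_equal(hit_rc$site, "AGTACTAATGTTCT")  # matched spelling

  # shorter than l: no-hit sentinel
  short <- best_site("ACGTACGTACGTA", p, uniform_q)
  expect_false(short$valid)
  expect_true(is.na(short$s_M))

  # all windows contain N
  enn <- best_site(paste0(strrep("A", 10), "N", strrep("A", 10)), p, uniform_q)
  expect_false(enn$valid)
})

test_that("scanner equals brute-force enumeration on random regions", {
  p <- build_profile(lexa_sites(), uniform_q)
  q <- c(A = 0.3, C = 0.2, G = 0.22, T = 0.28)
  withr::local_seed(21)
  for (i in 1:200) {
    region <- random_dna(60, gc = stats::runif(1, 0.3, 0.7))
    got <- best_site(region, p, q)
    want <- oracle_best_site(p, region, q)
    expect_identical(got$s_M, want$s_M)
    expect_identical(got$offset, as.integer(want$offset))
    expect_identical(got$strand_of_window, want$strand)
  }
})

test_that("mutating the best window toward the column argmax never lowers s_M", {
  p <- build_profile(lexa_sites(), uniform_q)
  withr::local_seed(33)
  for (i in 1:20) {
    region <- random_dna(80)
    hit <- best_site(region, p, uniform_q)
    argmax <- rownames(p$p)[apply(p$p, 2, which.max)]
    s_prev <- hit$s_M
    win <- strsplit(hit$site, "")[[1]]
    for (pos in sample(14)) {
      win[pos] <- argmax[pos]
      s_new <- score_window(p, paste(win, collapse = ""), uniform_q)
      expect_gte(s_new, s_prev - 1e-12)
      s_prev <- s_new
    }
  }
})

test_that("orthology bonus follows the similarity-weighted average and max rule", {
  site <- "AGTACTAATGTTCT"
  # one gene, one reference genome, identical best site: full weight
  os <- tibble::tibble(gene = "g1", genome = "G2", site = site, s_M = 6.0)
  b <- orthology_bonus(site, os)
  expect_equal(b$A_max, 6.0)
  expect_equal(b$bonus_gene, "g1")

  # one mismatch: weight (l-1)/l
  os2 <- tibble::tibble(gene = "g1", genome = "G2",
                        site = "AGTACTAATGTACT", s_M = 6.0)
  expect_equal(orthology_bonus(site, os2)$A_max, 13 / 14 * 6.0)

  # two genes: g1 averages 2.0 over two orthologs, g2 has 3.5 from one
  os3 <- tibble::tibble(
    gene = c("g1", "g1", "g2"), genome = c("G2", "G3", "G2"),
    site = site, s_M = c(1.5, 2.5, 3.5))
  b3 <- orthology_bonus(site, os3)
  expect_equal(b3$A_max, 3.5)
  expect_equal(b3$bonus_gene, "g2")

  # no orthologs: zero, not an error
  b0 <- orthology_bonus(site, NULL)
  expect_equal(b0$A_max, 0)

  # negative orthologous scores enter as-is
  osn <- tibble::tibble(gene = "g1", genome = "G2", site = site, s_M = -2)
  expect_equal(orthology_bonus(site, osn)$A_max, -2)

  expect_equal(refined_score(4.2, 0), 4.2)
  expect_equal(refined_score(4.2, 6.0), 10.2)
})

test_that("scan_genome ranks planted TUs on top and is reproducible", {
  sim <- simulate_genomes(simulation_config(
    n_genomes = 3, n_tus = 60, n_planted_tus = 6,
    ortholog_coverage = 0.5, seed = 77))
  p <- build_profile(lexa_sites(), sim$bundles$G1$background)
  hits <- scan_genome(sim$bundles$G1, p, sim$ortholog_map,
                      sim$bundles[c("G2", "G3")])
  planted <- sim$truth$tu_id[sim$truth$genome == "G1"]
  expect_length(planted, 6)
  expect_setequal(utils::head(hits$tu_id, 6), planted)
  # additivity of the refined score
  expect_equal(hits$s, hits$s_M + hits$A_max)

  hits2 <- scan_genome(sim$bundles$G1, p, sim$ortholog_map,
                       sim$bundles[c("G2", "G3")])
  expect_identical(hits, hits2)

  # without reference genomes every score reduces to s_M
  solo <- scan_genome(sim$bundles$G1, p)
  expect_equal(solo$s, solo$s_M)
  expect_true(all(solo$A_max[solo$valid] == 0))
})

test_that("hits flatten to TSV and sites to BED", {
  sim <- simulate_genomes(simulation_config(n_genomes = 1, n_tus = 20,
                                            n_planted_tus = 3, seed = 15))
  p <- build_profile(lexa_sites(), sim$bundles$G1$background)
  hits <- scan_genome(sim$bundles$G1, p)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(hits))
  expect_true(all(c("tu_id", "site", "s_M", "A_max", "s", "p_value") %in%
                    names(back)))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(hits, sim$bundles$G1, bed)
  b <- read_regions_bed(bed)
  expect_equal(nrow(b), sum(hits$valid))
})
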