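mk_hits <- function(tus, genes_per_tu, pvals) {
  tibble::tibble(
    tu_id = tus,
    gene_ids = genes_per_tu,
    s = rev(seq_along(tus)) + 10, s_M = 1, A_max = 0,
    p_value = pvals, valid = TRUE)
}

test_that("regulon membership is the gene union of passing TUs", {
  hits <- mk_hits(c("T1", "T2", "T3"),
                  list(c("a1", "a2"), c("b1", "b2", "b3"), "c1"),
                  c(0.001, 0.005, 0.5))
  reg <- predict_regulon(hits, "G1", threshold = 0.01)
  expect_equal(nrow(reg), 5)
  expect_setequal(reg$gene_id, c("a1", "a2", "b1", "b2", "b3"))

  none <- predict_regulon(mk_hits("T1", list("a1"), 0.9), "G1")
  expect_equal(nrow(none), 0)

  # monotone in the threshold
  hits2 <- mk_hits(c("T1", "T2"), list("a1", "b1"), c(0.005, 0.03))
  r01 <- predict_regulon(hits2, "G1", 0.01)
  r05 <- predict_regulon(hits2, "G1", 0.05)
  expect_true(all(r01$gene_id %in% r05$gene_id))
})

omap_pairs <- function(pairs) {
  tibble::tibble(genome_a = "Gi", gene_a = pairs[, 1],
                 genome_b = "Gj", gene_b = pairs[, 2],
                 evalue_ab = 1e-50, evalue_ba = 1e-50)
}

test_that("regulon conservation counts ortholog pairs Jaccard-style", {
  m <- omap_pairs(cbind(paste0("i", 1:4), paste0("j", 1:4)))
  # |Ri| = 4, |Rj| = 3, 2 ortholog pairs shared -> 2 / (4 + 3 - 2) = 0.4
  c1 <- regulon_conservation(paste0("i", 1:4), c("j1", "j2", "jx"), m,
                             "Gi", "Gj")
  expect_equal(c1, 0.4)

  # identical fully orthologous regulons -> 1
  expect_equal(regulon_conservation(paste0("i", 1:3), paste0("j", 1:3), m,
                                    "Gi", "Gj"), 1)
  # disjoint -> 0
  expect_equal(regulon_conservation(c("i1"), c("j2"), m, "Gi", "Gj"), 0)
  # both empty -> undefined, flagged
  expect_warning(cc <- regulon_conservation(character(0), character(0), m,
                                            "Gi", "Gj"), "undefined")
  expect_true(is.na(cc))
  # symmetric in its arguments
  c_rev <- regulon_conservation(c("j1", "j2", "jx"), paste0("i", 1:4), m,
                                "Gj", "Gi")
  expect_equal(c_rev, c1)
})

test_that("distance matrix takes reciprocals with a capped zero rule", {
  m <- dplyr::bind_rows(
    omap_pairs(cbind(paste0("i", 1:4), paste0("j", 1:4))),
    tibble::tibble(genome_a = "Gi", gene_a = paste0("i", 1:4),
                   genome_b = "Gk", gene_b = paste0("k", 1:4),
                   evalue_ab = 1e-50, evalue_ba = 1e-50),
    tibble::tibble(genome_a = "Gj", gene_a = paste0("j", 1:4),
                   genome_b = "Gk", gene_b = paste0("k", 1:4),
                   evalue_ab = 1e-50, evalue_ba = 1e-50))
  regs <- list(Gi = paste0("i", 1:4),
               Gj = c("j1", "j2"),         # c(Gi,Gj) = 2/(4+2-2) = 0.5
               Gk = c("k9"))               # no shared orthologs -> c = 0
  cm <- conservation_distance_matrix(regs, m)
  expect_equal(cm$c["Gi", "Gj"], 0.5)
  expect_equal(cm$d["Gi", "Gj"], 2)
  expect_equal(cm$c["Gi", "Gk"], 0)
  expect_equal(unname(diag(cm$d)), c(0, 0, 0))
  expect_true(isSymmetric(unname(cm$c)))
  # zero-conservation pairs get 10x the largest finite distance
  expect_equal(cm$d["Gi", "Gk"], 10 * 2)
  # c = 0.4 -> d = 2.5
  regs2 <- list(Gi = paste0("i", 1:4), Gj = c("j1", "j2", "jx"),
                Gk = paste0("k", 1:4))
  cm2 <- conservation_distance_matrix(regs2, m)
  expect_equal(cm2$d["Gi", "Gj"], 2.5)
  # c = 1 -> d = 1 off-diagonal
  expect_equal(cm2$c["Gi", "Gk"], 1)
  expect_equal(cm2$d["Gi", "Gk"], 1)
})

test_that("neighbor joining recovers an additive 4-taxon tree", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> pairwise path lengths
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  # the AB|CD split: A and B must be sisters
  best <- ls_best_topology(d)
  expect_equal(sort(rownames(d)[best$split]), c("A", "B"))
  expect_equal(best$rss, 0, tolerance = 1e-20)
  pair_ab <- ape::getMRCA(ape::root(tr, "C"), c("A", "B"))
  desc <- ape::extract.clade(ape::root(tr, "C"), pair_ab)$tip.label
  expect_setequal(desc, c("A", "B"))
  # branch lengths match the generating tree (tips 1,2,3,1; internal 1)
  tip_len <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(unname(tip_len[c("A", "B", "C", "D")]), c(1, 2, 3, 1),
               tolerance = 1e-9)
  expect_equal(sum(tr$edge.length), 8, tolerance = 1e-9)
  # least-squares oracle agrees with the NJ branch lengths
  expect_equal(sort(unname(best$coef)), sort(tr$edge.length),
               tolerance = 1e-9)
})

test_that("neighbor joining handles small and permuted inputs", {
  # ultrametric 3-taxon: star with equal branches
  d3 <- matrix(2, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  diag(d3) <- 0
  t3 <- neighbor_joining(d3)
  expect_equal(sort(t3$edge.length), c(1, 1, 1))

  expect_error(neighbor_joining(d3[1:2, 1:2]), "at least 3")

  # taxon order permutation gives an isomorphic tree
  d <- matrix(c(0, 3, 5, 3, 3, 0, 6, 4, 5, 6, 0, 4, 3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  perm <- c(3, 1, 4, 2)
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  # negative branch lengths are clamped
  dneg <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 1, 6, 6, 1, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  tn <- neighbor_joining(dneg)
  expect_true(all(tn$edge.length >= 0))
})

test_that("PHYLIP distance files round-trip to 6 decimals", {
  withr::local_seed(10)
  d <- matrix(stats::runif(25, 1, 9), 5, 5)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("Gen", 1:5), paste0("Gen", 1:5))
  path <- withr::local_tempfile(fileext = ".phylip")
  write_phylip_dist(d, path)
  back <- read_phylip_dist(path)
  expect_equal(back, d, tolerance = 1e-6)
  expect_equal(rownames(back), rownames(d))
})
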