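STOP_CODONS <- c("TAA", "TAG", "TGA")

# uniform sense-codon (stop-free) sequence of length L, coding-strand
.codon_seq <- function(L, codons = NULL) {
  if (is.null(codons)) {
    codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                    paste, collapse = "")
    codons <- setdiff(codons, STOP_CODONS)
  }
  s <- paste(sample(codons, ceiling(L / 3), replace = TRUE), collapse = "")
  substr(s, 1, L)
}

.gc_seq <- function(L, gc) {
  paste(sample(DNA_BASES, L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Configuration for the synthetic multi-genome generator
#'
#' Defines the statistical structure of the simulated genomes: TU-organized
#' gene layouts, stop-free codon-structured coding sequence, intergenic
#' background of chosen GC content, cross-genome ortholog families, and
#' motif instances sampled from a ground-truth PWM planted consistently in
#' the upstream regions of designated regulon TUs.
#'
#' @param n_genomes number of genomes.
#' @param n_tus transcription units per genome.
#' @param genes_per_tu named probability vector over genes-per-TU counts.
#' @param gene_length_range min/max gene length (bp; rounded to codons).
#' @param intergenic_range min/max inter-TU spacer length (bp).
#' @param intra_tu_gap_range min/max gap between genes inside a TU (bp).
#' @param gc_content GC fraction of intergenic sequence.
#' @param truth_sites character vector of equal-length sites defining the
#'   ground-truth PWM (default: the packaged LexA boxes, [lexa_sites()]).
#' @param n_planted_tus number of TUs that receive one planted site per
#'   genome in which their group is present.
#' @param planting_fidelity per-base mutation probability applied to each
#'   planted site after sampling it from the PWM.
#' @param ortholog_coverage fraction of non-planted gene families linked as
#'   orthologs across all genomes (planted families are always linked).
#' @param genome_groups integer group label per genome; planted TUs are
#'   split round-robin over groups and planted only in their group's
#'   genomes (default: one group, planted everywhere).
#' @param matched_composition generate intergenic sequence with the same
#'   codon-structured process as coding sequence, so the null model's
#'   composition matches the scanned regions exactly (calibration checks).
#' @param cap upstream window cap used to validate planting positions (bp).
#' @param seed RNG seed (mandatory).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genomes = 3, n_tus = 200,
                              genes_per_tu = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                              gene_length_range = c(300, 900),
                              intergenic_range = c(60, 250),
                              intra_tu_gap_range = c(5, 30),
                              gc_content = 0.5,
                              truth_sites = NULL,
                              n_planted_tus = 0,
                              planting_fidelity = 0.02,
                              ortholog_coverage = 0.3,
                              genome_groups = NULL,
                              matched_composition = FALSE,
                              cap = 800, seed) {
  if (missing(seed)) abort("a seed is mandatory for simulation")
  stopifnot(n_genomes >= 1, n_tus >= 1,
            abs(sum(genes_per_tu) - 1) < 1e-8, all(genes_per_tu >= 0),
            gc_content > 0, gc_content < 1,
            planting_fidelity >= 0, planting_fidelity <= 1,
            ortholog_coverage >= 0, ortholog_coverage <= 1,
            n_planted_tus <= n_tus)
  genome_groups <- genome_groups %||% rep(1L, n_genomes)
  stopifnot(length(genome_groups) == n_genomes)
  truth_sites <- truth_sites %||% lexa_sites()$sequence
  structure(list(n_genomes = n_genomes, n_tus = n_tus,
                 genes_per_tu = genes_per_tu,
                 gene_length_range = gene_length_range,
                 intergenic_range = intergenic_range,
                 intra_tu_gap_range = intra_tu_gap_range,
                 gc_content = gc_content, truth_sites = truth_sites,
                 n_planted_tus = n_planted_tus,
                 planting_fidelity = planting_fidelity,
                 ortholog_coverage = ortholog_coverage,
                 genome_groups = as.integer(genome_groups),
                 matched_composition = matched_composition,
                 cap = cap, seed = seed),
            class = "simulation_config")
}

# sample one site from the per-column base frequencies of the truth sites,
# then mutate each base independently with the given probability
.sample_site <- function(freq, mut_rate) {
  l <- ncol(freq)
  s <- vapply(seq_len(l), function(i)
    sample(DNA_BASES, 1, prob = freq[, i]), character(1))
  mut <- runif(l) < mut_rate
  if (any(mut)) {
    s[mut] <- vapply(s[mut], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
  }
  paste(s, collapse = "")
}

#' Simulate genomes with known orthologs and planted motif instances
#'
#' Generates `n_genomes` single-replicon genomes sharing one TU/gene-family
#' skeleton, an ortholog map derived from the shared family labels, and a
#' truth table of planted sites. Coding sequence is codon-structured
#' (uniform stop-free codons); intergenic sequence is i.i.d. at the chosen
#' GC content (or codon-structured under `matched_composition`). Each
#' planted TU carries one PWM-sampled site per member genome, placed
#' uniformly inside the extractable upstream window. Identical seeds give
#' identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `bundles` (named list of prepared [genome_bundle()]s),
#'   `ortholog_map`, `truth` (tibble: genome, tu_id, family, sequence,
#'   genomic `start`/`end`, `strand`, `offset` from the first coding base,
#'   negative upstream), and the echoed `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::local_seed(config$seed)
  cfg <- config
  l_site <- unique(nchar(cfg$truth_sites))
  stopifnot(length(l_site) == 1)
  site_mat <- do.call(rbind, strsplit(cfg$truth_sites, ""))
  freq <- vapply(seq_len(l_site), function(i)
    tabulate(factor(site_mat[, i], levels = DNA_BASES), nbins = 4) /
      nrow(site_mat), numeric(4))

  codons <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                          paste, collapse = ""), STOP_CODONS)

  # shared skeleton: gene counts per TU, family conservation, planting
  counts_tu <- sample(as.integer(names(cfg$genes_per_tu)), cfg$n_tus,
                      replace = TRUE, prob = cfg$genes_per_tu)
  fam <- tibble(tu = rep(seq_len(cfg$n_tus), counts_tu),
                gene_in_tu = unlist(lapply(counts_tu, seq_len)))
  fam$family <- sprintf("fam_t%04d_g%d", fam$tu, fam$gene_in_tu)
  planted_tus <- if (cfg$n_planted_tus > 0)
    sort(sample(cfg$n_tus, cfg$n_planted_tus)) else integer(0)
  groups <- sort(unique(cfg$genome_groups))
  planted_group <- setNames(rep(groups, length.out = length(planted_tus)),
                            planted_tus)
  fam$conserved <- runif(nrow(fam)) < cfg$ortholog_coverage |
    fam$tu %in% planted_tus

  genome_ids <- sprintf("G%d", seq_len(cfg$n_genomes))
  bundles <- list()
  truth <- list()

  for (gidx in seq_len(cfg$n_genomes)) {
    gid <- genome_ids[gidx]
    strands <- sample(c("+", "-"), cfg$n_tus, replace = TRUE)
    segs <- character(0)
    genes_rows <- list()
    cursor <- 0L
    for (t in seq_len(cfg$n_tus)) {
      ig <- sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1)
      segs <- c(segs, if (cfg$matched_composition) .codon_seq(ig, codons)
                      else .gc_seq(ig, cfg$gc_content))
      cursor <- cursor + ig
      ng <- counts_tu[t]
      glens <- 3L * sample((cfg$gene_length_range[1] %/% 3):
                             (cfg$gene_length_range[2] %/% 3), ng,
                           replace = TRUE)
      gaps <- if (ng > 1)
        sample(cfg$intra_tu_gap_range[1]:cfg$intra_tu_gap_range[2], ng - 1,
               replace = TRUE) else integer(0)
      # genome order of TU members: 5'->3' means left-to-right for '+',
      # right-to-left for '-'
      order_in_genome <- if (strands[t] == "+") seq_len(ng) else rev(seq_len(ng))
      for (k in seq_len(ng)) {
        j <- order_in_genome[k]
        cds <- .codon_seq(glens[j], codons)
        seg <- if (strands[t] == "+") cds else revcomp(cds)
        gstart <- cursor + 1L
        gend <- cursor + glens[j]
        segs <- c(segs, seg)
        cursor <- gend
        genes_rows[[length(genes_rows) + 1]] <- tibble(
          gene_id = sprintf("%s_t%04d_g%d", gid, t, j),
          replicon_id = "chr", start = gstart, end = gend,
          strand = strands[t], tu = t, gene_in_tu = j)
        if (k < ng) {
          gp <- gaps[k]
          segs <- c(segs, if (cfg$matched_composition) .codon_seq(gp, codons)
                          else .gc_seq(gp, cfg$gc_content))
          cursor <- cursor + gp
        }
      }
    }
    ig <- sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1)
    segs <- c(segs, if (cfg$matched_composition) .codon_seq(ig, codons)
                    else .gc_seq(ig, cfg$gc_content))
    seq_chr <- paste(segs, collapse = "")
    genes <- bind_rows(genes_rows)

    # plant sites in this genome's upstream windows
    for (t in planted_tus) {
      if (cfg$genome_groups[gidx] != planted_group[[as.character(t)]]) next
      gt <- filter(genes, .data$tu == t)
      site <- .sample_site(freq, cfg$planting_fidelity)
      if (strands[t] == "+") {
        g1 <- gt[which.min(gt$start), ]
        bound <- max(0L, genes$end[genes$end < g1$start])
        lo <- max(bound + 1L, g1$start - cfg$cap)
        hi <- g1$start - l_site
        if (hi < lo) abort("planted site does not fit the upstream window (config bug)")
        pstart <- sample(lo:hi, 1)
        substr(seq_chr, pstart, pstart + l_site - 1L) <- site
        offs <- pstart - g1$start
      } else {
        g1 <- gt[which.max(gt$end), ]
        bound <- min(nchar(seq_chr) + 1L, genes$start[genes$start > g1$end])
        hi <- min(bound - 1L, g1$end + cfg$cap) - l_site + 1L
        lo <- g1$end + 1L
        if (hi < lo) abort("planted site does not fit the upstream window (config bug)")
        pstart <- sample(lo:hi, 1)
        substr(seq_chr, pstart, pstart + l_site - 1L) <- revcomp(site)
        offs <- g1$end - (pstart + l_site - 1L)
      }
      truth[[length(truth) + 1]] <- tibble(
        genome = gid, tu_id = sprintf("%s_TU%04d", gid, t),
        family = sprintf("fam_t%04d", t), sequence = site,
        start = pstart, end = pstart + l_site - 1L,
        strand = strands[t], offset = offs)
    }

    bundle <- genome_bundle(gid, setNames(seq_chr, "chr"),
                            select(genes, -"tu", -"gene_in_tu"))
    tu_table <- genes |>
      group_by(.data$tu) |>
      summarise(gene_ids = list(.data$gene_id[order(.data$gene_in_tu)]),
                .groups = "drop") |>
      mutate(tu_id = sprintf("%s_TU%04d", gid, .data$tu)) |>
      select("tu_id", "gene_ids")
    bundle <- prepare_genome(bundle, tu_table = tu_table, cap = cfg$cap)
    bundles[[gid]] <- bundle
  }

  # ortholog map from conserved family labels: all genome pairs
  omap <- list()
  if (cfg$n_genomes >= 2) {
    cons <- filter(fam, .data$conserved)
    for (i in seq_len(cfg$n_genomes - 1)) for (j in (i + 1):cfg$n_genomes) {
      omap[[length(omap) + 1]] <- tibble(
        genome_a = genome_ids[i],
        gene_a = sprintf("%s_t%04d_g%d", genome_ids[i], cons$tu, cons$gene_in_tu),
        genome_b = genome_ids[j],
        gene_b = sprintf("%s_t%04d_g%d", genome_ids[j], cons$tu, cons$gene_in_tu),
        evalue_ab = 1e-50, evalue_ba = 1e-50)
    }
  }
  omap <- if (length(omap) > 0) bind_rows(omap) else
    tibble(genome_a = character(), gene_a = character(),
           genome_b = character(), gene_b = character(),
           evalue_ab = numeric(), evalue_ba = numeric())

  list(bundles = bundles, ortholog_map = omap,
       truth = if (length(truth) > 0) bind_rows(truth) else
         tibble(genome = character(), tu_id = character(),
                family = character(), sequence = character(),
                start = integer(), end = integer(), strand = character(),
                offset = integer()),
       config = cfg)
}

#' Toy reciprocal hit tables from an ortholog map
#'
#' Emits, for each genome pair in the map, a pair of outfmt-6-like hit
#' tables whose reciprocal best hits reproduce the map exactly; decoy
#' one-directional hits with worse E-values are mixed in so the
#' bidirectional-best-hit reader is genuinely exercised.
#'
#' @param ortholog_map tibble as produced by [simulate_genomes()].
#' @return named list (one element per genome pair, `"A__B"`) of lists with
#'   `ab` and `ba` hit tibbles.
#' @export
simulate_hit_tables <- function(ortholog_map) {
  pairs <- distinct(ortholog_map, .data$genome_a, .data$genome_b)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    m <- filter(ortholog_map, .data$genome_a == pairs$genome_a[r],
                .data$genome_b == pairs$genome_b[r])
    ab <- tibble(qseqid = m$gene_a, sseqid = m$gene_b,
                 evalue = m$evalue_ab, bitscore = 500)
    ba <- tibble(qseqid = m$gene_b, sseqid = m$gene_a,
                 evalue = m$evalue_ba, bitscore = 500)
    if (nrow(m) > 1) {
      # decoys: each query also weakly hits the next subject
      ab <- bind_rows(ab, tibble(qseqid = m$gene_a,
                                 sseqid = m$gene_b[c(2:nrow(m), 1)],
                                 evalue = 1e-5, bitscore = 50))
      ba <- bind_rows(ba, tibble(qseqid = m$gene_b,
                                 sseqid = m$gene_a[c(2:nrow(m), 1)],
                                 evalue = 1e-5, bitscore = 50))
    }
    out[[paste0(pairs$genome_a[r], "__", pairs$genome_b[r])]] <-
      list(ab = ab, ba = ba)
  }
  out
}

#' Write a simulated data set to disk
#'
#' Emits, per genome, the same plain-text formats the pipeline reads
#' (FASTA, gene TSV, TU TSV) plus the ortholog map TSV and a truth BED of
#' planted sites.
#'
#' @param sim result of [simulate_genomes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(sim$bundles)) {
    b <- sim$bundles[[gid]]
    Biostrings::writeXStringSet(b$seqs, file.path(dir, paste0(gid, ".fasta")))
    readr::write_tsv(select(b$genes, "gene_id", "start", "end", "strand",
                            replicon = "replicon_id"),
                     file.path(dir, paste0(gid, "_genes.tsv")))
    readr::write_tsv(
      mutate(b$tus, gene_ids = map_chr(.data$gene_ids, paste, collapse = ",")) |>
        select("tu_id", "gene_ids"),
      file.path(dir, paste0(gid, "_tus.tsv")))
  }
  write_ortholog_map(sim$ortholog_map, file.path(dir, "orthologs.tsv"))
  if (nrow(sim$truth) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = "chr",
      ranges = IRanges::IRanges(start = sim$truth$start, end = sim$truth$end),
      strand = sim$truth$strand)
    gr$name <- paste0(sim$truth$genome, ":", sim$truth$tu_id)
    gr$score <- 0L
    rtracklayer::export(gr, file.path(dir, "truth.bed"), format = "BED")
  }
  invisible(dir)
}

#' Evaluate recovery of planted sites
#'
#' A planted site counts as recovered when its TU passes the p-value
#' threshold and the reported window overlaps the planted interval by at
#' least half the site length. Precision is computed over all TUs called
#' at the threshold in the scanned genome.
#'
#' @param truth truth tibble from [simulate_genomes()] (rows of the scanned
#'   genome are used).
#' @param hits hits tibble from [scan_genome()] with `p_value` filled in.
#' @param threshold p-value threshold.
#' @return a `recovery_eval`: list with the per-planted-site `table`
#'   (rank, p-value, overlap, recovered) and summary fields `recall`,
#'   `precision`, `n_planted`, `n_called`.
#' @export
evaluate_recovery <- function(truth, hits, threshold = 0.01) {
  truth <- filter(truth, .data$tu_id %in% hits$tu_id)
  l <- nchar(truth$sequence[1] %||% "")
  ranked <- hits |>
    filter(.data$valid) |>
    mutate(rank = rank(-.data$s, ties.method = "min"))
  tab <- truth |>
    left_join(select(ranked, "tu_id", "site_start", "site_end", "s",
                     "p_value", "rank"),
              by = "tu_id") |>
    mutate(overlap = pmax(0L, pmin(.data$end, .data$site_end) -
                            pmax(.data$start, .data$site_start) + 1L),
           overlap = ifelse(is.na(.data$overlap), 0L, .data$overlap),
           recovered = !is.na(.data$p_value) & .data$p_value < threshold &
             .data$overlap >= l / 2)
  n_called <- sum(ranked$p_value < threshold, na.rm = TRUE)
  tp <- sum(tab$recovered)
  structure(list(table = tab,
                 recall = if (nrow(tab) > 0) tp / nrow(tab) else NA_real_,
                 precision = if (n_called > 0) tp / n_called else NA_real_,
                 n_planted = nrow(tab), n_called = n_called,
                 threshold = threshold),
            class = "recovery_eval")
}

#' @export
print.recovery_eval <- function(x, ...) {
  cat("<recovery_eval> ", x$n_planted, " planted sites, ", x$n_called,
      " TUs called at p < ", x$threshold, "\n", sep = "")
  cat(sprintf("  recall %.3f, precision %.3f\n", x$recall, x$precision))
  invisible(x)
}

#' @export
tidy.recovery_eval <- function(x, ...) x$table

#' @export
glance.recovery_eval <- function(x, ...) {
  tibble(recall = x$recall, precision = x$precision,
         n_planted = x$n_planted, n_called = x$n_called,
         mean_rank = mean(x$table$rank, na.rm = TRUE),
         threshold = x$threshold)
}
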