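#' Read a tabular protein hit table
#'
#' Accepts BLAST "outfmt 6"-style tab-separated tables. Files without a
#' header are assumed to carry the standard 12 columns; a header naming at
#' least `qseqid`, `sseqid`, `evalue` and `bitscore` is also accepted.
#'
#' @param path file path.
#' @return tibble with at least `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("qseqid", first, fixed = TRUE)
  if (has_header) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
    names(x) <- cols[seq_len(ncol(x))]
    x
  }
}

# best hit per query: minimum evalue, ties by higher bitscore then
# lexicographic subject id; self-hits dropped
.best_hits <- function(hits) {
  hits |>
    filter(.data$qseqid != .data$sseqid) |>
    arrange(.data$qseqid, .data$evalue, desc(.data$bitscore), .data$sseqid) |>
    distinct(.data$qseqid, .keep_all = TRUE) |>
    select("qseqid", "sseqid", "evalue")
}

#' Bidirectional-best-hit orthologs from two hit tables
#'
#' A cross-genome gene pair (a, b) is called orthologous when b is a's best
#' hit, a is b's best hit, and both E-values pass the cutoff (1e-10 in both
#' directions by default). "Best" means minimum E-value; ties are broken by
#' higher bitscore, then lexicographically smaller subject id, so the map is
#' independent of input row order. Self-hits are ignored.
#'
#' @param hits_ab,hits_ba hit tables (tibbles with `qseqid`, `sseqid`,
#'   `evalue`, `bitscore`), queries of genome A against genome B and vice
#'   versa.
#' @param genome_a,genome_b genome identifiers recorded in the map.
#' @param evalue_cutoff maximum E-value accepted in both directions.
#' @return an ortholog map: tibble with `genome_a`, `gene_a`, `genome_b`,
#'   `gene_b`, `evalue_ab`, `evalue_ba`, one row per pair. Maps for several
#'   genome pairs can simply be row-bound.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, genome_a = "A",
                                 genome_b = "B", evalue_cutoff = 1e-10) {
  empty <- tibble(genome_a = character(), gene_a = character(),
                  genome_b = character(), gene_b = character(),
                  evalue_ab = numeric(), evalue_ba = numeric())
  if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0) {
    warn("empty hit table: no ortholog pairs")
    return(empty)
  }
  ab <- .best_hits(as_tibble(hits_ab))
  ba <- .best_hits(as_tibble(hits_ba))
  pairs <- inner_join(ab, ba, by = c(qseqid = "sseqid", sseqid = "qseqid"),
                      suffix = c("_ab", "_ba")) |>
    filter(.data$evalue_ab <= evalue_cutoff, .data$evalue_ba <= evalue_cutoff)
  if (nrow(pairs) == 0) return(empty)
  tibble(genome_a = genome_a, gene_a = pairs$qseqid,
         genome_b = genome_b, gene_b = pairs$sseqid,
         evalue_ab = pairs$evalue_ab, evalue_ba = pairs$evalue_ba) |>
    arrange(.data$gene_a)
}

#' Orthologs of one gene across genomes
#'
#' Queries an ortholog map in both stored directions.
#'
#' @param ortholog_map tibble as returned by [reciprocal_best_hits()]
#'   (possibly row-bound over genome pairs).
#' @param genome,gene the query gene.
#' @return tibble with `genome`, `gene`: at most one ortholog per genome.
#' @export
orthologs_of <- function(ortholog_map, genome, gene) {
  fwd <- filter(ortholog_map, .data$genome_a == genome, .data$gene_a == gene)
  rev_ <- filter(ortholog_map, .data$genome_b == genome, .data$gene_b == gene)
  bind_rows(tibble(genome = fwd$genome_b, gene = fwd$gene_b),
            tibble(genome = rev_$genome_a, gene = rev_$gene_a)) |>
    distinct()
}

#' Upstream regions of a gene's orthologs
#'
#' For each genome holding an ortholog of `gene`, returns the upstream
#' region of the transcription unit containing that ortholog — one region
#' per genome even when several orthologous genes share a TU. Genomes whose
#' ortholog has no extractable region are skipped with a warning.
#'
#' @inheritParams orthologs_of
#' @param bundles named list of prepared [genome_bundle()]s keyed by genome
#'   id.
#' @return tibble of regions with leading `genome` and `gene` columns.
#' @export
ortholog_upstreams <- function(ortholog_map, genome, gene, bundles) {
  orths <- orthologs_of(ortholog_map, genome, gene)
  orths <- filter(orths, .data$genome %in% names(bundles))
  out <- pmap(list(orths$genome, orths$gene), function(gk, gidk) {
    b <- bundles[[gk]]
    tu <- b$tus$tu_id[map_lgl(b$tus$gene_ids, ~ gidk %in% .x)]
    if (length(tu) == 0) {
      warn(paste0("ortholog ", gidk, " in ", gk, " belongs to no TU; skipped"))
      return(NULL)
    }
    r <- filter(b$regions, .data$tu_id == tu[1])
    if (nrow(r) == 0) {
      warn(paste0("ortholog ", gidk, " in ", gk,
                  " has no extractable upstream region; skipped"))
      return(NULL)
    }
    bind_cols(tibble(genome = gk, gene = gidk), r[1, ])
  })
  out <- bind_rows(out)
  if (nrow(out) > 0) distinct(out, .data$genome, .keep_all = TRUE) else out
}

#' Write / read an ortholog map TSV
#'
#' @param ortholog_map tibble as from [reciprocal_best_hits()].
#' @param path file path.
#' @return `path` (write) or the map tibble (read).
#' @export
write_ortholog_map <- function(ortholog_map, path) {
  readr::write_tsv(ortholog_map, path)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    genome_a = "c", gene_a = "c", genome_b = "c",
                    gene_b = "c", evalue_ab = "d", evalue_ba = "d"))
}
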