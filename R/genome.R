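#' Load a genome and its gene annotation
#'
#' Reads a genome FASTA plus either a GFF3 file (gene features) or a plain
#' tab-separated gene table with columns `gene_id`, `start`, `end`, `strand`
#' and optionally `replicon` (required when the FASTA holds more than one
#' replicon). Coordinates are 1-based inclusive throughout the package.
#'
#' @param fasta_path path to the genome FASTA.
#' @param annotation_path path to a GFF3 (`.gff`/`.gff3`) or gene TSV.
#' @param genome_id identifier for the genome; defaults to the FASTA file
#'   name without extension.
#' @return a `genome_bundle`: a list holding the sequence(s) as a
#'   [Biostrings::DNAStringSet], the gene table as a tibble (sorted by
#'   replicon and start), and slots for transcription units, upstream
#'   regions, background model and coding pool filled by [prepare_genome()].
#' @export
load_genome <- function(fasta_path, annotation_path, genome_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  genome_id <- genome_id %||% tools::file_path_sans_ext(basename(fasta_path))

  if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(annotation_path)
    if (!is.null(gr$type) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    ids <- gr$ID %||% gr$locus_tag %||% gr$Name
    if (is.null(ids) || anyNA(ids)) {
      abort("GFF3 gene features must carry an ID, locus_tag or Name attribute")
    }
    genes <- tibble(
      gene_id = as.character(ids),
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    genes <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                             progress = FALSE)
    req <- c("gene_id", "start", "end", "strand")
    if (!all(req %in% names(genes))) {
      abort(paste0("gene table must have columns ", paste(req, collapse = ", ")))
    }
    if (!"replicon" %in% names(genes) && !"replicon_id" %in% names(genes)) {
      if (length(seqs) != 1L) {
        abort("gene table needs a replicon column for a multi-replicon FASTA")
      }
      genes$replicon_id <- names(seqs)[1]
    } else if ("replicon" %in% names(genes)) {
      genes <- rename(genes, replicon_id = "replicon")
    }
    genes <- select(genes, "gene_id", "replicon_id", "start", "end", "strand")
  }

  genes <- mutate(genes, gene_id = as.character(.data$gene_id),
                  start = as.integer(.data$start), end = as.integer(.data$end))
  bad <- filter(genes, .data$end < .data$start)
  if (nrow(bad) > 0) {
    abort(paste0("gene(s) with end < start: ",
                 paste(bad$gene_id, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicated gene_id: ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                       collapse = ", ")))
  }
  missing_rep <- setdiff(unique(genes$replicon_id), names(seqs))
  if (length(missing_rep) > 0) {
    abort(paste0("annotation references replicon(s) absent from FASTA: ",
                 paste(missing_rep, collapse = ", ")))
  }
  too_long <- genes$end > Biostrings::width(seqs)[match(genes$replicon_id,
                                                        names(seqs))]
  if (any(too_long)) {
    abort(paste0("gene(s) extend beyond their replicon: ",
                 paste(genes$gene_id[too_long], collapse = ", ")))
  }
  genes <- arrange(mutate(genes, genome_id = genome_id),
                   .data$replicon_id, .data$start, .data$end)
  genes <- select(genes, "gene_id", "genome_id", "replicon_id",
                  "start", "end", "strand")

  structure(list(genome_id = genome_id, seqs = seqs, genes = genes,
                 tus = NULL, regions = NULL, background = NULL,
                 cds = NULL, cds_pool = NULL),
            class = "genome_bundle")
}

#' Construct a genome bundle from in-memory pieces
#'
#' @param genome_id genome identifier.
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   replicon sequences.
#' @param genes tibble with `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand` columns.
#' @return a `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, seqs, genes) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  genes <- arrange(mutate(as_tibble(genes), genome_id = genome_id),
                   .data$replicon_id, .data$start, .data$end)
  structure(list(genome_id = genome_id, seqs = seqs, genes = genes,
                 tus = NULL, regions = NULL, background = NULL,
                 cds = NULL, cds_pool = NULL),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle> ", x$genome_id, "\n", sep = "")
  cat("  replicons: ", length(x$seqs), " (",
      sum(Biostrings::width(x$seqs)), " bp)\n", sep = "")
  cat("  genes: ", nrow(x$genes), sep = "")
  if (!is.null(x$tus)) cat("; TUs: ", nrow(x$tus), sep = "")
  if (!is.null(x$regions)) cat("; upstream regions: ", nrow(x$regions), sep = "")
  cat("\n")
  invisible(x)
}

#' Group genes into transcription units
#'
#' With a TU table the grouping is taken verbatim; without one a fallback
#' heuristic merges consecutive same-strand genes on the same replicon whose
#' intergenic gap is at most `gap_threshold` bp. The heuristic is a
#' convenience stand-in for a dedicated operon predictor and is deliberately
#' simple; supply a TU table whenever real operon calls are available.
#' Singleton genes form singleton TUs. Member genes are listed 5'→3' on the
#' coding strand.
#'
#' @param genes gene tibble (as in a [genome_bundle()]).
#' @param tu_table optional tibble with columns `tu_id` and `gene_ids`
#'   (comma-joined string or list of gene ids) covering every gene exactly
#'   once.
#' @param gap_threshold maximum intergenic gap (bp) merged by the heuristic.
#' @return tibble with `tu_id`, `genome_id`, `replicon_id`, `strand` and a
#'   `gene_ids` list-column.
#' @export
assemble_tus <- function(genes, tu_table = NULL, gap_threshold = 50) {
  genome_id <- genes$genome_id[1]
  if (!is.null(tu_table)) {
    tu_table <- as_tibble(tu_table)
    if (!is.list(tu_table$gene_ids)) {
      tu_table$gene_ids <- strsplit(as.character(tu_table$gene_ids), ",")
    }
    all_ids <- unlist(tu_table$gene_ids)
    if (anyDuplicated(all_ids)) {
      abort(paste0("TU table lists gene(s) more than once: ",
                   paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
    }
    unknown <- setdiff(all_ids, genes$gene_id)
    if (length(unknown) > 0) {
      abort(paste0("TU table references unknown gene(s): ",
                   paste(unknown, collapse = ", ")))
    }
    uncovered <- setdiff(genes$gene_id, all_ids)
    if (length(uncovered) > 0) {
      abort(paste0("TU table does not cover gene(s): ",
                   paste(uncovered, collapse = ", ")))
    }
    gtabs <- map(tu_table$gene_ids, ~ genes[match(.x, genes$gene_id), ])
    strand <- map_chr(gtabs, ~ {
      s <- unique(.x$strand)
      if (length(s) != 1) abort("TU members must share one strand")
      s
    })
    replicon <- map_chr(gtabs, ~ {
      r <- unique(.x$replicon_id)
      if (length(r) != 1) abort("TU members must share one replicon")
      r
    })
    # order 5'->3' on the coding strand
    ordered_ids <- map2(gtabs, strand, ~ {
      .x$gene_id[order(.x$start, decreasing = (.y == "-"))]
    })
    return(tibble(tu_id = tu_table$tu_id, genome_id = genome_id,
                  replicon_id = replicon, strand = strand,
                  gene_ids = ordered_ids))
  }

  genes |>
    group_by(.data$replicon_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(gap = .data$start - lag(.data$end) - 1L,
           new_tu = is.na(.data$gap) | .data$strand != lag(.data$strand) |
             .data$gap > gap_threshold,
           tu_idx = cumsum(.data$new_tu)) |>
    group_by(.data$replicon_id, .data$tu_idx) |>
    summarise(strand = first(.data$strand),
              gene_ids = list(if (first(.data$strand) == "-")
                rev(.data$gene_id) else .data$gene_id),
              .groups = "drop") |>
    mutate(tu_id = sprintf("%s_TU%04d", genome_id, row_number()),
           genome_id = genome_id) |>
    select("tu_id", "genome_id", "replicon_id", "strand", "gene_ids")
}

# 5'-most gene of a TU (first on the coding strand)
.first_gene <- function(tu_gene_ids, genes) {
  genes[match(tu_gene_ids[[1]], genes$gene_id), , drop = FALSE]
}

#' Extract the scanned upstream region of each transcription unit
#'
#' For every TU the inter-TU sequence between its first gene and the nearest
#' upstream gene body (any strand), truncated to the `cap` bases immediately
#' upstream when longer, is concatenated with the first `coding_extension`
#' bases of the first gene and reported 5'→3' on the TU's coding strand
#' (minus-strand TUs are reverse-complemented). TUs with no upstream
#' sequence at all yield a flagged region holding only the coding extension.
#'
#' @param tus TU tibble from [assemble_tus()].
#' @param bundle the [genome_bundle()] the TUs belong to.
#' @param cap maximum inter-TU length retained (bp).
#' @param coding_extension coding bases appended after the inter-TU part.
#' @return tibble of regions with genomic interval (`start`, `end`, 1-based
#'   inclusive, covering inter-TU plus coding extension), `strand`,
#'   `sequence`, `length`, `intertu_length` and a `flagged` column marking
#'   degenerate regions.
#' @export
extract_upstream <- function(tus, bundle, cap = 800, coding_extension = 40) {
  genes <- bundle$genes
  seq_cache <- setNames(as.character(bundle$seqs), names(bundle$seqs))
  regions <- pmap(list(tus$tu_id, tus$gene_ids, tus$strand, tus$replicon_id),
                  function(tu_id, gid, strand, repl) {
    g1 <- genes[match(gid[[1]], genes$gene_id), ]
    gr <- genes[genes$replicon_id == repl & genes$gene_id != g1$gene_id, ]
    rep_len <- Biostrings::width(bundle$seqs)[match(repl, names(bundle$seqs))]
    if (strand == "+") {
      bound <- suppressWarnings(max(0L, gr$end[gr$end < g1$start]))
      istart <- bound + 1L
      iend <- g1$start - 1L
      ilen <- max(0L, iend - istart + 1L)
      if (ilen > cap) istart <- g1$start - cap
      cstart <- g1$start
      cend <- min(g1$end, g1$start + coding_extension - 1L)
      full_start <- if (ilen > 0) istart else cstart
      full_end <- cend
      inter_seq <- if (ilen > 0) substr(seq_cache[[repl]], istart, iend) else ""
      cod_seq <- substr(seq_cache[[repl]], cstart, cend)
      seq <- paste0(inter_seq, cod_seq)
    } else {
      bound <- suppressWarnings(
        min(rep_len + 1L, gr$start[gr$start > g1$end]))
      iend <- bound - 1L
      istart <- g1$end + 1L
      ilen <- max(0L, iend - istart + 1L)
      if (ilen > cap) iend <- g1$end + cap
      cend <- g1$end
      cstart <- max(g1$start, g1$end - coding_extension + 1L)
      full_start <- cstart
      full_end <- if (ilen > 0) iend else cend
      inter_seq <- if (ilen > 0)
        revcomp(substr(seq_cache[[repl]], istart, iend)) else ""
      cod_seq <- revcomp(substr(seq_cache[[repl]], cstart, cend))
      seq <- paste0(inter_seq, cod_seq)
    }
    ilen_kept <- min(ilen, cap)
    tibble(region_id = paste0(tu_id, "_up"), tu_id = tu_id,
           genome_id = bundle$genome_id, replicon_id = repl,
           start = as.integer(full_start), end = as.integer(full_end),
           strand = strand, kind = "interTU", sequence = seq,
           length = nchar(seq), intertu_length = as.integer(ilen_kept),
           flagged = (ilen_kept == 0L))
  })
  bind_rows(regions)
}

#' Genome background base composition
#'
#' Base frequencies of the aggregated inter-TU sequence (the coding
#' extensions of the regions are excluded), with one pseudocount per base so
#' every frequency is strictly positive. Non-ACGT characters are ignored.
#'
#' @param regions region tibble from [extract_upstream()] (kind `interTU`).
#' @return named numeric vector `c(A=, C=, G=, T=)` summing to 1, with the
#'   genome id attached as attribute `genome_id`.
#' @export
compute_background <- function(regions) {
  regions <- filter(regions, .data$kind == "interTU")
  if (nrow(regions) == 0) abort("no inter-TU regions supplied")
  inter <- substr(regions$sequence, 1L, regions$intertu_length)
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(inter[nchar(inter) > 0]), DNA_BASES))
  if (sum(counts) == 0) abort("inter-TU regions contain no informative (ACGT) bases")
  q <- (counts + 1) / (sum(counts) + 4)
  q <- setNames(as.numeric(q), DNA_BASES)
  attr(q, "genome_id") <- regions$genome_id[1]
  q
}

#' Prepare a genome bundle for scanning
#'
#' Fills in transcription units, upstream regions, background model and the
#' coding-sequence pool used by the null model.
#'
#' @inheritParams assemble_tus
#' @inheritParams extract_upstream
#' @param bundle a [genome_bundle()].
#' @return the bundle with `tus`, `regions`, `background`, `cds` and
#'   `cds_pool` populated.
#' @export
prepare_genome <- function(bundle, tu_table = NULL, gap_threshold = 50,
                           cap = 800, coding_extension = 40) {
  bundle$tus <- assemble_tus(bundle$genes, tu_table, gap_threshold)
  bundle$regions <- extract_upstream(bundle$tus, bundle, cap, coding_extension)
  bundle$background <- compute_background(bundle$regions)

  # coding pool: every gene's sequence on its coding strand, concatenated
  genes <- bundle$genes
  seq_cache <- setNames(as.character(bundle$seqs), names(bundle$seqs))
  seq_chr <- substr(seq_cache[genes$replicon_id], genes$start, genes$end)
  neg <- genes$strand == "-"
  seq_chr[neg] <- revcomp(seq_chr[neg])
  lens <- nchar(seq_chr)
  bundle$cds <- tibble(gene_id = genes$gene_id, length = lens,
                       pool_offset = cumsum(c(0L, head(lens, -1))))
  bundle$cds_pool <- encode_dna(paste(seq_chr, collapse = ""))
  bundle
}

#' Write upstream regions to a BED6 file
#'
#' Intervals are converted from the package's 1-based inclusive coordinates
#' to BED's 0-based half-open convention.
#'
#' @param regions region tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$replicon_id,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    strand = regions$strand)
  gr$name <- regions$region_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 file back into an interval tibble
#'
#' @param path BED file written by [write_regions_bed()].
#' @return tibble with `region_id`, `replicon_id`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(region_id = gr$name,
         replicon_id = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)))
}
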