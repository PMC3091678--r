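#' Score a single window against a profile
#'
#' The match score of an l-mer is `sum_i I_i * log(p(i, h_i) / q(h_i))` in
#' nats: the per-position log-likelihood ratio of the window under the
#' profile versus the genome background, weighted by the column's normalized
#' information content so that uninformative columns contribute nothing.
#'
#' @param profile a [build_profile()] object.
#' @param lmer an ACGT string of the profile's length (no N allowed).
#' @param background named base-frequency vector of the scanned genome.
#' @return the score in nats.
#' @export
score_window <- function(profile, lmer,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lmer <- toupper(lmer)
  stopifnot(nchar(lmer) == profile$l)
  codes <- encode_dna(lmer)
  if (any(codes == 0L)) abort("window contains a non-ACGT base; skip it")
  w <- profile_weights(profile, background)
  sum(w[cbind(codes, seq_len(profile$l))])
}

#' Best-matching site per region
#'
#' Slides a window of the profile's length across each region (both
#' orientations by default) and keeps the single highest-scoring window.
#' Windows containing non-ACGT bases are skipped. Ties are broken toward
#' the lower offset, then the plus orientation. Regions shorter than the
#' profile, or with no valid window, yield a no-hit sentinel row
#' (`valid = FALSE`, `s_M = NA`).
#'
#' @param regions region tibble from [extract_upstream()], or a character
#'   vector of sequences.
#' @param profile a [build_profile()] object.
#' @param background named base-frequency vector of the scanned genome.
#' @param both_strands scan both orientations (default) or only the given
#'   one.
#' @return tibble with one row per region: `region_id`, `site` (matched
#'   spelling: the reverse complement is reported for minus-orientation
#'   windows), `offset` (0-based within the region), `strand_of_window`,
#'   `s_M` (nats) and `valid`.
#' @export
best_site <- function(regions, profile, background = profile$q,
                      both_strands = TRUE) {
  if (is.character(regions)) {
    regions <- tibble(region_id = paste0("seq", seq_along(regions)),
                      sequence = regions)
  }
  w <- profile_weights(profile, background)
  l <- profile$l
  res <- map(regions$sequence, function(s) {
    codes <- encode_dna(toupper(s))
    cpp_best_window(codes, w, both_strands)
  })
  score <- map_dbl(res, "score")
  offset <- map_int(res, ~ as.integer(.x$offset %||% NA_integer_))
  strand_i <- map_int(res, ~ as.integer(.x$strand %||% NA_integer_))
  site <- rep(NA_character_, nrow(regions))
  ok <- !is.na(score)
  site[ok] <- vapply(which(ok), function(i) {
    codes <- encode_dna(toupper(regions$sequence[i]))
    win <- codes[(offset[i] + 1):(offset[i] + l)]
    if (strand_i[i] == -1L) win <- revcomp_codes(win)
    decode_dna(win)
  }, character(1))
  tibble(region_id = regions$region_id,
         site = site, offset = offset,
         strand_of_window = ifelse(is.na(strand_i), NA_character_,
                                   ifelse(strand_i == 1L, "+", "-")),
         s_M = score, valid = ok)
}

#' Orthology bonus of a candidate site
#'
#' For each gene of the scanned TU with orthologs, averages over the
#' ortholog genomes the product of (i) the sequence similarity
#' `(l - d)/l` between the candidate site and the best site found upstream
#' of the ortholog (Hamming distance `d` on the matched spellings) and
#' (ii) that orthologous site's own match score. The bonus is the maximum
#' of these per-gene averages; genes without orthologs contribute zero, so
#' a TU with no orthologs anywhere gets `A_max = 0`. Negative orthologous
#' scores enter the average as-is.
#'
#' @param site the candidate site (matched spelling, length l).
#' @param ortholog_sites tibble with one row per (gene, ortholog genome):
#'   columns `gene`, `genome`, `site` (the orthologous region's best site,
#'   matched spelling) and `s_M` (its score in that genome).
#' @return list with `A_max`, `bonus_gene` (NA when no orthologs) and
#'   `detail`, the per-ortholog tibble with distance `d` and contribution.
#' @export
orthology_bonus <- function(site, ortholog_sites) {
  if (is.null(ortholog_sites) || nrow(ortholog_sites) == 0) {
    return(list(A_max = 0, bonus_gene = NA_character_,
                detail = tibble(gene = character(), genome = character(),
                                site = character(), s_M = numeric(),
                                d = integer(), contribution = numeric())))
  }
  l <- nchar(site)
  target <- site
  detail <- ortholog_sites |>
    mutate(d = hamming_distance(rep(.env$target, n()), .data$site),
           contribution = (l - .data$d) / l * .data$s_M)
  per_gene <- detail |>
    group_by(.data$gene) |>
    summarise(A = mean(.data$contribution), m = n(), .groups = "drop") |>
    arrange(desc(.data$A), .data$gene)
  list(A_max = per_gene$A[1], bonus_gene = per_gene$gene[1], detail = detail)
}

#' Refined site score
#'
#' The refined score of a candidate is its own match score plus the
#' orthology bonus: `s = s_M + A_max`.
#'
#' @param s_M match score (nats).
#' @param A_max orthology bonus (nats; 0 when no orthologs).
#' @return `s_M + A_max`.
#' @export
refined_score <- function(s_M, A_max) s_M + A_max

# cache of per-region best sites for a reference genome, scored with its
# own background, plus the gene -> region mapping
.ref_cache <- function(bundle, profile, both_strands = TRUE) {
  hits <- best_site(bundle$regions, profile, bundle$background, both_strands)
  hits$tu_id <- bundle$regions$tu_id
  gene2region <- bundle$tus |>
    select("tu_id", "gene_ids") |>
    unnest("gene_ids") |>
    rename(gene = "gene_ids")
  list(hits = hits, gene2region = gene2region,
       region_len = setNames(bundle$regions$length, bundle$regions$tu_id))
}

#' Scan a genome's upstream regions
#'
#' Finds the best-matching site of every transcription unit's upstream
#' region, adds the orthology bonus computed from reference genomes, and
#' returns the hits sorted by decreasing refined score. Reference genomes
#' are scanned against their own background composition; the profile's
#' information weights are fixed at build time.
#'
#' @param bundle prepared [genome_bundle()] to scan (the target genome).
#' @param profile a [build_profile()] object.
#' @param ortholog_map optional ortholog map linking the target to the
#'   reference genomes; `NULL` disables the bonus (`A_max = 0`).
#' @param ref_bundles named list of prepared reference [genome_bundle()]s.
#' @param both_strands scan both orientations.
#' @return tibble with one row per TU: `tu_id`, `region_id`, `gene_ids`
#'   (list-column), `site`, `offset`, `strand_of_window`, genomic site
#'   interval (`site_start`, `site_end`), `s_M`, `A_max`, `s`,
#'   `bonus_gene`, `m_max`, `p_value` (NA until [empirical_pvalue()] is
#'   applied), `valid`, and a `per_ortholog` list-column of per-ortholog
#'   detail tibbles.
#' @export
scan_genome <- function(bundle, profile, ortholog_map = NULL,
                        ref_bundles = list(), both_strands = TRUE) {
  stopifnot(!is.null(bundle$regions), !is.null(bundle$background))
  hits <- best_site(bundle$regions, profile, bundle$background, both_strands)
  hits <- bind_cols(
    bundle$regions |> select("tu_id", rstart = "start", rend = "end",
                             rstrand = "strand"),
    hits)
  hits$gene_ids <- bundle$tus$gene_ids[match(hits$tu_id, bundle$tus$tu_id)]

  # genomic interval of the reported window
  l <- profile$l
  hits <- hits |>
    mutate(site_start = ifelse(.data$rstrand == "+",
                               .data$rstart + .data$offset,
                               .data$rend - .data$offset - l + 1L),
           site_end = .data$site_start + l - 1L)

  use_orths <- !is.null(ortholog_map) && length(ref_bundles) > 0
  refs <- if (use_orths) {
    ref_bundles <- ref_bundles[setdiff(names(ref_bundles), bundle$genome_id)]
    map(ref_bundles, .ref_cache, profile = profile, both_strands = both_strands)
  } else list()

  A_max <- numeric(nrow(hits))
  bonus_gene <- rep(NA_character_, nrow(hits))
  m_max <- integer(nrow(hits))
  per_orth <- vector("list", nrow(hits))

  if (use_orths && length(refs) > 0) {
    # gene -> ortholog lookup restricted to the target genome, both directions
    g <- bundle$genome_id
    fwd <- ortholog_map |>
      filter(.data$genome_a == g, .data$genome_b %in% names(refs)) |>
      select(gene = "gene_a", o_genome = "genome_b", o_gene = "gene_b")
    bwd <- ortholog_map |>
      filter(.data$genome_b == g, .data$genome_a %in% names(refs)) |>
      select(gene = "gene_b", o_genome = "genome_a", o_gene = "gene_a")
    lut <- distinct(bind_rows(fwd, bwd))
    lut <- split(lut, lut$gene)

    for (r in which(hits$valid)) {
      genes_r <- hits$gene_ids[[r]]
      rows <- bind_rows(lut[intersect(genes_r, names(lut))])
      if (is.null(rows) || nrow(rows) == 0) next
      det <- pmap(list(rows$gene, rows$o_genome, rows$o_gene),
                  function(gene, ogenome, ogene) {
        rc <- refs[[ogenome]]
        tu <- rc$gene2region$tu_id[match(ogene, rc$gene2region$gene)]
        if (is.na(tu)) return(NULL)
        h <- rc$hits[match(tu, rc$hits$tu_id), ]
        if (!isTRUE(h$valid)) return(NULL)
        tibble(gene = gene, genome = ogenome, site = h$site, s_M = h$s_M)
      })
      det <- bind_rows(det)
      if (nrow(det) == 0) next
      # one region per ortholog genome per gene
      det <- distinct(det, .data$gene, .data$genome, .keep_all = TRUE)
      b <- orthology_bonus(hits$site[r], det)
      A_max[r] <- b$A_max
      bonus_gene[r] <- b$bonus_gene
      m_max[r] <- b$detail |> filter(.data$gene == b$bonus_gene) |> nrow()
      per_orth[[r]] <- b$detail
    }
  }

  hits |>
    mutate(A_max = ifelse(.data$valid, A_max, NA_real_),
           s = refined_score(.data$s_M, .data$A_max),
           bonus_gene = bonus_gene, m_max = m_max,
           p_value = NA_real_, per_ortholog = per_orth) |>
    select("tu_id", "region_id", "gene_ids", "site", "offset",
           "strand_of_window", "site_start", "site_end",
           "s_M", "A_max", "s", "bonus_gene", "m_max", "p_value", "valid",
           "per_ortholog") |>
    arrange(desc(ifelse(is.na(.data$s), -Inf, .data$s)))
}

#' Write a hits table to TSV
#'
#' Flattens the list-columns (`gene_ids` comma-joined; per-ortholog detail
#' dropped) for a plain-text record of a genome scan.
#'
#' @param hits tibble from [scan_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- hits |>
    mutate(gene_ids = map_chr(.data$gene_ids, paste, collapse = ",")) |>
    select(-any_of("per_ortholog"))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Predicted sites as a BED6 file
#'
#' @param hits tibble from [scan_genome()] (rows with a valid site).
#' @param bundle the scanned [genome_bundle()] (for replicon ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(hits, bundle, path) {
  hits <- filter(hits, .data$valid)
  repl <- bundle$regions$replicon_id[match(hits$region_id,
                                           bundle$regions$region_id)]
  strand_region <- bundle$regions$strand[match(hits$region_id,
                                               bundle$regions$region_id)]
  # site orientation on the genome: region strand flipped by a minus window
  site_strand <- ifelse(hits$strand_of_window == "-",
                        ifelse(strand_region == "+", "-", "+"), strand_region)
  gr <- GenomicRanges::GRanges(
    seqnames = repl,
    ranges = IRanges::IRanges(start = hits$site_start, end = hits$site_end),
    strand = site_strand)
  gr$name <- hits$tu_id
  gr$score <- round(pmin(1000, pmax(0, hits$s * 100)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
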