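# sample `count` start positions of length-L coding substrings.
# A single CDS long enough is preferred; otherwise the concatenated coding
# pool is used (flagged). Returns 1-based starts into the pool plus a flag.
.sample_coding_starts <- function(bundle, L, count) {
  eligible <- which(bundle$cds$length >= L)
  pool_len <- length(bundle$cds_pool)
  if (pool_len < L) abort("genome has no coding sequence of the required length")
  if (length(eligible) > 0) {
    gi <- eligible[sample.int(length(eligible), count, replace = TRUE)]
    off <- bundle$cds$pool_offset[gi]
    maxs <- bundle$cds$length[gi] - L + 1L
    starts <- off + 1L + floor(runif(count) * maxs)
    tibble(start = as.integer(starts), pool_fallback = FALSE)
  } else {
    starts <- 1L + floor(runif(count) * (pool_len - L + 1L))
    tibble(start = as.integer(starts), pool_fallback = TRUE)
  }
}

#' Random length-matched coding sequences for one region
#'
#' Draws `count` contiguous coding substrings of exactly the region's
#' length. Substrings are taken from a single coding sequence when one is
#' long enough; otherwise from the concatenated coding pool of the genome
#' (`flagged = TRUE`).
#'
#' @param bundle prepared [genome_bundle()].
#' @param region one row of the bundle's region tibble (or a bare length).
#' @param count number of samples.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return tibble of null regions (`kind = "null_coding"`) with `sequence`,
#'   `length` and `flagged`.
#' @export
sample_null_regions <- function(bundle, region, count = 300, seed = 1729) {
  L <- if (is.data.frame(region)) region$length[1] else as.integer(region)
  withr::local_seed(seed)
  st <- .sample_coding_starts(bundle, L, count)
  seqs <- vapply(st$start, function(s)
    decode_dna(bundle$cds_pool[s:(s + L - 1L)]), character(1))
  tibble(region_id = sprintf("null_%05d", seq_len(count)),
         genome_id = bundle$genome_id, kind = "null_coding",
         sequence = seqs, length = L, flagged = st$pool_fallback)
}

#' Empirical null distribution of refined scores
#'
#' For every scannable upstream region of the genome, scores `count`
#' random coding sequences of the same length with the full refined-score
#' machinery: each null sequence's best window gets an orthology bonus in
#' which every real ortholog slot of the region's TU is filled by a freshly
#' drawn, length-matched random coding substring from the corresponding
#' reference genome (scored with that genome's background). TUs without
#' orthologs yield pure match-score nulls. Regions shorter than the profile
#' are skipped.
#'
#' @param bundle prepared target [genome_bundle()].
#' @param profile a [build_profile()] object.
#' @param ortholog_map optional ortholog map (as in [scan_genome()]).
#' @param ref_bundles named list of prepared reference bundles.
#' @param count null samples per region.
#' @param seed RNG seed (mandatory; recorded on the result).
#' @param both_strands scan both orientations.
#' @return a `null_distribution`: list with `genome_id`, sorted `scores`,
#'   `n_samples_per_region`, `n_regions`, `seed`.
#' @export
null_distribution <- function(bundle, profile, ortholog_map = NULL,
                              ref_bundles = list(), count = 300,
                              seed = 1729, both_strands = TRUE) {
  stopifnot(!is.null(bundle$regions), !is.null(bundle$cds_pool))
  withr::local_seed(seed)
  l <- profile$l
  w_t <- profile_weights(profile, bundle$background)

  use_orths <- !is.null(ortholog_map) && length(ref_bundles) > 0
  slots <- NULL
  w_refs <- list()
  if (use_orths) {
    ref_bundles <- ref_bundles[setdiff(names(ref_bundles), bundle$genome_id)]
    w_refs <- map(ref_bundles, ~ profile_weights(profile, .x$background))
    # real ortholog slot structure: per TU/gene, the reference genome and
    # the length of the true orthologous upstream region
    g <- bundle$genome_id
    fwd <- ortholog_map |>
      filter(.data$genome_a == g, .data$genome_b %in% names(ref_bundles)) |>
      select(gene = "gene_a", o_genome = "genome_b", o_gene = "gene_b")
    bwd <- ortholog_map |>
      filter(.data$genome_b == g, .data$genome_a %in% names(ref_bundles)) |>
      select(gene = "gene_b", o_genome = "genome_a", o_gene = "gene_a")
    lut <- distinct(bind_rows(fwd, bwd))
    if (nrow(lut) > 0) {
      tu_gene <- bundle$tus |>
        select("tu_id", "gene_ids") |>
        unnest("gene_ids") |>
        rename(gene = "gene_ids")
      slots <- inner_join(tu_gene, lut, by = "gene",
                          relationship = "many-to-many")
      # gene -> upstream-region length lookup per reference genome
      ref_lookup <- map(ref_bundles, function(b) {
        b$tus |>
          select("tu_id", "gene_ids") |>
          unnest("gene_ids") |>
          rename(o_gene = "gene_ids") |>
          mutate(o_len = b$regions$length[match(.data$tu_id,
                                                b$regions$tu_id)]) |>
          select("o_gene", "o_len")
      })
      slots$o_len <- map2_int(slots$o_genome, slots$o_gene, function(gk, gidk) {
        tbl <- ref_lookup[[gk]]
        as.integer(tbl$o_len[match(gidk, tbl$o_gene)] %||% NA_integer_)
      })
      slots <- filter(slots, !is.na(.data$o_len), .data$o_len >= l) |>
        distinct(.data$tu_id, .data$gene, .data$o_genome, .keep_all = TRUE)
      slots <- split(slots, slots$tu_id)
    }
  }

  regions <- filter(bundle$regions, .data$length >= l)
  all_scores <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    L <- regions$length[r]
    st <- .sample_coding_starts(bundle, L, count)
    nb <- cpp_best_windows_at(bundle$cds_pool, st$start, L, w_t, both_strands)
    s_vec <- nb$score

    tu <- regions$tu_id[r]
    sl <- if (!is.null(slots)) slots[[tu]] else NULL
    if (!is.null(sl) && nrow(sl) > 0 && any(!is.na(s_vec))) {
      # matched-spelling windows of the null sequences
      abs_start <- st$start + nb$offset
      h_null <- cpp_extract_windows(bundle$cds_pool, as.integer(abs_start),
                                    as.integer(nb$strand), l)
      contrib <- matrix(0, nrow = count, ncol = nrow(sl))
      for (j in seq_len(nrow(sl))) {
        bk <- ref_bundles[[sl$o_genome[j]]]
        stk <- .sample_coding_starts(bk, sl$o_len[j], count)
        nbk <- cpp_best_windows_at(bk$cds_pool, stk$start, sl$o_len[j],
                                   w_refs[[sl$o_genome[j]]], both_strands)
        absk <- stk$start + nbk$offset
        h_k <- cpp_extract_windows(bk$cds_pool, as.integer(absk),
                                   as.integer(nbk$strand), l)
        d <- cpp_hamming_cols(h_null, h_k)
        contrib[, j] <- (l - d) / l * nbk$score
      }
      per_gene <- vapply(split(seq_len(nrow(sl)), sl$gene), function(idx)
        rowMeans(contrib[, idx, drop = FALSE]), numeric(count))
      A <- if (is.matrix(per_gene)) do.call(pmax, as.data.frame(per_gene))
           else per_gene
      s_vec <- s_vec + A
    }
    all_scores[[r]] <- s_vec[!is.na(s_vec)]
  }
  scores <- sort(unlist(all_scores))
  structure(list(genome_id = bundle$genome_id, scores = scores,
                 n_samples_per_region = count, n_regions = nrow(regions),
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$genome_id, ": ", length(x$scores),
      " scores (", x$n_samples_per_region, " per region x ", x$n_regions,
      " regions), seed ", x$seed, "\n", sep = "")
  cat("  quantiles: ", paste(sprintf("%.2f",
      quantile(x$scores, c(.5, .95, .99))), collapse = " / "),
      " (50/95/99%)\n", sep = "")
  invisible(x)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble(genome_id = x$genome_id, n = length(x$scores),
         n_regions = x$n_regions, seed = x$seed,
         q50 = quantile(x$scores, .5), q95 = quantile(x$scores, .95),
         q99 = quantile(x$scores, .99),
         cutoff_p05 = as.numeric(score_cutoff(x, 0.05)),
         cutoff_p01 = as.numeric(score_cutoff(x, 0.01)))
}

#' Empirical p-value of a score
#'
#' The fraction of null scores strictly greater than `s`. A p-value of zero
#' means "below the resolution of the null" (< 1/N).
#'
#' @param null a [null_distribution()].
#' @param s score(s) to evaluate.
#' @return numeric vector of p-values.
#' @export
empirical_pvalue <- function(null, s) {
  N <- length(null$scores)
  if (N == 0) abort("empty null distribution")
  p <- (N - findInterval(s, null$scores)) / N
  p[is.na(s)] <- NA_real_
  p
}

#' Score cutoff at a target p-value
#'
#' The smallest observed null score whose empirical p-value is strictly
#' below `p_target`. When `p_target` is at or below the null's resolution
#' (1/N) the cutoff is flagged unachievable (attribute `achievable`).
#'
#' @param null a [null_distribution()].
#' @param p_target target p-value (e.g. 0.01).
#' @return the cutoff score, with attribute `achievable`.
#' @export
score_cutoff <- function(null, p_target = 0.01) {
  N <- length(null$scores)
  u <- unique(null$scores)  # already sorted
  pv <- empirical_pvalue(null, u)
  achievable <- p_target > 1 / N
  if (!achievable) {
    warn(sprintf("p-value target %g is below the null resolution 1/%d", p_target, N))
  }
  idx <- which(pv < p_target)
  s_star <- if (length(idx) > 0) u[idx[1]] else u[length(u)]
  structure(s_star, achievable = achievable)
}

#' Log-odds-ratio curve of observed versus null score tails
#'
#' Evaluated on the sorted unique observed scores:
#' `LOR(s) = log(p(S_obs > s) / p(S_null > s))`, with both tail fractions
#' smoothed as `(count + 1)/(N + 1)` inside the log so it stays finite;
#' raw fractions and counts are reported alongside. The observed scores
#' are per sequence (one best site per upstream region), matching the
#' "fraction of inter-TU sequences containing a site above s" reading.
#'
#' @param observed numeric vector of observed refined scores, or a hits
#'   tibble from [scan_genome()] (valid rows are used).
#' @param null a [null_distribution()].
#' @return a `lor_curve` tibble with columns `s`, `n_obs_gt`, `n_null_gt`,
#'   `p_iu`, `p_cu` (raw fractions) and `lor` (smoothed log-odds ratio).
#' @export
lor_curve <- function(observed, null) {
  if (is.data.frame(observed)) observed <- observed$s[observed$valid]
  observed <- observed[!is.na(observed)]
  if (length(observed) == 0) abort("no observed scores")
  n_obs <- length(observed)
  n_null <- length(null$scores)
  grid <- sort(unique(observed))
  obs_sorted <- sort(observed)
  n_obs_gt <- n_obs - findInterval(grid, obs_sorted)
  n_null_gt <- n_null - findInterval(grid, null$scores)
  out <- tibble(s = grid,
                n_obs_gt = n_obs_gt, n_null_gt = n_null_gt,
                p_iu = n_obs_gt / n_obs, p_cu = n_null_gt / n_null,
                lor = log(((n_obs_gt + 1) / (n_obs + 1)) /
                            ((n_null_gt + 1) / (n_null + 1))))
  class(out) <- c("lor_curve", class(out))
  attr(out, "n_obs") <- n_obs
  attr(out, "n_null") <- n_null
  out
}

#' @export
autoplot.lor_curve <- function(object, ...) {
  long <- tibble(s = rep(object$s, 3),
                 value = c(object$p_iu, object$p_cu, object$lor),
                 curve = rep(c("p(S_IU > s)", "p(S_CU > s)", "LOR"),
                             each = nrow(object)),
                 panel = rep(c("tail probability", "tail probability",
                               "log-odds ratio"), each = nrow(object)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = tibble(panel = "log-odds ratio", y = 0),
                        ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c("LOR" = "red",
                                            "p(S_IU > s)" = "darkgreen",
                                            "p(S_CU > s)" = "blue")) +
    ggplot2::labs(x = "site score s (nats)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
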