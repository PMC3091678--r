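#' Read a flat key=value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are left
#' as strings; numeric coercion happens where the pipeline consumes them.
#'
#' @param path config file.
#' @return named list of strings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  setNames(map(kv, ~ paste(.x[-1], collapse = "=")), map_chr(kv, 1))
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full scanning and regulon-comparison pipeline
#'
#' Executes every stage in order for each genome in turn (the others serve
#' as reference genomes): profile construction from the site list, scan,
#' coding-sequence null, empirical p-values, score cutoffs and LOR curves
#' at both thresholds, regulon prediction, and — with at least three
#' genomes — the pairwise conservation matrix and neighbor-joining tree.
#' All artifacts are written to `out_dir` as plain text together with a
#' manifest (file + md5), the echoed configuration and a run log.
#'
#' @param bundles named list of prepared [genome_bundle()]s.
#' @param sites binding-site list for [build_profile()] (character vector
#'   or data frame with a `sequence` column).
#' @param ortholog_map ortholog map across the genomes, or `NULL` to run
#'   without the orthology bonus (a warning is logged).
#' @param out_dir output directory.
#' @param null_count null samples per region.
#' @param p_threshold regulon p-value threshold.
#' @param p_report p-value thresholds reported in the per-genome summary.
#' @param seed RNG seed for the null models.
#' @param both_strands scan both orientations.
#' @param profile_background background used to build the profile; default
#'   pools the inter-TU composition of all genomes.
#' @return invisibly, a list with the per-genome results (`hits`, `null`,
#'   `lor`), the `summary` tibble, `regulons`, `conservation` and `tree`
#'   (the last two `NULL` below three genomes), and `out_dir`.
#' @export
run_pipeline <- function(bundles, sites, ortholog_map = NULL, out_dir,
                         null_count = 300, p_threshold = 0.01,
                         p_report = c(0.05, 0.01), seed = 1729,
                         both_strands = TRUE,
                         profile_background = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "regulonscan ", as.character(utils::packageVersion("regulonscan")),
            " | seed ", seed, " | genomes: ", paste(names(bundles), collapse = ", "))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .log_line(log_con, "FAILED at stage '", name, "': ", conditionMessage(e))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (is.null(ortholog_map)) {
    .log_line(log_con, "WARNING: no ortholog map supplied; A_max = 0 everywhere")
  }

  # pooled background over all genomes' inter-TU regions
  profile_background <- profile_background %||% stage("background", {
    all_regions <- bind_rows(map(bundles, "regions"))
    compute_background(all_regions)
  })
  profile <- stage("profile", build_profile(sites, profile_background))
  write_meme_motif(profile, file.path(out_dir, "profile.meme"))
  .log_line(log_con, "profile: ", profile$n, " sites x ", profile$l,
            " bp; consensus ", consensus(profile))

  results <- list()
  summary_rows <- list()
  regulons <- list()
  for (gid in names(bundles)) {
    b <- bundles[[gid]]
    refs <- bundles[setdiff(names(bundles), gid)]
    hits <- stage(paste0("scan:", gid),
                  scan_genome(b, profile, ortholog_map, refs, both_strands))
    null <- stage(paste0("null:", gid),
                  null_distribution(b, profile, ortholog_map, refs,
                                    count = null_count, seed = seed,
                                    both_strands = both_strands))
    hits$p_value <- empirical_pvalue(null, hits$s)
    lor <- stage(paste0("lor:", gid), lor_curve(hits, null))
    results[[gid]] <- list(hits = hits, null = null, lor = lor)

    write_hits_tsv(hits, file.path(out_dir, paste0("hits_", gid, ".tsv")))
    readr::write_tsv(tibble(score = null$scores),
                     file.path(out_dir, paste0("null_", gid, ".tsv")))
    readr::write_tsv(lor, file.path(out_dir, paste0("lor_", gid, ".tsv")))
    write_regions_bed(b$regions, file.path(out_dir, paste0("regions_", gid, ".bed")))
    write_sites_bed(filter(hits, .data$p_value < p_threshold), b,
                    file.path(out_dir, paste0("sites_", gid, ".bed")))

    regulons[[gid]] <- predict_regulon(hits, gid, p_threshold)

    row <- tibble(genome = gid, n_tus = nrow(b$tus), n_genes = nrow(b$genes))
    for (p in p_report) {
      cut_p <- score_cutoff(null, p)
      lor_at <- lor$lor[findInterval(as.numeric(cut_p), lor$s)]
      if (length(lor_at) == 0 || is.na(lor_at)) lor_at <- NA_real_
      tag <- sub("^0\\.", "p", format(p))
      row[[paste0("score_", tag)]] <- as.numeric(cut_p)
      row[[paste0("lor_", tag)]] <- lor_at
      row[[paste0("n_sites_", tag)]] <-
        sum(hits$p_value < p, na.rm = TRUE)
    }
    summary_rows[[gid]] <- row
    .log_line(log_con, gid, ": ", nrow(b$tus), " TUs, ", nrow(b$genes),
              " genes; ", row[[length(row)]], " sites at p < ",
              p_report[length(p_report)])
  }
  summary <- bind_rows(summary_rows)
  readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))

  reg_all <- bind_rows(regulons)
  readr::write_tsv(reg_all, file.path(out_dir, "regulons.tsv"))

  conservation <- NULL; tree <- NULL
  all_nonempty <- all(map_int(regulons, nrow) > 0)
  if (length(bundles) >= 3 && !is.null(ortholog_map) && all_nonempty) {
    conservation <- stage("conservation",
      conservation_distance_matrix(reg_all, ortholog_map,
                                   genome_ids = names(bundles)))
    write_phylip_dist(conservation, file.path(out_dir, "dist.phylip"))
    tree <- stage("tree", neighbor_joining(conservation))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  } else {
    .log_line(log_con, "conservation tree skipped (needs >= 3 genomes, an ",
              "ortholog map and non-empty regulons)")
  }

  files <- setdiff(list.files(out_dir), c("manifest.tsv", "run.log"))
  manifest <- tibble(file = files,
                     md5 = as.character(tools::md5sum(file.path(out_dir, files))))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  .log_line(log_con, "done: ", nrow(manifest), " artifacts in ", out_dir)

  invisible(list(results = results, summary = summary, regulons = reg_all,
                 conservation = conservation, tree = tree,
                 profile = profile, out_dir = out_dir))
}
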