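#' Predict a regulon from scored hits
#'
#' The regulon at a p-value threshold is the union of the member genes of
#' every transcription unit whose best site has `p_value < threshold`
#' (strict). Monotone by construction: a looser threshold yields a
#' superset.
#'
#' @param hits hits tibble from [scan_genome()] with `p_value` filled in.
#' @param genome_id genome identifier recorded on the rows.
#' @param threshold p-value threshold (default 0.01; 0.05 is the customary
#'   looser alternative).
#' @return tibble with `genome_id`, `tu_id`, `gene_id`, one row per member
#'   gene; attribute `threshold`.
#' @export
predict_regulon <- function(hits, genome_id = NULL, threshold = 0.01) {
  if (any(is.na(hits$p_value) & hits$valid)) {
    abort("hits must carry p-values (run empirical_pvalue first)")
  }
  passing <- filter(hits, .data$valid, .data$p_value < threshold)
  out <- passing |>
    select("tu_id", "gene_ids") |>
    unnest("gene_ids") |>
    rename(gene_id = "gene_ids") |>
    mutate(genome_id = genome_id %||% NA_character_, .before = 1) |>
    distinct()
  attr(out, "threshold") <- threshold
  out
}

# ortholog pairs between two genomes as a two-column tibble
.pairs_between <- function(ortholog_map, gi, gj) {
  fwd <- filter(ortholog_map, .data$genome_a == gi, .data$genome_b == gj) |>
    select(gene_i = "gene_a", gene_j = "gene_b")
  bwd <- filter(ortholog_map, .data$genome_a == gj, .data$genome_b == gi) |>
    select(gene_i = "gene_b", gene_j = "gene_a")
  distinct(bind_rows(fwd, bwd))
}

#' Conservation between two regulons
#'
#' Jaccard-style similarity counted through ortholog pairs:
#' `c = |shared| / (|R_i| + |R_j| - |shared|)`, where `|shared|` is the
#' number of ortholog pairs with one member gene in each regulon.
#' Undefined (NA, with a warning) when both regulons are empty.
#'
#' @param genes_i,genes_j character vectors of regulon member gene ids (or
#'   regulon tibbles from [predict_regulon()]).
#' @param genome_i,genome_j their genome ids (taken from the tibbles when
#'   omitted).
#' @param ortholog_map ortholog map covering the genome pair.
#' @return similarity in `[0, 1]`, or NA when undefined.
#' @export
regulon_conservation <- function(genes_i, genes_j, ortholog_map,
                                 genome_i = NULL, genome_j = NULL) {
  if (is.data.frame(genes_i)) {
    genome_i <- genome_i %||% genes_i$genome_id[1]
    genes_i <- unique(genes_i$gene_id)
  }
  if (is.data.frame(genes_j)) {
    genome_j <- genome_j %||% genes_j$genome_id[1]
    genes_j <- unique(genes_j$gene_id)
  }
  genes_i <- unique(genes_i); genes_j <- unique(genes_j)
  if (length(genes_i) == 0 && length(genes_j) == 0) {
    warn("both regulons are empty: conservation undefined")
    return(NA_real_)
  }
  pairs <- .pairs_between(ortholog_map, genome_i, genome_j)
  shared <- nrow(filter(pairs, .data$gene_i %in% genes_i,
                        .data$gene_j %in% genes_j))
  shared / (length(genes_i) + length(genes_j) - shared)
}

#' Pairwise regulon conservation and distance matrices
#'
#' Computes the conservation `c(i,j)` for every genome pair and turns it
#' into a tree-ready distance `d(i,j) = 1/c(i,j)` (off-diagonal; the
#' diagonal is forced to zero). Pairs with `c = 0` get a finite capped
#' distance (`zero_cap`, default 10 times the largest finite distance).
#'
#' @param regulons tibble binding the [predict_regulon()] results of all
#'   genomes (`genome_id`, `gene_id`), or a named list of gene-id vectors.
#' @param ortholog_map ortholog map covering every genome pair.
#' @param genome_ids genomes to include (defaults to those present in
#'   `regulons`; list names when a list is given).
#' @param zero_cap distance assigned to `c = 0` pairs.
#' @return a `conservation_matrix`: list with genome ids, similarity matrix
#'   `c` and distance matrix `d`.
#' @export
conservation_distance_matrix <- function(regulons, ortholog_map,
                                         genome_ids = NULL, zero_cap = NULL) {
  if (is.data.frame(regulons)) {
    genome_ids <- genome_ids %||% unique(regulons$genome_id)
    reg_list <- map(setNames(genome_ids, genome_ids),
                    ~ unique(regulons$gene_id[regulons$genome_id == .x]))
  } else {
    genome_ids <- genome_ids %||% names(regulons)
    reg_list <- regulons[genome_ids]
  }
  k <- length(genome_ids)
  cm <- diag(1, k)
  dimnames(cm) <- list(genome_ids, genome_ids)
  undefined <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cij <- regulon_conservation(reg_list[[i]], reg_list[[j]], ortholog_map,
                                genome_ids[i], genome_ids[j])
    if (is.na(cij)) undefined <- c(undefined,
                                   paste0(genome_ids[i], "-", genome_ids[j]))
    cm[i, j] <- cm[j, i] <- cij
  }
  if (length(undefined) > 0) {
    abort(paste0("conservation undefined (both regulons empty) for pair(s): ",
                 paste(undefined, collapse = ", ")))
  }
  dm <- 1 / cm
  diag(dm) <- 0
  finite_max <- suppressWarnings(max(dm[is.finite(dm)]))
  if (is.null(zero_cap)) zero_cap <- 10 * finite_max
  dm[!is.finite(dm)] <- zero_cap
  structure(list(genome_ids = genome_ids, c = cm, d = dm,
                 zero_cap = zero_cap),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("<conservation_matrix> ", length(x$genome_ids), " genomes; ",
      "c in [", sprintf("%.3f", min(x$c[upper.tri(x$c)])), ", ",
      sprintf("%.3f", max(x$c[upper.tri(x$c)])), "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.conservation_matrix <- function(x, ...) {
  k <- length(x$genome_ids)
  idx <- which(upper.tri(x$c), arr.ind = TRUE)
  tibble(genome_i = x$genome_ids[idx[, 1]],
         genome_j = x$genome_ids[idx[, 2]],
         c = x$c[idx], d = x$d[idx])
}

#' Neighbor-joining tree of regulon conservation distances
#'
#' Standard neighbor-joining agglomeration of the pairwise distance
#' matrix. Negative branch lengths, which NJ can produce on non-additive
#' matrices, are clamped to zero with the deficit moved to the sister
#' branch so tip-to-tip path lengths through the parent are preserved.
#'
#' @param x a `conservation_matrix` (from
#'   [conservation_distance_matrix()]) or a symmetric numeric distance
#'   matrix with zero diagonal and row/column names.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(x) {
  d <- if (inherits(x, "conservation_matrix")) x$d else as.matrix(x)
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 taxa")
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative branch lengths, moving the deficit to the sister edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Write / read a square PHYLIP distance matrix
#'
#' Plain square PHYLIP format: the number of taxa on the first line, then
#' one line per taxon with its name and the full distance row. Distances
#' are written with 6 decimals and round-trip to that precision.
#'
#' @param x a `conservation_matrix` or a distance matrix with names.
#' @param path file path.
#' @return `path` (write) or the named distance matrix (read).
#' @export
write_phylip_dist <- function(x, path) {
  d <- if (inherits(x, "conservation_matrix")) x$d else as.matrix(x)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(rownames(d)[i],
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  nm <- vapply(toks, `[[`, character(1), 1)
  d <- t(vapply(toks, function(x) as.numeric(x[-1]), numeric(n)))
  dimnames(d) <- list(nm, nm)
  d
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
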