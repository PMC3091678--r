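#' Curated cyanobacterial LexA binding sites
#'
#' The 48 published 14-bp LexA boxes recovered by phylogenetic footprinting
#' across cyanobacterial genomes, shipped as a plain TSV. `position` is the
#' reported offset of the site relative to the translation start of the
#' transcription unit's first gene (negative = upstream).
#'
#' @return tibble with `genome`, `tu`, `name`, `sequence`, `position`.
#' @export
#' @examples
#' sites <- lexa_sites()
#' nrow(sites)       # 48
#' nchar(sites$sequence[1])  # 14
lexa_sites <- function() {
  path <- system.file("extdata", "lexa_sites.tsv", package = "regulonscan")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    genome = "c", tu = "c", name = "c",
                    sequence = "c", position = "i"))
}

#' Upper bound of a profile column's information content
#'
#' The relative entropy of a pseudocounted profile column against background
#' `q` is maximal when all `n` sites carry the background's rarest base; the
#' bound depends only on `n` and `q`:
#' `a = (n+1)/(n+4) log(n+1) - log(n+4) - 1/(n+4) sum(log q) - n/(n+4) log q0`
#' with `q0 = min(q)` (natural log, nats).
#'
#' @param n number of sites in the profile.
#' @param q background base frequencies (named `A`, `C`, `G`, `T`; all > 0).
#' @return the bound `a` in nats.
#' @export
info_bound <- function(n, q) {
  stopifnot(all(q > 0), abs(sum(q) - 1) < 1e-6)
  q0 <- min(q)
  (n + 1) / (n + 4) * log(n + 1) - log(n + 4) -
    sum(log(q)) / (n + 4) - n / (n + 4) * log(q0)
}

#' Build a motif profile from equal-length binding sites
#'
#' Per-position base counts receive one pseudocount each, giving frequencies
#' `p(i,b) = (counts(i,b)+1)/(n+4)`. Each column's relative entropy against
#' the background, `sum_b p log(p/q)`, is divided by its analytic upper
#' bound [info_bound()] so the normalized information `I_i` lies in (0, 1].
#' All logarithms are natural; scores downstream are in nats.
#'
#' @param sites character vector of equal-length ACGT strings, or a data
#'   frame with a `sequence` column (e.g. [lexa_sites()]).
#' @param background named base-frequency vector, e.g. from
#'   [compute_background()]; uniform by default.
#' @return a `motif_profile`: list with site length `l`, site count `n`,
#'   `counts` and `p` (4 x l matrices, rows A/C/G/T), background `q`,
#'   normalized information `I`, raw column information `info_raw` and the
#'   bound `a`.
#' @export
build_profile <- function(sites, background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  if (is.data.frame(sites)) sites <- sites$sequence
  sites <- toupper(as.character(sites))
  if (length(sites) < 1) abort("at least one site is required")
  l <- unique(nchar(sites))
  if (length(l) != 1) abort("all sites must have the same length")
  bad <- sites[grepl("[^ACGT]", sites)]
  if (length(bad) > 0) {
    abort(paste0("site(s) contain ambiguous bases: ",
                 paste(bad, collapse = ", ")))
  }
  q <- background[DNA_BASES]
  if (anyNA(q) || any(q <= 0)) abort("background must name A,C,G,T with positive frequencies")
  n <- length(sites)

  mat <- do.call(rbind, strsplit(sites, ""))
  counts <- vapply(seq_len(l), function(i) {
    tabulate(factor(mat[, i], levels = DNA_BASES), nbins = 4)
  }, integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  p <- (counts + 1) / (n + 4)
  info_raw <- colSums(p * log(p / as.numeric(q)))
  a <- info_bound(n, q)
  structure(list(l = l, n = n, counts = counts, p = p, q = q,
                 I = info_raw / a, info_raw = info_raw, a = a,
                 sites = sites),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("<motif_profile> ", x$n, " sites x ", x$l, " bp\n", sep = "")
  cat("  consensus: ", consensus(x), "\n", sep = "")
  cat("  normalized information per column (bound a = ",
      signif(x$a, 4), " nats):\n  ", sep = "")
  cat(paste(sprintf("%.2f", x$I), collapse = " "), "\n")
  invisible(x)
}

#' Degenerate IUPAC consensus of a profile
#'
#' Per column: the single base whose raw frequency (counts/n, without
#' pseudocounts) reaches `major_frac`; failing that, the two-base IUPAC code
#' when the top two bases jointly reach `pair_frac`; otherwise `N`.
#'
#' @param profile a [build_profile()] object.
#' @param major_frac single-base threshold.
#' @param pair_frac joint threshold for a two-base code.
#' @return a single IUPAC string of length `l`.
#' @export
consensus <- function(profile, major_frac = 0.5, pair_frac = 0.75) {
  iupac2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  freq <- profile$counts / profile$n
  chars <- vapply(seq_len(profile$l), function(i) {
    f <- sort(freq[, i], decreasing = TRUE)
    if (f[1] >= major_frac) return(names(f)[1])
    if (f[1] + f[2] >= pair_frac) {
      key <- paste(sort(names(f)[1:2]), collapse = "")
      return(iupac2[[key]])
    }
    "N"
  }, character(1))
  paste(chars, collapse = "")
}

#' Write a profile in minimal MEME motif format
#'
#' Writes the letter-probability matrix (pseudocounted frequencies) with the
#' profile's background, readable by standard motif tools; a read-back with
#' [read_meme_motif()] reproduces `p` to 1e-6.
#'
#' @param profile a [build_profile()] object.
#' @param path output file.
#' @param name motif name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(profile, path, name = "motif1") {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) abort(paste0("cannot write to ", path))
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, profile$q), collapse = " "),
               "",
               paste0("MOTIF ", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       profile$l, profile$n)), con)
  writeLines(apply(profile$p, 2, function(col)
    paste(sprintf("%.6f", col), collapse = " ")), con)
  invisible(path)
}

#' Read a minimal MEME motif file
#'
#' @param path file written by [write_meme_motif()] (or any single-motif
#'   minimal MEME file).
#' @return list with `name`, `w`, `nsites`, letter-probability matrix `p`
#'   (4 x w, rows A/C/G/T) and the file's background `q`.
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  q <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  if (length(bg_i) > 0) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    q <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])[DNA_BASES]
  }
  m_i <- grep("^MOTIF", lines)
  if (length(m_i) == 0) abort("no MOTIF record found")
  name <- strsplit(trimws(lines[m_i[1]]), "\\s+")[[1]][2]
  h_i <- grep("^letter-probability matrix", lines)
  hdr <- lines[h_i[1]]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
  nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
  rows <- lines[(h_i[1] + 1):(h_i[1] + w)]
  p <- vapply(strsplit(trimws(rows), "\\s+"),
              function(x) as.numeric(x[1:4]), numeric(4))
  rownames(p) <- DNA_BASES
  list(name = name, w = w, nsites = nsites, p = p, q = q)
}

# position-specific weight matrix for scanning a genome with background q:
# w[b, i] = I_i * log(p(i,b) / q(b)); I is fixed at profile build time.
profile_weights <- function(profile, q) {
  q <- q[DNA_BASES]
  w <- log(profile$p / as.numeric(q)) *
    matrix(profile$I, nrow = 4, ncol = profile$l, byrow = TRUE)
  dimnames(w) <- list(DNA_BASES, NULL)
  w
}

#' @export
tidy.motif_profile <- function(x, ...) {
  tibble(position = rep(seq_len(x$l), each = 4),
         base = rep(DNA_BASES, x$l),
         count = as.integer(x$counts),
         freq = as.numeric(x$p),
         info = rep(x$I, each = 4))
}

#' @export
glance.motif_profile <- function(x, ...) {
  tibble(l = x$l, n_sites = x$n, a = x$a,
         mean_info = mean(x$I), total_info_raw = sum(x$info_raw),
         consensus = consensus(x))
}

#' @export
autoplot.motif_profile <- function(object, ...) {
  df <- tibble(position = seq_len(object$l), info = object$I)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$info)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "motif position", y = "normalized information I",
                  title = "Profile column information (relative entropy / bound a)") +
    ggplot2::theme_minimal()
}
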