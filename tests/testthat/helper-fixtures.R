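# small in-code fixtures shared across tests

uniform_q <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a 3 kb single-replicon genome with 4 genes (2 plus, 2 minus) as a bundle
tiny_bundle <- function(seed = 42) {
  withr::with_seed(seed, {
    seq_chr <- random_dna(3000)
    genes <- tibble::tibble(
      gene_id = c("gA", "gB", "gC", "gD"),
      replicon_id = "chr",
      start = c(201L, 720L, 1500L, 2400L),
      end = c(700L, 1300L, 2100L, 2900L),
      strand = c("+", "+", "-", "-"))
    genome_bundle("tiny", c(chr = seq_chr), genes)
  })
}

# plain-R brute-force best-site oracle, independent of the scanner path:
# enumerates every l-mer on both strands and recomputes the score per column
oracle_best_site <- function(profile, seq_chr, q, both_strands = TRUE) {
  l <- profile$l
  n <- nchar(seq_chr)
  if (n < l) return(list(s_M = NA_real_, offset = NA_integer_, strand = NA))
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  score1 <- function(win) {
    b <- strsplit(win, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(NA_real_)
    tot <- 0
    for (i in seq_len(l)) {
      tot <- tot + profile$I[i] * log(profile$p[b[i], i] / q[[b[i]]])
    }
    unname(tot)
  }
  best <- list(s_M = NA_real_, offset = NA_integer_, strand = NA_character_)
  for (j in 0:(n - l)) {
    win <- substr(seq_chr, j + 1, j + l)
    sp <- score1(win)
    if (!is.na(sp) && (is.na(best$s_M) || sp > best$s_M)) {
      best <- list(s_M = sp, offset = j, strand = "+")
    }
    if (both_strands) {
      sm <- score1(rc(win))
      if (!is.na(sm) && (is.na(best$s_M) || sm > best$s_M)) {
        best <- list(s_M = sm, offset = j, strand = "-")
      }
    }
  }
  best
}

# fake null distribution from explicit scores
fake_null <- function(scores, genome_id = "fake") {
  structure(list(genome_id = genome_id, scores = sort(scores),
                 n_samples_per_region = length(scores), n_regions = 1L,
                 seed = 0L),
            class = "null_distribution")
}

# least-squares brute force over the three unrooted 4-taxon topologies:
# for each split, OLS-fit the 5 branch lengths to the 6 pairwise distances
# and keep the topology with the smallest residual sum of squares
ls_best_topology <- function(d) {
  splits <- list(c(1, 2), c(1, 3), c(1, 4))  # pair grouped with taxon 1
  fits <- lapply(splits, function(sp) {
    pair1 <- sp; pair2 <- setdiff(1:4, sp)
    combs <- utils::combn(4, 2)
    X <- t(apply(combs, 2, function(ij) {
      v <- numeric(5); v[ij[1]] <- 1; v[ij[2]] <- 1
      same <- (all(ij %in% pair1)) || (all(ij %in% pair2))
      if (!same) v[5] <- 1
      v
    }))
    y <- apply(combs, 2, function(ij) d[ij[1], ij[2]])
    fit <- stats::lm.fit(X, y)
    list(split = sp, rss = sum(fit$residuals^2), coef = fit$coefficients)
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}
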