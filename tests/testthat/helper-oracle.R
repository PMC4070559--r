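# Independent oracles used across the suite. These deliberately avoid the
# package's integer-coded index and vectorised alignment arrays: words are
# enumerated as strings, and alignment scores come from a top-down memoised
# reference aligner plus explicit enumeration over genes and split points.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# all masked words of a gene set under a seed, as strings
oracle_masked_words <- function(genes, seed) {
  out <- character(0)
  for (g in genes) {
    L <- nchar(g)
    if (L < seed$span) next
    for (p in seq_len(L - seed$span + 1L)) {
      w <- apply_seed(substr(g, p, p + seed$span - 1L), seed)
      if (!grepl("N", w, fixed = TRUE)) out <- c(out, w)
    }
  }
  unique(out)
}

# brute-force replacement for classify_word: substring scan of the germline
oracle_classify <- function(v_genes, j_genes, seed, word) {
  vw <- oracle_masked_words(v_genes, seed)
  jw <- oracle_masked_words(j_genes, seed)
  label_of <- function(w) {
    if (grepl("N", w, fixed = TRUE)) return("NONE")
    m <- apply_seed(w, seed)
    inv <- m %in% vw; inj <- m %in% jw
    if (inv && inj) "AMBIGUOUS" else if (inv) "V" else if (inj) "J" else "NONE"
  }
  f <- label_of(word)
  r <- label_of(reverse_complement(word))
  if (f != "NONE" && r != "NONE") {
    list(label = "AMBIGUOUS", strand = "conflict")
  } else if (f != "NONE") {
    list(label = f, strand = "+")
  } else if (r != "NONE") {
    list(label = r, strand = "-")
  } else {
    list(label = "NONE", strand = "+")
  }
}

# reference semi-global score matrix: h(i, j) = best score of an alignment
# of gene[.. j] against seq[.. i] ending exactly at (i, j), with free start
# in both sequences; computed by top-down memoised recursion
oracle_end_matrix <- function(seq, gene, scoring) {
  a <- strsplit(seq, "", fixed = TRUE)[[1L]]
  g <- strsplit(gene, "", fixed = TRUE)[[1L]]
  memo <- matrix(NA_real_, length(a) + 1L, length(g) + 1L)
  h <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    s <- if (a[i] == g[j]) scoring$match else scoring$mismatch
    val <- max(h(i - 1L, j - 1L) + s,
               h(i - 1L, j) + scoring$gap,
               h(i, j - 1L) + scoring$gap)
    memo[i + 1L, j + 1L] <<- val
    val
  }
  for (i in seq_along(a)) for (j in seq_along(g)) h(i, j)
  memo[is.na(memo)] <- 0
  memo
}

# best V-side score for every end position e (1-based), over genes and trims
oracle_best_v_end <- function(seq, v_genes, scoring) {
  n <- nchar(seq)
  best <- rep(-Inf, n)
  for (g in v_genes) {
    H <- oracle_end_matrix(seq, g, scoring)
    for (e in seq_len(n)) best[e] <- max(best[e], max(H[e + 1L, ]))
  }
  best
}

# best J-side score for every start position s (1-based): mirror from right
oracle_best_j_start <- function(seq, j_genes, scoring) {
  revstr <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                              collapse = "")
  n <- nchar(seq)
  rb <- oracle_best_v_end(revstr(seq), vapply(j_genes, revstr, character(1L)),
                          scoring)
  rb[n:1]
}

# brute-force designation score: enumerate all (v end, j start) pairs
oracle_segment_score <- function(seq, db, scoring) {
  bv <- oracle_best_v_end(seq, db$v_genes, scoring)
  bj <- oracle_best_j_start(seq, db$j_genes, scoring)
  n <- nchar(seq)
  best <- -Inf
  for (e in seq_len(n - 1L)) {
    for (s in (e + 1L):n) {
      best <- max(best, bv[e] + bj[s])
    }
  }
  best
}

# small fixed toy database used by several index/scan tests
toy_db <- function() {
  germline_db("TOY", v_genes = c(v1 = "AAACCC"), j_genes = c(j1 = "ACCCGG"),
              seed = seed_pattern("####"), w = 4L)
}

# a small but realistic synthetic TRG-like germline, cached per session
trg_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_synthetic_germline(rng_seed = 42L)
    cache
  }
})
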