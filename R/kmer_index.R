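# Integer encoding of masked k-words. Bases map A,C,G,T -> 0..3; any other
# character (N) gives NA, so words containing N never enter or match the
# index. A masked word of weight k is encoded in base 4 as a double; k <= 13
# keeps codes < 4^13, exactly representable.

.base_code_map <- local({
  m <- rep(NA_real_, 256L)
  m[utf8ToInt("A")] <- 0
  m[utf8ToInt("C")] <- 1
  m[utf8ToInt("G")] <- 2
  m[utf8ToInt("T")] <- 3
  m
})

# DNA string -> numeric vector of per-base codes (NA for non-ACGT)
seq_to_base_codes <- function(s) {
  .base_code_map[utf8ToInt(s)]
}

# complement in code space (A<->T, C<->G); NA stays NA
complement_codes <- function(b) 3 - b

# codes of all masked words of `seed` along a base-code vector; position i
# (1-based) covers bases i .. i+span-1. Returns numeric(0) if too short.
masked_word_codes <- function(base, seed) {
  n <- length(base) - seed$span + 1L
  if (n < 1L) return(numeric(0L))
  code <- numeric(n)
  idx <- seq_len(n)
  for (off in seed$offsets) {
    code <- code * 4 + base[idx + off - 1L]
  }
  code
}

# encode one raw word (length == span) under the seed; NA if it contains N
encode_word <- function(word, seed) {
  b <- seq_to_base_codes(word)
  if (length(b) != seed$span) {
    stop(sprintf("word length %d does not match seed span %d",
                 length(b), seed$span))
  }
  masked_word_codes(b, seed)
}

.LBL_NONE <- 0L
.LBL_V <- 1L
.LBL_J <- 2L
.LBL_AMBIG <- 3L

.label_names <- c("NONE", "V", "J", "AMBIGUOUS")

label_to_string <- function(lbl) .label_names[lbl + 1L]

#' Build the labeled k-word index over germline V and J genes
#'
#' Every masked k-word occurring in a forward-strand germline V (resp. J)
#' gene is labeled `V` (resp. `J`); words occurring in both sets are
#' labeled `AMBIGUOUS`. D genes are not indexed; words containing `N` are
#' skipped. This index is the heuristic's only germline knowledge: read
#' classification never aligns against germline sequences.
#'
#' The index is stored as a flat table of 4^k integer labels when the seed
#' weight k is small (build cost O(r + 4^k) for total germline size r), and
#' as a sorted key table otherwise. Both storage modes answer queries
#' identically.
#'
#' @param db A [germline_db()].
#' @param seed A `vdj_seed`; defaults to the database's seed.
#' @param storage "auto", "flat" or "hash".
#' @param flat_max_weight Maximum seed weight for which "auto" chooses the
#'   flat table (default 12).
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(db, seed = db$seed,
                             storage = c("auto", "flat", "hash"),
                             flat_max_weight = 12L) {
  stopifnot(inherits(db, "germline_db"), inherits(seed, "vdj_seed"))
  storage <- match.arg(storage)
  gene_codes <- function(genes) {
    out <- lapply(genes, function(g) {
      cc <- masked_word_codes(seq_to_base_codes(g), seed)
      cc[!is.na(cc)]
    })
    unique(unlist(out, use.names = FALSE))
  }
  v_codes <- gene_codes(db$v_genes)
  j_codes <- gene_codes(db$j_genes)
  if (length(v_codes) == 0L) {
    stop("build_kmer_index: no indexable k-word in the V gene set at seed ",
         seed$pattern)
  }
  if (length(j_codes) == 0L) {
    stop("build_kmer_index: no indexable k-word in the J gene set at seed ",
         seed$pattern)
  }
  both <- intersect(v_codes, j_codes)
  mode <- if (storage == "auto") {
    if (seed$weight <= flat_max_weight) "flat" else "hash"
  } else storage
  if (mode == "flat" && seed$weight > 15L) {
    stop("flat storage not addressable at seed weight ", seed$weight)
  }
  idx <- list(seed = seed, mode = mode, n_ambiguous = length(both))
  if (mode == "flat") {
    tab <- integer(4^seed$weight)
    tab[v_codes + 1] <- .LBL_V
    tab[j_codes + 1] <- .LBL_J
    tab[both + 1] <- .LBL_AMBIG
    idx$tab <- tab
  } else {
    keys <- sort(unique(c(v_codes, j_codes)))
    labels <- integer(length(keys))
    labels[keys %in% v_codes] <- .LBL_V
    labels[keys %in% j_codes] <- .LBL_J
    labels[keys %in% both] <- .LBL_AMBIG
    idx$keys <- keys
    idx$labels <- labels
  }
  structure(idx, class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  n <- if (x$mode == "flat") sum(x$tab != .LBL_NONE) else length(x$keys)
  cat(sprintf("kmer_index: seed %s, %s storage, %d labeled words (%d ambiguous)\n",
              x$seed$pattern, x$mode, n, x$n_ambiguous))
  invisible(x)
}

# vectorised label lookup for masked-word codes; NA codes -> NONE
lookup_codes <- function(idx, codes) {
  out <- integer(length(codes))
  ok <- !is.na(codes)
  if (!any(ok)) return(out)
  if (idx$mode == "flat") {
    out[ok] <- idx$tab[codes[ok] + 1]
  } else {
    m <- match(codes[ok], idx$keys)
    hit <- !is.na(m)
    vals <- integer(sum(ok))
    vals[hit] <- idx$labels[m[hit]]
    out[ok] <- vals
  }
  out
}

# forward and reverse-complement labels for every word start of a base-code
# vector; rlab[i] is the label of the reverse complement of the word at i
scan_labels <- function(idx, base) {
  flab <- lookup_codes(idx, masked_word_codes(base, idx$seed))
  rc <- complement_codes(rev(base))
  rlab <- rev(lookup_codes(idx, masked_word_codes(rc, idx$seed)))
  list(flab = flab, rlab = rlab)
}

# combine forward/reverse labels at one position into (label, strand)
combine_labels <- function(f, r) {
  if (f != .LBL_NONE && r != .LBL_NONE) {
    c(.LBL_AMBIG, 2L)                     # strand code 2 = conflict
  } else if (f != .LBL_NONE) {
    c(f, 0L)                              # 0 = +
  } else if (r != .LBL_NONE) {
    c(r, 1L)                              # 1 = -
  } else {
    c(.LBL_NONE, 0L)
  }
}

.strand_names <- c("+", "-", "conflict")

#' Classify one k-word against the index
#'
#' Looks up the masked word and the masked word of its reverse complement.
#' If exactly one strand gives a label, that label and strand are returned;
#' if both strands hit, the word is `AMBIGUOUS` with strand `conflict`; if
#' neither hits, `NONE`.
#'
#' @param idx A `kmer_index`.
#' @param word Raw subsequence of length `seed$span` over `{A,C,G,T,N}`.
#' @return List with `label` ("V", "J", "AMBIGUOUS" or "NONE") and
#'   `strand` ("+", "-" or "conflict").
#' @export
classify_word <- function(idx, word) {
  stopifnot(inherits(idx, "kmer_index"))
  if (grepl("[^ACGTN]", word)) stop("classify_word: word must be over {A,C,G,T,N}")
  f <- lookup_codes(idx, encode_word(word, idx$seed))
  r <- lookup_codes(idx, encode_word(reverse_complement(word), idx$seed))
  z <- combine_labels(f, r)
  list(label = label_to_string(z[1L]), strand = .strand_names[z[2L] + 1L])
}

#' Scan a read for labeled k-words
#'
#' Classifies the k-word at every start position of the read (0-based).
#' Positions where neither strand hits the index are omitted;
#' ambiguous/strand-conflicting hits are retained but flagged, and are
#' excluded from strand and boundary decisions downstream.
#'
#' @param idx A `kmer_index`.
#' @param read DNA string.
#' @return A data.frame with columns `pos` (0-based start), `label` and
#'   `strand`; zero rows if the read is shorter than the seed span.
#' @export
scan_sequence <- function(idx, read) {
  stopifnot(inherits(idx, "kmer_index"))
  base <- seq_to_base_codes(read)
  if (length(base) < idx$seed$span) {
    return(data.frame(pos = integer(0), label = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  sl <- scan_labels(idx, base)
  f <- sl$flab; r <- sl$rlab
  lab <- integer(length(f)); str <- integer(length(f))
  conflict <- f != .LBL_NONE & r != .LBL_NONE
  fonly <- f != .LBL_NONE & !conflict
  ronly <- r != .LBL_NONE & !conflict
  lab[conflict] <- .LBL_AMBIG; str[conflict] <- 2L
  lab[fonly] <- f[fonly]; str[fonly] <- 0L
  lab[ronly] <- r[ronly]; str[ronly] <- 1L
  keep <- lab != .LBL_NONE
  data.frame(pos = which(keep) - 1L,
             label = label_to_string(lab[keep]),
             strand = .strand_names[str[keep] + 1L],
             stringsAsFactors = FALSE)
}
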