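#' Spaced seed patterns
#'
#' A spaced seed is a pattern over `#` (care) and `-` (don't-care) positions
#' used to extract masked k-words from DNA. The seed weight is the number of
#' `#` positions; the span is the total pattern length. Spaced seeds improve
#' matching sensitivity to substitutions at fixed specificity: with the
#' default TRG seed `#####-#####`, an 11 bp subsequence is reduced to a
#' 10-letter word by dropping its middle base.
#'
#' @param pattern Character scalar over `{#, -}`, beginning and ending
#'   with `#`.
#' @return An object of class `vdj_seed` with elements `pattern`, `weight`,
#'   `span` and `offsets` (1-based positions of the `#` characters).
#' @examples
#' seed_pattern("#####-#####")
#' @export
seed_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("#", "-"))) {
    stop("seed pattern must use only '#' and '-': ", pattern)
  }
  if (chars[1L] != "#" || chars[length(chars)] != "#") {
    stop("seed pattern must begin and end with '#': ", pattern)
  }
  offsets <- which(chars == "#")
  structure(
    list(pattern = pattern, weight = length(offsets),
         span = length(chars), offsets = offsets),
    class = "vdj_seed"
  )
}

#' @export
print.vdj_seed <- function(x, ...) {
  cat(sprintf("spaced seed %s (weight %d, span %d)\n",
              x$pattern, x$weight, x$span))
  invisible(x)
}

#' Default seed pattern for a locus
#'
#' TRG uses the weight-10 seed `#####-#####`. TRB and IGH use a weight-12
#' seed, TRA a weight-13 seed; for those loci only the weight is canonical
#' and a single central don't-care is used by analogy with the TRG seed.
#' Unknown loci fall back to the TRG seed.
#'
#' @param locus Locus label such as "TRG", "TRB", "IGH", "TRA".
#' @return A `vdj_seed`.
#' @export
default_seed_for_locus <- function(locus) {
  up <- toupper(locus)
  pat <- if (up %in% c("TRB", "IGH")) {
    "######-######"
  } else if (up == "TRA") {
    "######-#######"
  } else {
    "#####-#####"
  }
  seed_pattern(pat)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` is its own complement.
#'
#' @param s Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,N}")
  }
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""),
         character(1L), USE.NAMES = FALSE)
}

#' Apply a spaced seed to a subsequence
#'
#' Concatenates the characters at the seed's `#` positions, producing a
#' masked word of length `seed$weight`.
#'
#' @param subsequence DNA string whose length equals `seed$span`.
#' @param seed A `vdj_seed`.
#' @return Masked word (character scalar of length `seed$weight`).
#' @examples
#' apply_seed("ACGTACGTACG", seed_pattern("#####-#####"))  # "ACGTAGTACG"
#' @export
apply_seed <- function(subsequence, seed) {
  stopifnot(inherits(seed, "vdj_seed"))
  if (nchar(subsequence) != seed$span) {
    stop(sprintf("apply_seed: subsequence length %d does not match seed span %d",
                 nchar(subsequence), seed$span))
  }
  chars <- strsplit(subsequence, "", fixed = TRUE)[[1L]]
  paste(chars[seed$offsets], collapse = "")
}

#' Germline gene database for one locus
#'
#' Holds named V, (optionally D,) and J germline gene sequences together
#' with the locus default seed and window length. The window length `w`
#' defaults to 40 bp for VJ-recombining loci and 60 bp for VDJ loci, so
#' that the extracted window always contains the complete N-diversity
#' region(s) plus germline flanks.
#'
#' @param locus Locus label (e.g. "TRG").
#' @param v_genes,j_genes Named character vectors of gene sequences
#'   (names are gene identifiers such as "TRGV5*01"); must be non-empty.
#' @param d_genes Named character vector of D genes, or `NULL` for a
#'   VJ-recombining locus.
#' @param seed A `vdj_seed`; defaults to [default_seed_for_locus()].
#' @param w Window length in bp; defaults to 40 (VJ) or 60 (VDJ).
#' @return An object of class `germline_db` with fields `locus`, `v_genes`,
#'   `d_genes`, `j_genes`, `seed`, `w` and `total_size_r` (summed gene
#'   lengths in bp).
#' @export
germline_db <- function(locus, v_genes, j_genes, d_genes = NULL,
                        seed = default_seed_for_locus(locus), w = NULL) {
  check_gene_set <- function(g, what, allow_empty = FALSE) {
    if (is.null(g) || length(g) == 0L) {
      if (allow_empty) return(invisible(NULL))
      stop("germline_db: ", what, " gene set must be non-empty")
    }
    if (is.null(names(g)) || any(names(g) == "") || anyNA(names(g))) {
      stop("germline_db: all ", what, " genes must be named")
    }
    if (anyDuplicated(names(g))) {
      stop("germline_db: duplicate ", what, " gene names: ",
           paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
    }
    if (any(nchar(g) == 0L)) stop("germline_db: empty ", what, " gene sequence")
    if (any(grepl("[^ACGTN]", g))) {
      stop("germline_db: ", what, " sequences must be over {A,C,G,T,N}")
    }
    invisible(NULL)
  }
  check_gene_set(v_genes, "V")
  check_gene_set(j_genes, "J")
  check_gene_set(d_genes, "D", allow_empty = TRUE)
  if (length(d_genes) == 0L) d_genes <- NULL
  stopifnot(inherits(seed, "vdj_seed"))
  if (is.null(w)) w <- if (is.null(d_genes)) 40L else 60L
  w <- as.integer(w)
  if (w < 2L || w %% 2L != 0L) stop("germline_db: w must be an even integer >= 2")
  structure(
    list(locus = locus, v_genes = v_genes, d_genes = d_genes,
         j_genes = j_genes, seed = seed, w = w,
         total_size_r = sum(nchar(v_genes)) + sum(nchar(j_genes)) +
           if (is.null(d_genes)) 0L else sum(nchar(d_genes))),
    class = "germline_db"
  )
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("germline_db %s: %d V, %d D, %d J genes (%d bp total), seed %s, w=%d\n",
              x$locus, length(x$v_genes), length(x$d_genes),
              length(x$j_genes), x$total_size_r, x$seed$pattern, x$w))
  invisible(x)
}

#' Load germline genes from a FASTA file
#'
#' Reads a (possibly gzip-compressed) FASTA file of germline genes.
#' Gene names are taken from the second `|`-separated header field when the
#' header contains `|` (the IMGT/GENE-DB dialect, e.g.
#' `>X58342|TRGV5*01|Homo sapiens|F|V-REGION` gives `TRGV5*01`), otherwise
#' from the first whitespace-delimited token. Sequences are uppercased and
#' `U` is mapped to `T`, so downstream code sees a single DNA alphabet.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @param gene_type One of "V", "D", "J" (recorded for the caller; the
#'   parsing itself is identical).
#' @param name_field "auto" (dialect sniffing as above), "imgt" (always the
#'   second `|` field) or "token" (always the first token).
#' @return Named character vector of uppercase gene sequences.
#' @export
load_germline_fasta <- function(path, gene_type = c("V", "D", "J"),
                                name_field = c("auto", "imgt", "token")) {
  gene_type <- match.arg(gene_type)
  name_field <- match.arg(name_field)
  if (!file.exists(path)) stop("germline FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("germline FASTA format error: no records in ", path)
  }
  headers <- names(set)
  pick_name <- function(h) {
    if (name_field == "imgt" || (name_field == "auto" && grepl("|", h, fixed = TRUE))) {
      fields <- strsplit(h, "|", fixed = TRUE)[[1L]]
      if (length(fields) < 2L) {
        stop("germline FASTA format error: cannot extract IMGT name from header '", h, "'")
      }
      trimws(fields[2L])
    } else {
      strsplit(trimws(h), "[[:space:]]+")[[1L]][1L]
    }
  }
  nms <- vapply(headers, pick_name, character(1L), USE.NAMES = FALSE)
  seqs <- chartr("U", "T", toupper(as.character(set)))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("germline FASTA format error: empty sequence for record '",
         nms[which(empty)[1L]], "'")
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    bad <- nms[grepl("[^ACGTN]", seqs)][1L]
    stop("germline FASTA format error: non-ACGTN characters in record '", bad, "'")
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(seqs) <- nms
  seqs
}

#' Write germline genes to a FASTA file
#'
#' @param genes Named character vector of gene sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(genes, path) {
  set <- Biostrings::DNAStringSet(genes)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
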