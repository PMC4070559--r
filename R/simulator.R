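# Local RNG handling: simulator entry points take an rng_seed and restore
# the caller's RNG state on exit, so simulations are reproducible without
# clobbering the session stream. rng_seed = NULL uses the current stream.

with_sim_rng <- function(rng_seed, expr) {
  if (is.null(rng_seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng_seed)
  expr
}

random_dna <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic germline database
#'
#' Draws i.i.d. uniform-ACGT germline genes with lengths uniform in the
#' typical ranges for V(D)J loci: V genes 250-310 bp, D genes 10-35 bp,
#' J genes 40-70 bp. The database is regenerated (bounded retries) until
#' the locus seed yields an index with zero ambiguous k-words, matching
#' the property of the real TRG germline under the weight-10 spaced seed.
#' Deterministic given `rng_seed`.
#'
#' @param n_v,n_j,n_d Gene counts (`n_v`, `n_j` >= 1; `n_d = 0` gives a
#'   VJ-recombining locus).
#' @param locus Locus label used for gene names and the default seed.
#' @param v_len_range,d_len_range,j_len_range Length ranges in bp.
#' @param seed A `vdj_seed`; defaults to the locus default.
#' @param w Window length; defaults to 40 (VJ) or 60 (VDJ).
#' @param rng_seed Integer seed.
#' @param max_retries Maximum regenerations before giving up.
#' @return A [germline_db()].
#' @export
make_synthetic_germline <- function(n_v = 5L, n_j = 3L, n_d = 0L,
                                    locus = "TRG",
                                    v_len_range = c(250L, 310L),
                                    d_len_range = c(10L, 35L),
                                    j_len_range = c(40L, 70L),
                                    seed = default_seed_for_locus(locus),
                                    w = NULL, rng_seed = 1L,
                                    max_retries = 25L) {
  if (n_v < 1L || n_j < 1L) {
    stop("make_synthetic_germline: need at least one V and one J gene")
  }
  with_sim_rng(rng_seed, {
    gene_set <- function(prefix, n, range) {
      lens <- sample(range[1L]:range[2L], n, replace = TRUE)
      stats::setNames(vapply(lens, random_dna, character(1L)),
                      paste0(locus, prefix, seq_len(n), "*01"))
    }
    for (try in seq_len(max_retries)) {
      v <- gene_set("V", n_v, v_len_range)
      j <- gene_set("J", n_j, j_len_range)
      d <- if (n_d > 0L) gene_set("D", n_d, d_len_range) else NULL
      db <- germline_db(locus, v, j, d_genes = d, seed = seed, w = w)
      idx <- build_kmer_index(db)
      if (idx$n_ambiguous == 0L) return(db)
    }
    stop("make_synthetic_germline: could not obtain an ambiguity-free germline in ",
         max_retries, " tries; use a longer seed")
  })
}

#' Simulate one V(D)J recombination
#'
#' Chooses V and J (and D, when present) genes uniformly, draws end
#' deletions uniformly from `del_range` (resampling when a deletion would
#' exceed the chosen gene) and N-region lengths uniformly from
#' `n_len_range` with uniform-ACGT content (two N regions for VDJ). The
#' full sequence is assembled with [reconstruct_from_designation()].
#' Uses the current RNG stream unless `rng_seed` is given.
#'
#' @param db A [germline_db()].
#' @param del_range,n_len_range Integer ranges (inclusive).
#' @param rng_seed Optional integer seed.
#' @return List with the designation fields (`v_name`, `v_del`,
#'   `n_region` or `n1`/`d_name`/`d5_del`/`d3_del`/`n2`, `j_del`,
#'   `j_name`), `full_sequence` and `junction_center` (0-based midpoint of
#'   the inserted region; the last V base when nothing is inserted).
#' @export
simulate_recombination <- function(db, del_range = c(0L, 8L),
                                   n_len_range = c(0L, 10L),
                                   rng_seed = NULL) {
  stopifnot(inherits(db, "germline_db"))
  with_sim_rng(rng_seed, {
    draw_in <- function(range) sample(range[1L]:range[2L], 1L)
    v_name <- sample(names(db$v_genes), 1L)
    j_name <- sample(names(db$j_genes), 1L)
    v_len <- nchar(db$v_genes[[v_name]])
    j_len <- nchar(db$j_genes[[j_name]])
    repeat { v_del <- draw_in(del_range); if (v_del < v_len) break }
    repeat { j_del <- draw_in(del_range); if (j_del < j_len) break }
    seg <- list(segmented = TRUE, v_name = v_name, v_del = v_del,
                j_del = j_del, j_name = j_name)
    if (is.null(db$d_genes)) {
      seg$n_region <- random_dna(draw_in(n_len_range))
    } else {
      d_name <- sample(names(db$d_genes), 1L)
      d_len <- nchar(db$d_genes[[d_name]])
      repeat {
        d5 <- draw_in(del_range); d3 <- draw_in(del_range)
        if (d5 + d3 < d_len) break
      }
      seg$d_name <- d_name; seg$d5_del <- d5; seg$d3_del <- d3
      seg$n1 <- random_dna(draw_in(n_len_range))
      seg$n2 <- random_dna(draw_in(n_len_range))
    }
    full <- reconstruct_from_designation(seg, db)
    v_eff <- v_len - v_del
    insert_len <- nchar(full) - v_eff - (j_len - j_del)
    seg$full_sequence <- full
    seg$junction_center <- v_eff + as.integer(floor((insert_len - 1) / 2))
    seg
  })
}

#' Simulate a set of clones
#'
#' @param db A [germline_db()].
#' @param n_clones Number of clones.
#' @inheritParams simulate_recombination
#' @param rng_seed Integer seed (deterministic output).
#' @return List of clones as returned by [simulate_recombination()], each
#'   with an added `clone_id`.
#' @export
simulate_clones <- function(db, n_clones, del_range = c(0L, 8L),
                            n_len_range = c(0L, 10L), rng_seed = 1L) {
  with_sim_rng(rng_seed, {
    lapply(seq_len(n_clones), function(i) {
      cl <- simulate_recombination(db, del_range, n_len_range)
      cl$clone_id <- sprintf("clone%02d", i)
      cl
    })
  })
}

# parse abundances: numeric vector (checked to sum to 1), "geometric(ratio)"
# or NULL (uniform)
resolve_abundances <- function(abundances, n_clones) {
  if (is.null(abundances)) return(rep(1 / n_clones, n_clones))
  if (is.character(abundances)) {
    m <- regmatches(abundances,
                    regexec("^geometric\\(([0-9.eE+-]+)\\)$", abundances))[[1L]]
    if (length(m) != 2L) stop("unrecognised abundance spec: ", abundances)
    ratio <- as.numeric(m[2L])
    a <- ratio^(seq_len(n_clones) - 1L)
    return(a / sum(a))
  }
  if (length(abundances) != n_clones) {
    stop("abundances length ", length(abundances),
         " does not match clone count ", n_clones)
  }
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  abundances
}

#' Generate error-bearing reads from simulated clones
#'
#' Each read is drawn from a clone according to the abundances. In
#' `amplicon` mode the read is the full clone sequence; in `fragment` mode
#' it is a uniform random substring of length `fragment_length`.
#' Substitutions are applied i.i.d. per base at rate `p_sub` (never to the
#' original base); homopolymer indels (+-1 base, Ion Torrent-like) occur
#' with probability `p_homo` per run of length >= 2. The truth sidecar
#' records, per read, the clone, the emitted strand and the junction
#' center in the read's V-to-J orientation after all coordinate
#' transformations (indels upstream of the junction shift it; the strand
#' flip does not). `true_center` is `NA` when a fragment misses the
#' junction.
#'
#' @param clones List of clones from [simulate_clones()].
#' @param n_reads Number of reads.
#' @param abundances Numeric fractions summing to 1, a string
#'   `"geometric(ratio)"`, or `NULL` for uniform.
#' @param read_model "amplicon" or "fragment".
#' @param fragment_length Fragment length L (required in fragment mode;
#'   must not exceed any clone sequence length).
#' @param p_sub Per-base substitution rate.
#' @param p_homo Per-homopolymer-run indel rate.
#' @param random_strand Emit each read on a uniformly random strand.
#' @param rng_seed Integer seed (deterministic output).
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `clone_id`, `strand`, `true_center`,
#'   `v_flank`, `j_flank`).
#' @export
generate_reads <- function(clones, n_reads, abundances = NULL,
                           read_model = c("amplicon", "fragment"),
                           fragment_length = NULL,
                           p_sub = 0, p_homo = 0, random_strand = TRUE,
                           rng_seed = 1L) {
  read_model <- match.arg(read_model)
  n_clones <- length(clones)
  stopifnot(n_clones >= 1L, n_reads >= 0L)
  abund <- resolve_abundances(abundances, n_clones)
  clone_seqs <- vapply(clones, `[[`, character(1L), "full_sequence")
  clone_centers <- vapply(clones, `[[`, numeric(1L), "junction_center")
  clone_ids <- vapply(clones, `[[`, character(1L), "clone_id")
  if (read_model == "fragment") {
    if (is.null(fragment_length)) stop("fragment mode requires fragment_length")
    if (any(nchar(clone_seqs) < fragment_length)) {
      stop("fragment_length ", fragment_length,
           " exceeds a clone sequence length")
    }
  }
  with_sim_rng(rng_seed, {
    assign <- sample.int(n_clones, n_reads, replace = TRUE, prob = abund)
    ids <- sprintf("read%06d", seq_len(n_reads))
    flip <- if (random_strand) stats::runif(n_reads) < 0.5 else rep(FALSE, n_reads)
    error_free <- p_sub == 0 && p_homo == 0
    if (error_free && read_model == "amplicon") {
      rc_seqs <- reverse_complement(clone_seqs)
      reads <- ifelse(flip, rc_seqs[assign], clone_seqs[assign])
      truth <- data.frame(read_id = ids, clone_id = clone_ids[assign],
                          strand = ifelse(flip, "-", "+"),
                          true_center = as.integer(clone_centers[assign]),
                          v_flank = as.integer(clone_centers[assign]),
                          j_flank = nchar(clone_seqs)[assign] - 1L -
                            as.integer(clone_centers[assign]),
                          stringsAsFactors = FALSE)
      names(reads) <- ids
      return(list(reads = reads, truth = truth))
    }
    clone_base <- lapply(clone_seqs, seq_to_base_codes)
    reads <- character(n_reads)
    center_out <- rep(NA_integer_, n_reads)
    vfl <- rep(NA_integer_, n_reads); jfl <- rep(NA_integer_, n_reads)
    for (i in seq_len(n_reads)) {
      cl <- assign[i]
      b <- clone_base[[cl]]
      center <- clone_centers[cl]            # 0-based, may go NA if lost
      if (read_model == "fragment") {
        L <- fragment_length
        start0 <- sample.int(length(b) - L + 1L, 1L) - 1L
        b <- b[(start0 + 1L):(start0 + L)]
        center <- center - start0
        if (center < 0 || center > L - 1L) center <- NA_integer_
      }
      if (p_sub > 0) {
        hit <- which(stats::runif(length(b)) < p_sub)
        if (length(hit) > 0L) {
          b[hit] <- (b[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4
        }
      }
      if (p_homo > 0) {
        r <- rle(b)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- which(r$lengths >= 2L)
        if (length(runs) > 0L) {
          ev <- runs[stats::runif(length(runs)) < p_homo]
          for (p in rev(starts[ev])) {       # right to left keeps positions valid
            if (stats::runif(1L) < 0.5) {
              b <- append(b, b[p], after = p - 1L)   # insertion before p
              if (!is.na(center) && p - 1L <= center) center <- center + 1L
            } else {
              b <- b[-p]                             # deletion of base p
              if (!is.na(center) && p - 1L < center) center <- center - 1L
            }
          }
        }
      }
      if (flip[i]) b_out <- complement_codes(rev(b)) else b_out <- b
      reads[i] <- base_codes_to_string(b_out)
      center_out[i] <- as.integer(center)
      if (!is.na(center)) {
        vfl[i] <- as.integer(center)
        jfl[i] <- length(b) - 1L - as.integer(center)
      }
    }
    names(reads) <- ids
    truth <- data.frame(read_id = ids, clone_id = clone_ids[assign],
                        strand = ifelse(flip, "-", "+"),
                        true_center = center_out,
                        v_flank = vfl, j_flank = jfl,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ records carry a constant quality of `I` (the pipeline never uses
#' quality values).
#'
#' @param reads Named character vector of reads.
#' @param path Output path; a `.fastq`/`.fq` extension (optionally `.gz`)
#'   selects FASTQ, anything else FASTA.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads)
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ (plain or gzip)
#'
#' @param path Input path; `.fastq`/`.fq` (optionally `.gz`) is parsed as
#'   FASTQ, anything else as FASTA. Qualities are read but ignored.
#' @return Named character vector of uppercase reads; names are the first
#'   whitespace-delimited header tokens.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(names(set), function(h)
    strsplit(trimws(h), "[[:space:]]+")[[1L]][1L], character(1L),
    USE.NAMES = FALSE)
  seqs
}
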