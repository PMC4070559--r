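#' Representative-sequence parameters
#'
#' @param k_rep k-mer length used for clone-wide support counting. Defaults
#'   to the locus seed weight (10 for TRG) for consistency with the window
#'   heuristic, but is an independent parameter.
#' @param threshold Relative support threshold in (0, 1]: a k-mer is
#'   supported when it is present in at least `ceiling(threshold * clone
#'   size)` of the clone's reads (default 0.5).
#' @return An object of class `representative_params`.
#' @export
representative_params <- function(k_rep = 10L, threshold = 0.5) {
  k_rep <- as.integer(k_rep)
  if (is.na(k_rep) || k_rep < 4L) stop("representative_params: k_rep must be >= 4")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("representative_params: threshold must be in (0, 1]")
  }
  structure(list(k_rep = k_rep, threshold = threshold),
            class = "representative_params")
}

# k-mer start positions of one read that are over {A,C,G,T} entirely
read_kmers <- function(read, k) {
  L <- nchar(read)
  if (k > L) return(character(0))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(read, starts, starts + k - 1L)
  kmers[!grepl("N", kmers, fixed = TRUE)]
}

#' Count per-read k-mer presence within a clone
#'
#' Each k-mer is counted once per read containing it (presence, not
#' occurrences), so the counts are comparable to the clone size. k-mers
#' containing `N` are skipped.
#'
#' @param reads Character vector of the clone's reads (non-empty).
#' @param k_rep k-mer length.
#' @return Named integer vector: k-mer -> number of reads containing it
#'   (empty when `k_rep` exceeds every read length).
#' @export
clone_kmer_presence <- function(reads, k_rep) {
  stopifnot(length(reads) >= 1L)
  per_read <- lapply(reads, function(r) unique(read_kmers(r, k_rep)))
  all_kmers <- unlist(per_read, use.names = FALSE)
  if (length(all_kmers) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(all_kmers)
  stats::setNames(as.integer(tab), names(tab))
}

#' Compute a clone's representative sequence
#'
#' Counts the k-mers of all clone reads, then scans each read for maximal
#' runs of positions whose every k-mer has support at least
#' `T = ceiling(threshold * clone size)` (representative regions). Among
#' candidate regions that fully contain the clone's seed window the longest
#' is returned (ties: first read in input order, then leftmost). If no
#' candidate contains the window, the longest candidate overlapping it is
#' returned; if none overlaps, the window string itself is the fallback.
#' Full containment is preferred over bare overlap because the refined
#' V(D)J designation needs germline flanks on both sides of the junction.
#'
#' @param reads Character vector of the clone's reads, in input order.
#' @param window The clone's seed w-window.
#' @param params A [representative_params()].
#' @return A DNA string: substring of one clone read, or the window itself
#'   under the fallback.
#' @export
representative_region <- function(reads, window, params = representative_params()) {
  stopifnot(inherits(params, "representative_params"), length(reads) >= 1L)
  k <- params$k_rep
  support <- clone_kmer_presence(reads, k)
  T_req <- as.integer(ceiling(params$threshold * length(reads)))
  best_contain <- NULL; best_overlap <- NULL
  contain_len <- -1L; overlap_len <- -1L
  wlen <- nchar(window)
  for (read in reads) {
    L <- nchar(read)
    if (k > L) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(read, starts, starts + k - 1L)
    m <- match(kmers, names(support))
    good <- !is.na(m)
    good[good] <- support[m[good]] >= T_req
    if (!any(good)) next
    # window location(s) in this read (1-based starts)
    wpos <- integer(0)
    if (wlen <= L) {
      hit <- gregexpr(window, read, fixed = TRUE)[[1L]]
      if (hit[1L] != -1L) wpos <- as.integer(hit)
    }
    r <- rle(good)
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    for (ri in which(r$values)) {
      reg_start <- run_starts[ri]                 # 1-based k-mer start
      reg_end <- run_ends[ri] + k - 1L            # 1-based last base
      reg_len <- reg_end - reg_start + 1L
      if (length(wpos) > 0L) {
        contains <- any(reg_start <= wpos & wpos + wlen - 1L <= reg_end)
        overlaps <- any(reg_start <= wpos + wlen - 1L & wpos <= reg_end)
      } else {
        contains <- FALSE; overlaps <- FALSE
      }
      if (contains && reg_len > contain_len) {
        contain_len <- reg_len
        best_contain <- substr(read, reg_start, reg_end)
      } else if (overlaps && reg_len > overlap_len) {
        overlap_len <- reg_len
        best_overlap <- substr(read, reg_start, reg_end)
      }
    }
  }
  if (!is.null(best_contain)) return(best_contain)
  if (!is.null(best_overlap)) return(best_overlap)
  window
}
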