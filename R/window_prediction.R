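#' Window prediction parameters
#'
#' @param w Window length in bp; even, >= 2. Defaults to 40 for VJ loci
#'   and 60 for VDJ loci when taken from a [germline_db()].
#' @param strand_tolerance Maximum number of opposite-strand informative
#'   hits ignored before a read is discarded as strand-conflicting
#'   (default 1: a single stray hit does not discard a read).
#' @return An object of class `window_params`.
#' @export
window_params <- function(w = 40L, strand_tolerance = 1L) {
  w <- as.integer(w)
  if (is.na(w) || w < 2L || w %% 2L != 0L) {
    stop("window_params: w must be an even integer >= 2")
  }
  strand_tolerance <- as.integer(strand_tolerance)
  if (is.na(strand_tolerance) || strand_tolerance < 0L) {
    stop("window_params: strand_tolerance must be >= 0")
  }
  structure(list(w = w, strand_tolerance = strand_tolerance),
            class = "window_params")
}

.SEG_STATUSES <- c("SEGMENTED", "UNSEG_TOO_FEW", "UNSEG_STRAND_CONFLICT",
                   "UNSEG_ORDER", "UNSEG_WINDOW_OOB", "UNSEG_TOO_SHORT")

# core per-read heuristic on base-code vectors; returns list(status, strand,
# center (0-based in V->J orientation) or NA, oriented base codes)
analyze_base_codes <- function(idx, base, params) {
  span <- idx$seed$span
  L <- length(base)
  if (L < span) {
    return(list(status = "UNSEG_TOO_SHORT", strand = "+", center = NA_integer_,
                base = base))
  }
  sl <- scan_labels(idx, base)
  f <- sl$flab; r <- sl$rlab
  conflict <- f != .LBL_NONE & r != .LBL_NONE
  # informative hits: unambiguous V/J on exactly one strand
  plus_inf <- !conflict & (f == .LBL_V | f == .LBL_J)
  minus_inf <- !conflict & f == .LBL_NONE & (r == .LBL_V | r == .LBL_J)
  n_plus <- sum(plus_inf); n_minus <- sum(minus_inf)
  if (min(n_plus, n_minus) > params$strand_tolerance) {
    return(list(status = "UNSEG_STRAND_CONFLICT", strand = "+",
                center = NA_integer_, base = base))
  }
  strand <- if (n_plus >= n_minus) "+" else "-"
  if (strand == "+") {
    v_pos <- which(plus_inf & f == .LBL_V) - 1L
    j_pos <- which(plus_inf & f == .LBL_J) - 1L
    oriented <- base
  } else {
    v_pos0 <- which(minus_inf & r == .LBL_V) - 1L
    j_pos0 <- which(minus_inf & r == .LBL_J) - 1L
    # remap hit starts onto the reverse-complemented read
    v_pos <- L - span - v_pos0
    j_pos <- L - span - j_pos0
    oriented <- complement_codes(rev(base))
  }
  if (length(v_pos) == 0L || length(j_pos) == 0L) {
    return(list(status = "UNSEG_TOO_FEW", strand = strand,
                center = NA_integer_, base = base))
  }
  last_v <- max(v_pos)
  first_j <- min(j_pos)
  if (first_j < last_v) {
    return(list(status = "UNSEG_ORDER", strand = strand,
                center = NA_integer_, base = base))
  }
  e <- last_v + span - 1L   # last base covered by the last V k-word
  s <- first_j              # first base of the first J k-word
  center <- (e + s) %/% 2L
  list(status = "SEGMENTED", strand = strand, center = center, base = oriented)
}

base_codes_to_string <- function(base) {
  chars <- c("A", "C", "G", "T")[base + 1L]
  chars[is.na(base)] <- "N"
  paste(chars, collapse = "")
}

#' Analyze one read: strand, validity and junction center
#'
#' Scans the read's k-words against the index and applies the discard
#' rules: too short, strand-conflicting (more than `strand_tolerance`
#' informative hits on each strand), missing V or J evidence, or V words
#' after J words. For retained reads the junction center is the midpoint
#' `floor((e+s)/2)` between the last base covered by the last V k-word (e)
#' and the first base of the first J k-word (s), in the V-to-J oriented
#' read. Ambiguous and strand-conflicting k-words never count as evidence.
#'
#' @param idx A `kmer_index`.
#' @param read DNA string.
#' @param params A [window_params()].
#' @return List with `status` (one of `SEGMENTED`, `UNSEG_TOO_FEW`,
#'   `UNSEG_STRAND_CONFLICT`, `UNSEG_ORDER`, `UNSEG_TOO_SHORT`), `strand`,
#'   `center` (0-based, or `NA`), and `oriented` (the read in V-to-J
#'   orientation).
#' @export
analyze_read <- function(idx, read, params = window_params()) {
  stopifnot(inherits(idx, "kmer_index"), inherits(params, "window_params"))
  res <- analyze_base_codes(idx, seq_to_base_codes(read), params)
  list(status = res$status, strand = res$strand, center = res$center,
       oriented = base_codes_to_string(res$base))
}

#' Extract the w-window around a predicted center
#'
#' The window is `oriented[center - w/2, center - w/2 + w)` (0-based
#' half-open) of the V-to-J oriented read. Windows extending past either
#' read end are discarded (`UNSEG_WINDOW_OOB`) rather than clipped, since
#' clipped windows would break exact-match clustering.
#'
#' @param oriented Read in V-to-J orientation.
#' @param center 0-based predicted junction center.
#' @param params A [window_params()].
#' @return List with `status` (`SEGMENTED` or `UNSEG_WINDOW_OOB`) and
#'   `window` (string of length `w`, or `NA`).
#' @export
extract_window <- function(oriented, center, params = window_params()) {
  w <- params$w
  start <- center - w %/% 2L            # 0-based
  if (start < 0L || start + w > nchar(oriented)) {
    return(list(status = "UNSEG_WINDOW_OOB", window = NA_character_))
  }
  list(status = "SEGMENTED", window = substr(oriented, start + 1L, start + w))
}

#' Predict w-windows for a set of reads
#'
#' Runs [analyze_read()] and [extract_window()] over all reads.
#'
#' @param idx A `kmer_index`.
#' @param reads Named character vector of reads (names are read ids;
#'   unnamed reads get ids `read1`, `read2`, ...).
#' @param params A [window_params()].
#' @return A data.frame with columns `read_id`, `status`, `strand`,
#'   `center` (0-based, `NA` unless a center was determined) and `window`
#'   (`NA` unless `SEGMENTED`).
#' @export
predict_windows <- function(idx, reads, params = window_params()) {
  stopifnot(inherits(idx, "kmer_index"), inherits(params, "window_params"))
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) {
    ids <- if (n == 0L) character(0) else paste0("read", seq_len(n))
  }
  status <- character(n); strand <- character(n)
  center <- rep(NA_integer_, n); window <- rep(NA_character_, n)
  w <- params$w
  half <- w %/% 2L
  for (i in seq_len(n)) {
    res <- analyze_base_codes(idx, seq_to_base_codes(reads[[i]]), params)
    st <- res$status
    if (st == "SEGMENTED") {
      ctr <- res$center
      start <- ctr - half
      if (start < 0L || start + w > length(res$base)) {
        st <- "UNSEG_WINDOW_OOB"
      } else {
        window[i] <- base_codes_to_string(res$base[(start + 1L):(start + w)])
      }
      center[i] <- ctr
    }
    status[i] <- st
    strand[i] <- res$strand
  }
  data.frame(read_id = ids, status = status, strand = strand,
             center = center, window = window, stringsAsFactors = FALSE)
}
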