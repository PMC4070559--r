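#' Alignment scoring for the refined V(D)J designation
#'
#' Linear gap penalties; defaults are +2 match, -1 mismatch, -2 gap.
#'
#' @param match,mismatch,gap Numeric scores; `match` must exceed both
#'   `mismatch` and `gap`.
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -1, gap = -2) {
  if (!(match > mismatch && match > gap)) {
    stop("alignment_scoring: match score must exceed mismatch and gap scores")
  }
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

# Semi-global scores of one gene against seq, free start in both sequences.
# Returns, for every end position e in seq (1-based), the best score of an
# alignment of a gene prefix ending at e, and the prefix length q achieving
# it (largest q on score ties, i.e. fewest 3' deletions).
semiglobal_end_scores <- function(seq_chars, gene, scoring) {
  g <- strsplit(gene, "", fixed = TRUE)[[1L]]
  n <- length(seq_chars); m <- length(g)
  gp <- scoring$gap
  best <- numeric(n); bestq <- integer(n)
  prev <- numeric(m + 1L)            # H[i-1, 0..m]; row 0 is all zeros
  tvec <- 0:m
  gap_t <- gp * tvec
  for (i in seq_len(n)) {
    subscore <- ifelse(g == seq_chars[i], scoring$match, scoring$mismatch)
    D <- pmax(prev[1:m] + subscore, prev[2:(m + 1L)] + gp)
    A <- c(0, D)
    row <- cummax(A - gap_t) + gap_t
    mx <- max(row)
    best[i] <- mx
    bestq[i] <- tvec[max(which(row == mx))]
    prev <- row
  }
  list(score = best, q = bestq)
}

# combine per-position best alignments across a gene set;
# ties: fewer deletions (len - q), then lexicographically smaller name
combine_gene_ends <- function(seq_chars, genes, scoring) {
  n <- length(seq_chars)
  score <- rep(-Inf, n); q <- integer(n)
  gene <- rep(NA_character_, n); del <- rep(NA_integer_, n)
  for (nm in sort(names(genes))) {
    res <- semiglobal_end_scores(seq_chars, genes[[nm]], scoring)
    d <- nchar(genes[[nm]]) - res$q
    better <- res$score > score | (res$score == score & d < del)
    better[is.na(better)] <- TRUE
    score[better] <- res$score[better]
    q[better] <- res$q[better]
    del[better] <- d[better]
    gene[better] <- nm
  }
  list(score = score, q = q, del = del, gene = gene)
}

#' Best semi-global gene alignment at one end of a sequence
#'
#' For `side = "end_of_V"`, maximises over genes, end positions `e` in
#' `seq` and gene prefix lengths `q` the score of aligning the gene prefix
#' against a region of `seq` ending at `e`, with free start in both
#' sequences; `deletions = len(gene) - q` are the bases trimmed from the
#' gene 3' end. `side = "start_of_J"` mirrors the computation from the
#' right, with deletions at the gene 5' end. Ties are broken toward fewer
#' deletions, then the lexicographically smaller gene name, then the
#' boundary position closest to the respective sequence end.
#'
#' @param seq Non-empty DNA string.
#' @param genes Named character vector of germline genes (non-empty).
#' @param side "end_of_V" or "start_of_J".
#' @param scoring An [alignment_scoring()].
#' @return List with `gene`, `pos` (0-based boundary position in `seq`:
#'   last V base or first J base), `deletions` and `score`.
#' @export
best_gene_alignment <- function(seq, genes, side = c("end_of_V", "start_of_J"),
                                scoring = alignment_scoring()) {
  side <- match.arg(side)
  if (length(genes) == 0L) stop("best_gene_alignment: empty gene list")
  stopifnot(nchar(seq) > 0L)
  n <- nchar(seq)
  if (side == "end_of_V") {
    sc <- strsplit(seq, "", fixed = TRUE)[[1L]]
    cmb <- combine_gene_ends(sc, genes, scoring)
    e <- which.max(cmb$score)                  # smallest e on ties
    list(gene = cmb$gene[e], pos = e - 1L, deletions = cmb$del[e],
         score = cmb$score[e])
  } else {
    sc <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
    rgenes <- vapply(genes, function(g)
      paste(rev(strsplit(g, "", fixed = TRUE)[[1L]]), collapse = ""),
      character(1L))
    cmb <- combine_gene_ends(sc, rgenes, scoring)
    e <- which.max(cmb$score)
    list(gene = cmb$gene[e], pos = n - e, deletions = cmb$del[e],
         score = cmb$score[e])
  }
}

# Longest exact (ungapped, mismatch-free) common run between character
# vectors a and g, with the run's end position in a constrained to
# <= end_max (1-based). Ties prefer the larger end in a, then the larger
# end in g (fewer gene-end deletions). Used to refine V(D)J boundaries:
# only exactly germline-matching flanks are attributed to a gene, which
# keeps designations reconstruction-faithful.
longest_exact_run <- function(a, g, end_max = length(a)) {
  m <- length(g)
  prev <- integer(m)
  best_len <- 0L; best_ae <- NA_integer_; best_ge <- NA_integer_
  for (i in seq_len(end_max)) {
    eq <- g == a[i]
    cur <- integer(m)
    if (any(eq)) cur[eq] <- c(0L, prev[-m])[eq] + 1L
    mx <- max(cur)
    if (mx > 0L && mx >= best_len) {
      best_len <- mx
      best_ae <- i
      best_ge <- max(which(cur == mx))
    }
    prev <- cur
  }
  list(len = best_len, a_end = best_ae, g_end = best_ge)
}

#' Refined V(D)J designation of a representative sequence
#'
#' Computes, for every split point, the best semi-global V alignment ending
#' at or before it and the best J alignment starting after it, and keeps
#' the split maximising the summed score; among equal-score splits the
#' largest V end (longer V, then longer J, hence smallest N) is preferred.
#' The score DP fixes the V and J genes and the approximate split; the
#' reported boundaries are then refined to the longest exactly
#' germline-matching run on each side, so that the designation never
#' implies bases the sequence does not contain (junction bases are
#' attributed to a gene only when they coincide with its deleted end).
#' The bases between the V end and the J start form the N-diversity
#' region. When the locus has D genes, the longest exact D-gene run inside
#' the N region is accepted as a D assignment when its match score reaches
#' `d_min_score`, splitting N into N1/D/N2. Runs in O(l*r) time for a
#' representative of length l and germline of total size r.
#'
#' @param representative DNA string in V-to-J orientation.
#' @param db A [germline_db()].
#' @param scoring An [alignment_scoring()].
#' @param min_score Minimum V and J alignment scores (default 10); below
#'   it the clone is flagged unsegmented (reported with its window only).
#' @param d_min_score Minimum accepted D score (default 8).
#' @return An object of class `vdj_segmentation`: fields `segmented`,
#'   `v_name`, `v_del`, `n_region`, optional `d_name`/`d5_del`/`d3_del`/
#'   `n1`/`n2`, `j_del`, `j_name`, `v_end`, `j_start` (0-based positions in
#'   the representative) and `score`.
#' @export
segment_sequence <- function(representative, db, scoring = alignment_scoring(),
                             min_score = 10, d_min_score = 8) {
  stopifnot(inherits(db, "germline_db"))
  n <- nchar(representative)
  failed <- structure(list(segmented = FALSE), class = "vdj_segmentation")
  if (n < 2L) return(failed)
  sc <- strsplit(representative, "", fixed = TRUE)[[1L]]
  vcmb <- combine_gene_ends(sc, db$v_genes, scoring)
  rgenes <- vapply(db$j_genes, function(g)
    paste(rev(strsplit(g, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1L))
  jcmb_rev <- combine_gene_ends(rev(sc), rgenes, scoring)
  # js_*[s+1]: best J alignment starting at 0-based position s
  ridx <- n:1
  js_score <- jcmb_rev$score[ridx]
  js_del <- jcmb_rev$del[ridx]
  js_gene <- jcmb_rev$gene[ridx]
  # prefix best V (ties -> larger end), suffix best J (ties -> smaller start)
  pv_score <- numeric(n); pv_e <- integer(n)
  cur <- -Inf; cure <- NA_integer_
  for (e in seq_len(n)) {
    if (vcmb$score[e] >= cur) { cur <- vcmb$score[e]; cure <- e }
    pv_score[e] <- cur; pv_e[e] <- cure
  }
  sj_score <- numeric(n); sj_s <- integer(n)
  cur <- -Inf; curs <- NA_integer_
  for (s in n:1) {
    if (js_score[s] >= cur) { cur <- js_score[s]; curs <- s }
    sj_score[s] <- cur; sj_s[s] <- curs
  }
  best_tot <- -Inf; best_e <- NA_integer_; best_s <- NA_integer_
  for (x in seq_len(n - 1L)) {
    tot <- pv_score[x] + sj_score[x + 1L]
    if (tot > best_tot || (tot == best_tot && pv_e[x] > best_e)) {
      best_tot <- tot; best_e <- pv_e[x]; best_s <- sj_s[x + 1L]
    }
  }
  v_score <- vcmb$score[best_e]
  j_score <- js_score[best_s]
  if (!is.finite(best_tot) || v_score < min_score || j_score < min_score) {
    return(failed)
  }
  v_name <- vcmb$gene[best_e]
  j_name <- js_gene[best_s]
  # Boundary refinement: the score DP fixes the genes and the approximate
  # split, but with unit penalties it can absorb junction bases that only
  # partly resemble a deleted gene end, which would make the designation
  # imply bases the sequence does not contain. The reported boundaries are
  # therefore taken from the longest exact germline run on each side
  # (which for a clean sequence is the whole retained gene portion, plus
  # any junction bases that coincide with the deleted gene end).
  vg <- strsplit(db$v_genes[[v_name]], "", fixed = TRUE)[[1L]]
  jg <- strsplit(db$j_genes[[j_name]], "", fixed = TRUE)[[1L]]
  vrun <- longest_exact_run(sc, vg, end_max = best_e)
  jrun <- longest_exact_run(rev(sc), rev(jg), end_max = n + 1L - best_s)
  if (vrun$len > 0L) {
    v_end1 <- vrun$a_end
    v_del <- length(vg) - vrun$g_end
  } else {
    v_end1 <- best_e
    v_del <- vcmb$del[best_e]
  }
  if (jrun$len > 0L) {
    j_start1 <- n + 1L - jrun$a_end
    j_del <- length(jg) - jrun$g_end
  } else {
    j_start1 <- best_s
    j_del <- js_del[best_s]
  }
  if (v_end1 >= j_start1) {
    # exact runs may overrun each other by coincidence; keep the longer V
    shift <- v_end1 - j_start1 + 1L
    if (jrun$len > shift) {
      j_start1 <- j_start1 + shift
      j_del <- j_del + shift
    } else if (vrun$len > shift) {
      v_end1 <- v_end1 - shift
      v_del <- v_del + shift
    } else {
      return(failed)
    }
  }
  n_region <- if (j_start1 > v_end1 + 1L) {
    substr(representative, v_end1 + 1L, j_start1 - 1L)
  } else ""
  seg <- list(segmented = TRUE,
              v_name = v_name, v_del = v_del,
              n_region = n_region,
              j_del = j_del, j_name = j_name,
              v_end = v_end1 - 1L, j_start = j_start1 - 1L,
              score = best_tot)
  if (!is.null(db$d_genes) && nchar(n_region) >= 1L) {
    nr <- strsplit(n_region, "", fixed = TRUE)[[1L]]
    best_d <- NULL
    for (nm in sort(names(db$d_genes))) {
      run <- longest_exact_run(nr, strsplit(db$d_genes[[nm]], "",
                                            fixed = TRUE)[[1L]])
      if (run$len > 0L && (is.null(best_d) || run$len > best_d$len)) {
        best_d <- run; best_d$name <- nm
      }
    }
    if (!is.null(best_d) && scoring$match * best_d$len >= d_min_score) {
      m <- nchar(db$d_genes[[best_d$name]])
      seg$d_name <- best_d$name
      seg$d5_del <- best_d$g_end - best_d$len
      seg$d3_del <- m - best_d$g_end
      seg$n1 <- substr(n_region, 1L, best_d$a_end - best_d$len)
      seg$n2 <- substr(n_region, best_d$a_end + 1L, nchar(n_region))
    }
  }
  structure(seg, class = "vdj_segmentation")
}

#' @export
print.vdj_segmentation <- function(x, ...) {
  if (!isTRUE(x$segmented)) {
    cat("vdj_segmentation: not segmented\n")
  } else {
    cat("vdj_segmentation:", format_designation(x), sprintf("(score %g)\n", x$score))
  }
  invisible(x)
}

#' Format a V(D)J designation string
#'
#' Renders a designation in the compact field notation
#' `V -dv/N/dj J` (e.g. `TRGV5*01 -5/CC/0 TRGJ1*02`: V gene TRGV5*01 with
#' its last five nucleotides deleted, two inserted Cs, J gene TRGJ1*02
#' with no deletion). Zero deletions print as `0`, nonzero as `-d`; an
#' empty N region prints as an empty field. With a D gene the N field
#' expands to `N1/-d5 D -d3/N2`.
#'
#' @param seg A `vdj_segmentation` (or a list with the same fields).
#' @return Character scalar.
#' @export
format_designation <- function(seg) {
  if (!isTRUE(seg$segmented)) stop("format_designation: sequence was not segmented")
  tok <- function(d) if (d == 0L) "0" else paste0("-", d)
  mid <- if (!is.null(seg$d_name)) {
    paste0(seg$n1, "/", tok(seg$d5_del), " ", seg$d_name, " ",
           tok(seg$d3_del), "/", seg$n2)
  } else {
    seg$n_region
  }
  paste0(seg$v_name, " ", tok(seg$v_del), "/", mid, "/", tok(seg$j_del),
         " ", seg$j_name)
}

#' Rebuild the recombined sequence implied by a designation
#'
#' Concatenates the deletion-trimmed V prefix, the N region (or N1, the
#' trimmed D, and N2), and the deletion-trimmed J suffix. Used to check
#' designations by sequence equivalence: two designations that differ only
#' in the attribution of junction bases reconstruct the same sequence.
#'
#' @param seg A `vdj_segmentation` or list with fields `v_name`, `v_del`,
#'   `n_region` (or `n1`/`d_name`/`d5_del`/`d3_del`/`n2`), `j_del`,
#'   `j_name`.
#' @param db A [germline_db()] containing the named genes.
#' @return The reconstructed DNA string.
#' @export
reconstruct_from_designation <- function(seg, db) {
  stopifnot(inherits(db, "germline_db"))
  get_gene <- function(set, nm, what) {
    if (is.null(nm) || !(nm %in% names(set))) {
      stop("reconstruct_from_designation: unknown ", what, " gene '", nm, "'")
    }
    set[[nm]]
  }
  v <- get_gene(db$v_genes, seg$v_name, "V")
  j <- get_gene(db$j_genes, seg$j_name, "J")
  if (seg$v_del < 0L || seg$v_del > nchar(v)) {
    stop("reconstruct_from_designation: V deletion ", seg$v_del,
         " exceeds gene length ", nchar(v))
  }
  if (seg$j_del < 0L || seg$j_del > nchar(j)) {
    stop("reconstruct_from_designation: J deletion ", seg$j_del,
         " exceeds gene length ", nchar(j))
  }
  mid <- if (!is.null(seg$d_name)) {
    d <- get_gene(db$d_genes, seg$d_name, "D")
    if (seg$d5_del < 0L || seg$d3_del < 0L ||
        seg$d5_del + seg$d3_del > nchar(d)) {
      stop("reconstruct_from_designation: D deletions exceed gene length")
    }
    paste0(seg$n1, substr(d, seg$d5_del + 1L, nchar(d) - seg$d3_del), seg$n2)
  } else {
    seg$n_region
  }
  paste0(substr(v, 1L, nchar(v) - seg$v_del), mid,
         substr(j, seg$j_del + 1L, nchar(j)))
}
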