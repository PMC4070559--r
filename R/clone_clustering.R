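#' Clustering and clone-selection parameters
#'
#' By default no mismatch between windows is tolerated: the clone
#' definition is exact w-window identity, a deliberately stringent choice
#' that avoids gathering sequences from different clones. Bounded
#' edit-distance merging (substitutions / plain indels / homopolymer
#' indels) is available for error-prone sequencers, as are unconditional
#' user-specified merges of window pairs.
#'
#' @param max_subst,max_indel,max_homo Maximum substitutions, plain indels
#'   and homopolymer indels allowed between two windows for an automatic
#'   merge (all default 0).
#' @param manual_pairs List of length-2 character vectors (or a 2-column
#'   matrix / data.frame) of window pairs to merge unconditionally.
#' @param top_n Number of most abundant clones reported (default 20).
#' @param min_reads Minimum reads for a clone to be processed (default 10).
#' @param followed_windows Character vector of windows whose clones are
#'   always reported, regardless of rank or count.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(max_subst = 0L, max_indel = 0L, max_homo = 0L,
                           manual_pairs = NULL, top_n = 20L, min_reads = 10L,
                           followed_windows = character(0)) {
  if (is.matrix(manual_pairs) || is.data.frame(manual_pairs)) {
    manual_pairs <- lapply(seq_len(nrow(manual_pairs)),
                           function(i) as.character(unlist(manual_pairs[i, 1:2])))
  }
  stopifnot(max_subst >= 0, max_indel >= 0, max_homo >= 0,
            top_n >= 0, min_reads >= 0)
  structure(list(max_subst = as.integer(max_subst),
                 max_indel = as.integer(max_indel),
                 max_homo = as.integer(max_homo),
                 manual_pairs = manual_pairs,
                 top_n = as.integer(top_n),
                 min_reads = as.integer(min_reads),
                 followed_windows = as.character(followed_windows)),
            class = "cluster_params")
}

# internal group representation: list(windows = named integer counts,
# read_ids = character). Seed window = max count, ties lexicographic.
group_seed <- function(g) {
  cnt <- g$windows
  mx <- max(cnt)
  ws <- names(cnt)[cnt == mx]
  min(ws)
}

groups_to_table <- function(groups, total_segmented) {
  if (length(groups) == 0L) {
    tab <- data.frame(seed_window = character(0), read_count = integer(0),
                      n_windows = integer(0), followed = logical(0),
                      stringsAsFactors = FALSE)
    tab$member_windows <- list()
    tab$read_ids <- list()
  } else {
    seeds <- vapply(groups, group_seed, character(1L))
    counts <- vapply(groups, function(g) sum(g$windows), numeric(1L))
    ord <- order(-counts, seeds)
    groups <- groups[ord]
    tab <- data.frame(seed_window = seeds[ord],
                      read_count = as.integer(counts[ord]),
                      n_windows = vapply(groups, function(g) length(g$windows),
                                         integer(1L)),
                      followed = vapply(groups, function(g)
                        isTRUE(g$followed), logical(1L)),
                      stringsAsFactors = FALSE)
    tab$member_windows <- lapply(groups, function(g) g$windows)
    tab$read_ids <- lapply(groups, function(g) g$read_ids)
  }
  attr(tab, "total_segmented") <- as.integer(total_segmented)
  class(tab) <- c("clone_table", class(tab))
  tab
}

table_to_groups <- function(table) {
  lapply(seq_len(nrow(table)), function(i) {
    list(windows = table$member_windows[[i]],
         read_ids = table$read_ids[[i]],
         followed = isTRUE(table$followed[i]))
  })
}

#' Total segmented reads behind a clone table
#'
#' @param table A `clone_table`.
#' @return Integer count of segmented reads the table was built from.
#' @export
total_segmented <- function(table) attr(table, "total_segmented")

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf("clone_table: %d clones, %d segmented reads\n",
              nrow(x), total_segmented(x)))
  cols <- intersect(c("seed_window", "read_count", "n_windows", "followed",
                      "designation"), names(x))
  show <- utils::head(as.data.frame(x)[, cols, drop = FALSE], 10L)
  print.data.frame(show, ...)
  invisible(x)
}

#' Count w-windows into singleton clone clusters
#'
#' Distinct windows are sorted and counted; the relative abundance of a
#' clonotype is the number of reads carrying its window. Ordering is
#' deterministic: read count descending, then window lexicographic.
#'
#' @param hits Data.frame with columns `read_id` and `window` (e.g. the
#'   output of [predict_windows()]; rows with `status != "SEGMENTED"` or
#'   `NA` windows are dropped).
#' @return A `clone_table` of singleton clusters.
#' @export
count_windows <- function(hits) {
  if (!is.null(hits$status)) hits <- hits[hits$status == "SEGMENTED", ]
  hits <- hits[!is.na(hits$window), ]
  n <- nrow(hits)
  if (n == 0L) return(groups_to_table(list(), 0L))
  by_win <- split(hits$read_id, hits$window)
  groups <- lapply(names(by_win), function(w) {
    ids <- by_win[[w]]
    list(windows = stats::setNames(length(ids), w), read_ids = ids)
  })
  groups_to_table(groups, n)
}

#' Edit distance between two windows, split by error type
#'
#' Computes a minimum-cost unit-cost alignment of `a` and `b` (ties broken
#' toward fewer indels, then a fixed leftmost traceback) and classifies the
#' edits as substitutions, plain indels and homopolymer indels. An indel is
#' homopolymer-type iff the inserted/deleted base equals the base
#' immediately preceding or following its location in the other sequence,
#' the characteristic error of flow-based sequencers. The pair is
#' canonicalised (lexicographically) before alignment so the returned
#' triple is symmetric in its arguments.
#'
#' @param a,b Non-empty DNA strings.
#' @return Named integer vector `c(substitutions, plain_indels,
#'   homopolymer_indels)`.
#' @export
window_distance <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  # DP over (cost, indels), lexicographic; op preference diag > up > left
  COST <- matrix(0L, n + 1L, m + 1L)
  IND <- matrix(0L, n + 1L, m + 1L)
  COST[, 1L] <- 0:n; IND[, 1L] <- 0:n
  COST[1L, ] <- 0:m; IND[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dc <- COST[i, j] + (av[i] != bv[j]); di <- IND[i, j]
      uc <- COST[i, j + 1L] + 1L; ui <- IND[i, j + 1L] + 1L
      lc <- COST[i + 1L, j] + 1L; li <- IND[i + 1L, j] + 1L
      bc <- dc; bi <- di
      if (uc < bc || (uc == bc && ui < bi)) { bc <- uc; bi <- ui }
      if (lc < bc || (lc == bc && li < bi)) { bc <- lc; bi <- li }
      COST[i + 1L, j + 1L] <- bc
      IND[i + 1L, j + 1L] <- bi
    }
  }
  subs <- 0L; plain <- 0L; homo <- 0L
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    cur_c <- COST[i + 1L, j + 1L]; cur_i <- IND[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        COST[i, j] + (av[i] != bv[j]) == cur_c && IND[i, j] == cur_i) {
      if (av[i] != bv[j]) subs <- subs + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               COST[i, j + 1L] + 1L == cur_c && IND[i, j + 1L] + 1L == cur_i) {
      # deletion of av[i], located between bv[j] and bv[j+1]
      if ((j >= 1L && bv[j] == av[i]) || (j < m && bv[j + 1L] == av[i])) {
        homo <- homo + 1L
      } else plain <- plain + 1L
      i <- i - 1L
    } else {
      # insertion of bv[j], located between av[i] and av[i+1]
      if ((i >= 1L && av[i] == bv[j]) || (i < n && av[i + 1L] == bv[j])) {
        homo <- homo + 1L
      } else plain <- plain + 1L
      j <- j - 1L
    }
  }
  c(substitutions = subs, plain_indels = plain, homopolymer_indels = homo)
}

within_bounds <- function(d, params) {
  d[["substitutions"]] <= params$max_subst &&
    d[["plain_indels"]] <= params$max_indel &&
    d[["homopolymer_indels"]] <= params$max_homo
}

#' Merge similar windows into clones
#'
#' Manual pairs are merged first and unconditionally. Then a greedy pass
#' over the remaining groups in table order compares each group's seed
#' window to the seed windows of already-formed clusters (in cluster
#' order), merging into the first cluster whose seed satisfies all three
#' [window_distance()] bounds; otherwise the group starts a new cluster.
#' With all bounds at their zero defaults and no manual pairs, clustering
#' is the identity. Read counts are conserved.
#'
#' @param table A `clone_table` (from [count_windows()]).
#' @param params A [cluster_params()].
#' @return A re-sorted `clone_table`.
#' @export
cluster_windows <- function(table, params = cluster_params()) {
  stopifnot(inherits(table, "clone_table"), inherits(params, "cluster_params"))
  no_auto <- params$max_subst == 0L && params$max_indel == 0L &&
    params$max_homo == 0L
  if (no_auto && length(params$manual_pairs) == 0L) return(table)
  groups <- table_to_groups(table)
  # unconditional manual merges
  for (pair in params$manual_pairs) {
    find <- function(w) {
      for (gi in seq_along(groups)) {
        if (!is.null(groups[[gi]]) && w %in% names(groups[[gi]]$windows)) {
          return(gi)
        }
      }
      NA_integer_
    }
    i1 <- find(pair[[1L]]); i2 <- find(pair[[2L]])
    if (is.na(i1) || is.na(i2)) {
      warning("manual pair references an absent window: ",
              pair[[1L]], " / ", pair[[2L]], " (skipped)")
      next
    }
    if (i1 == i2) next
    g1 <- groups[[i1]]; g2 <- groups[[i2]]
    g1$windows <- c(g1$windows, g2$windows)
    g1$read_ids <- c(g1$read_ids, g2$read_ids)
    g1$followed <- isTRUE(g1$followed) || isTRUE(g2$followed)
    groups[[i1]] <- g1
    groups[[i2]] <- list(NULL)
    groups[[i2]] <- NULL
  }
  if (!no_auto) {
    # deterministic processing order: count desc, seed lex asc
    seeds <- vapply(groups, group_seed, character(1L))
    counts <- vapply(groups, function(g) sum(g$windows), numeric(1L))
    groups <- groups[order(-counts, seeds)]
    clusters <- list()
    for (g in groups) {
      gs <- group_seed(g)
      merged <- FALSE
      for (ci in seq_along(clusters)) {
        cs <- group_seed(clusters[[ci]])
        if (within_bounds(window_distance(gs, cs), params)) {
          cl <- clusters[[ci]]
          cl$windows <- c(cl$windows, g$windows)
          cl$read_ids <- c(cl$read_ids, g$read_ids)
          cl$followed <- isTRUE(cl$followed) || isTRUE(g$followed)
          clusters[[ci]] <- cl
          merged <- TRUE
          break
        }
      }
      if (!merged) clusters[[length(clusters) + 1L]] <- g
    }
    groups <- clusters
  }
  groups_to_table(groups, total_segmented(table))
}

#' Select clones for detailed processing
#'
#' Keeps the `top_n` most abundant clones having at least `min_reads`
#' reads, plus any clone containing a followed window (regardless of rank
#' or count; such clones carry `followed = TRUE`). Clones not selected
#' remain counted in the segmented total but are not processed further.
#'
#' @param table A `clone_table`.
#' @param params A [cluster_params()].
#' @return A `clone_table` restricted to the selected clones.
#' @export
select_clones <- function(table, params = cluster_params()) {
  stopifnot(inherits(table, "clone_table"), inherits(params, "cluster_params"))
  if (nrow(table) == 0L) return(table)
  followed <- vapply(table$member_windows, function(wc)
    any(names(wc) %in% params$followed_windows), logical(1L))
  eligible <- which(table$read_count >= params$min_reads)
  kept <- utils::head(eligible, params$top_n)
  sel <- sort(union(kept, which(followed)))
  out <- table[sel, , drop = FALSE]
  out$followed <- followed[sel]
  attr(out, "total_segmented") <- total_segmented(table)
  class(out) <- class(table)
  out
}
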