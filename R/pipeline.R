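#' Load a germline run configuration from YAML
#'
#' The YAML file maps a locus to its germline FASTA files and optional
#' seed/window overrides:
#' \preformatted{
#' locus: TRG
#' v: trgv.fasta
#' j: trgj.fasta
#' # d: trgd.fasta      (VDJ loci only)
#' # seed: "#####-#####"
#' # w: 40
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Path to the YAML config.
#' @return A [germline_db()].
#' @export
load_germline_config <- function(path) {
  if (!file.exists(path)) stop("germline config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (fld in c("locus", "v", "j")) {
    if (is.null(cfg[[fld]])) stop("germline config missing field '", fld, "'")
  }
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  v <- load_germline_fasta(resolve(cfg$v), "V")
  j <- load_germline_fasta(resolve(cfg$j), "J")
  d <- if (!is.null(cfg$d)) load_germline_fasta(resolve(cfg$d), "D") else NULL
  seed <- if (!is.null(cfg$seed)) seed_pattern(cfg$seed)
          else default_seed_for_locus(cfg$locus)
  germline_db(cfg$locus, v, j, d_genes = d, seed = seed, w = cfg$w)
}

status_count_table <- function(status) {
  counts <- stats::setNames(integer(length(.SEG_STATUSES)), .SEG_STATUSES)
  tab <- table(status)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Run the full two-stage analysis
#'
#' Index construction, per-read window prediction, window counting,
#' optional bounded-distance clustering, clone selection, representative
#' computation and refined V(D)J designation, in that order. Fully
#' deterministic for fixed inputs and parameters.
#'
#' @param reads Named character vector of reads, or a path to a
#'   FASTA/FASTQ file (optionally gzipped).
#' @param germline A [germline_db()] or the path to a YAML germline
#'   config (see [load_germline_config()]).
#' @param window A [window_params()]; defaults to the germline's `w`.
#' @param clustering A [cluster_params()].
#' @param rep_params A [representative_params()]; `k_rep` defaults to the
#'   germline seed weight.
#' @param scoring An [alignment_scoring()].
#' @param out_dir Optional output directory; when given, writes
#'   `windows.tsv` (read_id, status, strand, center, window),
#'   `clones.tsv`, `clones.json`, `representatives.fasta` and `stats.tsv`.
#'   All coordinates in outputs are 0-based (half-open for intervals).
#' @return A `run_report`: list with `n_reads`, `status_counts`,
#'   `segmented_fraction`, `hits` (the per-read table), `clones` (the
#'   selected `clone_table` with `representative` and `designation`
#'   columns), `all_clones` (unselected table), and a parameter echo.
#' @export
run_pipeline <- function(reads, germline,
                         window = NULL,
                         clustering = cluster_params(),
                         rep_params = NULL,
                         scoring = alignment_scoring(),
                         out_dir = NULL) {
  db <- if (inherits(germline, "germline_db")) germline
        else load_germline_config(germline)
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    reads <- read_reads(reads)
  }
  if (is.null(names(reads)) && length(reads) > 0L) {
    names(reads) <- paste0("read", seq_along(reads))
  }
  if (is.null(window)) window <- window_params(w = db$w)
  if (is.null(rep_params)) rep_params <- representative_params(k_rep = db$seed$weight)
  idx <- build_kmer_index(db)
  hits <- predict_windows(idx, reads, window)
  tab <- count_windows(hits)
  tab <- cluster_windows(tab, clustering)
  sel <- select_clones(tab, clustering)
  representative <- character(nrow(sel))
  designation <- rep(NA_character_, nrow(sel))
  seg_score <- rep(NA_real_, nrow(sel))
  v_end <- rep(NA_integer_, nrow(sel)); j_start <- rep(NA_integer_, nrow(sel))
  if (nrow(sel) > 0L) {
    # reads must be in V->J orientation for the representative
    orient_read <- function(id) {
      row <- hits[match(id, hits$read_id), ]
      r <- reads[[id]]
      if (row$strand == "-") reverse_complement(r) else r
    }
    for (ci in seq_len(nrow(sel))) {
      ids <- sel$read_ids[[ci]]
      clone_reads <- vapply(ids, orient_read, character(1L), USE.NAMES = FALSE)
      representative[ci] <- representative_region(clone_reads,
                                                  sel$seed_window[ci],
                                                  rep_params)
      seg <- segment_sequence(representative[ci], db, scoring)
      if (isTRUE(seg$segmented)) {
        designation[ci] <- format_designation(seg)
        seg_score[ci] <- seg$score
        v_end[ci] <- seg$v_end; j_start[ci] <- seg$j_start
      }
    }
  }
  sel$representative <- representative
  sel$designation <- designation
  sel$seg_score <- seg_score
  sel$v_end <- v_end
  sel$j_start <- j_start
  counts <- status_count_table(hits$status)
  n_seg <- total_segmented(tab)
  report <- list(
    n_reads = length(reads),
    status_counts = counts,
    segmented_fraction = if (length(reads) > 0L) n_seg / length(reads) else 0,
    hits = hits,
    clones = sel,
    all_clones = tab,
    params = list(locus = db$locus, seed = db$seed$pattern, w = window$w,
                  strand_tolerance = window$strand_tolerance,
                  top_n = clustering$top_n, min_reads = clustering$min_reads,
                  max_subst = clustering$max_subst,
                  max_indel = clustering$max_indel,
                  max_homo = clustering$max_homo,
                  k_rep = rep_params$k_rep,
                  rep_threshold = rep_params$threshold),
    version = as.character(utils::packageVersion("vdjwin"))
  )
  class(report) <- "run_report"
  if (length(reads) > 0L && n_seg == 0L) {
    warning("run_pipeline: no read could be segmented")
  }
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d reads, %.1f%% segmented, %d clones selected\n",
              x$n_reads, 100 * x$segmented_fraction, nrow(x$clones)))
  print(x$status_counts)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$hits, "windows.tsv")
  cl <- report$clones
  clone_df <- data.frame(rank = seq_len(nrow(cl)),
                         seed_window = cl$seed_window,
                         read_count = cl$read_count,
                         fraction = if (total_segmented(report$all_clones) > 0)
                           cl$read_count / total_segmented(report$all_clones)
                           else numeric(nrow(cl)),
                         n_windows = cl$n_windows,
                         followed = cl$followed,
                         designation = cl$designation,
                         seg_score = cl$seg_score,
                         v_end = cl$v_end, j_start = cl$j_start,
                         stringsAsFactors = FALSE)
  tsv(clone_df, "clones.tsv")
  jlist <- lapply(seq_len(nrow(cl)), function(i) {
    c(as.list(clone_df[i, ]),
      list(member_windows = as.list(cl$member_windows[[i]]),
           representative = cl$representative[i]))
  })
  jsonlite::write_json(
    list(clones = jlist,
         total_segmented = total_segmented(report$all_clones),
         status_counts = as.list(report$status_counts),
         params = report$params, version = report$version),
    file.path(out_dir, "clones.json"), auto_unbox = TRUE, pretty = TRUE)
  if (nrow(cl) > 0L) {
    reps <- stats::setNames(cl$representative,
                            paste0("clone-", seq_len(nrow(cl)), "-",
                                   cl$seed_window))
    write_germline_fasta(reps, file.path(out_dir, "representatives.fasta"))
  } else {
    file.create(file.path(out_dir, "representatives.fasta"))
  }
  stats_df <- data.frame(status = names(report$status_counts),
                         reads = as.integer(report$status_counts),
                         stringsAsFactors = FALSE)
  tsv(stats_df, "stats.tsv")
  invisible(out_dir)
}

#' Window-center accuracy against simulator truth
#'
#' Over reads that received a predicted window and whose truth record has
#' a defined junction center, computes the fraction whose predicted center
#' lies strictly within `tolerance` bp of the true center.
#'
#' @param hits Data.frame from [predict_windows()].
#' @param truth Truth data.frame from [generate_reads()].
#' @param tolerance Distance bound in bp (strict inequality).
#' @return List with `fraction`, `n_evaluated`, `distances` (absolute
#'   per-read distances) and `histogram` (a `table` of distances).
#' @export
center_accuracy <- function(hits, truth, tolerance = 15L) {
  m <- match(hits$read_id, truth$read_id)
  if (all(is.na(m))) stop("center_accuracy: hit and truth read ids are disjoint")
  evald <- hits$status == "SEGMENTED" & !is.na(hits$window) &
    !is.na(m) & !is.na(truth$true_center[m])
  if (!any(evald)) stop("center_accuracy: empty evaluation set")
  d <- abs(hits$center[evald] - truth$true_center[m[evald]])
  list(fraction = mean(d < tolerance),
       n_evaluated = sum(evald),
       distances = d,
       histogram = table(d))
}

#' Clone abundance recovery against simulator truth
#'
#' Maps each simulated clone to its w-window by running the window
#' heuristic on the clone's own full sequence, then compares the true read
#' fraction of each clone with the fraction of segmented reads carrying
#' its window. Simulated clones without a detected window are reported
#' with estimate 0; detected clones matching no simulated clone are
#' flagged spurious.
#'
#' @param table A `clone_table`.
#' @param truth Truth data.frame from [generate_reads()].
#' @param clones List of clones from [simulate_clones()].
#' @param idx The `kmer_index` used by the pipeline.
#' @param params The [window_params()] used by the pipeline.
#' @return Data.frame with columns `clone_id` (`NA` for spurious clones),
#'   `window`, `true_fraction`, `est_fraction`, `spurious`.
#' @export
abundance_recovery <- function(table, truth, clones, idx,
                               params = window_params()) {
  clone_ids <- vapply(clones, `[[`, character(1L), "clone_id")
  clone_windows <- vapply(clones, function(cl) {
    res <- analyze_read(idx, cl$full_sequence, params)
    if (res$status != "SEGMENTED") return(NA_character_)
    ext <- extract_window(res$oriented, res$center, params)
    ext$window
  }, character(1L))
  n_total <- nrow(truth)
  true_frac <- as.numeric(table(factor(truth$clone_id, levels = clone_ids))) /
    max(n_total, 1L)
  tot_seg <- total_segmented(table)
  est_for <- function(w) {
    if (is.na(w) || tot_seg == 0L) return(0)
    hit <- vapply(table$member_windows, function(wc) w %in% names(wc),
                  logical(1L))
    if (!any(hit)) return(0)
    sum(table$read_count[hit]) / tot_seg
  }
  est <- vapply(clone_windows, est_for, numeric(1L))
  out <- data.frame(clone_id = clone_ids, window = clone_windows,
                    true_fraction = true_frac, est_fraction = est,
                    spurious = FALSE, stringsAsFactors = FALSE)
  matched <- vapply(table$member_windows, function(wc)
    any(names(wc) %in% clone_windows), logical(1L))
  if (any(!matched)) {
    sp <- data.frame(clone_id = NA_character_,
                     window = table$seed_window[!matched],
                     true_fraction = 0,
                     est_fraction = table$read_count[!matched] /
                       max(tot_seg, 1L),
                     spurious = TRUE, stringsAsFactors = FALSE)
    out <- rbind(out, sp)
  }
  out
}
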