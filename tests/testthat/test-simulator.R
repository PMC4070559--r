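test_that("simulation is byte-identical for a fixed rng seed", {
  db1 <- make_synthetic_germline(rng_seed = 4L)
  db2 <- make_synthetic_germline(rng_seed = 4L)
  expect_identical(db1$v_genes, db2$v_genes)
  expect_identical(db1$j_genes, db2$j_genes)
  cl1 <- simulate_clones(db1, 5, rng_seed = 8L)
  cl2 <- simulate_clones(db2, 5, rng_seed = 8L)
  expect_identical(cl1, cl2)
  g1 <- generate_reads(cl1, 200, p_sub = 0.02, p_homo = 0.01, rng_seed = 15L)
  g2 <- generate_reads(cl2, 200, p_sub = 0.02, p_homo = 0.01, rng_seed = 15L)
  expect_identical(g1, g2)
  # and a different seed changes the output
  g3 <- generate_reads(cl1, 200, p_sub = 0.02, p_homo = 0.01, rng_seed = 16L)
  expect_false(identical(g1$reads, g3$reads))
})

test_that("synthetic germlines respect the locus length ranges", {
  db <- make_synthetic_germline(n_v = 5, n_j = 3, rng_seed = 1L)
  expect_length(db$v_genes, 5L)
  expect_length(db$j_genes, 3L)
  expect_true(all(nchar(db$v_genes) >= 250 & nchar(db$v_genes) <= 310))
  expect_true(all(nchar(db$j_genes) >= 40 & nchar(db$j_genes) <= 70))
  expect_null(db$d_genes)
  expect_error(make_synthetic_germline(n_v = 0), "at least one")
})

test_that("recombination draws stay inside the deletion and N ranges", {
  db <- trg_db()
  set.seed(61)
  draws <- replicate(300, simulate_recombination(db), simplify = FALSE)
  v_dels <- vapply(draws, `[[`, integer(1), "v_del")
  j_dels <- vapply(draws, `[[`, integer(1), "j_del")
  n_lens <- vapply(draws, function(d) nchar(d$n_region), integer(1))
  expect_true(all(v_dels >= 0 & v_dels <= 8))
  expect_true(all(j_dels >= 0 & j_dels <= 8))
  expect_true(all(n_lens >= 0 & n_lens <= 10))
  # every full sequence equals its own reconstruction
  for (d in draws[1:20]) {
    expect_identical(reconstruct_from_designation(d, db), d$full_sequence)
  }
  # all junction deletion/N values are actually visited
  expect_gt(length(unique(v_dels)), 5L)
  expect_gt(length(unique(n_lens)), 6L)
})

test_that("substitutions hit at the requested rate and never keep the base", {
  db <- trg_db()
  clones <- simulate_clones(db, 3, rng_seed = 31L)
  p <- 0.06
  gr <- generate_reads(clones, 400, p_sub = p, p_homo = 0,
                       random_strand = FALSE, rng_seed = 37L)
  clone_of <- setNames(vapply(clones, `[[`, character(1), "full_sequence"),
                       vapply(clones, `[[`, character(1), "clone_id"))
  n_bases <- 0L; n_diff <- 0L
  for (i in seq_along(gr$reads)) {
    ref <- clone_of[[gr$truth$clone_id[i]]]
    a <- strsplit(gr$reads[[i]], "")[[1]]
    b <- strsplit(ref, "")[[1]]
    expect_length(a, length(b))          # substitutions only
    n_bases <- n_bases + length(a)
    n_diff <- n_diff + sum(a != b)
  }
  expect_gt(n_bases, 1e5)
  sd5 <- 5 * sqrt(p * (1 - p) / n_bases)
  expect_lt(abs(n_diff / n_bases - p), sd5)
})

test_that("amplicon reads without errors equal the clone sequence", {
  db <- trg_db()
  clones <- simulate_clones(db, 4, rng_seed = 43L)
  gr <- generate_reads(clones, 100, p_sub = 0, p_homo = 0,
                       random_strand = FALSE, rng_seed = 47L)
  clone_of <- setNames(vapply(clones, `[[`, character(1), "full_sequence"),
                       vapply(clones, `[[`, character(1), "clone_id"))
  centers <- setNames(vapply(clones, `[[`, numeric(1), "junction_center"),
                      vapply(clones, `[[`, character(1), "clone_id"))
  expect_identical(unname(gr$reads), unname(clone_of[gr$truth$clone_id]))
  expect_identical(gr$truth$true_center,
                   as.integer(centers[gr$truth$clone_id]))
  expect_true(all(gr$truth$strand == "+"))
})

test_that("fragment mode emits fixed-length reads and junction coverage truth", {
  db <- trg_db()
  clones <- simulate_clones(db, 3, rng_seed = 53L)
  gr <- generate_reads(clones, 300, read_model = "fragment",
                       fragment_length = 100, p_sub = 0, p_homo = 0,
                       random_strand = FALSE, rng_seed = 59L)
  expect_true(all(nchar(gr$reads) == 100L))
  covered <- !is.na(gr$truth$true_center)
  expect_gt(sum(covered), 10L)
  expect_gt(sum(!covered), 10L)
  expect_true(all(gr$truth$true_center[covered] >= 0 &
                  gr$truth$true_center[covered] <= 99))
  # fragments that cover the junction carry the window content of the clone
  expect_error(generate_reads(clones, 10, read_model = "fragment",
                              fragment_length = 10000),
               "exceeds")
})

test_that("clone read fractions follow the requested abundances", {
  db <- trg_db()
  clones <- simulate_clones(db, 3, rng_seed = 67L)
  ab <- c(0.7, 0.2, 0.1)
  n <- 5000L
  gr <- generate_reads(clones, n, abundances = ab, p_sub = 0, p_homo = 0,
                       rng_seed = 71L)
  frac <- as.numeric(table(factor(gr$truth$clone_id,
                                  levels = sprintf("clone%02d", 1:3)))) / n
  for (i in 1:3) {
    expect_lt(abs(frac[i] - ab[i]), 4 * sqrt(ab[i] * (1 - ab[i]) / n))
  }
  # geometric shorthand resolves and normalises
  gr2 <- generate_reads(clones, 100, abundances = "geometric(0.5)",
                        rng_seed = 73L)
  expect_equal(nrow(gr2$truth), 100L)
  expect_error(generate_reads(clones, 10, abundances = c(0.5, 0.5)),
               "does not match")
  expect_error(generate_reads(clones, 10, abundances = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("reads round-trip through FASTA and FASTQ writers", {
  db <- trg_db()
  clones <- simulate_clones(db, 2, rng_seed = 79L)
  gr <- generate_reads(clones, 20, p_sub = 0.01, rng_seed = 83L)
  fa <- tempfile(fileext = ".fasta")
  fq <- tempfile(fileext = ".fastq")
  write_reads(gr$reads, fa)
  write_reads(gr$reads, fq)
  expect_identical(read_reads(fa), gr$reads)
  expect_identical(read_reads(fq), gr$reads)
})
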