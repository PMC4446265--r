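test_that("generation is reproducible and honors the truth table", {
  plants <- list(plant_spec("TGACTCAT", 0.6, "ap1"),
                 plant_spec("CACGTGAC", 0.4, "ebox"))
  sim1 <- simulate_peak_sequences(50, 40, 150, plants = plants, seed = 7)
  sim2 <- simulate_peak_sequences(50, 40, 150, plants = plants, seed = 7)
  expect_identical(sim1$seqs$seq, sim2$seqs$seq)
  expect_identical(sim1$truth, sim2$truth)

  expect_equal(sum(sim1$seqs$label > 0), 50)
  expect_equal(sum(sim1$seqs$label < 0), 40)
  expect_equal(nchar(sim1$seqs$seq), rep(150, 90))

  # every truth record points at a real planted instance
  for (i in seq_len(nrow(sim1$truth))) {
    tr <- sim1$truth[i, ]
    inst <- substr(sim1$seqs$seq[match(tr$id, sim1$seqs$id)],
                   tr$start + 1, tr$start + 8)
    planted <- if (tr$motif == "ap1") "TGACTCAT" else "CACGTGAC"
    if (tr$strand == "-") planted <- oracle_revcomp(planted)
    expect_equal(inst, planted)
  }
  # instances respect the edge margin
  expect_true(all(sim1$truth$start >= 5))
  expect_true(all(sim1$truth$start + 8 <= 145))

  expect_error(simulate_peak_sequences(5, 5, 150, plants = plants),
               "seed")
  expect_error(simulate_peak_sequences(5, 5, 10, plants = plants,
                                       seed = 1), "longer")
})

test_that("plant fractions land within binomial bounds", {
  plants <- list(plant_spec("TGACTCAT", 0.6, "ap1"),
                 plant_spec("CACGTGAC", 0.4, "ebox"))
  sim <- simulate_peak_sequences(500, 10, 150, plants = plants, seed = 11)
  n_ap1 <- sum(sim$truth$motif == "ap1")
  n_ebox <- sum(sim$truth$motif == "ebox")
  # 99.9% binomial intervals around 300 and 200
  expect_true(abs(n_ap1 - 300) < 3.3 * sqrt(500 * 0.6 * 0.4))
  expect_true(abs(n_ebox - 200) < 3.3 * sqrt(500 * 0.4 * 0.6))
  # both strands appear
  expect_true(all(c("+", "-") %in% sim$truth$strand))
})

test_that("fraction-zero plants leave classes exchangeable", {
  sim <- simulate_peak_sequences(40, 40, 80, plants = list(
    plant_spec("TGACTCAT", 0, "never")), seed = 3)
  expect_equal(nrow(sim$truth), 0)
})

test_that("background follows the transition matrix", {
  # uniform background: base frequencies near 0.25
  sim <- simulate_peak_sequences(0, 100, 200, background = "uniform",
                                 seed = 5)
  bases <- table(strsplit(paste(sim$seqs$seq, collapse = ""), "")[[1]])
  expect_equal(unname(bases / sum(bases)), rep(0.25, 4),
               tolerance = 0.02, ignore_attr = TRUE)

  # default CpG-depleted background: chi-square against the stationary
  # distribution is not rejected at 0.001, and CG dinucleotides are
  # depleted relative to GC
  sim2 <- simulate_peak_sequences(0, 500, 200, seed = 6)
  all_seq <- paste(sim2$seqs$seq, collapse = "")
  P <- peakgl:::.default_background()
  pi0 <- peakgl:::.stationary(P)
  obs <- table(factor(strsplit(all_seq, "")[[1]],
                      levels = c("A", "C", "G", "T")))
  chisq <- suppressWarnings(stats::chisq.test(obs, p = pi0))
  expect_gt(chisq$p.value, 0.001)
  dn <- dinuc_counts(all_seq)
  expect_lt(dn[["CG"]], 0.5 * dn[["GC"]])
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    out <- dinucleotide_shuffle(seq, seed = rep)
    expect_equal(dinuc_counts(out), dinuc_counts(seq))
    expect_equal(substr(out, 1, 1), substr(seq, 1, 1))
    expect_equal(substr(out, n, n), substr(seq, n, n))
  }
})

test_that("short-string shuffles stay within the valid Eulerian set", {
  # all shuffles of ACGCGT must preserve dinucleotides {AC,CG,GC,CG,GT};
  # enumerate the valid arrangements by brute force and compare
  seq <- "ACGCGT"
  valid <- character(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  for (p in perms(strsplit(seq, "")[[1]])) {
    cand <- paste(p, collapse = "")
    if (identical(dinuc_counts(cand), dinuc_counts(seq)) &&
        substr(cand, 1, 1) == "A" && substr(cand, 6, 6) == "T") {
      valid <- c(valid, cand)
    }
  }
  seen <- vapply(1:40, function(s) dinucleotide_shuffle(seq, seed = s),
                 character(1))
  expect_true(all(seen %in% valid))
  # a longer string admits many arrangements; the shuffle explores them
  long <- "ACGTCATGCATTGCAGCTACGT"
  seen_long <- vapply(1:20, function(s)
    dinucleotide_shuffle(long, seed = s), character(1))
  expect_gt(length(unique(seen_long)), 1)
})

test_that("two-motif benchmark partitions positives between motifs", {
  set <- simulate_two_motif_set(seed = 2, n_pos = 100, n_neg = 50)
  expect_equal(sum(set$seqs$label > 0), 100)
  expect_equal(sum(set$seqs$label < 0), 50)
  expect_equal(sum(set$truth$motif == "motif_a"), 60)
  expect_equal(sum(set$truth$motif == "motif_b"), 40)
  # disjoint carriers covering all positives
  expect_equal(sort(set$truth$id),
               sort(set$seqs$id[set$seqs$label > 0]))
  expect_identical(
    set$seqs$seq,
    simulate_two_motif_set(seed = 2, n_pos = 100, n_neg = 50)$seqs$seq)
})
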