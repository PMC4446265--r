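# shared small fitted model on a planted one-motif set
fit_one_motif <- function(seed = 19, n = 120, width = 60) {
  sp <- kmer_feature_space(6, 1)
  sim <- simulate_peak_sequences(
    n, n, width, plants = list(plant_spec("TGACTG", 1, "m")), seed = seed)
  M <- select_features(count_features(sim$seqs, sp), 120)
  A <- cluster_features(M, 5)
  lmax <- sgl_lambda_max(M, A)
  fit <- sgl_fit(M, A, 0.02 * lmax$lambda1_max, 0.02 * lmax$lambda2_max)
  list(sim = sim, M = M, A = A, fit = fit, sp = sp)
}

test_that("class scores follow the loss formula and activation rule", {
  ctx <- fit_one_motif()
  consensus_grp <- ctx$A$group_of[[
    match(canonical_kmer("TGACTG"), ctx$M$space$patterns)]]
  cs <- class_scores(ctx$fit, ctx$M, consensus_grp)

  # loss form: score(g,i) = log(1 + exp(-y_i a_i)), summed per class
  a <- cs$activations
  y <- ctx$M$labels
  expect_equal(cs$class_score_pos, sum(log1p(exp(-y[y > 0] * a[y > 0]))))
  expect_equal(cs$class_score_neg,
               sum(log1p(exp(-y[y < 0] * a[y < 0]))))
  # motif group activates positives
  expect_equal(cs$class, 1L)
  # zero-activation example scores log 2 under the formula
  expect_equal(log1p(exp(0)), log(2))

  # all-zero group has no class
  zero_groups <- setdiff(seq_len(ctx$A$G),
                         unique(ctx$A$group_of[ctx$fit$w != 0]))
  if (length(zero_groups)) {
    cz <- class_scores(ctx$fit, ctx$M, zero_groups[1])
    expect_true(is.na(cz$class))
    # both sums are N_class * log 2
    expect_equal(cz$class_score_pos, sum(y > 0) * log(2))
  }
  expect_error(class_scores(ctx$fit, ctx$M, 99), "no such group")
})

test_that("loss-form class association is available and sign-inverted", {
  ctx <- fit_one_motif()
  g <- ctx$A$group_of[[match(canonical_kmer("TGACTG"),
                             ctx$M$space$patterns)]]
  act_mode <- class_scores(ctx$fit, ctx$M, g, method = "activation")
  score_mode <- class_scores(ctx$fit, ctx$M, g, method = "score")
  # a well-fit positive group has small positive-class loss, so the
  # literal max-of-sums rule points at the negative class
  expect_equal(act_mode$class, 1L)
  expect_equal(score_mode$class, -1L)
})

test_that("empirical p-values and BH calls match the brute-force rule", {
  # maximal separation: every p = 1/(N_null + 1), all significant
  act <- stats::setNames(c(rep(5, 10), rep(0, 100)),
                         paste0("e", 1:110))
  lab <- c(rep(1, 10), rep(-1, 100))
  sig <- call_significant(act, lab, class = 1, fdr = 0.05)
  expect_equal(sig$p, rep(1 / 101, 10))
  expect_true(all(sig$significant))

  # BH against the brute-force step-up oracle on many short vectors
  set.seed(40)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    p <- round(runif(n), 3)
    q <- stats::p.adjust(p, "BH")
    for (alpha in seq(0.05, 1, by = 0.05)) {
      expect_equal(q <= alpha, bh_reject(p, alpha), info = paste(rep, alpha))
    }
  }

  # the known worked example: only the first two rejected at 5%
  q <- stats::p.adjust(c(0.01, 0.02, 0.2, 0.9), "BH")
  expect_equal(q <= 0.05, c(TRUE, TRUE, FALSE, FALSE))

  expect_error(call_significant(act, rep(1, 110), class = 1), "null")
})

test_that("empirical p-values are super-uniform under exchangeability", {
  set.seed(77)
  for (rep in 1:5) {
    act <- stats::setNames(rnorm(400), paste0("e", 1:400))
    lab <- rep(c(1, -1), each = 200)
    sig <- call_significant(act, lab, class = 1, fdr = 0.05)
    for (t in c(0.01, 0.05, 0.1)) {
      se <- sqrt(t * (1 - t) / 200)
      expect_lte(mean(sig$p <= t), t + 3 * se)
    }
    # mirrored tail for negative-class groups
    sign <- call_significant(act, lab, class = -1, fdr = 0.05)
    expect_true(all(sign$p > 0 & sign$p <= 1))
  }
})

test_that("hits land on planted instances with deterministic tie-breaks", {
  ctx <- fit_one_motif()
  g <- ctx$A$group_of[[match(canonical_kmer("TGACTG"),
                             ctx$M$space$patterns)]]
  pos_seqs <- ctx$sim$seqs[ctx$sim$seqs$label > 0, ][1:40, ]
  hits <- locate_hits(ctx$fit, ctx$M, pos_seqs, g)
  expect_gt(nrow(hits), 30)
  truth <- ctx$sim$truth[match(hits$example_id, ctx$sim$truth$id), ]
  k <- 6
  dist <- abs((hits$position + k / 2) - (truth$start + 3))
  expect_gt(mean(dist <= 10), 0.8)

  # per-position scores summed over positions equal the activation
  acts <- class_scores(ctx$fit, ctx$M, g)$activations
  expect_equal(unname(hits$activation),
               unname(acts[hits$example_id]))

  # leftmost tie-break: two identical instances, single-pattern group
  w <- stats::setNames(rep(0, length(ctx$fit$w)), names(ctx$fit$w))
  cons <- canonical_kmer("TGACTG")
  w[cons] <- 1
  fake_fit <- ctx$fit
  fake_fit$w <- w
  two <- labeled_seqs("two", paste0(
    strrep("C", 10), "TGACTG", strrep("C", 20), "TGACTG",
    strrep("C", 18)), 1)
  h <- locate_hits(fake_fit, ctx$M,
                   two, ctx$A$group_of[[match(cons, ctx$M$space$patterns)]])
  expect_equal(h$position, 10)
  # canonical name of TGACTG is its reverse complement CAGTCA, so the
  # planted forward instance is a reverse-orientation match
  expect_equal(h$strand, if (cons == "TGACTG") "+" else "-")

  # no match anywhere -> skipped with warning
  blank <- labeled_seqs("blank", strrep("C", 60), 1)
  expect_warning(h0 <- locate_hits(fake_fit, ctx$M, blank,
                                   ctx$A$group_of[[match(cons, ctx$M$space$patterns)]]),
                 "skipped")
  expect_equal(nrow(h0), 0)
})

test_that("hit windows export round-trips and clips at edges", {
  ctx <- fit_one_motif()
  g <- ctx$A$group_of[[match(canonical_kmer("TGACTG"),
                             ctx$M$space$patterns)]]
  pos_seqs <- ctx$sim$seqs[ctx$sim$seqs$label > 0, ][1:30, ]
  hits <- locate_hits(ctx$fit, ctx$M, pos_seqs, g)
  fa <- tempfile(fileext = ".fa")
  export_hit_windows(hits, pos_seqs, fa, window_bases = 50)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), nrow(hits))
  # record sequence equals the window substring of its source
  i <- 1
  src <- pos_seqs$seq[match(hits$example_id[i], pos_seqs$id)]
  expect_equal(as.character(back[[i]]),
               substr(src, hits$win_start[i] + 1, hits$win_end[i]))
  # 60-wide sequences always clip a 50-wide window unless centered;
  # clipped records carry a len= tag
  short <- Biostrings::width(back) < 50
  if (any(short)) {
    expect_true(all(grepl("len=", names(back)[short])))
  }
})

test_that("group PFMs align instances and conserve column sums", {
  ctx <- fit_one_motif(seed = 23, n = 150)
  g <- ctx$A$group_of[[match(canonical_kmer("TGACTG"),
                             ctx$M$space$patterns)]]
  pos_seqs <- ctx$sim$seqs[ctx$sim$seqs$label > 0, ]
  hits <- locate_hits(ctx$fit, ctx$M, pos_seqs, g)
  pfm <- build_group_pfm(hits, pos_seqs, k = 6)
  expect_equal(dim(pfm), c(4, 6))
  expect_equal(unname(colSums(pfm)), rep(nrow(hits), 6))
  # consensus of the PFM equals the planted consensus (possibly as RC)
  cons <- paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  expect_true(canonical_kmer(cons) == canonical_kmer("TGACTG"))
  expect_error(build_group_pfm(hits[1:3, ], pos_seqs, 6), "at least")

  # all-identical hits give indicator columns
  ids <- paste0("s", 1:30)
  seqs30 <- labeled_seqs(ids, rep(paste0("AAAA", "ACGTAC", "AAAA"), 30),
                         rep(1, 30))
  h <- data.frame(example_id = ids, group = 1, position = 4,
                  strand = "+", win_start = 0, win_end = 14,
                  activation = 1, q = 0.01)
  pfm1 <- build_group_pfm(h, seqs30, 6, min_examples = 10)
  expect_equal(unname(apply(pfm1, 2, max)), rep(30, 6))
})

test_that("group report tabulates significance and motif eligibility", {
  ctx <- fit_one_motif()
  rep_ <- group_report(ctx$fit, ctx$M, fdr = 0.05, min_examples = 25)
  tab <- rep_$table
  expect_equal(nrow(tab), ctx$A$G)
  g <- ctx$A$group_of[[match(canonical_kmer("TGACTG"),
                             ctx$M$space$patterns)]]
  expect_equal(tab$class[g], "+1")
  expect_true(tab$n_significant[g] >= 25)
  expect_true(tab$eligible_for_motif[g])
  # q-values respect the fdr count
  det <- rep_$details[[g]]
  expect_equal(sum(det$q <= 0.05), tab$n_significant[g])
})

test_that("MEME export is well-formed", {
  pfm <- matrix(c(10, 0, 0, 0,  0, 10, 0, 0,  0, 0, 10, 0), 4, 3,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  path <- tempfile(fileext = ".meme")
  write_meme(list(group_1 = pfm), path)
  lines <- readLines(path)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^MOTIF group_1", lines)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 3",
                        lines)))
})
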