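# Synthetic peak/flank sequence sets with planted motif instances and a
# ground-truth table, so every stage of the pipeline is testable without
# external data.

#' Specification of a motif to plant
#'
#' @param motif position probability matrix, `width x 4` with columns
#'   A, C, G, T and rows summing to 1 (a consensus string is also
#'   accepted and converted to a deterministic PPM).
#' @param fraction proportion of positive sequences receiving an
#'   instance.
#' @param name motif identifier used in the truth table.
#' @param placement `"uniform"` (anywhere inside the margins) or
#'   `"center"` (Gaussian around the window center).
#' @param strand_prob probability that an instance is inserted as its
#'   reverse complement (default 0.5).
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(motif, fraction, name = "motif",
                       placement = c("uniform", "center"),
                       strand_prob = 0.5) {
  placement <- match.arg(placement)
  if (is.character(motif)) {
    chars <- strsplit(toupper(motif), "")[[1]]
    stopifnot(all(chars %in% c("A", "C", "G", "T")))
    m <- matrix(0, length(chars), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- 1
    motif <- m
  }
  stopifnot(is.matrix(motif), ncol(motif) == 4,
            all(abs(rowSums(motif) - 1) < 1e-9),
            fraction >= 0, fraction <= 1)
  colnames(motif) <- c("A", "C", "G", "T")
  structure(list(motif = motif, fraction = fraction, name = name,
                 placement = placement, strand_prob = strand_prob),
            class = "plant_spec")
}

#' Consensus string of a position probability matrix
#'
#' @param ppm `width x 4` PPM (or a `plant_spec`).
#' @return Consensus string (highest-probability base per position).
#' @export
ppm_consensus <- function(ppm) {
  if (inherits(ppm, "plant_spec")) ppm <- ppm$motif
  paste(c("A", "C", "G", "T")[max.col(ppm, ties.method = "first")],
        collapse = "")
}

# default order-1 background: uniform transitions with the C->G
# transition down-weighted 4-fold, mimicking genomic CpG depletion
.default_background <- function() {
  P <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  P["C", "G"] <- 0.25 * 0.25
  P["C", ] <- P["C", ] / sum(P["C", ])
  P
}

# stationary distribution of a transition matrix (left eigenvector)
.stationary <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}

.sample_markov <- function(n, width, P, pi0) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    s <- integer(width)
    s[1] <- sample.int(4, 1, prob = pi0)
    for (j in 2:width) {
      s[j] <- sample.int(4, 1, prob = P[s[j - 1], ])
    }
    out[i] <- paste(bases[s], collapse = "")
  }
  out
}

.sample_instance <- function(ppm) {
  bases <- c("A", "C", "G", "T")
  paste(bases[apply(ppm, 1, function(p) sample.int(4, 1, prob = p))],
        collapse = "")
}

#' Generate labeled peak/flank sequences with planted motifs
#'
#' Negatives are pure order-1 Markov background; each positive
#' independently receives an instance of each planted motif with its
#' specified fraction, sampled column-wise from the PPM, reverse
#' complemented with probability `strand_prob`, and placed uniformly
#' inside the window margins.  Overlap between instances in the same
#' sequence is resolved by redrawing the position up to `max_attempts`
#' times, after which the instance is skipped (and recorded as such in
#' the attrition count).  The whole set is reproducible from `seed`.
#'
#' @param n_pos,n_neg numbers of positive and negative sequences.
#' @param width sequence width in bases (default 150).
#' @param plants list of [plant_spec()] objects.
#' @param background `"markov"` (default: CpG-depleted order-1 model),
#'   `"uniform"`, or a 4 x 4 transition matrix with rows A, C, G, T.
#' @param seed integer seed (required).
#' @param edge_margin bases at each end kept free of instances
#'   (default 5), so downstream hit windows rarely clip.
#' @param max_attempts redraw attempts for overlapping placements
#'   (default 100).
#' @param task optional task id stored on all sequences.
#' @return list with `seqs` (a `labeled_seqs` data frame), `truth`
#'   (data frame `id`, `motif`, `start` 0-based, `strand`), and
#'   `params`.
#' @export
simulate_peak_sequences <- function(n_pos, n_neg, width = 150,
                                    plants = list(), background = "markov",
                                    seed, edge_margin = 5,
                                    max_attempts = 100, task = NA) {
  if (missing(seed)) stop("seed is required")
  for (pl in plants) {
    if (nrow(pl$motif) > width - 2 * edge_margin) {
      stop("motif ", pl$name, " longer than usable window")
    }
  }
  P <- if (is.matrix(background)) background
  else if (background == "uniform") matrix(0.25, 4, 4)
  else .default_background()
  pi0 <- .stationary(P)

  .with_seed(seed, {
    pos <- .sample_markov(n_pos, width, P, pi0)
    neg <- .sample_markov(n_neg, width, P, pi0)

    truth <- list()
    n_skipped <- 0L
    for (i in seq_len(n_pos)) {
      occupied <- matrix(FALSE, 1, width)[1, ]
      for (pl in plants) {
        if (stats::runif(1) > pl$fraction) next
        wm <- nrow(pl$motif)
        inst <- .sample_instance(pl$motif)
        strand <- "+"
        if (stats::runif(1) < pl$strand_prob) {
          inst <- revcomp(inst)
          strand <- "-"
        }
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          start <- sample.int(width - 2 * edge_margin - wm + 1, 1) +
            edge_margin - 1L            # 0-based start
          span <- (start + 1):(start + wm)
          if (!any(occupied[span])) {
            occupied[span] <- TRUE
            substr(pos[i], start + 1, start + wm) <- inst
            truth[[length(truth) + 1]] <- data.frame(
              id = paste0("pos_", i), motif = pl$name,
              start = start, strand = strand,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) n_skipped <- n_skipped + 1L
      }
    }

    mk_ids <- function(tag, n) {
      if (n == 0) character(0) else paste0(tag, seq_len(n))
    }
    seqs <- labeled_seqs(
      id = c(mk_ids("pos_", n_pos), mk_ids("neg_", n_neg)),
      seq = c(pos, neg),
      label = rep(c(1L, -1L), c(n_pos, n_neg)),
      task = task)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(0), motif = character(0),
                 start = integer(0), strand = character(0))
    list(seqs = seqs, truth = truth,
         params = list(n_pos = n_pos, n_neg = n_neg, width = width,
                       background = P, seed = seed,
                       edge_margin = edge_margin,
                       n_skipped_instances = n_skipped))
  })
}

#' Two-motif benchmark sequence set
#'
#' The standard end-to-end validation fixture: positives are partitioned
#' into two disjoint subsets carrying exact consensus instances of two
#' different motifs (a fraction `frac_a` of positives carries
#' `motif_a`, the remainder `motif_b`), negatives are pure background.
#' Every positive carries exactly one planted signal, so near-perfect
#' test discrimination is attainable and each motif's k-mer family
#' occupies its own co-occurrence cluster.
#'
#' @param seed integer seed.
#' @param n_pos,n_neg numbers of sequences (defaults 500/500).
#' @param width sequence width (default 150).
#' @param motif_a,motif_b consensus strings or PPMs for the two planted
#'   motifs (defaults: AP-1-like TGACTCAT and E-box-like CACGTGAC).
#' @param frac_a fraction of positives carrying `motif_a`
#'   (default 0.6).
#' @param background passed to [simulate_peak_sequences()].
#' @return list with `seqs`, `truth`, and the two consensus strings
#'   (`consensus_a`, `consensus_b`).
#' @export
simulate_two_motif_set <- function(seed, n_pos = 500, n_neg = 500,
                                   width = 150,
                                   motif_a = "TGACTCAT",
                                   motif_b = "CACGTGAC",
                                   frac_a = 0.6,
                                   background = "markov") {
  n_a <- round(frac_a * n_pos)
  sub_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1, 2))
  sim_a <- simulate_peak_sequences(
    n_a, 0, width, plants = list(plant_spec(motif_a, 1, "motif_a")),
    background = background, seed = sub_seeds[1])
  sim_b <- simulate_peak_sequences(
    n_pos - n_a, n_neg, width,
    plants = list(plant_spec(motif_b, 1, "motif_b")),
    background = background, seed = sub_seeds[2])
  rename <- function(x) sub("^pos_", "posB_", x)
  sim_b$seqs$id <- rename(sim_b$seqs$id)
  sim_b$truth$id <- rename(sim_b$truth$id)
  seqs <- as_labeled_seqs(rbind(sim_a$seqs, sim_b$seqs))
  spec_a <- plant_spec(motif_a, 1)
  spec_b <- plant_spec(motif_b, 1)
  list(seqs = seqs, truth = rbind(sim_a$truth, sim_b$truth),
       consensus_a = ppm_consensus(spec_a),
       consensus_b = ppm_consensus(spec_b))
}

#' Two-task benchmark sequence set
#'
#' The standard multitask validation fixture: two peak-vs-flank tasks
#' whose positives share one motif, while a second motif occurs in
#' task 1 only.  Used to examine how the multitask model distributes
#' shared versus context-specific sequence signals between the common
#' and task-specific weight blocks.
#'
#' @param seed integer seed.
#' @param n_per_class sequences per class per task (default 200).
#' @param width sequence width (default 150).
#' @param shared,private consensus strings (or PPMs) of the shared and
#'   task-1-only motifs.
#' @param fraction fraction of positives carrying each applicable
#'   motif (default 0.9).
#' @param background passed to [simulate_peak_sequences()].
#' @return list with `seqs` (tasks `T1`, `T2`), the two `truth` tables,
#'   and the canonical consensus strings.
#' @export
simulate_two_task_set <- function(seed, n_per_class = 200, width = 150,
                                  shared = "TGACTCAT",
                                  private = "CCATTGGC",
                                  fraction = 0.9,
                                  background = "markov") {
  sub <- .with_seed(seed, sample.int(.Machine$integer.max - 1, 2))
  t1 <- simulate_peak_sequences(
    n_per_class, n_per_class, width,
    plants = list(plant_spec(shared, fraction, "shared"),
                  plant_spec(private, fraction, "private")),
    background = background, seed = sub[1], task = "T1")
  t2 <- simulate_peak_sequences(
    n_per_class, n_per_class, width,
    plants = list(plant_spec(shared, fraction, "shared")),
    background = background, seed = sub[2], task = "T2")
  t2$seqs$id <- paste0("t2_", t2$seqs$id)
  t2$truth$id <- paste0("t2_", t2$truth$id)
  list(seqs = as_labeled_seqs(rbind(t1$seqs, t2$seqs)),
       truth = rbind(t1$truth, t2$truth),
       consensus_shared = ppm_consensus(plant_spec(shared, 1)),
       consensus_private = ppm_consensus(plant_spec(private, 1)))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-walk shuffle: the output is a random
#' permutation of the input's dinucleotide multigraph walks, so it has
#' exactly the same dinucleotide multiset (and hence the same base
#' composition), and the same first and last base.  Used to build
#' composition-matched negative sets.
#'
#' @param seq input sequence string (length >= 3, A/C/G/T).
#' @param seed integer seed.
#' @return Shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  .with_seed(seed, {
    verts <- unique(chars)
    from <- chars[-n]
    to <- chars[-1]
    last_vert <- chars[n]

    # out-edge adjacency lists
    adj <- split(to, factor(from, levels = verts))

    # choose, for every vertex except the terminal one, a designated
    # last out-edge such that the chosen edges form a tree into the
    # terminal vertex (guarantees the shuffled walk is Eulerian)
    repeat {
      last_edge <- vapply(verts, function(v) {
        if (v == last_vert || !length(adj[[v]])) NA_character_
        else sample(adj[[v]], 1)
      }, character(1))
      # connectivity check: follow last edges toward the terminal vertex
      ok <- TRUE
      for (v in verts) {
        if (v == last_vert || !length(adj[[v]])) next
        cur <- v
        steps <- 0
        while (cur != last_vert && steps <= length(verts)) {
          cur <- last_edge[[cur]]
          if (is.na(cur)) break
          steps <- steps + 1
        }
        if (is.na(cur) || cur != last_vert) { ok <- FALSE; break }
      }
      if (ok) break
    }

    # shuffle the remaining edges of each vertex, append the last edge
    shuffled <- lapply(verts, function(v) {
      edges <- adj[[v]]
      if (!length(edges)) return(character(0))
      if (v == last_vert || is.na(last_edge[[v]])) return(sample(edges))
      drop1 <- match(last_edge[[v]], edges)
      rest <- edges[-drop1]
      c(if (length(rest)) sample(rest) else character(0), last_edge[[v]])
    })
    names(shuffled) <- verts

    # walk
    out <- character(n)
    out[1] <- chars[1]
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    for (i in 2:n) {
      v <- out[i - 1]
      out[i] <- shuffled[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
    }
    paste(out, collapse = "")
  })
}
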