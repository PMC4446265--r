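#' Cluster k-mer features into co-occurrence groups
#'
#' Features that tend to occur in the same examples — the exact consensus
#' k-mer of a binding signal together with its wildcarded and shifted
#' variants — are gathered into groups that then act as the blocks of the
#' group lasso penalty.  The distance between two features is
#' `1 - Spearman rank correlation` of their count columns across all
#' examples (both classes); the agglomerative tree is cut into exactly
#' `G` clusters.
#'
#' Constant count columns have no rank variance; their correlation with
#' every other feature is defined as 0 (distance 1) and a warning is
#' emitted.
#'
#' @param M a `feature_matrix`.
#' @param G number of groups, `1 <= G <=` number of features.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).  Ward's criterion produces compact,
#'   balanced clusters; average linkage tends to chain the many weakly
#'   correlated background features into one giant cluster that can
#'   swallow several distinct motifs' k-mer families.
#' @return An object of class `group_assignment`: list with `group_of`
#'   (integer vector, one entry per feature, named by pattern), `sizes`
#'   (`l_g`), and `G`.
#' @export
cluster_features <- function(M, G, linkage = "ward.D2") {
  stopifnot(inherits(M, "feature_matrix"))
  p <- ncol(M$counts)
  if (G < 1 || G > p) stop("G must be in [1, number of features]")

  if (G == p) {
    return(.as_group_assignment(stats::setNames(seq_len(p),
                                                M$space$patterns)))
  }

  X <- as.matrix(M$counts)
  ranks <- apply(X, 2, rank)          # midranks for ties
  sds <- apply(ranks, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s): correlation with ",
            "all other features set to 0")
    # give constant columns zero variance contribution; fixed up below
    ranks[, const] <- 0
  }
  Z <- scale(ranks)
  Z[, const] <- 0
  C <- crossprod(Z) / (nrow(Z) - 1)
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1

  d <- stats::as.dist(1 - C)
  tree <- stats::hclust(d, method = linkage)
  grp <- stats::cutree(tree, k = G)
  names(grp) <- M$space$patterns
  .as_group_assignment(grp)
}

.as_group_assignment <- function(group_of) {
  sizes <- tabulate(group_of, nbins = max(group_of))
  stopifnot(all(sizes >= 1), sum(sizes) == length(group_of))
  structure(list(group_of = group_of, sizes = sizes,
                 G = max(group_of)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group assignment:", length(x$group_of), "features in", x$G,
      "groups (sizes ", paste(x$sizes, collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a group assignment as two-column TSV
#'
#' @param A a `group_assignment`.
#' @param path TSV path (columns `feature`, `group`).
#' @return `path` (write) or a `group_assignment` (read).
#' @export
write_groups <- function(A, path) {
  utils::write.table(
    data.frame(feature = names(A$group_of), group = A$group_of),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .as_group_assignment(stats::setNames(as.integer(df$group), df$feature))
}
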