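#' Dice similarity between two binary fingerprints
#'
#' `dice(a, b) = 2|a AND b| / (|a| + |b|)` where `|.|` counts 1s: the
#' proportion of shared bands among all bands of the two accessions. Equals
#' 1 for identical non-empty band sets, 0 for disjoint ones. Undefined (an
#' error) when both vectors carry no band at all.
#'
#' Note that `1 - dice` is not guaranteed to satisfy the triangle
#' inequality; downstream code never assumes it is a metric.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @examples
#' dice(c(1, 1, 0, 1), c(1, 0, 1, 1)) # 2/3
#' @export
dice <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) abort("inputs must be 0/1 vectors")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) abort("Dice similarity is undefined for two all-zero fingerprints")
  2 * sum(a == 1 & b == 1) / (na + nb)
}

#' Pairwise Dice similarity matrix
#'
#' Computes Dice similarity over all allele columns for every accession
#' pair. Missing amplifications (see [missing_mask()]) are handled by
#' policy: `"zeros"` (default) scores a missing locus as absent bands;
#' `"pairwise-complete"` drops, for each pair, the columns of loci missing
#' in either accession before computing the coefficient.
#'
#' @param x An `allele_matrix` with at least 2 accessions.
#' @param missing_policy `"zeros"` or `"pairwise-complete"`.
#' @return A `similarity_matrix`: symmetric numeric matrix with unit
#'   diagonal and accession dimnames.
#' @export
similarity_matrix <- function(x, missing_policy = c("zeros", "pairwise-complete")) {
  stopifnot(inherits(x, "allele_matrix"))
  missing_policy <- match.arg(missing_policy)
  m <- as_matrix(x)
  if (nrow(m) < 2) abort("need at least 2 accessions")
  zero_rows <- rownames(m)[rowSums(m) == 0]
  if (length(zero_rows) > 0) {
    abort(sprintf("accession(s) with no scored band: %s",
                  paste(zero_rows, collapse = ", ")))
  }
  miss <- missing_mask(x)
  if (missing_policy == "zeros" || nrow(miss) == 0) {
    inter <- m %*% t(m)
    sums <- rowSums(m)
    s <- 2 * inter / outer(sums, sums, `+`)
  } else {
    cmap <- column_map(x)
    n <- nrow(m)
    s <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
    miss_by_acc <- split(miss$locus, miss$accession)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        bad <- unique(c(miss_by_acc[[rownames(m)[i]]], miss_by_acc[[rownames(m)[j]]]))
        keep <- !cmap$locus %in% bad
        if (!any(keep)) {
          abort(sprintf("accessions %s and %s share no amplified locus",
                        rownames(m)[i], rownames(m)[j]))
        }
        a <- m[i, keep]
        b <- m[j, keep]
        if (sum(a) + sum(b) == 0) {
          abort(sprintf("accession pair %s/%s has no scored band after dropping missing loci",
                        rownames(m)[i], rownames(m)[j]))
        }
        s[i, j] <- s[j, i] <- 2 * sum(a & b) / (sum(a) + sum(b))
      }
    }
  }
  diag(s) <- 1
  structure(s, class = c("similarity_matrix", "matrix", "array"))
}

# lexicographic key for a cluster's member set
member_key <- function(members) paste(sort(members), collapse = "\x1f")

#' UPGMA agglomerative clustering
#'
#' Unweighted pair-group method with arithmetic averages: repeatedly merges
#' the pair of clusters at minimal distance; the distance from the merged
#' cluster to any other is the size-weighted average of its parts, i.e. the
#' unweighted mean of all original cross-pair distances. Ties at the
#' minimal distance are broken toward the lexicographically smallest pair
#' of member-id sets, so results are reproducible. Each internal node sits
#' at height = merge distance / 2 (molecular-clock convention), making the
#' tree ultrametric with leaf-to-leaf cophenetic distance equal to the
#' merge distance.
#'
#' @param d A square symmetric non-negative distance matrix with zero
#'   diagonal (typically `1 - similarity_matrix(x)`), or a [stats::dist].
#' @return An `ssr_dendrogram`, inheriting from [stats::hclust] (`$height`
#'   stores merge distances, the hclust convention; halving gives node
#'   heights).
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' tree <- upgma(d)
#' cophenetic_matrix(tree)
#' @seealso [cut_k()], [to_newick()], [cophenetic_correlation()]
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (anyNA(d)) abort("distance matrix contains NA")
  if (any(d < 0)) abort("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-12)) abort("distance matrix must be symmetric")
  if (any(diag(d) != 0)) abort("distance diagonal must be zero")
  n <- nrow(d)
  if (n < 2) abort("need at least 2 leaves")
  labels <- rownames(d) %||% as.character(seq_len(n))

  D <- d
  active <- seq_len(n)
  code <- -seq_len(n)           # hclust codes: -leaf or merge-row index
  size <- rep(1L, n)
  members <- as.list(labels)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- active
    sub <- D[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(rc) {
        a <- idx[rc[1]]
        b <- idx[rc[2]]
        paste(sort(c(member_key(members[[a]]), member_key(members[[b]]))),
              collapse = "\x1e")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- idx[cand[1, 1]]
    j <- idx[cand[1, 2]]

    pair <- sort(c(code[i], code[j]))
    merge[step, ] <- pair
    height[step] <- D[i, j]

    # weighted-average update: new cluster lives in slot i
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      D[i, others] <- (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j])
      D[others, i] <- D[i, others]
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    code[i] <- step
    active <- setdiff(active, j)
  }

  order <- dendrogram_order(merge)
  res <- list(
    merge = merge, height = height, order = order, labels = labels,
    method = "upgma", call = match.call(),
    dist.method = "user-supplied"
  )
  class(res) <- c("ssr_dendrogram", "hclust")
  res
}

# leaf order by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.ssr_dendrogram <- function(x, ...) {
  cat(sprintf("# UPGMA dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height) / 2))
  invisible(x)
}

#' Cophenetic matrix and cophenetic correlation
#'
#' The cophenetic distance between two leaves is twice the height of their
#' lowest common ancestor -- for a UPGMA tree, the distance at which the two
#' accessions were merged. The cophenetic correlation is the Pearson
#' correlation between the original pairwise distances and the cophenetic
#' ones over all unordered pairs: a clustering-fit diagnostic, 1 for an
#' exactly ultrametric input.
#'
#' @param dendrogram An `ssr_dendrogram` (see [upgma()]).
#' @return `cophenetic_matrix()`: symmetric matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "hclust"))
  as.matrix(stats::cophenetic(dendrogram))
}

#' @rdname cophenetic_matrix
#' @param original Square matrix (or `dist`) of the distances that were
#'   clustered.
#' @param coph Cophenetic matrix on the same leaves (any ordering; matched
#'   by dimnames).
#' @return `cophenetic_correlation()`: Pearson r in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(original, coph) {
  if (inherits(original, "dist")) original <- as.matrix(original)
  if (inherits(coph, "dist")) coph <- as.matrix(coph)
  stopifnot(identical(dim(original), dim(coph)))
  if (!is.null(rownames(original)) && !is.null(rownames(coph))) {
    coph <- coph[rownames(original), colnames(original)]
  }
  ut <- upper.tri(original)
  a <- original[ut]
  b <- coph[ut]
  if (sd(a) == 0 || sd(b) == 0) {
    abort("cophenetic correlation undefined: constant distance vector")
  }
  cor(a, b)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; the k remaining subtrees are the
#' clusters. Clusters are labelled A, B, C, ... by the position of their
#' leftmost leaf in the dendrogram layout (left to right), a deterministic
#' stand-in for arbitrary group naming.
#'
#' @param dendrogram An `ssr_dendrogram`.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return A `cluster_assignment` tibble with columns `accession`,
#'   `cluster` (letter labels), carrying `k` as an attribute.
#' @export
cut_k <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) abort(sprintf("k must be in [1, %d]", n))
  raw <- stats::cutree(dendrogram, k = k)
  # leftmost-leaf position of each cluster in the layout
  pos <- match(seq_len(n), dendrogram$order)  # leaf index -> layout position
  first_pos <- tapply(pos, raw, min)
  ranked <- rank(first_pos)
  labels <- alpha_labels(k)[ranked[as.character(raw)]]
  out <- tibble(accession = dendrogram$labels, cluster = unname(labels))
  out <- new_tibble(out, class = "cluster_assignment")
  attr(out, "k") <- as.integer(k)
  out
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are node-height differences under the height =
#' merge-distance / 2 convention, so the leaf-to-leaf path length in the
#' exported tree equals the cophenetic distance. The string parses back
#' (e.g. with `ape::read.tree`) to an identical ultrametric tree.
#'
#' @param dendrogram An `ssr_dendrogram`.
#' @return A single Newick string terminated by `";"`.
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' to_newick(upgma(d)) # "((A:1,B:1):3,C:4);"
#' @export
to_newick <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "hclust"))
  merge <- dendrogram$merge
  height <- dendrogram$height / 2
  labels <- dendrogram$labels
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  # returns list(text, smallest leaf label) for deterministic child order
  render <- function(node, parent_height) {
    if (node < 0) {
      lab <- labels[-node]
      return(list(text = paste0(lab, ":", fmt(parent_height)), min = lab))
    }
    kids <- lapply(merge[node, ], render, parent_height = height[node])
    kids <- kids[order(vapply(kids, `[[`, character(1), "min"))]
    list(
      text = paste0("(", paste(vapply(kids, `[[`, character(1), "text"),
                               collapse = ","), "):",
                    fmt(parent_height - height[node])),
      min = kids[[1]]$min
    )
  }
  root <- nrow(merge)
  kids <- lapply(merge[root, ], render, parent_height = height[root])
  kids <- kids[order(vapply(kids, `[[`, character(1), "min"))]
  paste0("(", paste(vapply(kids, `[[`, character(1), "text"), collapse = ","),
         ");")
}
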