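# Rarefaction, Bray-Curtis dissimilarity, and neighbour-joining clustering.

#' Rarefaction curve of taxon richness
#'
#' Repeatedly subsamples the FC1 read labels without replacement at each
#' depth and records the number of distinct taxa observed. At full depth
#' the curve equals the full-sample richness with zero spread.
#'
#' @param labels Character vector with one taxon label per FC1 read.
#' @param depths Increasing integer subsampling depths (default: 20
#'   log-spaced depths from 1 to `length(labels)`).
#' @param replicates Subsampling replicates per depth (default 100).
#' @param seed RNG seed; the curve is reproducible given the seed.
#' @return A `rarefaction_curve` data.frame with columns `depth`,
#'   `mean_richness`, `sd_richness`; attributes `replicates` and `seed`.
#' @export
rarefy <- function(labels, depths = NULL, replicates = 100L, seed = 1L) {
  n <- length(labels)
  if (n < 1L) .fail("no labels to rarefy")
  if (replicates < 1L) .fail("replicates must be >= 1")
  if (is.null(depths))
    depths <- unique(round(exp(seq(log(1), log(n), length.out = 20L))))
  depths <- as.integer(depths)
  if (any(depths < 1L)) .fail("depths must be >= 1")
  if (any(depths > n))
    .fail("depth %d exceeds the number of reads (%d)", max(depths), n)
  if (is.unsorted(depths, strictly = TRUE))
    .fail("depths must be strictly increasing")

  res <- withr::with_seed(seed, {
    vapply(depths, function(d) {
      rich <- vapply(seq_len(replicates), function(r) {
        length(unique(labels[sample.int(n, d)]))
      }, 1L)
      c(mean(rich), stats::sd(rich))
    }, c(0, 0))
  })
  out <- data.frame(depth = depths, mean_richness = res[1L, ],
                    sd_richness = ifelse(is.na(res[2L, ]), 0, res[2L, ]))
  structure(out, class = c("rarefaction_curve", "data.frame"),
            replicates = replicates, seed = seed)
}

#' Bray-Curtis dissimilarity between two count profiles
#'
#' `d = 1 - 2 * sum(min(p_i, q_i)) / (sum(p) + sum(q))`, computed on raw
#' counts (equivalently on relative abundances when totals are equal).
#' Identical profiles give 0; profiles with disjoint support give 1.
#'
#' @param p,q Named non-negative count vectors (taxon -> count); names are
#'   aligned, absent taxa count as 0.
#' @return The dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(a = 80, b = 20), c(a = 50, b = 30, c = 20))  # 0.30
bray_curtis <- function(p, q) {
  if (is.null(names(p)) || is.null(names(q)))
    .fail("profiles must be named vectors (taxon -> count)")
  if (any(p < 0) || any(q < 0)) .fail("counts must be non-negative")
  if (sum(p) + sum(q) <= 0) .fail("both profiles are empty")
  taxa <- union(names(p), names(q))
  pv <- setNames(rep(0, length(taxa)), taxa)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  1 - 2 * sum(pmin(pv, qv)) / (sum(pv) + sum(qv))
}

#' Pairwise Bray-Curtis distance matrix over labeled profiles
#'
#' @param profiles Named list of named count vectors (one per community).
#' @param normalize If `TRUE`, profiles are converted to proportions before
#'   the comparison (useful when sampling depths differ wildly); default
#'   `FALSE`, operating on the counts as given.
#' @return Symmetric matrix of dissimilarities with zero diagonal.
#' @export
bray_curtis_matrix <- function(profiles, normalize = FALSE) {
  if (length(profiles) < 2L) .fail("need at least 2 profiles")
  if (is.null(names(profiles))) .fail("profiles list must be named")
  if (normalize)
    profiles <- lapply(profiles, function(p) p / sum(p))
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- bray_curtis(profiles[[i]], profiles[[j]])
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via `ape::nj`) producing an
#' unrooted tree with branch lengths. Negative branch lengths, which NJ
#' can produce on non-additive input, are clamped to zero with the deficit
#' moved to the sister branch so adjacent path lengths are preserved. On
#' distances that are exactly additive the generating tree is recovered.
#'
#' @param D Symmetric numeric matrix (or `dist`) with labels and zero
#'   diagonal; at least 2 labels.
#' @return An `ape::phylo` tree (serializable with `ape::write.tree`).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) .fail("D must be square")
  if (is.null(rownames(D))) .fail("D must carry labels")
  if (nrow(D) < 2L) .fail("need at least 2 labels")
  if (max(abs(D - t(D))) > 1e-8) .fail("distance matrix is not symmetric")
  if (max(abs(diag(D))) > 1e-12) .fail("distance matrix diagonal must be 0")
  if (nrow(D) == 2L) {
    d <- D[1L, 2L]
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(D)[1L], d / 2,
                   rownames(D)[2L], d / 2)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(stats::as.dist(D))
  clamp_negative_edges(tree)
}

# Set negative branch lengths to zero, moving each deficit onto the sister
# branch so the distance between the flanking nodes is preserved.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sib)) {
      s <- sib[1L]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
      if (tree$edge.length[s] < 0) tree$edge.length[s] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
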