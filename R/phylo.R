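# p-distances, neighbor-joining and haplotype counting over clone
# alignments: the quantitative summaries of intragenomic variation.

as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "clone_alignment")) return(alignment$matrix)
  if (is.matrix(alignment)) return(alignment)
  if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1) stop("sequences must have equal length")
    mat <- do.call(rbind, strsplit(alignment, ""))
    rownames(mat) <- names(alignment) %||%
      paste0("seq", seq_along(alignment))
    return(mat)
  }
  stop("cannot interpret alignment input")
}

#' Pairwise p-distance matrix over an alignment
#'
#' p-distance = proportion of differing sites between two aligned
#' sequences. Under `pairwise_deletion` a column counts for a pair when
#' neither sequence is gapped there; under `complete_deletion` columns with
#' a gap in any sequence are removed first.
#'
#' @param alignment A `clone_alignment`, a character matrix (rows =
#'   sequences, gaps `"-"`), or a character vector of equal-length strings.
#' @param gap_mode `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @return Symmetric numeric matrix with zero diagonal; `NA` (with a
#'   warning) for pairs with no comparable sites.
#' @export
p_distance_matrix <- function(alignment,
                              gap_mode = c("pairwise_deletion",
                                           "complete_deletion")) {
  gap_mode <- match.arg(gap_mode)
  mat <- as_alignment_matrix(alignment)
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  if (gap_mode == "complete_deletion") {
    keep <- colSums(mat == "-") == 0
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  labels <- rownames(mat) %||% paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  gap <- mat == "-"
  any_na <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0) {
        D[i, j] <- D[j, i] <- NA_real_
        any_na <- TRUE
      } else {
        d <- sum(mat[i, ok] != mat[j, ok]) / nc
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  if (any_na) warning("some pairs had zero comparable sites; entries are NA")
  D
}

#' Maximum and mean pairwise p-distance
#'
#' @param D Symmetric distance matrix (as from [p_distance_matrix()]).
#' @return Named numeric vector `c(max = , mean = )` over the strict upper
#'   triangle, ignoring missing entries.
#' @export
distance_summary <- function(D) {
  if (!is.matrix(D) || nrow(D) < 2) stop("need a matrix over >= 2 sequences")
  up <- D[upper.tri(D)]
  c(max = max(up, na.rm = TRUE), mean = mean(up, na.rm = TRUE))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the smallest pair of current node indices.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sibling branch, so path lengths through the joined pair are
#' preserved. The result is unrooted (final trifurcation).
#'
#' @param D Complete symmetric distance matrix over >= 3 taxa.
#' @return An object of class `phylo` (ape).
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || any(is.na(D))) stop("need a complete distance matrix")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  sub <- labels  # subtree newick string per active node
  Dm <- D

  fmt <- function(x) formatC(x, digits = 10, format = "g")
  while (length(sub) > 3) {
    r <- length(sub)
    rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j)
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- 0.5 * Dm[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- Dm[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(vi), sub[j], fmt(vj))
    dk <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    Dm2 <- Dm[keep, keep, drop = FALSE]
    Dm2 <- rbind(cbind(Dm2, dk[keep]), c(dk[keep], 0))
    Dm <- Dm2
    sub <- c(sub[keep], new_sub)
  }
  # final three-point join
  va <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  vb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  vc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(va), sub[2], fmt(vb),
                 sub[3], fmt(vc))
  ape::read.tree(text = nwk)
}

#' Count distinct haplotypes in a clone alignment
#'
#' Clones identical over the (unmasked) alignment columns collapse to one
#' haplotype.
#'
#' @param alignment A `clone_alignment` or character matrix.
#' @return List with `n` (haplotype count) and `membership` (named list of
#'   clone ids per haplotype).
#' @export
count_haplotypes <- function(alignment) {
  mat <- as_alignment_matrix(alignment)
  if (inherits(alignment, "clone_alignment") && any(alignment$masked)) {
    mat <- mat[, !alignment$masked, drop = FALSE]
  }
  if (!nrow(mat)) stop("empty alignment")
  keys <- apply(mat, 1, paste, collapse = "")
  groups <- split(rownames(mat) %||% seq_len(nrow(mat)), keys)
  names(groups) <- paste0("hap", seq_along(groups))
  list(n = length(groups), membership = groups)
}
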