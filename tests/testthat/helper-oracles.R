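# Shared fixtures and independent oracles used across the test files.

# small reference unit (230 bp) for fast end-to-end fixtures
tiny_unit <- function(seed = 1L) {
  make_reference_unit(c(SSU18S = 60, ITS1 = 40, R5_8S = 30, ITS2 = 40,
                        LSU28S = 60), gc = 0.5, seed = seed)
}

# mid-size unit used by the copy-number tests (1 kb)
cn_unit <- function(seed = 9L) {
  make_reference_unit(c(SSU18S = 300, ITS1 = 150, R5_8S = 100, ITS2 = 150,
                        LSU28S = 300), gc = 0.5, seed = seed)
}

# single-haplotype (homogeneous) set with a given copy count
homogeneous_hapset <- function(unit, copies = 8L, seed = 2L) {
  m <- heterogeneity_model("accumulated_mutation", n_haplotypes = 1,
                           region_rates = c(ITS = 0, SSU18S = 0, LSU28S = 0),
                           indel_rate = 0)
  evolve_haplotypes(unit, m, seed = seed,
                    copy_counts = stats::setNames(as.integer(copies), "h1"))
}

DNA_BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# --- brute-force p-distance oracle (column scan, no vectorized tricks) ----
brute_p_distance <- function(mat, gap_mode = "pairwise_deletion") {
  if (gap_mode == "complete_deletion") {
    keep <- apply(mat, 2, function(col) all(col != "-"))
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- 0L; comp <- 0L
      for (cc in seq_len(ncol(mat))) {
        a <- mat[i, cc]; b <- mat[j, cc]
        if (a == "-" || b == "-") next
        comp <- comp + 1L
        if (a != b) diff <- diff + 1L
      }
      D[i, j] <- if (comp == 0) NA_real_ else diff / comp
    }
  }
  D
}

# --- exhaustive affine-gap alignment oracle (memoized recursion) ----------
# states: 0 = none/diagonal, 1 = gap in a (consuming b), 2 = gap in b
brute_affine_global <- function(a, b, match, mismatch, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0L))
    }
    if (j <= m) {  # gap in a, consumes b
      cost <- gap_extend + if (state == 1L) 0 else gap_open
      best <- max(best, cost + rec(i, j + 1, 1L))
    }
    if (i <= n) {  # gap in b, consumes a
      cost <- gap_extend + if (state == 2L) 0 else gap_open
      best <- max(best, cost + rec(i + 1, j, 2L))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# semiglobal score = best global score of a against any substring of b
brute_affine_semiglobal <- function(a, b, match, mismatch, gap_open,
                                    gap_extend) {
  m <- nchar(b)
  best <- -Inf
  for (j0 in 1:m) {
    for (j1 in (j0 - 1):m) {  # j1 = j0 - 1 gives the empty substring
      sub <- if (j1 < j0) "" else substr(b, j0, j1)
      sc <- if (nchar(sub) == 0) {
        gap_open + nchar(a) * gap_extend
      } else {
        brute_affine_global(a, sub, match, mismatch, gap_open, gap_extend)
      }
      best <- max(best, sc)
    }
  }
  best
}

# --- additive distance matrices from random trees (NJ oracle) -------------
random_additive_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    tr
  })
}

# score-free alignment of expectations: verdict of a record by key
record_verdict <- function(records, pos, alt) {
  as.character(records$verdict[records$position == pos & records$alt == alt])
}

# score an explicit alignment (gapped char vectors) under affine gaps
rescore_alignment <- function(qa, ra, sc) {
  stopifnot(length(qa) == length(ra))
  score <- 0L
  in_gap <- ""
  for (i in seq_along(qa)) {
    if (qa[i] == "-" || ra[i] == "-") {
      side <- if (qa[i] == "-") "q" else "r"
      if (!identical(in_gap, side)) score <- score + sc$gap_open
      score <- score + sc$gap_extend
      in_gap <- side
    } else {
      score <- score +
        (if (qa[i] == ra[i]) sc$match else sc$mismatch)
      in_gap <- ""
    }
  }
  as.integer(score)
}
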