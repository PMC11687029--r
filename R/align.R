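# Reference-anchored alignment and pileup construction: the internal
# analog of a read mapper plus samtools-style pileup, built on the affine
# Needleman-Wunsch kernel in src/.

#' Global pairwise alignment with affine gaps
#'
#' Optimal global (Needleman-Wunsch) alignment of a query against a
#' reference under affine gap scoring (a gap of length L costs
#' `gap_open + L * gap_extend`). Traceback ties are broken deterministically
#' preferring match/mismatch over a gap in the query over a gap in the
#' reference.
#'
#' @param query,ref Nucleotide strings (non-empty).
#' @param scoring List with integer `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (penalties negative).
#' @return An object of class `pairwise_alignment`: `query_aln`, `ref_aln`
#'   (gapped strings of equal length) and `score`.
#' @export
align_to_reference <- function(query, ref, scoring = default_scoring()) {
  if (!nzchar(query) || !nzchar(ref)) stop("sequences must be non-empty")
  r <- nw_align_cpp(query, ref, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend, FALSE)
  structure(list(query_aln = r$a_aln, ref_aln = r$b_aln, score = r$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment: score", x$score, "| length",
      nchar(x$query_aln), "\n")
  invisible(x)
}

#' Build a strand-aware pileup from reads
#'
#' Maps every read to the reference with a seed-and-extend banded affine
#' aligner (both orientations tried), drops reads whose best alignment
#' falls below the identity floor, and accumulates per-position counts of
#' A/C/G/T/deletion by strand plus insertion events anchored to the
#' preceding reference position.
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param ref An `rdna_unit`, or a reference string. When `region` is given
#'   and `ref` is a unit, the pileup is built against that region and
#'   positions are reported in unit coordinates.
#' @param scoring Alignment scoring list.
#' @param region Optional region name to restrict the reference.
#' @param k Seed k-mer size.
#' @param band Alignment band half-width around the seeded diagonal (bases);
#'   must exceed the largest indel expected in a read.
#' @param identity_floor Minimum alignment identity for a read to count.
#' @param end_trim Aligned bases excluded from the counts at each read end.
#'   Reads ending one base past a deletion (or starting one base inside
#'   one) have a score-optimal gapless alignment whose terminal base shows
#'   a spurious substitution; trimming read ends suppresses this recurrent
#'   indel edge artifact, the pileup-level analog of local realignment.
#' @return An object of class `pileup`: count matrices `fwd`/`rev`
#'   (rows A, C, G, T, del), `depth` per position, an `insertions`
#'   data.frame (`pos`, `seq`, `strand`), the position offset, and mapping
#'   tallies.
#' @export
build_pileup <- function(reads, ref, scoring = default_scoring(),
                         region = NULL, k = 13L, band = 48L,
                         identity_floor = 0.9, end_trim = 2L) {
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  offset <- 0L
  if (inherits(ref, "rdna_unit")) {
    if (!is.null(region)) {
      b <- region_bounds(ref, region)
      offset <- b[1] - 1L
      ref_seq <- substr(ref$sequence, b[1], b[2])
    } else {
      ref_seq <- ref$sequence
    }
  } else {
    ref_seq <- ref
  }
  if (!length(seqs)) {
    L <- nchar(ref_seq)
    z <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "del"), NULL))
    return(structure(list(ref_seq = ref_seq, offset = offset, fwd = z,
                          rev = z, depth = integer(L),
                          insertions = data.frame(pos = integer(),
                                                  seq = character(),
                                                  strand = character()),
                          n_reads = 0L, n_mapped = 0L, n_unmapped = 0L),
                     class = "pileup"))
  }
  res <- pileup_from_reads_cpp(seqs, ref_seq, k, band, scoring$match,
                               scoring$mismatch, scoring$gap_open,
                               scoring$gap_extend, identity_floor,
                               TRUE, TRUE, as.integer(end_trim))
  fwd <- res$fwd; rev <- res$rev
  rownames(fwd) <- rownames(rev) <- c("A", "C", "G", "T", "del")
  depth <- as.integer(colSums(fwd) + colSums(rev))
  ins <- data.frame(pos = res$ins_pos + offset,
                    seq = res$ins_seq,
                    strand = ifelse(res$ins_fwd == 1, "+", "-"),
                    stringsAsFactors = FALSE)
  structure(list(ref_seq = ref_seq, offset = offset, fwd = fwd, rev = rev,
                 depth = depth, insertions = ins,
                 n_reads = length(seqs), n_mapped = sum(res$mapped),
                 n_unmapped = sum(!res$mapped)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup over %d bp: %d/%d reads mapped, mean depth %.0f\n",
              length(x$depth), x$n_mapped, x$n_reads, mean(x$depth)))
  invisible(x)
}
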