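# Site-wise variant calling from pileups with hard filters on depth,
# quality, quality-by-depth and Fisher strand bias, plus the clone-column
# caller for Sanger clone libraries.

#' Hard-filter thresholds for variant calls
#'
#' Defaults follow common GATK-style hard filtering: calls failing
#' `DP < dp`, `QD < qd`, `QUAL < qual` or `FS > fs` are flagged. The depth
#' threshold is `dp` when supplied; otherwise
#' `max(dp_floor, 0.10 * mean depth of called sites)` — ten percent of the
#' average read depth, with 200 reads as the reference floor for data in
#' the ~2000x depth regime.
#'
#' @param dp_floor Depth floor in reads.
#' @param qd Minimum quality-by-depth.
#' @param qual Minimum phred-scaled call quality.
#' @param fs Maximum phred-scaled Fisher strand bias.
#' @param dp Optional fixed depth threshold overriding the 10%-of-mean rule.
#' @return A list of thresholds.
#' @export
variant_filters <- function(dp_floor = 200, qd = 2.0, qual = 30.0,
                            fs = 200.0, dp = NULL) {
  list(dp_floor = dp_floor, qd = qd, qual = qual, fs = fs, dp = dp)
}

# left-align a deletion of ref position `pos` (local coordinates)
left_align_del <- function(pos, ref_chars) {
  pos <- as.integer(pos)
  while (pos > 1L && ref_chars[pos - 1L] == ref_chars[pos]) pos <- pos - 1L
  pos
}

# left-align an insertion anchored after `pos` (local coordinates)
left_align_ins <- function(pos, seq, ref_chars) {
  pos <- as.integer(pos)
  n <- nchar(seq)
  while (pos > 1L && substr(seq, n, n) == ref_chars[pos]) {
    seq <- paste0(substr(seq, n, n), substr(seq, 1, n - 1))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

phred_fisher <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  m <- matrix(c(ref_fwd, ref_rev, alt_fwd, alt_rev), 2)
  p <- stats::fisher.test(m)$p.value
  -10 * log10(max(p, 1e-300))
}

new_variant_table <- function(calls, method, run_id, mean_depth,
                              depth_by_pos = NULL, offset = 0L,
                              dp_threshold = NA_real_, n_clones = NA_integer_) {
  if (is.null(calls) || !nrow(calls)) {
    calls <- data.frame(position = integer(), ref = character(),
                        alt = character(), depth = integer(),
                        alt_count = integer(), frequency = numeric(),
                        qual = numeric(), qd = numeric(), fs = numeric(),
                        method = character(), run_id = integer(),
                        filter_status = character(),
                        stringsAsFactors = FALSE)
  }
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("variant_table", "data.frame"),
            method = method, run_id = run_id, mean_depth = mean_depth,
            depth_by_pos = depth_by_pos, offset = offset,
            dp_threshold = dp_threshold, n_clones = n_clones)
}

#' Call nucleotide variants from a pileup
#'
#' For every site and non-reference allele (base, deletion or insertion)
#' with at least `min_alt_count` supporting reads, emits one call with:
#' `QUAL = -10 log10 P[X >= alt_count]` where `X ~ Binomial(depth,
#' base_error)` (the probability of seeing this many non-reference reads
#' from sequencing error alone), `QD = QUAL / depth`, and `FS` the
#' phred-scaled two-sided Fisher exact test of (ref, alt) x (+, -) strand
#' counts. Calls are then flagged against the hard-filter thresholds; the
#' depth threshold follows the 10%-of-average-depth rule (see
#' [variant_filters()]). Indel alleles are left-aligned in homopolymers.
#'
#' @param pileup A `pileup`.
#' @param base_error Assumed per-base error probability of the platform.
#' @param min_alt_count Minimum supporting reads to emit a call.
#' @param thresholds A [variant_filters()] list.
#' @param method Label: `"amplicon"` or `"wgs"`.
#' @param run_id Run identifier (amplicon runs), or `NA`.
#' @return A `variant_table` (data.frame) with one row per
#'   (position, alt allele); positions are 1-based on the reference unit.
#'   Attributes carry the per-position depth vector, the mean depth over
#'   called sites and the applied depth threshold.
#' @export
call_variants <- function(pileup, base_error = 0.001, min_alt_count = 5L,
                          thresholds = variant_filters(),
                          method = "amplicon", run_id = NA_integer_) {
  stopifnot(inherits(pileup, "pileup"))
  ref_chars <- strsplit(pileup$ref_seq, "")[[1]]
  L <- length(ref_chars)
  cnt <- pileup$fwd + pileup$rev
  depth <- pileup$depth

  rows <- list()
  for (allele in c("A", "C", "G", "T", "del")) {
    hit <- which(cnt[allele, ] >= min_alt_count &
                   (allele == "del" | ref_chars != allele) & depth > 0)
    for (p in hit) {
      pos <- p
      al <- allele
      if (allele == "del") {
        pos <- left_align_del(p, ref_chars)
        al <- "-"
      }
      rows[[length(rows) + 1]] <- data.frame(
        local_pos = pos, count_pos = p, ref = ref_chars[pos], alt = al,
        alt_fwd = pileup$fwd[allele, p], alt_rev = pileup$rev[allele, p],
        stringsAsFactors = FALSE)
    }
  }
  # insertions: normalize anchors, then group by (pos, sequence)
  ins <- pileup$insertions
  if (nrow(ins)) {
    ins$pos <- ins$pos - pileup$offset  # local coordinates
    norm <- lapply(seq_len(nrow(ins)), function(i) {
      left_align_ins(ins$pos[i], ins$seq[i], ref_chars)
    })
    ins$pos <- vapply(norm, `[[`, 1L, "pos")
    ins$seq <- vapply(norm, `[[`, "", "seq")
    key <- paste(ins$pos, ins$seq)
    for (g in split(ins, key)) {
      if (nrow(g) < min_alt_count) next
      rows[[length(rows) + 1]] <- data.frame(
        local_pos = g$pos[1], count_pos = g$pos[1], ref = ref_chars[g$pos[1]],
        alt = paste0("+", g$seq[1]),
        alt_fwd = sum(g$strand == "+"), alt_rev = sum(g$strand == "-"),
        stringsAsFactors = FALSE)
    }
  }

  if (!length(rows)) {
    return(new_variant_table(NULL, method, run_id, mean_depth = NA_real_,
                             depth_by_pos = depth, offset = pileup$offset))
  }
  calls <- do.call(rbind, rows)

  # merge alleles that normalized onto the same (pos, alt)
  key <- paste(calls$local_pos, calls$alt)
  if (anyDuplicated(key)) {
    calls <- do.call(rbind, lapply(split(calls, key), function(g) {
      g$alt_fwd[1] <- sum(g$alt_fwd); g$alt_rev[1] <- sum(g$alt_rev)
      g[1, , drop = FALSE]
    }))
  }

  calls$alt_count <- calls$alt_fwd + calls$alt_rev
  calls$depth <- depth[calls$local_pos]
  calls$frequency <- calls$alt_count / calls$depth
  calls$qual <- -10 / log(10) *
    pbinom(calls$alt_count - 1L, calls$depth, base_error,
           lower.tail = FALSE, log.p = TRUE)
  calls$qd <- calls$qual / calls$depth
  is_ref <- match(calls$ref, c("A", "C", "G", "T"))
  calls$fs <- vapply(seq_len(nrow(calls)), function(i) {
    p <- calls$count_pos[i]
    phred_fisher(pileup$fwd[is_ref[i], p], pileup$rev[is_ref[i], p],
                 calls$alt_fwd[i], calls$alt_rev[i])
  }, 0)

  mean_depth <- mean(calls$depth)
  dp_thr <- thresholds$dp %||% max(thresholds$dp_floor, 0.10 * mean_depth)
  calls$filter_status <- ifelse(calls$depth < dp_thr, "fail_depth",
                         ifelse(calls$qd < thresholds$qd, "fail_qd",
                         ifelse(calls$qual < thresholds$qual, "fail_qual",
                         ifelse(calls$fs > thresholds$fs, "fail_fs",
                                "pass"))))

  calls$position <- calls$local_pos + pileup$offset
  calls$method <- method
  calls$run_id <- run_id
  keep <- c("position", "ref", "alt", "depth", "alt_count", "frequency",
            "qual", "qd", "fs", "method", "run_id", "filter_status")
  new_variant_table(calls[, keep], method, run_id, mean_depth,
                    depth_by_pos = depth, offset = pileup$offset,
                    dp_threshold = dp_thr)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table (%s): %d calls, %d pass\n",
              attr(x, "method") %||% "?", nrow(x),
              sum(x$filter_status == "pass")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}

#' Detect variants in a Sanger clone library
#'
#' Aligns each clone globally to the reference region, builds a
#' reference-anchored clone alignment (insertion columns expanded), and
#' emits one call per alignment column state that differs from the
#' reference. Frequency is the number of clones showing the allele divided
#' by the total number of clones. Clone calls carry no read-level quality
#' annotations (`qual`/`qd`/`fs` are `NA`) and are never hard-filtered.
#'
#' @param clones A `clone_set` (>= 2 clones).
#' @param unit The `rdna_unit` the clones derive from.
#' @param scoring Alignment scoring list.
#' @return A list with `table` (a `variant_table`, `method = "cloning"`)
#'   and `alignment` (a `clone_alignment`: character matrix of clones x
#'   columns, per-column unit positions, and insertion-column flags).
#' @export
detect_clone_variants <- function(clones, unit, scoring = default_scoring()) {
  stopifnot(inherits(clones, "clone_set"), inherits(unit, "rdna_unit"))
  if (length(clones$clones) < 2) stop("need at least 2 clones")
  b <- region_bounds(unit, clones$region)
  offset <- b[1] - 1L
  ref_seq <- substr(unit$sequence, b[1], b[2])
  ref_chars <- strsplit(ref_seq, "")[[1]]
  L <- length(ref_chars)
  n <- length(clones$clones)

  states <- matrix("-", n, L,
                   dimnames = list(names(clones$clones), NULL))
  ins_events <- list()  # per event: clone index, anchor (local), seq
  for (ci in seq_len(n)) {
    a <- align_to_reference(clones$clones[[ci]], ref_seq, scoring)
    qa <- strsplit(a$query_aln, "")[[1]]
    ra <- strsplit(a$ref_aln, "")[[1]]
    rp <- 0L
    i <- 1L
    while (i <= length(qa)) {
      if (ra[i] == "-") {
        s <- ""
        while (i <= length(qa) && ra[i] == "-") {
          s <- paste0(s, qa[i]); i <- i + 1L
        }
        if (rp > 0L && i <= length(qa)) {
          nrm <- left_align_ins(rp, s, ref_chars)
          ins_events[[length(ins_events) + 1]] <-
            list(clone = ci, pos = nrm$pos, seq = nrm$seq)
        }
        next
      }
      rp <- rp + 1L
      states[ci, rp] <- if (qa[i] == "-") "-" else qa[i]
      i <- i + 1L
    }
  }

  # expand insertion columns after their anchors
  ins_cols <- list()
  if (length(ins_events)) {
    anchors <- vapply(ins_events, `[[`, 1L, "pos")
    for (p in sort(unique(anchors))) {
      ev <- ins_events[anchors == p]
      width <- max(vapply(ev, function(e) nchar(e$seq), 1L))
      block <- matrix("-", n, width)
      for (e in ev) {
        chars <- strsplit(e$seq, "")[[1]]
        block[e$clone, seq_along(chars)] <- chars
      }
      ins_cols[[as.character(p)]] <- block
    }
  }
  if (length(ins_cols)) {
    blocks <- list()
    col_pos <- integer(0)
    col_ins <- logical(0)
    prev <- 0L
    for (p in sort(as.integer(names(ins_cols)))) {
      blocks[[length(blocks) + 1]] <- states[, (prev + 1):p, drop = FALSE]
      col_pos <- c(col_pos, (prev + 1):p)
      col_ins <- c(col_ins, rep(FALSE, p - prev))
      blk <- ins_cols[[as.character(p)]]
      blocks[[length(blocks) + 1]] <- blk
      col_pos <- c(col_pos, rep(p, ncol(blk)))
      col_ins <- c(col_ins, rep(TRUE, ncol(blk)))
      prev <- p
    }
    if (prev < L) {
      blocks[[length(blocks) + 1]] <- states[, (prev + 1):L, drop = FALSE]
      col_pos <- c(col_pos, (prev + 1):L)
      col_ins <- c(col_ins, rep(FALSE, L - prev))
    }
    mat <- do.call(cbind, blocks)
  } else {
    mat <- states
    col_pos <- seq_len(L)
    col_ins <- rep(FALSE, L)
  }
  alignment <- structure(list(matrix = mat,
                              ref_pos = col_pos + offset,
                              is_insertion = col_ins,
                              region = clones$region, offset = offset,
                              masked = logical(ncol(mat))),
                         class = "clone_alignment")

  # variant table from reference columns
  rows <- list()
  for (p in seq_len(L)) {
    st <- states[, p]
    for (al in unique(st[st != ref_chars[p]])) {
      cnt <- sum(st == al)
      npos <- if (al == "-") left_align_del(p, ref_chars) else p
      rows[[length(rows) + 1]] <- data.frame(
        position = npos + offset, ref = ref_chars[npos], alt = al,
        depth = n, alt_count = cnt, frequency = cnt / n,
        qual = NA_real_, qd = NA_real_, fs = NA_real_,
        method = "cloning", run_id = NA_integer_, filter_status = "pass",
        stringsAsFactors = FALSE)
    }
  }
  if (length(ins_events)) {
    keys <- vapply(ins_events, function(e) paste(e$pos, e$seq), "")
    for (kk in unique(keys)) {
      ev <- ins_events[keys == kk]
      cl <- unique(vapply(ev, `[[`, 1L, "clone"))
      p <- ev[[1]]$pos
      rows[[length(rows) + 1]] <- data.frame(
        position = p + offset, ref = ref_chars[p],
        alt = paste0("+", ev[[1]]$seq),
        depth = n, alt_count = length(cl), frequency = length(cl) / n,
        qual = NA_real_, qd = NA_real_, fs = NA_real_,
        method = "cloning", run_id = NA_integer_, filter_status = "pass",
        stringsAsFactors = FALSE)
    }
  }
  # adjacent deleted columns left-align onto one (position, "-") key; keep
  # the best-supported row rather than double-counting the same clones
  if (length(rows)) {
    calls <- do.call(rbind, rows)
    key <- paste(calls$position, calls$alt)
    if (anyDuplicated(key)) {
      calls <- do.call(rbind, lapply(split(calls, key), function(g) {
        g[which.max(g$alt_count), , drop = FALSE]
      }))
    }
    rows <- list(calls)
  }
  tbl <- new_variant_table(if (length(rows)) do.call(rbind, rows) else NULL,
                           "cloning", NA_integer_, mean_depth = n,
                           depth_by_pos = rep(n, L), offset = offset,
                           n_clones = n)
  list(table = tbl, alignment = alignment)
}
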