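# Cross-method reconciliation of variant evidence: run-consistency for
# multi-run amplicon data, the consensus/validity rules (singleton-clone
# artefact exclusion, the two-method rescue of filter-failed calls), the
# conflict taxonomy, and artefact correction of the clone alignment.

table_positions <- function(tbl) tbl$position
table_covered <- function(tbl, pos) {
  d <- attr(tbl, "depth_by_pos")
  off <- attr(tbl, "offset") %||% 0L
  local <- pos - off
  ok <- local >= 1 & local <= length(d)
  out <- logical(length(pos))
  out[ok] <- d[local[ok]] > 0
  out
}
table_depth_at <- function(tbl, pos) {
  d <- attr(tbl, "depth_by_pos")
  off <- attr(tbl, "offset") %||% 0L
  local <- pos - off
  out <- numeric(length(pos))
  ok <- local >= 1 & local <= length(d)
  out[ok] <- d[local[ok]]
  out
}
# reference-allele read support at positions: depth minus all alt counts
table_ref_support <- function(tbl, pos) {
  dep <- table_depth_at(tbl, pos)
  alt <- vapply(pos, function(p) {
    sum(tbl$alt_count[tbl$position == p])
  }, 0)
  pmax(dep - alt, 0)
}

#' Evaluate variant-call consistency across independent amplicon runs
#'
#' Collects every (position, allele) called in any run and records per-run
#' presence, average frequency over the runs where the site was covered
#' (frequency 0 when covered but not called), and whether detection was
#' consistent across all covering runs. With a single run consistency is
#' trivially satisfied.
#'
#' @param tables List of `variant_table` objects, one per amplicon run.
#' @return An object of class `run_consistency` with a `sites` data.frame
#'   (`position`, `ref`, `alt`, `n_runs_present`, `n_runs_covered`,
#'   `mean_freq`, `consistent`, `any_pass`) and the number of runs.
#' @export
compute_run_consistency <- function(tables) {
  if (inherits(tables, "variant_table")) tables <- list(tables)
  if (!length(tables)) stop("need at least one run")
  n_runs <- length(tables)
  all_calls <- do.call(rbind, lapply(tables, as.data.frame))
  keys <- unique(all_calls[, c("position", "ref", "alt")])
  keys <- keys[order(keys$position, keys$alt), , drop = FALSE]

  pres <- matrix(FALSE, nrow(keys), n_runs)
  freq <- matrix(NA_real_, nrow(keys), n_runs)
  pass <- matrix(FALSE, nrow(keys), n_runs)
  cov <- matrix(FALSE, nrow(keys), n_runs)
  for (r in seq_len(n_runs)) {
    tbl <- tables[[r]]
    cov[, r] <- table_covered(tbl, keys$position)
    m <- match(paste(keys$position, keys$alt),
               paste(tbl$position, tbl$alt))
    hit <- !is.na(m)
    pres[hit, r] <- TRUE
    freq[hit, r] <- tbl$frequency[m[hit]]
    pass[hit, r] <- tbl$filter_status[m[hit]] == "pass"
    freq[!hit & cov[, r], r] <- 0
  }
  sites <- data.frame(
    position = keys$position, ref = keys$ref, alt = keys$alt,
    n_runs_present = rowSums(pres),
    n_runs_covered = rowSums(cov),
    mean_freq = rowMeans(freq, na.rm = TRUE),
    any_pass = rowSums(pass) > 0,
    stringsAsFactors = FALSE)
  sites$consistent <- sites$n_runs_present == pmax(sites$n_runs_covered, 1L)
  rownames(sites) <- NULL
  structure(list(sites = sites, n_runs = n_runs, tables = tables),
            class = "run_consistency")
}

#' @export
print.run_consistency <- function(x, ...) {
  cat(sprintf("run_consistency: %d sites over %d runs (%d inconsistent)\n",
              nrow(x$sites), x$n_runs, sum(!x$sites$consistent)))
  invisible(x)
}

#' Merge variant evidence across detection methods
#'
#' Builds one record per (position, allele) over the union of all methods'
#' calls, with per-method presence and frequency. An allele is a provisional
#' consensus variant when it is detected by at least two methods —
#' "present" means pre-filter: at least one clone, called in at least one
#' amplicon run at any filter status, or called in WGS at any filter status
#' (this is what lets a hard-filter-failed call be rescued by independent
#' methods) — or, when only a single method has data, when it passes that
#' method's own rules (hard filters for read methods; at least two
#' supporting clones for cloning). Singleton-clone alleles with no
#' read-based support are never consensus.
#'
#' @param cloning A `variant_table` from [detect_clone_variants()], or NULL.
#' @param amplicon A `run_consistency` object (or list of per-run
#'   `variant_table`s), or NULL.
#' @param wgs A `variant_table` from WGS calling, or NULL.
#' @return An object of class `consensus_records`: a data.frame with
#'   per-method evidence columns and a logical `consensus` column.
#'   Verdicts are assigned by [classify_conflicts()].
#' @export
merge_methods <- function(cloning = NULL, amplicon = NULL, wgs = NULL) {
  if (!is.null(amplicon) && !inherits(amplicon, "run_consistency")) {
    amplicon <- compute_run_consistency(amplicon)
  }
  if (is.null(cloning) && is.null(amplicon) && is.null(wgs)) {
    stop("at least one method's table must be given")
  }
  keys <- data.frame(position = integer(), ref = character(),
                     alt = character(), stringsAsFactors = FALSE)
  add_keys <- function(keys, df) {
    unique(rbind(keys, df[, c("position", "ref", "alt")]))
  }
  if (!is.null(cloning)) keys <- add_keys(keys, as.data.frame(cloning))
  if (!is.null(amplicon)) keys <- add_keys(keys, amplicon$sites)
  if (!is.null(wgs)) keys <- add_keys(keys, as.data.frame(wgs))
  keys <- keys[order(keys$position, keys$alt), , drop = FALSE]
  n <- nrow(keys)
  k <- paste(keys$position, keys$alt)

  rec <- keys
  rec$clone_support <- if (is.null(cloning)) NA_integer_ else 0L
  rec$clone_freq <- if (is.null(cloning)) NA_real_ else 0
  if (!is.null(cloning)) {
    m <- match(k, paste(cloning$position, cloning$alt))
    hit <- !is.na(m)
    rec$clone_support[hit] <- cloning$alt_count[m[hit]]
    rec$clone_freq[hit] <- cloning$frequency[m[hit]]
    rec$n_clones <- attr(cloning, "n_clones")
  } else rec$n_clones <- NA_integer_

  if (!is.null(amplicon)) {
    s <- amplicon$sites
    m <- match(k, paste(s$position, s$alt))
    hit <- !is.na(m)
    rec$amp_present <- hit
    rec$amp_mean_freq <- ifelse(hit, s$mean_freq[m], 0)
    rec$amp_runs_present <- ifelse(hit, s$n_runs_present[m], 0L)
    rec$amp_runs_covered <- ifelse(hit, s$n_runs_covered[m], NA_integer_)
    rec$amp_consistent <- ifelse(hit, s$consistent[m], NA)
    rec$amp_any_pass <- ifelse(hit, s$any_pass[m], FALSE)
    rec$amp_n_runs <- amplicon$n_runs
    covs <- vapply(amplicon$tables, table_covered, logical(n), rec$position)
    covs <- matrix(covs, nrow = n)
    rec$amp_covered <- rowSums(covs) > 0
    rec$amp_runs_covered[!hit] <- rowSums(covs)[!hit]
    refs <- vapply(amplicon$tables, table_ref_support, numeric(n),
                   rec$position)
    rec$amp_ref_support <- rowSums(matrix(refs, nrow = n))
  } else {
    rec$amp_present <- NA
    rec$amp_mean_freq <- NA_real_
    rec$amp_runs_present <- NA_integer_
    rec$amp_runs_covered <- NA_integer_
    rec$amp_consistent <- NA
    rec$amp_any_pass <- NA
    rec$amp_n_runs <- NA_integer_
    rec$amp_covered <- NA
    rec$amp_ref_support <- NA_real_
  }

  if (!is.null(wgs)) {
    m <- match(k, paste(wgs$position, wgs$alt))
    hit <- !is.na(m)
    rec$wgs_present <- hit
    rec$wgs_freq <- ifelse(hit, wgs$frequency[m], 0)
    rec$wgs_filter <- ifelse(hit, wgs$filter_status[m], NA_character_)
    rec$wgs_pass <- ifelse(hit, wgs$filter_status[m] == "pass", FALSE)
    rec$wgs_covered <- table_covered(wgs, rec$position)
    rec$wgs_ref_support <- table_ref_support(wgs, rec$position)
  } else {
    rec$wgs_present <- NA
    rec$wgs_freq <- NA_real_
    rec$wgs_filter <- NA_character_
    rec$wgs_pass <- NA
    rec$wgs_covered <- NA
    rec$wgs_ref_support <- NA_real_
  }

  avail <- c(cloning = !is.null(cloning), amplicon = !is.null(amplicon),
             wgs = !is.null(wgs))
  present <- cbind(
    cloning = if (avail["cloning"]) rec$clone_support > 0 else FALSE,
    amplicon = if (avail["amplicon"]) rec$amp_present else FALSE,
    wgs = if (avail["wgs"]) rec$wgs_present else FALSE)
  rec$n_methods_present <- rowSums(present)
  rec$n_methods_available <- sum(avail)

  sole_pass <- rep(FALSE, n)
  if (sum(avail) == 1) {
    sole_pass <- switch(names(avail)[avail],
      cloning = rec$clone_support >= 2,
      amplicon = rec$amp_any_pass,
      wgs = rec$wgs_pass)
  }
  rec$consensus <- rec$n_methods_present >= 2 | sole_pass
  rownames(rec) <- NULL
  structure(rec, class = c("consensus_records", "data.frame"),
            methods_available = avail)
}

CONFLICT_VERDICTS <- c("consensus_variant", "cloning_artifact",
                       "amplicon_edge", "clone_undersampling",
                       "amplicon_false_call", "run_inconsistent",
                       "reference_error", "ambiguous", "other")

#' Classify cross-method conflicts
#'
#' Assigns every merged record exactly one verdict with a deterministic
#' precedence: (1) `reference_error` when the reference base has zero read
#' support in every covering read-based method (only the variant base is
#' seen, so the reference sequence itself is wrong); (2)
#' `consensus_variant` per the merge rules; (3) `clone_undersampling` when
#' the available read methods agree on the allele but no sampled clone
#' carries it; (4) for cloning-only alleles, `amplicon_edge` within the
#' edge window of the amplicon 3' end (coverage decays there, so amplicon
#' sequencing can hardly detect the variant), `cloning_artifact` for
#' singleton clones, otherwise `ambiguous`; (5) `run_inconsistent` when
#' amplicon runs disagree and WGS is absent or negative; (6)
#' `amplicon_false_call` when an amplicon-only allele is absent from WGS
#' and clones; (7) `other`.
#'
#' @param records A `consensus_records` object from [merge_methods()].
#' @param amplicon_geometry List with `end` (unit position of the amplicon
#'   3' terminus) and `window` (edge window width in bases, default 50).
#' @return The records with `verdict` and a `conflict` annotation column
#'   (`"none"`, or a note such as `"inadequate_clone_sampling"` for
#'   consensus variants the clone library missed).
#' @export
classify_conflicts <- function(records,
                               amplicon_geometry = list(end = NA, window = 50)) {
  rec <- records
  n <- nrow(rec)
  avail <- attr(rec, "methods_available")
  has_clo <- avail["cloning"]; has_amp <- avail["amplicon"]
  has_wgs <- avail["wgs"]

  clo_pres <- if (has_clo) rec$clone_support > 0 else rep(FALSE, n)
  amp_pres <- if (has_amp) rec$amp_present else rep(FALSE, n)
  wgs_pres <- if (has_wgs) rec$wgs_present else rep(FALSE, n)
  amp_cov <- if (has_amp) rec$amp_covered else rep(FALSE, n)
  wgs_cov <- if (has_wgs) rec$wgs_covered else rep(FALSE, n)

  # (1) inaccurate reference: covered by >= 1 read-based method, and the
  # reference base is unsupported in every covering read-based method
  ref_err <- (amp_cov | wgs_cov) &
    (!amp_cov | rec$amp_ref_support == 0) &
    (!wgs_cov | rec$wgs_ref_support == 0)
  ref_err[is.na(ref_err)] <- FALSE

  # (3) read methods agree, clones lack the allele (only reachable when a
  # single read method is available: two read methods already make consensus)
  read_agree <- (!has_amp | (amp_pres & rec$amp_consistent %in% TRUE)) &
    (!has_wgs | wgs_pres) & (has_amp | has_wgs)
  undersamp <- has_clo & !clo_pres & read_agree & (amp_pres | wgs_pres)

  # (4) cloning-only alleles
  clo_only <- clo_pres & !amp_pres & !wgs_pres
  near_edge <- if (has_amp && !is.na(amplicon_geometry$end)) {
    rec$position >= amplicon_geometry$end - amplicon_geometry$window &
      rec$position <= amplicon_geometry$end
  } else rep(FALSE, n)

  # (5) amplicon run disagreement with no WGS corroboration
  run_inc <- amp_pres & rec$amp_consistent %in% FALSE &
    (!has_wgs | !wgs_pres)

  # (6) amplicon-only allele contradicted by (or lacking) the other methods
  amp_false <- amp_pres & !wgs_pres & !clo_pres &
    (has_wgs & wgs_cov | (!has_wgs & rec$amp_n_runs == 1L))

  verdict <- rep("other", n)
  verdict[amp_false] <- "amplicon_false_call"
  verdict[run_inc] <- "run_inconsistent"
  verdict[clo_only] <- "ambiguous"
  verdict[clo_only & rec$clone_support == 1] <- "cloning_artifact"
  verdict[clo_only & near_edge] <- "amplicon_edge"
  verdict[undersamp] <- "clone_undersampling"
  verdict[rec$consensus] <- "consensus_variant"
  verdict[ref_err] <- "reference_error"
  rec$verdict <- factor(verdict, levels = CONFLICT_VERDICTS)

  conflict <- rep("none", n)
  miss_clone <- rec$verdict == "consensus_variant" & has_clo & !clo_pres
  conflict[miss_clone] <- "inadequate_clone_sampling"
  miss_read <- rec$verdict == "consensus_variant" &
    ((has_amp & !amp_pres & amp_cov) | (has_wgs & !wgs_pres & wgs_cov))
  conflict[miss_read] <- "missed_by_one_read_method"
  rec$conflict <- conflict
  rec
}

#' @export
print.consensus_records <- function(x, ...) {
  cat(sprintf("consensus_records: %d alleles, %d consensus variants\n",
              nrow(x), sum(x$consensus)))
  if ("verdict" %in% names(x)) print(table(x$verdict))
  invisible(x)
}

#' Extract the valid (consensus) variant list
#' @param records Classified `consensus_records`.
#' @return Data.frame of consensus variant alleles.
#' @export
consensus_variants <- function(records) {
  stopifnot("verdict" %in% names(records))
  as.data.frame(records[records$verdict == "consensus_variant", , drop = FALSE])
}

# alleles present in a clone-alignment column, as (position, allele) pairs
column_alleles <- function(alignment, unit, cols) {
  ref_chars <- strsplit(unit$sequence, "")[[1]]
  out <- list()
  for (cc in cols) {
    pos <- alignment$ref_pos[cc]
    st <- alignment$matrix[, cc]
    if (alignment$is_insertion[cc]) {
      # reconstruct full inserted strings per carrier over the anchor block
      blk <- which(alignment$ref_pos == pos & alignment$is_insertion)
      carriers <- which(rowSums(alignment$matrix[, blk, drop = FALSE] != "-") > 0)
      for (ci in carriers) {
        s <- paste(alignment$matrix[ci, blk][alignment$matrix[ci, blk] != "-"],
                   collapse = "")
        out[[length(out) + 1]] <- data.frame(pos = pos,
                                             alt = paste0("+", s),
                                             stringsAsFactors = FALSE)
      }
    } else {
      alts <- unique(st[st != ref_chars[pos]])
      for (al in alts) {
        npos <- if (al == "-") left_align_del(pos, ref_chars) else pos
        out[[length(out) + 1]] <- data.frame(pos = npos, alt = al,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(pos = integer(), alt = character()))
  unique(do.call(rbind, out))
}

#' Correct the clone alignment for cloning artefacts
#'
#' Masks alignment columns whose only variation consists of alleles with
#' verdict `cloning_artifact` — the manual-exclusion step applied to
#' suspected PCR-cloning-sequencing errors before recomputing p-distances.
#' Masking can move pairwise p-distances in either direction: removing a
#' mismatch column lowers the distance of the pair that differed there,
#' but also shrinks the denominator of every other pair.
#'
#' @param alignment A `clone_alignment` from [detect_clone_variants()].
#' @param records Classified `consensus_records`.
#' @param unit The `rdna_unit` (for reference bases during allele lookup).
#' @param gap_mode Gap handling passed to [p_distance_matrix()] for the
#'   before/after summaries.
#' @return A list with `alignment` (masked columns flagged and removed from
#'   the corrected matrix) and `report` (a `correction_report` comparing
#'   raw and corrected variant-site counts and p-distance summaries).
#' @export
correct_clone_alignment <- function(alignment, records, unit,
                                    gap_mode = "pairwise_deletion") {
  stopifnot(inherits(alignment, "clone_alignment"),
            "verdict" %in% names(records))
  mat <- alignment$matrix
  ref_chars <- strsplit(unit$sequence, "")[[1]]
  n_col <- ncol(mat)
  varies <- vapply(seq_len(n_col), function(cc) {
    length(unique(mat[, cc])) > 1 ||
      (alignment$is_insertion[cc] && any(mat[, cc] != "-")) ||
      (!alignment$is_insertion[cc] &&
         any(mat[, cc] != ref_chars[alignment$ref_pos[cc]]))
  }, TRUE)
  rk <- paste(records$position, records$alt)
  masked <- logical(n_col)
  for (cc in which(varies)) {
    al <- column_alleles(alignment, unit, cc)
    if (!nrow(al)) next
    v <- records$verdict[match(paste(al$pos, al$alt), rk)]
    if (!anyNA(v) && all(v == "cloning_artifact")) masked[cc] <- TRUE
  }
  # a variant "site" = a polymorphic reference column or insertion anchor
  count_sites <- function(keep) {
    cols <- which(varies & keep)
    length(unique(paste(alignment$ref_pos[cols],
                        alignment$is_insertion[cols])))
  }
  raw_sites <- count_sites(rep(TRUE, n_col))
  cor_sites <- count_sites(!masked)

  raw_D <- p_distance_matrix(mat, gap_mode = gap_mode)
  cor_mat <- mat[, !masked, drop = FALSE]
  cor_D <- p_distance_matrix(cor_mat, gap_mode = gap_mode)
  raw_s <- distance_summary(raw_D)
  cor_s <- distance_summary(cor_D)

  alignment$masked <- masked
  corrected <- alignment
  corrected$matrix <- cor_mat
  corrected$ref_pos <- alignment$ref_pos[!masked]
  corrected$is_insertion <- alignment$is_insertion[!masked]
  corrected$masked <- logical(sum(!masked))

  report <- structure(list(
    masked_columns = which(masked),
    n_masked = sum(masked),
    raw_variant_sites = raw_sites,
    corrected_variant_sites = cor_sites,
    raw_max_p = unname(raw_s["max"]), raw_mean_p = unname(raw_s["mean"]),
    corrected_max_p = unname(cor_s["max"]),
    corrected_mean_p = unname(cor_s["mean"])),
    class = "correction_report")
  list(alignment = corrected, report = report, raw_alignment = alignment)
}

#' @export
print.correction_report <- function(x, ...) {
  cat("correction_report:\n")
  cat(sprintf("  masked columns: %d\n", x$n_masked))
  cat(sprintf("  variant sites: %d raw -> %d corrected\n",
              x$raw_variant_sites, x$corrected_variant_sites))
  cat(sprintf("  max p-distance: %.4f raw -> %.4f corrected\n",
              x$raw_max_p, x$corrected_max_p))
  cat(sprintf("  mean p-distance: %.4f raw -> %.4f corrected\n",
              x$raw_mean_p, x$corrected_mean_p))
  invisible(x)
}
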