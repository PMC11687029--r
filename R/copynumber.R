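# rDNA copy-number estimation from read-mapping proportions: reads map
# once to unique genomic regions but many times onto the collapsed rDNA
# reference, so the ratio of mapped-read proportions, scaled by the size
# ratio of the two references, estimates the copy number.

#' Read-mapping statistics for copy-number estimation
#'
#' Maps every read independently against the reference rDNA unit and
#' against the genome assembly; a read counts toward a target when its
#' best alignment reaches the identity floor. A read may count toward both
#' targets. The rDNA unit is indexed in doubled (tandem) form so reads
#' spanning the junction between adjacent repeat copies still map
#' end-to-end, matching the tandem context they came from.
#'
#' @param reads A `read_set` (typically WGS) or character vector.
#' @param unit The reference `rdna_unit`.
#' @param assembly Genome assembly sequence (string), e.g.
#'   `genome$assembly`.
#' @param identity_floor Minimum alignment identity to count as mapped.
#' @param scoring Alignment scoring list.
#' @param k,band Mapper seed size and alignment band half-width.
#' @return An object of class `mapping_stats` with fractions
#'   `pct_reads_on_rdna`, `pct_reads_on_assembly`, and sizes `rdna_length`,
#'   `assembly_size`, `n_reads`.
#' @export
mapping_stats_from_reads <- function(reads, unit, assembly,
                                     identity_floor = 0.9,
                                     scoring = default_scoring(),
                                     k = 13L, band = 48L) {
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  if (!length(seqs)) stop("no reads given")
  stopifnot(inherits(unit, "rdna_unit"))
  rdna_ref <- paste0(unit$sequence, unit$sequence)  # tandem context
  on_rdna <- reads_mapped_cpp(seqs, rdna_ref, k, band, scoring$match,
                              scoring$mismatch, scoring$gap_open,
                              scoring$gap_extend, identity_floor, TRUE)
  on_asm <- reads_mapped_cpp(seqs, assembly, k, band, scoring$match,
                             scoring$mismatch, scoring$gap_open,
                             scoring$gap_extend, identity_floor, TRUE)
  if (!any(on_asm)) stop("no reads map to the assembly; estimator undefined")
  structure(list(pct_reads_on_rdna = mean(on_rdna),
                 pct_reads_on_assembly = mean(on_asm),
                 rdna_length = unit_length(unit),
                 assembly_size = nchar(assembly),
                 n_reads = length(seqs)),
            class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf(paste0("mapping_stats: %.3f%% of %d reads on rDNA (%d bp), ",
                     "%.1f%% on assembly (%d bp)\n"),
              100 * x$pct_reads_on_rdna, x$n_reads, x$rdna_length,
              100 * x$pct_reads_on_assembly, x$assembly_size))
  invisible(x)
}

#' Estimate rDNA copy number from mapping proportions
#'
#' copies = (fraction of reads mapped to the rDNA reference x assembly
#' size) / (rDNA reference length x fraction of reads mapped to the
#' assembly). With the rDNA array absent from (collapsed in) the assembly,
#' this fold difference in mapped-read density is a proxy for the number
#' of repeat copies in the genome.
#'
#' @param stats A `mapping_stats` object (or a list with the same fields).
#' @return An object of class `copy_number_estimate` with `estimate`
#'   (positive real) and `rounded`.
#' @export
estimate_rdna_copy_number <- function(stats) {
  p_r <- stats$pct_reads_on_rdna
  p_a <- stats$pct_reads_on_assembly
  if (is.null(p_r) || is.null(p_a)) stop("invalid mapping stats")
  denom <- stats$rdna_length * p_a
  if (denom <= 0) stop("zero denominator: no reads map to the assembly")
  est <- (p_r * stats$assembly_size) / denom
  structure(list(estimate = est, rounded = round(est), stats = stats),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("estimated rDNA copy number: %.2f (~%d copies)\n",
              x$estimate, x$rounded))
  invisible(x)
}
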