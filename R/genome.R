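#' Embed an rDNA haplotype array in a background genome
#'
#' Builds the physical genome used by the WGS simulator: a non-repetitive
#' random background with every rDNA haplotype copy inserted in tandem at
#' its midpoint, plus the corresponding genome *assembly* in which the
#' repeat array is collapsed to at most one consensus copy (assemblers
#' collapse near-identical tandem repeats, so rDNA arrays are typically
#' absent from draft assemblies).
#'
#' @param hapset A `haplotype_set`.
#' @param background_len Length of the non-repetitive background in bases;
#'   must be at least 10 times the unit length so that rDNA stays a minor
#'   genome fraction.
#' @param collapse_in_assembly If `TRUE` (default) the assembly contains one
#'   collapsed consensus rDNA copy; if `FALSE` it is the background only.
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @return An object of class `genome_model` with elements `background`,
#'   `array` (the haplotype set), `physical` (background + tandem array),
#'   `assembly`, `rdna_start` (1-based start of the array in `physical`)
#'   and `total_rdna_copies`.
#' @export
assemble_genome <- function(hapset, background_len, collapse_in_assembly = TRUE,
                            gc = 0.5, seed = 1L) {
  stopifnot(inherits(hapset, "haplotype_set"))
  ulen <- unit_length(hapset$unit)
  if (background_len < 10 * ulen) {
    stop("background_len must be at least 10x the unit length")
  }
  with_seed(seed, {
    background <- random_sequence(background_len, gc)
    half <- background_len %/% 2
    left <- substr(background, 1, half)
    right <- substr(background, half + 1, background_len)
    copies <- rep(names(hapset$copy_counts), hapset$copy_counts)
    array_seq <- paste(hapset$haplotypes[copies], collapse = "")
    physical <- paste0(left, array_seq, right)
    assembly <- if (collapse_in_assembly) {
      paste0(left, collapse_consensus(hapset), right)
    } else {
      background
    }
    structure(list(background = background, array = hapset,
                   physical = physical, assembly = assembly,
                   rdna_start = half + 1L,
                   total_rdna_copies = sum(hapset$copy_counts)),
              class = "genome_model")
  })
}

# collapsed consensus of the repeat array: the reference unit with
# majority-frequency substitution alleles applied (indels are left out of
# the collapsed copy, mimicking a substitution-level consensus)
collapse_consensus <- function(hapset) {
  chars <- strsplit(hapset$unit$sequence, "")[[1]]
  tv <- hapset$true_variant_sites
  subs <- tv[tv$type == "sub" & tv$freq > 0.5, , drop = FALSE]
  if (nrow(subs)) chars[subs$pos] <- subs$alt
  paste(chars, collapse = "")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d bp background, %d rDNA copies (%d bp unit)\n",
              nchar(x$background), x$total_rdna_copies,
              unit_length(x$array$unit)))
  cat(sprintf("  physical genome %d bp; assembly %d bp\n",
              nchar(x$physical), nchar(x$assembly)))
  invisible(x)
}
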