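#' Build an annotated reference rDNA repeat unit
#'
#' Generates a random reference sequence for one rDNA repeat unit with the
#' five canonical regions (partial 18S, ITS1, 5.8S, ITS2, partial 28S) laid
#' out contiguously in that order. Coordinates are 1-based inclusive and the
#' regions tile the whole sequence.
#'
#' @param region_lengths Named integer vector of region lengths in bases.
#'   Names must be `SSU18S`, `ITS1`, `R5_8S`, `ITS2`, `LSU28S`; every length
#'   must be at least 1. The default mirrors a typical basidiomycete
#'   reference: partial 18S 1683 bp, ITS 846 bp, partial 28S 2165 bp.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed; the unit is deterministic given the seed.
#' @return An object of class `rdna_unit`: a list with `sequence` (character
#'   scalar) and `regions` (data.frame with `region`, `start`, `end`).
#' @examples
#' u <- make_reference_unit(c(SSU18S = 50, ITS1 = 20, R5_8S = 15,
#'                            ITS2 = 20, LSU28S = 50), gc = 0.5, seed = 1)
#' unit_length(u)
#' @export
make_reference_unit <- function(region_lengths = c(SSU18S = 1683, ITS1 = 300,
                                                   R5_8S = 160, ITS2 = 386,
                                                   LSU28S = 2165),
                                gc = 0.5, seed = 1L) {
  if (!all(RDNA_REGIONS %in% names(region_lengths))) {
    stop("region_lengths must be named with: ",
         paste(RDNA_REGIONS, collapse = ", "))
  }
  lens <- as.integer(region_lengths[RDNA_REGIONS])
  if (any(is.na(lens)) || any(lens < 1)) {
    stop("every region length must be a positive integer")
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  seq <- with_seed(seed, random_sequence(sum(lens), gc))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  unit <- list(
    sequence = seq,
    regions = data.frame(region = RDNA_REGIONS, start = starts, end = ends,
                         stringsAsFactors = FALSE)
  )
  class(unit) <- "rdna_unit"
  validate_rdna_unit(unit)
  unit
}

validate_rdna_unit <- function(unit) {
  stopifnot(inherits(unit, "rdna_unit"))
  r <- unit$regions
  if (!identical(r$region, RDNA_REGIONS)) stop("regions out of order")
  if (r$start[1] != 1L) stop("first region must start at 1")
  if (any(r$end < r$start)) stop("empty region")
  if (any(r$start[-1] != head(r$end, -1) + 1L)) stop("regions must tile")
  if (r$end[nrow(r)] != nchar(unit$sequence)) {
    stop("regions must cover the whole sequence")
  }
  invisible(unit)
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat("rDNA reference unit,", nchar(x$sequence), "bp\n")
  r <- x$regions
  its <- sum(r$end[2:4] - r$start[2:4] + 1L)
  cat(sprintf("  18S %d bp | ITS %d bp (ITS1/5.8S/ITS2) | 28S %d bp\n",
              r$end[1] - r$start[1] + 1L, its,
              r$end[5] - r$start[5] + 1L))
  invisible(x)
}

#' Total length of an rDNA unit
#' @param unit An `rdna_unit`.
#' @return Integer length in bases.
#' @export
unit_length <- function(unit) nchar(unit$sequence)

#' Region coordinates on the reference unit
#'
#' `"ITS"` spans ITS1 through ITS2 (the aggregate ITS1-5.8S-ITS2 barcode
#' region); `"whole"` spans the full unit.
#'
#' @param unit An `rdna_unit`.
#' @param region One of the five region names, `"ITS"`, or `"whole"`.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
region_bounds <- function(unit, region) {
  r <- unit$regions
  if (region == "whole") return(c(1L, nchar(unit$sequence)))
  if (region == "ITS") return(c(r$start[r$region == "ITS1"],
                                r$end[r$region == "ITS2"]))
  if (!region %in% r$region) stop("unknown region: ", region)
  c(r$start[r$region == region], r$end[r$region == region])
}

# which aggregate region (18S / ITS / 28S) a unit position falls in
region_of_position <- function(unit, pos) {
  r <- unit$regions
  out <- character(length(pos))
  out[pos <= r$end[1]] <- "18S"
  out[pos > r$end[1] & pos <= r$end[4]] <- "ITS"
  out[pos > r$end[4]] <- "28S"
  out
}
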