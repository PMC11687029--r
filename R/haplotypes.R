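#' Specify a heterogeneity model for rDNA haplotype evolution
#'
#' The three models correspond to the major sources of intragenomic rDNA
#' variation: relaxed concerted evolution letting each repeat accumulate
#' mutations independently (`accumulated_mutation`), two diverged parental
#' repeat clusters co-existing after hybridization (`hybridization`), and a
#' foreign DNA element inserted into one repeat class (`foreign_element`).
#'
#' @param mode One of `"accumulated_mutation"`, `"hybridization"`,
#'   `"foreign_element"`.
#' @param n_haplotypes Number of distinct repeat haplotypes (>= 1;
#'   hybridization requires >= 2).
#' @param region_rates Named numeric vector of per-base substitution
#'   probabilities per region; names may be the five region names or the
#'   aggregate `"ITS"` (expanded to ITS1/5.8S/ITS2). All rates in [0, 0.25].
#' @param indel_rate Per-base probability of a single-base indel.
#' @param hybrid_divergence Substitutions/site between the two parental
#'   clusters (hybridization mode only).
#' @param insert_length Length in bases of the foreign insert
#'   (foreign_element mode only).
#' @return An object of class `heterogeneity_model`.
#' @export
heterogeneity_model <- function(mode = c("accumulated_mutation",
                                         "hybridization", "foreign_element"),
                                n_haplotypes = 4L,
                                region_rates = c(ITS = 0.01, SSU18S = 0.001,
                                                 LSU28S = 0.001),
                                indel_rate = 0,
                                hybrid_divergence = 0.02,
                                insert_length = 30L) {
  mode <- match.arg(mode)
  n_haplotypes <- as.integer(n_haplotypes)
  if (n_haplotypes < 1) stop("n_haplotypes must be >= 1")
  if (mode == "hybridization" && n_haplotypes < 2) {
    stop("hybridization requires n_haplotypes >= 2")
  }
  rates <- c(region_rates, indel = unname(indel_rate),
             divergence = unname(hybrid_divergence))
  if (any(rates < 0) || any(rates > 0.25)) stop("all rates must be in [0, 0.25]")
  ok <- c(RDNA_REGIONS, "ITS")
  if (length(region_rates) && !all(names(region_rates) %in% ok)) {
    stop("region_rates names must be region names or 'ITS'")
  }
  structure(list(mode = mode, n_haplotypes = n_haplotypes,
                 region_rates = region_rates, indel_rate = indel_rate,
                 hybrid_divergence = hybrid_divergence,
                 insert_length = as.integer(insert_length)),
            class = "heterogeneity_model")
}

# expand an "ITS" entry of region_rates into the three spacer/5.8S regions
expand_region_rates <- function(region_rates) {
  if ("ITS" %in% names(region_rates)) {
    its <- region_rates[["ITS"]]
    region_rates <- region_rates[names(region_rates) != "ITS"]
    add <- c(ITS1 = its, R5_8S = its, ITS2 = its)
    region_rates <- c(region_rates, add[!names(add) %in% names(region_rates)])
  }
  region_rates
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

# --- edit bookkeeping --------------------------------------------------------
# An edit is (pos, type, alt): type "sub" (alt = new base), "del" (alt = ""),
# "ins" (alt = inserted string, placed after pos).

empty_edits <- function() {
  data.frame(pos = integer(), type = character(), alt = character(),
             stringsAsFactors = FALSE)
}

# left-align an indel edit against the reference (VCF-style normalization);
# substitutions pass through unchanged
normalize_edit <- function(pos, type, alt, ref_chars) {
  pos <- as.integer(pos)
  if (type == "del") {
    while (pos > 1L && ref_chars[pos - 1L] == ref_chars[pos]) pos <- pos - 1L
  } else if (type == "ins") {
    n <- nchar(alt)
    while (pos > 1L && substr(alt, n, n) == ref_chars[pos]) {
      alt <- paste0(substr(alt, n, n), substr(alt, 1, n - 1))
      pos <- pos - 1L
    }
  }
  list(pos = pos, alt = alt)
}

edit_allele <- function(type, alt) {
  switch(type, sub = alt, del = "-", ins = paste0("+", alt))
}

# draw rate-based edits for one haplotype
draw_edits <- function(unit, region_rates, indel_rate) {
  region_rates <- expand_region_rates(region_rates)
  L <- unit_length(unit)
  ed <- empty_edits()
  chars <- strsplit(unit$sequence, "")[[1]]
  for (rn in names(region_rates)) {
    rate <- region_rates[[rn]]
    if (rate <= 0) next
    b <- region_bounds(unit, rn)
    pos <- (b[1]:b[2])[runif(b[2] - b[1] + 1) < rate]
    if (length(pos)) {
      alt <- vapply(pos, function(p) sample(OTHER_BASES[[chars[p]]], 1), "")
      ed <- rbind(ed, data.frame(pos = pos, type = "sub", alt = alt,
                                 stringsAsFactors = FALSE))
    }
  }
  if (indel_rate > 0 && L > 2) {
    cand <- 2:(L - 1)
    pos <- cand[runif(length(cand)) < indel_rate]
    if (length(pos)) {
      is_del <- runif(length(pos)) < 0.5
      alt <- ifelse(is_del, "",
                    sample(c("A", "C", "G", "T"), length(pos), replace = TRUE))
      ed <- rbind(ed, data.frame(pos = pos,
                                 type = ifelse(is_del, "del", "ins"),
                                 alt = alt, stringsAsFactors = FALSE))
    }
  }
  ed[!duplicated(ed$pos), , drop = FALSE]
}

# assemble a haplotype_set from per-haplotype edit lists
build_haplotype_set <- function(unit, edits_by_hap, copy_counts) {
  H <- length(edits_by_hap)
  ref_chars <- strsplit(unit$sequence, "")[[1]]
  ids <- names(edits_by_hap)
  char_maps <- vector("list", H)
  seqs <- character(H)
  norm_edits <- vector("list", H)
  for (h in seq_len(H)) {
    ed <- edits_by_hap[[h]]
    chars <- ref_chars
    if (nrow(ed)) {
      nl <- lapply(seq_len(nrow(ed)), function(i) {
        normalize_edit(ed$pos[i], ed$type[i], ed$alt[i], ref_chars)
      })
      ed$norm_pos <- vapply(nl, `[[`, 1L, "pos")
      ed$norm_alt <- vapply(nl, `[[`, "", "alt")
      for (i in seq_len(nrow(ed))) {
        p <- ed$pos[i]
        chars[p] <- switch(ed$type[i],
                           sub = ed$alt[i],
                           del = "",
                           ins = paste0(chars[p], ed$alt[i]))
      }
    } else {
      ed$norm_pos <- integer(0)
      ed$norm_alt <- character(0)
    }
    char_maps[[h]] <- chars
    seqs[h] <- paste(chars, collapse = "")
    norm_edits[[h]] <- ed
  }
  names(seqs) <- ids
  names(char_maps) <- ids
  names(norm_edits) <- ids

  stopifnot(identical(sort(names(copy_counts)), sort(ids)))
  copy_counts <- setNames(as.integer(copy_counts), names(copy_counts))
  total <- sum(copy_counts)

  # ground-truth variant table: group normalized edits by (pos, allele)
  rows <- do.call(rbind, lapply(ids, function(id) {
    ed <- norm_edits[[id]]
    if (!nrow(ed)) return(NULL)
    data.frame(hap = id, pos = ed$norm_pos, type = ed$type,
               allele = mapply(edit_allele, ed$type, ed$norm_alt,
                               USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || !nrow(rows)) {
    truth <- data.frame(pos = integer(), ref = character(),
                        alt = character(), type = character(),
                        n_copies = integer(), freq = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(rows$pos, rows$allele)
    agg <- split(rows, key)
    truth <- do.call(rbind, lapply(agg, function(g) {
      nc <- sum(copy_counts[unique(g$hap)])
      data.frame(pos = g$pos[1], ref = ref_chars[g$pos[1]],
                 alt = g$allele[1], type = g$type[1],
                 n_copies = nc, freq = nc / total,
                 stringsAsFactors = FALSE)
    }))
    truth <- truth[order(truth$pos, truth$alt), , drop = FALSE]
    rownames(truth) <- NULL
  }

  structure(list(unit = unit, haplotypes = seqs,
                 copy_counts = copy_counts[ids],
                 true_variant_sites = truth,
                 edits = norm_edits, char_maps = char_maps),
            class = "haplotype_set")
}

default_copy_counts <- function(n_haplotypes, total = 8L) {
  n_haplotypes <- as.integer(n_haplotypes)
  total <- as.integer(total)
  # keep total copies small so every carried allele is at detectable
  # frequency (>= 1/total)
  if (n_haplotypes >= total) {
    cc <- rep(1L, n_haplotypes)
  } else {
    cc <- rep(total %/% n_haplotypes, n_haplotypes)
    extra <- total %% n_haplotypes
    if (extra > 0) cc[seq_len(extra)] <- cc[seq_len(extra)] + 1L
  }
  names(cc) <- paste0("h", seq_len(n_haplotypes))
  cc
}

#' Evolve rDNA haplotypes from a reference unit
#'
#' Generates `n_haplotypes` repeat sequences from the reference unit under
#' the chosen heterogeneity model, together with the exact ground-truth
#' variant table (position, reference base, alternative allele, true
#' frequency given the copy counts). Indel alleles are left-aligned against
#' the reference. Deletions are written `"-"`, insertions `"+SEQ"` anchored
#' to the preceding reference position.
#'
#' @param unit An `rdna_unit`.
#' @param model A `heterogeneity_model`.
#' @param seed Integer seed.
#' @param copy_counts Optional named integer vector of copies per haplotype
#'   (names `h1`, `h2`, ...). Default: 8 total copies spread as evenly as
#'   possible, so every carried allele has frequency >= 1/8.
#' @return An object of class `haplotype_set`.
#' @export
evolve_haplotypes <- function(unit, model, seed = 1L, copy_counts = NULL) {
  stopifnot(inherits(unit, "rdna_unit"), inherits(model, "heterogeneity_model"))
  H <- model$n_haplotypes
  if (is.null(copy_counts)) copy_counts <- default_copy_counts(H)
  ids <- paste0("h", seq_len(H))
  ref_chars <- strsplit(unit$sequence, "")[[1]]
  L <- unit_length(unit)

  with_seed(seed, {
    edits_by_hap <- switch(model$mode,
      accumulated_mutation = {
        lapply(ids, function(id) {
          draw_edits(unit, model$region_rates, model$indel_rate)
        })
      },
      hybridization = {
        # parental cluster B differs from the unit by Bernoulli(divergence)
        # substitutions; haplotypes split between the two parents and then
        # accrue their own mutations
        pos <- which(runif(L) < model$hybrid_divergence)
        parent <- if (length(pos)) {
          data.frame(pos = pos, type = "sub",
                     alt = vapply(pos, function(p) {
                       sample(OTHER_BASES[[ref_chars[p]]], 1)
                     }, ""), stringsAsFactors = FALSE)
        } else empty_edits()
        n_a <- ceiling(H / 2)
        lapply(seq_len(H), function(h) {
          own <- draw_edits(unit, model$region_rates, model$indel_rate)
          if (h > n_a) {
            own <- own[!own$pos %in% parent$pos, , drop = FALSE]
            rbind(parent, own)
          } else own
        })
      },
      foreign_element = {
        eds <- lapply(ids, function(id) {
          draw_edits(unit, model$region_rates, model$indel_rate)
        })
        p <- sample(seq(20L, L - 20L), 1)
        ins <- data.frame(pos = p, type = "ins",
                          alt = random_sequence(model$insert_length, 0.5),
                          stringsAsFactors = FALSE)
        last <- eds[[H]]
        eds[[H]] <- rbind(last[last$pos != p, , drop = FALSE], ins)
        eds
      })
    names(edits_by_hap) <- ids
    build_haplotype_set(unit, edits_by_hap, copy_counts)
  })
}

#' Construct haplotypes with an exact number of variant sites
#'
#' Places exactly `n_substitutions` substitution sites and `n_indels`
#' single-base indel sites at distinct, well-separated positions inside one
#' region of the unit, and assigns each site to a random proper subset of
#' haplotypes. This is the generator used for calibration experiments where
#' the true variant-site count must be controlled exactly (for example a
#' strain with 15 ITS variant sites, all at detectable frequency).
#'
#' @param unit An `rdna_unit`.
#' @param n_substitutions,n_indels Exact site counts to place. About one
#'   third of the indel sites are single-base insertions, the rest
#'   single-base deletions.
#' @param n_haplotypes Number of haplotypes (>= 2 so that sites segregate).
#' @param copy_counts As in [evolve_haplotypes()].
#' @param region Region to place the sites in (default `"ITS"`).
#' @param seed Integer seed.
#' @param margin Minimum distance of any site from the region ends.
#' @param min_spacing Minimum spacing between sites in bases.
#' @return A `haplotype_set` whose `true_variant_sites` has exactly
#'   `n_substitutions + n_indels` rows, each with frequency in (0, 1).
#' @export
make_haplotypes_exact <- function(unit, n_substitutions = 10L, n_indels = 5L,
                                  n_haplotypes = 4L, copy_counts = NULL,
                                  region = "ITS", seed = 1L, margin = 10L,
                                  min_spacing = 4L) {
  stopifnot(inherits(unit, "rdna_unit"), n_haplotypes >= 2)
  n_substitutions <- as.integer(n_substitutions)
  n_indels <- as.integer(n_indels)
  n_haplotypes <- as.integer(n_haplotypes)
  if (is.null(copy_counts)) copy_counts <- default_copy_counts(n_haplotypes)
  b <- region_bounds(unit, region)
  ref_chars <- strsplit(unit$sequence, "")[[1]]
  n_sites <- n_substitutions + n_indels
  ids <- paste0("h", seq_len(n_haplotypes))

  with_seed(seed, {
    # choose spaced positions whose left-aligned form stays put and unique
    chosen <- integer(0)
    cand <- seq(b[1] + margin, b[2] - margin)
    attempts <- 0
    while (length(chosen) < n_sites) {
      attempts <- attempts + 1
      if (attempts > 10000) stop("could not place variant sites; region too small")
      p <- sample(cand, 1)
      if (all(abs(p - chosen) >= min_spacing) &&
          ref_chars[p - 1] != ref_chars[p]) {
        chosen <- c(chosen, p)
      }
    }
    n_ins <- n_indels %/% 3
    types <- sample(c(rep("sub", n_substitutions),
                      rep("del", n_indels - n_ins), rep("ins", n_ins)))
    alts <- vapply(seq_len(n_sites), function(i) {
      p <- chosen[i]
      switch(types[i],
             sub = sample(OTHER_BASES[[ref_chars[p]]], 1),
             del = "",
             # pick an inserted base that cannot left-shift
             ins = sample(setdiff(c("A", "C", "G", "T"), ref_chars[p]), 1))
    }, "")
    # assign each site to a proper subset of haplotypes
    carriers <- lapply(seq_len(n_sites), function(i) {
      k <- sample(seq_len(n_haplotypes - 1), 1)
      sample(ids, k)
    })
    edits_by_hap <- lapply(ids, function(id) {
      sel <- vapply(carriers, function(cs) id %in% cs, TRUE)
      if (!any(sel)) return(empty_edits())
      data.frame(pos = chosen[sel], type = types[sel], alt = alts[sel],
                 stringsAsFactors = FALSE)
    })
    names(edits_by_hap) <- ids
    build_haplotype_set(unit, edits_by_hap, copy_counts)
  })
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$haplotypes), "haplotypes,",
      sum(x$copy_counts), "total rDNA copies\n")
  cat("  true variant sites:", nrow(x$true_variant_sites), "\n")
  invisible(x)
}

#' Haplotype subsequences for a unit region
#'
#' Extracts, per haplotype, the sequence corresponding to a region of the
#' reference unit, following any indels that haplotype carries (deleted
#' reference positions contribute nothing; insertions anchored inside the
#' region are included).
#'
#' @param hapset A `haplotype_set`.
#' @param region Region name, `"ITS"`, or `"whole"`.
#' @return Named character vector, one sequence per haplotype.
#' @export
hap_region_seq <- function(hapset, region = "ITS") {
  b <- region_bounds(hapset$unit, region)
  vapply(hapset$char_maps, function(chars) {
    paste(chars[b[1]:b[2]], collapse = "")
  }, "")
}

#' Pairwise p-distances between the haplotype sequences of a set
#'
#' p-distance over a pairwise global alignment of each haplotype pair
#' (gapped columns excluded pairwise).
#' @param hapset A `haplotype_set`.
#' @param scoring Alignment scoring list.
#' @return Symmetric matrix of proportions.
#' @export
haplotype_p_distances <- function(hapset, scoring = default_scoring()) {
  seqs <- hapset$haplotypes
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- align_to_reference(seqs[[i]], seqs[[j]], scoring)
    qa <- strsplit(a$query_aln, "")[[1]]
    ra <- strsplit(a$ref_aln, "")[[1]]
    keep <- qa != "-" & ra != "-"
    D[i, j] <- D[j, i] <- mean(qa[keep] != ra[keep])
  }
  D
}
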