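# Simulators for the three data-acquisition arms: PCR-cloning-Sanger
# clone libraries, multi-run targeted amplicon sequencing, and WGS reads.
# Every clone/read keeps its true source molecule so downstream estimators
# can be checked against exact truth.

# apply independent per-base substitution errors to a character vector of
# sequences; returns list(seqs, n_errors)
apply_base_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) {
    return(list(seqs = seqs, n_errors = 0L))
  }
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1, total, error_rate)
  if (n_err == 0) return(list(seqs = seqs, n_errors = 0L))
  flat <- sample.int(total, n_err)
  cum <- cumsum(lens)
  idx <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = FALSE)
  offs <- flat - c(0L, cum)[idx]
  for (i in seq_len(n_err)) {
    s <- seqs[idx[i]]
    b <- substr(s, offs[i], offs[i])
    substr(seqs[idx[i]], offs[i], offs[i]) <- sample(OTHER_BASES[[b]], 1)
  }
  list(seqs = seqs, n_errors = n_err)
}

#' Sample a PCR-cloning-Sanger clone library
#'
#' Each clone is drawn from one haplotype with probability proportional to
#' its copy count, then subjected to independent per-base substitution
#' errors that model polymerase and cloning artefacts introduced before
#' Sanger sequencing.
#'
#' @param hapset A `haplotype_set`.
#' @param n_clones Number of clones to sample (>= 1).
#' @param error_rate Per-base process error probability in [0, 0.01].
#' @param seed Integer seed.
#' @param region Region cloned (default `"ITS"`, the usual amplicon).
#' @return An object of class `clone_set`: named clone sequences, their
#'   source haplotype ids, and the error rate used.
#' @export
sample_clones <- function(hapset, n_clones, error_rate = 5e-4, seed = 1L,
                          region = "ITS") {
  stopifnot(inherits(hapset, "haplotype_set"))
  if (!length(hapset$haplotypes)) stop("empty haplotype set")
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (error_rate < 0 || error_rate > 0.01) {
    stop("error_rate must be in [0, 0.01]")
  }
  hseq <- hap_region_seq(hapset, region)
  with_seed(seed, {
    src <- sample(names(hseq), n_clones, replace = TRUE,
                  prob = hapset$copy_counts[names(hseq)])
    res <- apply_base_errors(unname(hseq[src]), error_rate)
    clones <- setNames(res$seqs, paste0("clone", seq_len(n_clones)))
    structure(list(clones = clones, source = src,
                   error_rate = error_rate, region = region,
                   n_errors = res$n_errors),
              class = "clone_set")
  })
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set: %d clones of region %s from %d haplotypes\n",
              length(x$clones), x$region, length(unique(x$source))))
  invisible(x)
}

new_read_set <- function(reads, strand, origin, offset, run_id, read_length,
                         method, region = NULL) {
  structure(list(reads = reads, strand = strand, origin = origin,
                 offset = offset, run_id = run_id, read_length = read_length,
                 method = method, region = region),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set (%s): %d reads of %d bp%s\n", x$method,
              length(x$reads), x$read_length,
              if (!is.null(x$run_id)) paste0(", run ", x$run_id) else ""))
  invisible(x)
}

# draw reads from a set of template molecules: per-read template index,
# uniform start, then substitution errors and random strand
draw_reads <- function(templates, weights, n_reads, read_length, error_rate) {
  tlen <- nchar(templates)
  ti <- sample(seq_along(templates), n_reads, replace = TRUE, prob = weights)
  maxs <- pmax(tlen[ti] - read_length + 1L, 1L)
  starts <- floor(runif(n_reads) * maxs) + 1L
  reads <- substring(templates[ti], starts,
                     pmin(starts + read_length - 1L, tlen[ti]))
  res <- apply_base_errors(reads, error_rate)
  reads <- res$seqs
  minus <- runif(n_reads) < 0.5
  if (any(minus)) reads[minus] <- revcomp(reads[minus])
  list(reads = unname(reads), strand = ifelse(minus, "-", "+"),
       template = ti, start = starts)
}

#' Simulate multi-run targeted amplicon sequencing
#'
#' One read set per independent sequencing run. Per-run mean depth is the
#' nominal depth perturbed by a run-level jitter factor, modeling the
#' coverage inconsistency observed between independent amplicon runs.
#' Read start positions are uniform over each template amplicon, so
#' coverage decays naturally within one read length of the amplicon ends.
#'
#' @param hapset A `haplotype_set`.
#' @param region Amplified region (default `"ITS"`).
#' @param depth Nominal mean read depth per site (interior of the amplicon).
#' @param read_length Read length in bases.
#' @param error_rate Per-base sequencing error probability.
#' @param n_runs Number of independent runs (>= 1).
#' @param run_depth_jitter Fractional run-to-run depth perturbation; each
#'   run's depth is `depth * (1 + u)`, `u ~ Uniform(-jitter, jitter)`.
#' @param seed Integer seed.
#' @return List of `read_set` objects, one per run (`run_id` 1..n_runs).
#' @export
simulate_amplicon_reads <- function(hapset, region = "ITS", depth = 2000,
                                    read_length = 150L, error_rate = 0.001,
                                    n_runs = 2L, run_depth_jitter = 0.2,
                                    seed = 1L) {
  stopifnot(inherits(hapset, "haplotype_set"))
  if (depth < 1) stop("depth must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  b <- region_bounds(hapset$unit, region)  # errors on unknown region
  L <- b[2] - b[1] + 1L
  templates <- hap_region_seq(hapset, region)
  w <- hapset$copy_counts[names(templates)]
  with_seed(seed, {
    lapply(seq_len(n_runs), function(run) {
      d <- depth * (1 + runif(1, -run_depth_jitter, run_depth_jitter))
      n_reads <- max(1L, as.integer(round(d * L / read_length)))
      dr <- draw_reads(templates, w, n_reads, read_length, error_rate)
      new_read_set(dr$reads, dr$strand, names(templates)[dr$template],
                   dr$start, run, read_length, "amplicon", region)
    })
  })
}

#' Simulate whole-genome shotgun reads
#'
#' Reads are drawn uniformly from the physical genome, which carries every
#' rDNA copy in tandem, so expected depth over the rDNA unit is about
#' `coverage * total_rdna_copies` once reads from all copies are collapsed
#' onto the single reference unit.
#'
#' @param genome A `genome_model`.
#' @param coverage Genome-wide fold coverage (> 0).
#' @param read_length Read length in bases.
#' @param error_rate Per-base sequencing error probability.
#' @param seed Integer seed.
#' @return A `read_set` with `method = "wgs"`.
#' @export
simulate_wgs_reads <- function(genome, coverage, read_length = 150L,
                               error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(coverage) || coverage <= 0) stop("coverage must be > 0")
  glen <- nchar(genome$physical)
  n_reads <- max(1L, as.integer(round(coverage * glen / read_length)))
  with_seed(seed, {
    dr <- draw_reads(genome$physical, 1, n_reads, read_length, error_rate)
    new_read_set(dr$reads, dr$strand, rep("genome", n_reads), dr$start,
                 NULL, read_length, "wgs")
  })
}
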