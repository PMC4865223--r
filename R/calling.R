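## Read-count genotype calling and locus-level recovery classification.

#' Call genotypes from allele read counts
#'
#' Transparent threshold caller.  A call is missing when total depth is
#' below `min_depth`.  A heterozygote requires at least `het_minor_reads`
#' reads of the minor allele and a minor-allele fraction of at least
#' `het_minor_fraction`; otherwise the majority allele is called
#' homozygous.  Equal counts that fail the heterozygote rule are
#' uncallable and returned as missing.
#'
#' @param reads_a,reads_b Non-negative integer vectors of reads supporting
#'   the Dic2 (A) and Silur (B) alleles.
#' @param min_depth Minimum total reads for any call (default 2, the
#'   targeted-locus threshold; use 4 for untargeted/bonus positions).
#' @param het_minor_fraction Minimum minor-allele read fraction for a
#'   heterozygote (default 0.2).
#' @param het_minor_reads Minimum minor-allele reads for a heterozygote
#'   (default 2).
#' @return Character vector of calls: "A", "B", "H" or NA (missing).
#' @export
call_genotype <- function(reads_a, reads_b, min_depth = 2L,
                          het_minor_fraction = 0.2, het_minor_reads = 2L) {
  if (any(reads_a < 0 | reads_b < 0, na.rm = TRUE))
    stop_arg("read counts must be non-negative")
  depth <- reads_a + reads_b
  minor <- pmin(reads_a, reads_b)
  call <- rep(NA_character_, length(depth))
  ok <- !is.na(depth) & depth >= min_depth
  het <- ok & minor >= het_minor_reads & minor / depth >= het_minor_fraction
  call[het] <- "H"
  homo <- ok & !het & reads_a != reads_b
  call[homo & reads_a > reads_b] <- "A"
  call[homo & reads_a < reads_b] <- "B"
  call
}

#' Build a genotype matrix from a long read-count table
#'
#' @param counts Long data.frame with columns `locus`, `individual`,
#'   `reads_a`, `reads_b` (as produced by
#'   [simulate_capture_readcounts()]).
#' @param min_depth,het_minor_fraction,het_minor_reads Passed to
#'   [call_genotype()].
#' @return Character matrix (loci x individuals) of "A"/"B"/"H"/NA with a
#'   `depth` attribute holding the per-cell total depth.
#' @export
call_genotype_matrix <- function(counts, min_depth = 2L,
                                 het_minor_fraction = 0.2,
                                 het_minor_reads = 2L) {
  counts <- as.data.frame(counts)
  loci <- unique(counts$locus)
  inds <- unique(counts$individual)
  call <- call_genotype(counts$reads_a, counts$reads_b, min_depth,
                        het_minor_fraction, het_minor_reads)
  g <- matrix(NA_character_, length(loci), length(inds),
              dimnames = list(loci, inds))
  d <- matrix(0L, length(loci), length(inds), dimnames = list(loci, inds))
  ij <- cbind(match(counts$locus, loci), match(counts$individual, inds))
  g[ij] <- call
  d[ij] <- counts$reads_a + counts$reads_b
  attr(g, "depth") <- d
  g
}

#' Classify a targeted locus by its calls
#'
#' Partitions targeted loci into the recovery categories used in capture
#' bookkeeping: `not_captured` (no calls at all), `monomorphic` (all
#' homozygous calls in one class, allowing up to `max_het_rescue` stray H
#' calls), `het_only` (heterozygous calls exclusively) and `ER`
#' ("expected recovered": a usable segregating locus).
#'
#' @param calls Character vector of "A"/"B"/"H"/NA over the population.
#' @param is_targeted Logical; untargeted loci get status "bonus".
#' @param max_het_rescue Number of H calls ignored when deciding
#'   monomorphism (default 0).
#' @return List with `status` and `n_genotyped`.
#' @export
classify_locus <- function(calls, is_targeted = TRUE, max_het_rescue = 0L) {
  obs <- calls[!is.na(calls)]
  n <- length(obs)
  status <- if (!is_targeted) "bonus"
  else if (n == 0) "not_captured"
  else {
    nh <- sum(obs == "H")
    nA <- sum(obs == "A"); nB <- sum(obs == "B")
    if (nh == n) "het_only"
    else if ((nA == 0 || nB == 0) && nh <= max_het_rescue) "monomorphic"
    else "ER"
  }
  list(status = status, n_genotyped = n)
}

#' Classify every locus of a genotype matrix
#'
#' @param genotypes Loci x individuals call matrix.
#' @param is_targeted Logical vector (recycled) marking targeted loci.
#' @param max_het_rescue Passed to [classify_locus()].
#' @return data.frame: locus, status, n_genotyped.
#' @export
classify_loci <- function(genotypes, is_targeted = TRUE, max_het_rescue = 0L) {
  is_targeted <- rep(is_targeted, length.out = nrow(genotypes))
  res <- lapply(seq_len(nrow(genotypes)), function(i)
    classify_locus(genotypes[i, ], is_targeted[i], max_het_rescue))
  data.frame(locus = rownames(genotypes),
             status = vapply(res, `[[`, "", "status"),
             n_genotyped = vapply(res, `[[`, 0L, "n_genotyped"),
             stringsAsFactors = FALSE)
}

#' Discover bonus SNPs on untargeted positions
#'
#' Calls genotypes at untargeted positions with the stricter bonus depth
#' threshold and emits the positions that segregate (both parental
#' classes observed among calls).  Each record is flagged
#' `on_targeted_contig` for downstream per-contig de-duplication.
#'
#' @param counts Long read-count table restricted to untargeted positions;
#'   needs columns `locus`, `contig`, `individual`, `reads_a`, `reads_b`.
#' @param targeted_contigs Character vector of contigs carrying a bait
#'   target.
#' @param min_depth Bonus-position calling threshold (default 4).
#' @param het_minor_fraction,het_minor_reads Passed to [call_genotype()].
#' @return List with `genotypes` (call matrix of emitted loci) and
#'   `records` (locus, contig, on_targeted_contig, n_genotyped).
#' @export
discover_bonus_snps <- function(counts, targeted_contigs, min_depth = 4L,
                                het_minor_fraction = 0.2,
                                het_minor_reads = 2L) {
  counts <- as.data.frame(counts)
  g <- call_genotype_matrix(counts, min_depth, het_minor_fraction,
                            het_minor_reads)
  contig_of <- counts$contig[match(rownames(g), counts$locus)]
  seg <- apply(g, 1, function(x) {
    obs <- x[!is.na(x)]
    sum(obs == "A") > 0 && sum(obs == "B") > 0
  })
  g <- g[seg, , drop = FALSE]
  records <- data.frame(
    locus = rownames(g), contig = contig_of[seg],
    on_targeted_contig = contig_of[seg] %in% targeted_contigs,
    n_genotyped = rowSums(!is.na(g)), stringsAsFactors = FALSE)
  list(genotypes = g, records = records)
}

#' Write a genotype matrix as CSV
#'
#' Rows are markers (`contig@pos`), columns individuals; codes A/B/H and
#' "-" for missing.
#'
#' @param genotypes Call matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(genotypes, path) {
  out <- genotypes
  out[is.na(out)] <- "-"
  write.csv(data.frame(marker = rownames(out), out, check.names = FALSE,
                       stringsAsFactors = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix CSV written by [write_genotypes()]
#'
#' @param path CSV path.
#' @return Call matrix with NA for "-".
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m == "-"] <- NA_character_
  m
}
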