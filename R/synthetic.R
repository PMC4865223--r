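## Synthetic data: reference contigs, parental SNPs, an F6 RIL population
## and capture read counts with the coverage pathologies of a real capture
## experiment (bait-dose effects, capture failure, microsatellite "sink"
## contigs that soak up reads).

#' Map specification for a simulated RIL population
#'
#' Describes the true genetic architecture underlying a simulation: the
#' chromosomes (name and length in centimorgans) and the loci (one SNP per
#' contig) with their genetic and physical positions.
#'
#' @param chromosomes data.frame with columns `name` and `length_cM`.
#' @param loci data.frame with columns `contig`, `chromosome`, `position_cM`,
#'   `position_bp` and optionally `polymorphic` (logical; monomorphic loci
#'   carry the reference allele in every line), `bait_count` (2 or 4) and
#'   `is_targeted` (FALSE for bonus loci on homeologous contigs).
#' @return An object of class `map_spec`.
#' @export
map_spec <- function(chromosomes, loci) {
  chromosomes <- as.data.frame(chromosomes)
  loci <- as.data.frame(loci)
  stopifnot(all(c("name", "length_cM") %in% names(chromosomes)),
            all(c("contig", "chromosome", "position_cM", "position_bp") %in%
                  names(loci)))
  if (any(chromosomes$length_cM < 0))
    stop_arg("chromosome lengths must be non-negative")
  if (anyDuplicated(loci$contig))
    stop_arg("contig ids must be unique (one SNP per contig)")
  if (!all(loci$chromosome %in% chromosomes$name))
    stop_arg("locus on unknown chromosome")
  len <- chromosomes$length_cM[match(loci$chromosome, chromosomes$name)]
  if (any(loci$position_cM < 0 | loci$position_cM > len))
    stop_arg("locus position outside chromosome length")
  if (is.null(loci$polymorphic)) loci$polymorphic <- TRUE
  if (is.null(loci$bait_count)) loci$bait_count <- 2L
  if (is.null(loci$is_targeted)) loci$is_targeted <- TRUE
  if (!all(loci$bait_count %in% c(2L, 4L)))
    stop_arg("bait_count must be 2 or 4")
  ## order loci along each chromosome; bp must increase with cM
  loci <- loci[order(match(loci$chromosome, chromosomes$name),
                     loci$position_cM, loci$position_bp), ]
  for (chr in chromosomes$name) {
    l <- loci[loci$chromosome == chr, ]
    inc <- diff(l$position_cM) > 0
    if (any(inc & diff(l$position_bp) <= 0))
      stop_arg("bp positions must increase with cM positions on ", chr)
  }
  rownames(loci) <- NULL
  structure(list(chromosomes = chromosomes, loci = loci), class = "map_spec")
}

#' @export
print.map_spec <- function(x, ...) {
  cat("Map specification:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$loci), "loci\n")
  cat("  total length:", round(sum(x$chromosomes$length_cM), 1), "cM;",
      sum(!x$loci$is_targeted), "bonus loci;",
      sum(!x$loci$polymorphic), "monomorphic targets\n")
  invisible(x)
}

#' Coverage model for capture read-count simulation
#'
#' Parameters of the stochastic coverage process observed in targeted
#' capture: a per-locus capture-efficiency factor (lognormal), bait-dose
#' scaling (4-bait loci receive twice the coverage of 2-bait loci),
#' negative-binomial sampling of per-individual depth, complete capture
#' failure for a fraction of loci, and a handful of microsatellite-bearing
#' "sink" contigs that divert a large share of the total read budget.
#'
#' @param mean_depth Target median reads per targeted 2-bait locus per
#'   individual (default 11.4).
#' @param capture_failure_rate Fraction of loci receiving zero reads in
#'   every individual (default 0.06).
#' @param sink_contig_count Number of read-sink contigs (default 20).
#' @param sink_read_fraction Fraction of all mapped reads absorbed by the
#'   sink contigs (default 0.42).
#' @param sequencing_error Allele cross-talk probability per read (default
#'   0.01).
#' @param overdispersion Negative-binomial size parameter for
#'   per-individual depth (default 3).
#' @param locus_log_sd Standard deviation (log scale) of the per-locus
#'   capture-efficiency factor (default 0.6); gives depth its heavy
#'   right skew across loci.
#' @param bonus_depth_factor Depth multiplier for untargeted (bonus) loci
#'   captured through homeologous baits (default 0.5).
#' @return An object of class `coverage_model`.
#' @export
coverage_model <- function(mean_depth = 11.4, capture_failure_rate = 0.06,
                           sink_contig_count = 20L, sink_read_fraction = 0.42,
                           sequencing_error = 0.01, overdispersion = 3,
                           locus_log_sd = 0.6, bonus_depth_factor = 0.5) {
  probs <- c(capture_failure_rate, sink_read_fraction, sequencing_error)
  if (any(probs < 0 | probs > 1)) stop_arg("probabilities must lie in [0, 1]")
  if (mean_depth <= 0) stop_arg("mean_depth must be positive")
  if (overdispersion <= 0) stop_arg("overdispersion must be positive")
  structure(list(mean_depth = mean_depth,
                 capture_failure_rate = capture_failure_rate,
                 sink_contig_count = as.integer(sink_contig_count),
                 sink_read_fraction = sink_read_fraction,
                 sequencing_error = sequencing_error,
                 overdispersion = overdispersion,
                 locus_log_sd = locus_log_sd,
                 bonus_depth_factor = bonus_depth_factor),
            class = "coverage_model")
}

valid_exon_spec <- function(spec) {
  if (is.numeric(spec) && length(spec) == 2) spec <- list(min = spec[1], max = spec[2])
  if (!is.list(spec) || is.null(spec$min) || is.null(spec$max))
    stop_arg("exon length distribution must be list(min=, max=) or c(min, max)")
  if (spec$min < 1 || spec$max < spec$min)
    stop_arg("invalid exon length distribution: need 1 <= min <= max")
  spec
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate a synthetic capture reference
#'
#' Builds reference contigs, an exon annotation and a parental SNP table
#' with the features the downstream pipeline has to cope with: one
#' candidate biallelic SNP per contig inside an exon, a configurable
#' fraction of contigs with a homeologous near-copy carrying a segregating
#' bonus site, a fraction with an embedded tandem microsatellite, and a
#' fraction of "EPO"-origin targets that are in fact monomorphic between
#' the two parents.
#'
#' @param n_contigs Number of targeted contigs (>= 1).
#' @param exon_length_distribution Exon length spec, `list(min=, max=)` or
#'   `c(min, max)`; lengths drawn uniformly. Default 120--400 bp.
#' @param seed Integer seed; all output is reproducible byte-for-byte.
#' @param homeolog_fraction Fraction of contigs receiving a homeologous
#'   near-copy (default 0.1).
#' @param microsat_fraction Fraction of contigs with an embedded tandem
#'   microsatellite near the target (default 0.02).
#' @param epo_fraction Fraction of targets of EPO (external reference
#'   panel) origin rather than direct parental contrast (default
#'   1888/6240).
#' @param epo_monomorphic_fraction Fraction of EPO-origin targets that are
#'   monomorphic between the parents (default 768/1888).
#' @param homeolog_divergence Per-base substitution rate between a contig
#'   and its homeologous copy (default 0.03).
#' @return List with `contigs` (named character), `exons`, `snps`
#'   (including the truth columns `truly_polymorphic`, `has_homeolog`,
#'   `has_microsat`) and `bonus_sites` (segregating sites on homeologous
#'   copies).
#' @export
generate_reference <- function(n_contigs, exon_length_distribution = c(120, 400),
                               seed = 1L, homeolog_fraction = 0.1,
                               microsat_fraction = 0.02,
                               epo_fraction = 1888 / 6240,
                               epo_monomorphic_fraction = 768 / 1888,
                               homeolog_divergence = 0.03) {
  if (n_contigs < 1) stop_arg("n_contigs must be >= 1")
  spec <- valid_exon_spec(exon_length_distribution)
  with_seed(seed, {
    ids <- sprintf("contig%05d", seq_len(n_contigs))
    exon_len <- floor(runif(n_contigs, spec$min, spec$max + 1))
    flank <- 150L                      # room for flanking baits
    contigs <- character(n_contigs)
    exon_start <- integer(n_contigs); exon_end <- integer(n_contigs)
    snp_pos <- integer(n_contigs)
    a1 <- character(n_contigs); a2 <- character(n_contigs)
    has_ms <- runif(n_contigs) < microsat_fraction
    for (i in seq_len(n_contigs)) {
      len <- exon_len[i] + 2L * flank
      seqc <- random_dna(len)
      exon_start[i] <- flank + 1L
      exon_end[i] <- flank + exon_len[i]
      ## SNP near the exon centre so most layouts fit
      lo <- exon_start[i] + min(59L, (exon_len[i] - 1L) %/% 2L)
      hi <- exon_end[i] - min(59L, (exon_len[i] - 1L) %/% 2L)
      snp_pos[i] <- if (lo >= hi) (exon_start[i] + exon_end[i]) %/% 2L else
        sample(lo:hi, 1)
      a1[i] <- substr(seqc, snp_pos[i], snp_pos[i])
      a2[i] <- sample(setdiff(c("A", "C", "G", "T"), a1[i]), 1)
      if (has_ms[i]) {
        ## embed (AC)x10 outside the exon, near the target
        ms <- strrep("AC", 10)
        at <- max(1L, exon_start[i] - 40L)
        substr(seqc, at, at + nchar(ms) - 1L) <- ms
      }
      contigs[i] <- seqc
    }
    names(contigs) <- ids
    origin <- ifelse(runif(n_contigs) < epo_fraction, "EPO", "DS")
    truly_poly <- rep(TRUE, n_contigs)
    is_epo <- origin == "EPO"
    truly_poly[is_epo] <- runif(sum(is_epo)) >= epo_monomorphic_fraction
    has_hom <- runif(n_contigs) < homeolog_fraction

    ## homeologous near-copies with one segregating bonus site each
    bonus <- NULL
    hom_ids <- ids[has_hom]
    hom_seqs <- character(0)
    for (id in hom_ids) {
      hseq <- mutate_dna(contigs[[id]], homeolog_divergence)
      i <- match(id, ids)
      bpos <- snp_pos[i] + sample(c(-30L, -20L, 20L, 30L), 1)
      bpos <- min(max(bpos, 1L), nchar(hseq))
      ref <- substr(hseq, bpos, bpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      hid <- paste0(id, "_h")
      hom_seqs[hid] <- hseq
      bonus <- rbind(bonus, data.frame(
        contig = hid, source_contig = id, pos = bpos,
        allele_dic2 = ref, allele_silur = alt, stringsAsFactors = FALSE))
    }
    contigs <- c(contigs, hom_seqs)

    snps <- data.frame(contig = ids, pos = snp_pos,
                       allele_dic2 = a1, allele_silur = a2, origin = origin,
                       truly_polymorphic = truly_poly,
                       has_homeolog = has_hom, has_microsat = has_ms,
                       stringsAsFactors = FALSE)
    exons <- data.frame(contig = ids, exon_start = exon_start,
                        exon_end = exon_end, stringsAsFactors = FALSE)
    list(contigs = contigs, exons = exons, snps = snps,
         bonus_sites = bonus %||% data.frame(
           contig = character(), source_contig = character(),
           pos = integer(), allele_dic2 = character(),
           allele_silur = character(), stringsAsFactors = FALSE))
  })
}

#' Lay a synthetic reference out on chromosomes
#'
#' Assigns each locus (targeted SNPs and bonus sites from
#' [generate_reference()]) to a chromosome and gives it a genetic (cM) and
#' physical (bp) position, producing the true map a simulation runs on.
#' Physical positions increase monotonically with genetic positions at a
#' roughly constant rate (default 1 cM/Mb) plus jitter.
#'
#' @param ref Output of [generate_reference()], or a data.frame of SNPs
#'   with a `contig` column.
#' @param n_chromosomes Number of chromosomes (default 14).
#' @param chr_length_cM Chromosome lengths in cM, recycled (default 150).
#' @param mb_per_cM Physical-to-genetic scale (default 1 Mb/cM).
#' @param seed Integer seed.
#' @return A [map_spec()] object. Bonus loci carry `is_targeted = FALSE`.
#' @export
make_map_spec <- function(ref, n_chromosomes = 14L, chr_length_cM = 150,
                          mb_per_cM = 1, seed = 1L) {
  if (is.data.frame(ref)) {
    snps <- ref
    bonus <- NULL
  } else {
    snps <- ref$snps
    bonus <- ref$bonus_sites
  }
  with_seed(seed, {
    chrs <- data.frame(
      name = paste0(rep(1:((n_chromosomes + 1) %/% 2), each = 2,
                        length.out = n_chromosomes),
                    rep(c("A", "B"), length.out = n_chromosomes)),
      length_cM = rep(chr_length_cM, length.out = n_chromosomes),
      stringsAsFactors = FALSE)
    loci <- data.frame(contig = snps$contig,
                       snp_pos = snps$pos %||% rep(1L, nrow(snps)),
                       polymorphic = snps$truly_polymorphic %||% TRUE,
                       is_targeted = TRUE, stringsAsFactors = FALSE)
    if (!is.null(bonus) && nrow(bonus) > 0) {
      loci <- rbind(loci, data.frame(contig = bonus$contig,
                                     snp_pos = bonus$pos,
                                     polymorphic = TRUE, is_targeted = FALSE,
                                     stringsAsFactors = FALSE))
    }
    n <- nrow(loci)
    chr_i <- sample(seq_len(n_chromosomes), n, replace = TRUE)
    pos <- runif(n, 0, chrs$length_cM[chr_i])
    loci$chromosome <- chrs$name[chr_i]
    loci$position_cM <- pos
    ## physical position: monotone in cM with multiplicative jitter
    loci$position_bp <- round(pos * mb_per_cM * 1e6 *
                                exp(rnorm(n, 0, 0.02))) + 1
    o <- order(chr_i, pos)
    loci <- loci[o, ]
    ## enforce strict bp monotonicity within chromosome
    for (chr in chrs$name) {
      idx <- which(loci$chromosome == chr)
      if (length(idx) > 1)
        loci$position_bp[idx] <- cummax(loci$position_bp[idx]) +
          seq_along(idx)
    }
    map_spec(chrs, loci)
  })
}

#' Expected residual heterozygosity after selfing
#'
#' The per-locus heterozygote frequency expected after `generations`
#' rounds of selfing from an F1, (1/2)^g in the large-population limit:
#' 1.5625% for the default six rounds.
#'
#' @param generations Number of selfing rounds (>= 0).
#' @return Expected heterozygote frequency in [0, 1].
#' @export
expected_het_frequency <- function(generations = 6L) {
  stopifnot(generations >= 0)
  0.5^generations
}

## One meiotic gamete for one chromosome: crossovers as a Poisson process
## on the cM scale (Haldane, no interference).
gamete <- function(hap1, hap2, pos_cM, len_cM) {
  n_xo <- rpois(1, len_cM / 100)
  first <- sample(1:2, 1)
  if (n_xo == 0) return(if (first == 1) hap1 else hap2)
  xo <- sort(runif(n_xo, 0, len_cM))
  seg <- findInterval(pos_cM, xo)
  cur <- (first - 1L + seg) %% 2    # 0 -> hap1, 1 -> hap2
  ifelse(cur == 0L, hap1, hap2)
}

#' Simulate a selfed RIL population
#'
#' Starts from the F1 of a biparental cross (heterozygous at every locus)
#' and applies `generations` rounds of selfing by single-seed descent.
#' Each generation, two gametes are drawn per line; crossovers follow a
#' no-interference Poisson process on the cM scale.  After g rounds the
#' expected residual heterozygosity is (1/2)^g per locus (1.5625% for the
#' default g = 6).
#'
#' @param map_spec A [map_spec()] object (truth).
#' @param n_individuals Number of RILs (>= 1).
#' @param generations Number of selfing rounds from the F1 (>= 1,
#'   default 6).
#' @param seed Integer seed.
#' @return An object of class `sim_truth`: list with `genotypes` (loci x
#'   individuals character matrix, "A" = Dic2 homozygote, "B" = Silur
#'   homozygote, "H" = residual heterozygote; monomorphic loci are all
#'   "A"), `map_spec`, `generations`.
#' @export
simulate_ril_population <- function(map_spec, n_individuals, generations = 6L,
                                    seed = 1L) {
  stopifnot(inherits(map_spec, "map_spec"))
  if (n_individuals < 1) stop_arg("n_individuals must be >= 1")
  if (generations < 1) stop_arg("generations must be >= 1")
  loci <- map_spec$loci
  chrs <- map_spec$chromosomes
  with_seed(seed, {
    geno <- matrix("A", nrow = nrow(loci), ncol = n_individuals,
                   dimnames = list(marker_name(loci$contig,
                                               locus_positions(loci)), NULL))
    for (ci in seq_len(nrow(chrs))) {
      idx <- which(loci$chromosome == chrs$name[ci])
      if (!length(idx)) next
      pos <- loci$position_cM[idx]
      len <- chrs$length_cM[ci]
      m <- length(idx)
      for (ind in seq_len(n_individuals)) {
        h1 <- rep(0L, m); h2 <- rep(1L, m)    # F1
        for (g in seq_len(generations)) {
          n1 <- gamete(h1, h2, pos, len)
          n2 <- gamete(h1, h2, pos, len)
          h1 <- n1; h2 <- n2
        }
        s <- h1 + h2
        geno[idx, ind] <- c("A", "H", "B")[s + 1L]
      }
    }
    geno[!loci$polymorphic, ] <- "A"
    colnames(geno) <- sprintf("RIL%03d", seq_len(n_individuals))
    structure(list(genotypes = geno, map_spec = map_spec,
                   generations = as.integer(generations)),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  g <- x$genotypes
  cat("Simulated RIL population:", ncol(g), "lines x", nrow(g), "loci (",
      x$generations, "selfing rounds )\n")
  cat("  heterozygote frequency:",
      signif(mean(g == "H"), 3), "\n")
  invisible(x)
}

#' Simulate capture read counts
#'
#' Draws per-locus, per-individual allele read counts under a
#' [coverage_model()]: per-locus lognormal capture efficiency scaled by
#' bait dose (4-bait loci get twice the 2-bait mean), negative-binomial
#' per-individual depth, a fraction of loci failing capture entirely, and
#' allele counts split by true genotype with `sequencing_error` cross-talk.
#' A set of microsatellite sink contigs absorbs `sink_read_fraction` of
#' the total read budget; the budget accounting (targeted + sink = total)
#' is returned exactly.
#'
#' @param truth A `sim_truth` object.
#' @param model A [coverage_model()].
#' @param seed Integer seed.
#' @return List of class `capture_sim`: `counts` (long data.frame: locus,
#'   individual, reads_a, reads_b), `sink` (contig, reads), `total_reads`,
#'   `failed_loci` (character).
#' @export
simulate_capture_readcounts <- function(truth, model = coverage_model(),
                                        seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(model, "coverage_model"))
  loci <- truth$map_spec$loci
  geno <- truth$genotypes
  n_loc <- nrow(loci); n_ind <- ncol(geno)
  with_seed(seed, {
    eff <- exp(rnorm(n_loc, 0, model$locus_log_sd))
    mu <- model$mean_depth * (loci$bait_count / 2) * eff
    mu[!loci$is_targeted] <- mu[!loci$is_targeted] * model$bonus_depth_factor
    failed <- runif(n_loc) < model$capture_failure_rate
    mu[failed] <- 0
    depth <- matrix(rnbinom(n_loc * n_ind, mu = rep(mu, n_ind),
                            size = model$overdispersion),
                    nrow = n_loc, ncol = n_ind)
    g <- as.vector(geno)
    d <- as.vector(depth)
    err <- model$sequencing_error
    b <- integer(length(d))
    isA <- g == "A"; isB <- g == "B"; isH <- g == "H"
    b[isA] <- rbinom(sum(isA), d[isA], err)
    b[isB] <- d[isB] - rbinom(sum(isB), d[isB], err)
    b[isH] <- rbinom(sum(isH), d[isH], 0.5)
    a <- d - b
    mk <- marker_name(loci$contig, locus_positions(loci))
    counts <- data.frame(
      locus = rep(mk, n_ind),
      contig = rep(loci$contig, n_ind),
      individual = rep(colnames(geno), each = n_loc),
      is_targeted = rep(loci$is_targeted, n_ind),
      reads_a = a, reads_b = b, stringsAsFactors = FALSE)
    total_target <- sum(d)
    f <- model$sink_read_fraction
    k <- model$sink_contig_count
    sink_total <- if (f > 0 && f < 1 && k > 0)
      round(total_target * f / (1 - f)) else 0
    sink <- if (k > 0 && sink_total > 0) {
      w <- rgamma(k, shape = 1)
      data.frame(contig = sprintf("sink%02d", seq_len(k)),
                 reads = as.vector(rmultinom(1, sink_total, w)),
                 stringsAsFactors = FALSE)
    } else data.frame(contig = character(), reads = integer())
    structure(list(counts = counts, sink = sink,
                   total_reads = total_target + sum(sink$reads),
                   failed_loci = loci$contig[failed]),
              class = "capture_sim")
  })
}

## Marker position used in names: for synthetic loci the within-contig SNP
## position is not tracked in map_spec; use 1-based bp order id instead.
locus_positions <- function(loci) {
  if (!is.null(loci$snp_pos)) loci$snp_pos else rep(1L, nrow(loci))
}

#' Write synthetic reference artifacts to disk
#'
#' Writes contigs as FASTA (via Biostrings), the exon annotation as a
#' 4-column tab file (contig, exon_start, exon_end, 1-based inclusive) and
#' the parental SNP table as CSV (truth columns dropped).
#'
#' @param ref Output of [generate_reference()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "contigs.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), fa)
  ex <- file.path(dir, "exons.tsv")
  write.table(cbind(ref$exons, strand = "+"), ex, sep = "\t",
              quote = FALSE, row.names = FALSE)
  snp <- file.path(dir, "snps.csv")
  pub <- ref$snps[, c("contig", "pos", "allele_dic2", "allele_silur", "origin")]
  names(pub)[2] <- "pos_1based"
  write.csv(pub, snp, row.names = FALSE, quote = FALSE)
  invisible(c(fasta = fa, exons = ex, snps = snp))
}
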