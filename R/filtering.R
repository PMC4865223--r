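## Quality-filter cascade: Fis, completeness, Nei's expected
## heterozygosity, per-contig de-duplication, and the full recovery
## accounting.

#' Filter thresholds for the SNP cleaning cascade
#'
#' @param fis_min Minimum inbreeding coefficient; loci must have
#'   Fis strictly above this (default 0.8).
#' @param n_genotyped_min Minimum genotyped individuals (default 100).
#' @param he_min Minimum Nei expected heterozygosity, inclusive
#'   (default 0.34).
#' @param depth_targeted,depth_bonus Calling depth thresholds carried for
#'   provenance (defaults 2 and 4).
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(fis_min = 0.8, n_genotyped_min = 100L,
                              he_min = 0.34, depth_targeted = 2L,
                              depth_bonus = 4L) {
  if (he_min < 0 || he_min > 0.5) stop_arg("he_min must lie in [0, 0.5]")
  if (fis_min < 0 || fis_min > 1) stop_arg("fis_min must lie in [0, 1]")
  structure(list(fis_min = fis_min,
                 n_genotyped_min = as.integer(n_genotyped_min),
                 he_min = he_min, depth_targeted = as.integer(depth_targeted),
                 depth_bonus = as.integer(depth_bonus)),
            class = "filter_thresholds")
}

allele_freq_a <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (!length(obs)) return(NA_real_)
  ## each H contributes half an allele to each class
  (sum(obs == "A") + 0.5 * sum(obs == "H")) / length(obs)
}

#' Nei's expected heterozygosity of a biallelic locus
#'
#' He = 2pq with p the A-allele frequency among non-missing calls
#' (heterozygotes contribute half an allele to each class).  No
#' small-sample correction is applied.
#'
#' @param calls Character vector of "A"/"B"/"H"/NA.
#' @return He in [0, 0.5].
#' @export
nei_he <- function(calls) {
  p <- allele_freq_a(calls)
  if (is.na(p)) stop_arg("cannot compute He: all calls missing")
  2 * p * (1 - p)
}

#' Inbreeding coefficient Fis of a locus
#'
#' Fis = 1 - Ho/He with Ho the observed heterozygote frequency among
#' non-missing calls.  Undefined (NA) when He = 0 (the locus is
#' monomorphic).
#'
#' @param calls Character vector of "A"/"B"/"H"/NA.
#' @return Fis, or NA when He = 0.
#' @export
fis <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (!length(obs)) stop_arg("cannot compute Fis: all calls missing")
  he <- nei_he(calls)
  if (he == 0) return(NA_real_)
  ho <- mean(obs == "H")
  1 - ho / he
}

#' Per-locus filter statistics
#'
#' @param genotypes Loci x individuals call matrix.
#' @return data.frame: locus, n_genotyped, p (A-allele frequency), He,
#'   Ho, Fis.
#' @export
locus_stats <- function(genotypes) {
  n <- rowSums(!is.na(genotypes))
  nA <- rowSums(genotypes == "A", na.rm = TRUE)
  nH <- rowSums(genotypes == "H", na.rm = TRUE)
  p <- ifelse(n > 0, (nA + 0.5 * nH) / n, NA_real_)
  he <- 2 * p * (1 - p)
  ho <- ifelse(n > 0, nH / n, NA_real_)
  fis <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  data.frame(locus = rownames(genotypes), n_genotyped = n, p = p,
             He = he, Ho = ho, Fis = fis, stringsAsFactors = FALSE,
             row.names = NULL)
}

passes_filters <- function(stats, thresholds) {
  with(stats, !is.na(Fis) & Fis > thresholds$fis_min &
         !is.na(He) & He >= thresholds$he_min &
         n_genotyped >= thresholds$n_genotyped_min)
}

#' Apply the quality-filter cascade
#'
#' ER loci (targeted, segregating) and bonus loci are filtered by the
#' conjunction Fis > `fis_min`, He >= `he_min` and at least
#' `n_genotyped_min` genotyped individuals.  Bonus loci are then
#' de-duplicated per contig ([dedupe_per_contig()]) and the full recovery
#' accounting assembled.
#'
#' @param genotypes Targeted-locus call matrix.
#' @param classifications Output of [classify_loci()] for the same loci.
#' @param thresholds A [filter_thresholds()] object.
#' @param bonus Optional output of [discover_bonus_snps()].
#' @return List with `er_clean` (locus names), `bonus_clean`,
#'   `bonus_kept` (one per contig, off-target contigs only), `stats`,
#'   `accounting` (see [snp_accounting()]).
#' @export
apply_filters <- function(genotypes, classifications,
                          thresholds = filter_thresholds(), bonus = NULL) {
  stopifnot(identical(rownames(genotypes), classifications$locus))
  stats <- locus_stats(genotypes)
  er <- classifications$status == "ER"
  er_clean <- stats$locus[er & passes_filters(stats, thresholds)]

  bonus_clean <- character(0)
  bonus_kept <- character(0)
  n_bonus_on_target <- 0L
  if (!is.null(bonus) && nrow(bonus$records) > 0) {
    bstats <- locus_stats(bonus$genotypes)
    bpass <- passes_filters(bstats, thresholds)
    bonus_clean <- bstats$locus[bpass]
    rec <- bonus$records[bonus$records$locus %in% bonus_clean, , drop = FALSE]
    n_bonus_on_target <- sum(rec$on_targeted_contig)
    bonus_kept <- dedupe_per_contig(rec, bstats)
  }
  counts <- table(factor(classifications$status,
                         levels = c("not_captured", "monomorphic",
                                    "het_only", "ER")))
  acc <- snp_accounting(list(
    targeted = nrow(genotypes),
    not_captured = unname(counts["not_captured"]),
    monomorphic = unname(counts["monomorphic"]),
    het_only = unname(counts["het_only"]),
    er_clean = length(er_clean),
    bonus_clean = length(bonus_clean),
    bonus_on_targeted_contig = n_bonus_on_target,
    bonus_one_per_contig = length(bonus_kept)))
  list(er_clean = er_clean, bonus_clean = bonus_clean,
       bonus_kept = bonus_kept, stats = stats, accounting = acc)
}

#' Keep one bonus SNP per off-target contig
#'
#' Bonus markers on targeted contigs are discarded (they are redundant
#' with the targeted SNP through strong linkage disequilibrium); among the
#' rest exactly one marker per contig is kept.  Tie-break: most genotyped
#' individuals, then highest He, then smallest position in the marker
#' name.
#'
#' @param records Bonus records (locus, contig, on_targeted_contig), e.g.
#'   from [discover_bonus_snps()].
#' @param stats Optional [locus_stats()] rows for the same loci (used for
#'   the tie-break); without it the tie-break is by name.
#' @return Character vector of kept locus names.
#' @export
dedupe_per_contig <- function(records, stats = NULL) {
  rec <- records[!records$on_targeted_contig, , drop = FALSE]
  if (nrow(rec) == 0) return(character(0))
  if (!is.null(stats)) {
    i <- match(rec$locus, stats$locus)
    rec$n_genotyped <- stats$n_genotyped[i]
    rec$He <- stats$He[i]
  } else {
    rec$n_genotyped <- 0L
    rec$He <- 0
  }
  pos <- suppressWarnings(as.integer(sub("^.*@", "", rec$locus)))
  pos[is.na(pos)] <- .Machine$integer.max
  o <- order(rec$contig, -rec$n_genotyped, -rec$He, pos, rec$locus)
  rec <- rec[o, , drop = FALSE]
  rec$locus[!duplicated(rec$contig)]
}

#' Capture recovery accounting
#'
#' Derives the complete bookkeeping of a capture experiment from its
#' primary category counts: recovered (ER) loci, clean sets, bonus
#' de-duplication and the headline recovery ratios.  Identities are
#' enforced: targeted = not_captured + monomorphic + het_only + ER, and
#' total_for_map = er_clean + bonus_one_per_contig.
#'
#' @param counts Named list/vector with (a subset of): `targeted` (or
#'   `targeted_ds` + `targeted_epo`), `not_captured`, `monomorphic`,
#'   `het_only`, `er_clean`, `bonus_clean`, `bonus_on_targeted_contig`,
#'   `bonus_one_per_contig`, and optionally `snps_available_ds`,
#'   `snps_available_bwr` (discovery-panel sizes).
#' @return List of class `snp_accounting` with all category counts, the
#'   derived totals (`er`, `bonus_untargeted`, `total_clean`,
#'   `total_for_map`, `snps_available`) and percentages
#'   (`pct_not_captured`, `pct_clean_of_targeted`,
#'   `pct_clean_of_polymorphic` -- the latter uses the DS-polymorphic
#'   target count when `targeted_ds` is given, else targets minus
#'   monomorphic EPO loci).
#' @export
snp_accounting <- function(counts) {
  counts <- as.list(counts)
  num <- function(x) if (is.null(counts[[x]])) NA_real_ else as.numeric(counts[[x]])
  targeted <- if (!is.null(counts$targeted)) num("targeted") else
    num("targeted_ds") + num("targeted_epo")
  not_captured <- num("not_captured"); mono <- num("monomorphic")
  het_only <- num("het_only")
  er <- targeted - not_captured - mono - het_only
  bonus_clean <- num("bonus_clean")
  bonus_on_tc <- num("bonus_on_targeted_contig")
  bonus_untargeted <- bonus_clean - bonus_on_tc
  er_clean <- num("er_clean")
  bonus_kept <- num("bonus_one_per_contig")
  total_clean <- er_clean + bonus_clean
  total_for_map <- er_clean + bonus_kept
  snps_available <- if (!is.null(counts$snps_available_ds))
    num("snps_available_ds") + num("snps_available_bwr") else NA_real_
  polymorphic_targets <- if (!is.null(counts$targeted_ds)) num("targeted_ds")
    else targeted - mono
  out <- list(
    snps_available = snps_available,
    targeted = targeted, not_captured = not_captured,
    monomorphic = mono, het_only = het_only, er = er,
    er_clean = er_clean, bonus_clean = bonus_clean,
    bonus_on_targeted_contig = bonus_on_tc,
    bonus_untargeted = bonus_untargeted,
    bonus_one_per_contig = bonus_kept,
    total_clean = total_clean, total_for_map = total_for_map,
    pct_not_captured = round(100 * not_captured / targeted),
    pct_er = round(100 * er / targeted),
    pct_clean_of_targeted = round(100 * er_clean / targeted),
    pct_clean_of_polymorphic = round(100 * er_clean / polymorphic_targets))
  structure(out, class = "snp_accounting")
}

#' @export
print.snp_accounting <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", format(v, big.mark = ","))
  cat("Capture recovery accounting\n")
  if (!is.na(x$snps_available))
    cat("  SNPs available (discovery):", fmt(x$snps_available), "\n")
  cat("  Targeted SNPs:            ", fmt(x$targeted), "\n")
  cat("    Not captured:           ", fmt(x$not_captured),
      sprintf("(%s%%)", fmt(x$pct_not_captured)), "\n")
  cat("    Captured but monomorphic:", fmt(x$monomorphic), "\n")
  cat("    Heterozygote state only:", fmt(x$het_only), "\n")
  cat("    ER (recovered):         ", fmt(x$er),
      sprintf("(%s%%)", fmt(x$pct_er)), "\n")
  cat("    ER clean:               ", fmt(x$er_clean),
      sprintf("(%s%% of targets, %s%% of polymorphic targets)",
              fmt(x$pct_clean_of_targeted), fmt(x$pct_clean_of_polymorphic)),
      "\n")
  cat("  Bonus clean:              ", fmt(x$bonus_clean), "\n")
  cat("    On untargeted contigs:  ", fmt(x$bonus_untargeted), "\n")
  cat("    Kept (one per contig):  ", fmt(x$bonus_one_per_contig), "\n")
  cat("  SNPs for the map:         ", fmt(x$total_for_map), "\n")
  invisible(x)
}

#' Write an accounting table as CSV
#'
#' @param acc A [snp_accounting()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_accounting <- function(acc, path) {
  df <- data.frame(category = names(unclass(acc)),
                   count = unlist(unclass(acc), use.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
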