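## End-to-end orchestration on synthetic data, plus map summary tables.

#' Summarise per-chromosome map features
#'
#' Computes, per chromosome: marker count, map length (position of the
#' last marker, cM), mean inter-marker distance (length / (count - 1),
#' the mean adjacent spacing),
#' biggest adjacent gap (between unique positions) and the number of
#' unique positions (bins).
#'
#' @param gmap A `genetic_map` object or a map data.frame (`marker`,
#'   `chromosome`, `position_cM`).
#' @return data.frame with one row per chromosome plus the aggregate
#'   rows of [summarize_map_features()].
#' @export
summarize_map <- function(gmap) {
  map <- if (inherits(gmap, "genetic_map")) gmap$map else as.data.frame(gmap)
  rows <- lapply(split(map, map$chromosome), function(mm) {
    pos <- sort(mm$position_cM)
    upos <- unique(round(pos, 6))
    data.frame(chromosome = mm$chromosome[1],
               snps = nrow(mm),
               length_cM = max(pos),
               mean_distance_cM = if (nrow(mm) > 1)
                 max(pos) / (nrow(mm) - 1) else NA_real_,
               biggest_gap_cM = if (length(upos) > 1) max(diff(upos)) else 0,
               unique_positions = length(upos),
               stringsAsFactors = FALSE)
  })
  per_chr <- do.call(rbind, rows)
  rownames(per_chr) <- NULL
  summarize_map_features(per_chr)
}

#' Aggregate per-chromosome map features
#'
#' Appends Mean/Total rows and, when chromosome names carry genome
#' letters (1A, 1B, ...), per-genome means and totals, to a table of
#' per-chromosome map features.
#'
#' @param per_chr data.frame with columns `chromosome`, `snps`,
#'   `length_cM` and optionally `mean_distance_cM`, `biggest_gap_cM`,
#'   `unique_positions`.
#' @return The input with aggregate rows appended (`chromosome` set to
#'   "Mean", "Total", "Mean A", "Total A", ...).
#' @export
summarize_map_features <- function(per_chr) {
  per_chr <- as.data.frame(per_chr)
  stopifnot(all(c("chromosome", "snps", "length_cM") %in% names(per_chr)))
  if (is.null(per_chr$mean_distance_cM))
    per_chr$mean_distance_cM <- per_chr$length_cM / (per_chr$snps - 1)
  numcols <- setdiff(names(per_chr), "chromosome")
  agg <- function(rows, label, fun) {
    out <- per_chr[1, , drop = FALSE]
    out$chromosome <- label
    for (cc in numcols) out[[cc]] <- fun(per_chr[[cc]][rows])
    ## a mean distance is re-derived, not averaged, for totals
    if (identical(fun, sum)) out$mean_distance_cM <- NA_real_
    out
  }
  n <- nrow(per_chr)
  res <- rbind(per_chr,
               agg(seq_len(n), "Mean", mean),
               agg(seq_len(n), "Total", sum))
  genome <- ifelse(grepl("[AB]$", per_chr$chromosome),
                   sub("^.*([AB])$", "\\1", per_chr$chromosome), NA)
  for (g in c("A", "B")) {
    rows <- which(!is.na(genome) & genome == g)
    if (length(rows)) {
      res <- rbind(res,
                   agg(rows, paste("Mean", g), mean),
                   agg(rows, paste("Total", g), sum))
    }
  }
  rownames(res) <- NULL
  res
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()].
#' Any stochastic stage requires a seed.
#'
#' @param seed Master seed (required).
#' @param n_contigs Number of targeted contigs to simulate.
#' @param n_individuals RIL population size (default 135).
#' @param generations Selfing rounds (default 6).
#' @param n_chromosomes,chr_length_cM True map shape.
#' @param coverage A [coverage_model()].
#' @param thresholds A [filter_thresholds()].
#' @param lod_min,rf_max,min_shared,min_group,n_iter,t0 Mapping
#'   parameters (see [build_genetic_map()]).
#' @param homeolog_fraction,microsat_fraction,epo_fraction,
#'   epo_monomorphic_fraction Reference generator fractions.
#' @param out_dir Output directory, or NULL to skip writing files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, n_contigs = 1400L, n_individuals = 135L,
                            generations = 6L, n_chromosomes = 14L,
                            chr_length_cM = 150,
                            coverage = coverage_model(),
                            thresholds = filter_thresholds(),
                            lod_min = 7, rf_max = 0.14, min_shared = 30L,
                            min_group = 3L, n_iter = 30000L, t0 = 5,
                            homeolog_fraction = 0.1,
                            microsat_fraction = 0.02,
                            epo_fraction = 1888 / 6240,
                            epo_monomorphic_fraction = 768 / 1888,
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop_arg("a seed is required: the pipeline has stochastic stages")
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              n_individuals = as.integer(n_individuals),
              generations = as.integer(generations),
              n_chromosomes = as.integer(n_chromosomes),
              chr_length_cM = chr_length_cM, coverage = coverage,
              thresholds = thresholds, lod_min = lod_min, rf_max = rf_max,
              min_shared = as.integer(min_shared),
              min_group = as.integer(min_group),
              n_iter = as.integer(n_iter), t0 = t0,
              homeolog_fraction = homeolog_fraction,
              microsat_fraction = microsat_fraction,
              epo_fraction = epo_fraction,
              epo_monomorphic_fraction = epo_monomorphic_fraction,
              out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv1a_hash(paste(deparse(cfg), collapse = ""))
}

provenance_header <- function(config) {
  c(sprintf("# capmapr %s", as.character(packageVersion("capmapr"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config: %s", config_hash(config)))
}

write_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a provenance header
#'
#' @param path A CSV written by [run_pipeline()].
#' @return List with `version`, `seed`, `config_hash`.
#' @export
read_provenance <- function(path) {
  lines <- readLines(path, n = 3)
  list(version = sub("^# capmapr ", "", lines[1]),
       seed = as.integer(sub("^# seed: ", "", lines[2])),
       config_hash = sub("^# config: ", "", lines[3]))
}

log_stage <- function(level, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full synthetic capture-to-map pipeline
#'
#' Stages: reference generation, bait design (with microsatellite
#' screen), true-map layout, RIL simulation, capture read-count
#' simulation, genotype calling (targeted depth 2, bonus depth 4), locus
#' classification, the filter cascade with accounting, linkage-map
#' construction, and validation against the true positions.  Re-running
#' with an identical configuration reproduces identical outputs; every
#' CSV written carries a provenance header (version, seed, config hash).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging (default FALSE).
#' @return List of class `pipeline_result`: `reference`, `baits`,
#'   `truth`, `readcounts`, `genotypes`, `classifications`, `filters`,
#'   `accounting`, `genetic_map`, `validation`, `truth_positions`,
#'   `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  note <- if (quiet) function(...) invisible() else
    function(...) log_stage("info", ...)
  stage <- function(name, expr) {
    note("stage: ", name)
    tryCatch(expr, error = function(e)
      stop_arg("pipeline stage '", name, "' failed: ",
               conditionMessage(e)))
  }
  seeds <- lapply(1:6, function(i) derive_seed(config$seed, i))

  ref <- stage("reference", generate_reference(
    config$n_contigs, seed = seeds[[1]],
    homeolog_fraction = config$homeolog_fraction,
    microsat_fraction = config$microsat_fraction,
    epo_fraction = config$epo_fraction,
    epo_monomorphic_fraction = config$epo_monomorphic_fraction))

  design <- stage("bait_design", {
    sel <- select_targets(ref$snps, ref$exons)
    design_bait_set(sel, ref$contigs)
  })

  truth <- stage("simulate", {
    ms <- make_map_spec(ref, config$n_chromosomes, config$chr_length_cM,
                        seed = seeds[[2]])
    bc <- design$bait_counts[ms$loci$contig]
    ms$loci$bait_count <- ifelse(is.na(bc), 2L, pmin(as.integer(bc), 4L))
    ms$loci$bait_count[!(ms$loci$bait_count %in% c(2L, 4L))] <- 2L
    simulate_ril_population(ms, config$n_individuals, config$generations,
                            seed = seeds[[3]])
  })

  rc <- stage("capture", simulate_capture_readcounts(
    truth, config$coverage, seed = seeds[[4]]))

  calls <- stage("call", {
    tgt <- rc$counts[rc$counts$is_targeted, ]
    g <- call_genotype_matrix(tgt, min_depth = config$thresholds$depth_targeted)
    bonus_counts <- rc$counts[!rc$counts$is_targeted, ]
    bonus <- if (nrow(bonus_counts)) {
      discover_bonus_snps(bonus_counts,
                          targeted_contigs = unique(tgt$contig),
                          min_depth = config$thresholds$depth_bonus)
    } else NULL
    list(genotypes = g, bonus = bonus)
  })

  cls <- stage("classify", classify_loci(calls$genotypes))

  flt <- stage("filter", apply_filters(calls$genotypes, cls,
                                       config$thresholds, calls$bonus))

  gmap <- stage("map", {
    keep <- c(flt$er_clean, flt$bonus_kept)
    g <- rbind(calls$genotypes[intersect(rownames(calls$genotypes),
                                         flt$er_clean), , drop = FALSE],
               if (!is.null(calls$bonus))
                 calls$bonus$genotypes[intersect(rownames(calls$bonus$genotypes),
                                                 flt$bonus_kept), ,
                                       drop = FALSE])
    truth_pos <- truth$map_spec$loci
    assignments <- data.frame(
      marker = marker_name(truth_pos$contig, locus_positions(truth_pos)),
      chromosome = truth_pos$chromosome,
      position_bp = truth_pos$position_bp,
      position_cM_putative = truth_pos$position_cM,
      stringsAsFactors = FALSE)
    list(map = build_genetic_map(g, assignments, config$lod_min,
                                 config$rf_max, config$min_shared,
                                 config$min_group, seed = seeds[[5]],
                                 n_iter = config$n_iter, t0 = config$t0),
         assignments = assignments)
  })

  val <- stage("validate", validate_map(gmap$map, gmap$assignments))

  if (!is.null(config$out_dir)) stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hd <- provenance_header(config)
    write_reference(ref, config$out_dir)
    if (!is.null(design$baits))
      write_baits(design$baits, file.path(config$out_dir, "baits.fasta"))
    gt <- calls$genotypes; gt[is.na(gt)] <- "-"
    write_with_header(data.frame(marker = rownames(gt), gt,
                                 check.names = FALSE),
                      file.path(config$out_dir, "genotypes.csv"), hd)
    write_with_header(as.data.frame(summarize_map(gmap$map)),
                      file.path(config$out_dir, "map_summary.csv"), hd)
    write_with_header(gmap$map$map,
                      file.path(config$out_dir, "map.csv"), hd)
    write_with_header(
      data.frame(category = names(unclass(flt$accounting)),
                 count = unlist(unclass(flt$accounting),
                                use.names = FALSE)),
      file.path(config$out_dir, "accounting.csv"), hd)
  })

  structure(list(reference = ref, baits = design, truth = truth,
                 readcounts = rc, genotypes = calls$genotypes,
                 bonus = calls$bonus, classifications = cls,
                 filters = flt, accounting = flt$accounting,
                 genetic_map = gmap$map, assignments = gmap$assignments,
                 validation = val, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("capmapr pipeline result (seed ", x$config$seed, ")\n", sep = "")
  print(x$accounting)
  print(x$genetic_map)
  invisible(x)
}
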