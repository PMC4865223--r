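## Map validation against putative physical/genetic positions: rank
## correlations, cubic genetic-vs-physical regression with outlier
## tagging, translocation-block detection and segment recombination
## rates.

#' Per-chromosome Spearman correlation of map vs putative positions
#'
#' @param map Map data.frame (`marker`, `chromosome`, `position_cM`).
#' @param positions data.frame with `marker` and one of `position_bp` /
#'   `position_cM_putative` (choose via `column`); markers missing the
#'   coordinate are excluded.
#' @param column Name of the putative coordinate column in `positions`.
#' @param min_markers Minimum usable markers per chromosome (default 3);
#'   chromosomes below it get NA and a flag.
#' @return data.frame: chromosome, n, rho, flagged.
#' @export
spearman_by_chromosome <- function(map, positions, column = "position_bp",
                                   min_markers = 3L) {
  stopifnot(column %in% names(positions))
  put <- positions[[column]][match(map$marker, positions$marker)]
  out <- lapply(split(seq_len(nrow(map)), map$chromosome), function(idx) {
    x <- map$position_cM[idx]; y <- put[idx]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_markers)
      data.frame(n = n, rho = NA_real_, flagged = TRUE)
    else
      data.frame(n = n,
                 rho = suppressWarnings(cor(x[ok], y[ok],
                                            method = "spearman")),
                 flagged = FALSE)
  })
  res <- do.call(rbind, out)
  data.frame(chromosome = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cubic genetic-vs-physical regression with outlier tagging
#'
#' Fits a least-squares polynomial (degree 3) of genetic position on
#' physical position and tags markers whose genetic position falls
#' outside the pointwise 95% band.  By default the band is a prediction
#' band (includes residual spread, appropriate for tagging individual
#' markers); `band = "confidence"` switches to the mean-response band.
#'
#' @param genetic_cM,physical_bp Numeric vectors (pairs with NA in
#'   either are dropped).
#' @param degree Polynomial degree (default 3).
#' @param level Band level (default 0.95).
#' @param band "prediction" (default) or "confidence".
#' @return List: `fit` (lm), `adj_r_squared`, `outlier` (logical over
#'   the input pairs, NA where unusable), `n`, `outlier_fraction`,
#'   `band` (data.frame x, fit, lwr, upr, sorted by x).
#' @export
polyfit_outliers <- function(genetic_cM, physical_bp, degree = 3L,
                             level = 0.95, band = c("prediction",
                                                    "confidence")) {
  band <- match.arg(band)
  ok <- !is.na(genetic_cM) & !is.na(physical_bp)
  n <- sum(ok)
  if (n < degree + 2) stop_arg("need at least degree + 2 markers")
  x <- physical_bp[ok]; y <- genetic_cM[ok]
  if (length(unique(x)) <= degree)
    stop_arg("degenerate design: too few distinct physical positions")
  ## centre and scale the regressor: raw cubic terms of bp-scale
  ## positions are numerically catastrophic
  xs <- (x - mean(x)) / stats::sd(x)
  df <- data.frame(xs = xs, y = y)
  fit <- lm(y ~ poly(xs, degree, raw = TRUE), data = df)
  pr <- suppressWarnings(predict(fit, interval = band, level = level))
  ## an (essentially) interpolating fit has no residual spread to tag
  ## against; declare no outliers rather than flag numerical noise
  sm <- suppressWarnings(summary(fit))
  if (sm$sigma <= 1e-8 * max(stats::sd(y), .Machine$double.eps)) {
    out_ok <- rep(FALSE, length(y))
  } else {
    out_ok <- y < pr[, "lwr"] | y > pr[, "upr"]
  }
  outlier <- rep(NA, length(genetic_cM))
  outlier[ok] <- out_ok
  o <- order(x)
  list(fit = fit, adj_r_squared = sm$adj.r.squared,
       outlier = outlier, n = n, outlier_fraction = mean(out_ok),
       band = data.frame(x = x[o], fit = pr[o, "fit"], lwr = pr[o, "lwr"],
                         upr = pr[o, "upr"]))
}

#' Detect translocation-like assignment blocks
#'
#' Scans each chromosome of an ordered map for maximal runs of at least
#' `min_block` consecutive assigned markers (adjacent gaps at most
#' `max_gap_cM`) whose putative chromosome is identical but
#' non-homeologous to the mapped chromosome.  Markers without an
#' assignment are skipped; markers assigned elsewhere break a run.
#'
#' @param map Map data.frame (`marker`, `chromosome`, `position_cM`),
#'   ordered within chromosome.
#' @param assignments data.frame `marker`, `chromosome`.
#' @param min_block Minimum run length (default 3).
#' @param max_gap_cM Maximum adjacent gap inside a run (default 10).
#' @return data.frame: mapped_chromosome, putative_chromosome, n_markers,
#'   start_cM, end_cM, markers (comma-separated).
#' @export
detect_translocation_blocks <- function(map, assignments, min_block = 3L,
                                        max_gap_cM = 10) {
  res <- list()
  put <- assignments$chromosome[match(map$marker, assignments$marker)]
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr & !is.na(put))
    idx <- idx[order(map$position_cM[idx])]
    if (!length(idx)) next
    pchr <- put[idx]
    pos <- map$position_cM[idx]
    hom <- homeolog_of(chr)
    foreign <- pchr != chr & (is.na(hom) | pchr != hom)
    run_start <- 1L
    flush <- function(s, e) {
      if (e - s + 1L >= min_block && foreign[s]) {
        res[[length(res) + 1L]] <<- data.frame(
          mapped_chromosome = chr, putative_chromosome = pchr[s],
          n_markers = e - s + 1L, start_cM = pos[s], end_cM = pos[e],
          markers = paste(map$marker[idx[s:e]], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_along(idx)[-1]) {
      same_run <- foreign[i] && foreign[i - 1L] &&
        pchr[i] == pchr[i - 1L] && (pos[i] - pos[i - 1L]) <= max_gap_cM
      if (!same_run) { flush(run_start, i - 1L); run_start <- i }
    }
    flush(run_start, length(idx))
  }
  if (!length(res))
    return(data.frame(mapped_chromosome = character(0),
                      putative_chromosome = character(0),
                      n_markers = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), markers = character(0)))
  do.call(rbind, res)
}

#' Recombination rate of a physical segment
#'
#' Genetic span (cM) of the markers inside a physical interval divided
#' by their physical span (Mb).
#'
#' @param genetic_cM,physical_bp Numeric vectors for one chromosome.
#' @param segment_bp Length-2 numeric: physical interval (bp,
#'   inclusive).
#' @return cM/Mb, or NA when fewer than 2 markers fall in the segment
#'   or the physical span is zero.
#' @export
segment_recomb_rate <- function(genetic_cM, physical_bp, segment_bp) {
  stopifnot(length(segment_bp) == 2)
  ok <- !is.na(genetic_cM) & !is.na(physical_bp) &
    physical_bp >= min(segment_bp) & physical_bp <= max(segment_bp)
  if (sum(ok) < 2) return(NA_real_)
  gspan <- diff(range(genetic_cM[ok]))
  pspan <- diff(range(physical_bp[ok])) / 1e6
  if (pspan == 0) return(NA_real_)
  gspan / pspan
}

#' Validate a genetic map against putative positions
#'
#' Convenience wrapper producing a validation report: per-chromosome
#' Spearman correlations (vs physical and, when available, putative
#' genetic positions), cubic-fit outlier tags and translocation blocks.
#'
#' @param gmap A `genetic_map` object or its `map` data.frame.
#' @param positions data.frame: `marker`, `chromosome`, `position_bp`,
#'   optionally `position_cM_putative`.
#' @param level Outlier band level (default 0.95).
#' @param min_block,max_gap_cM Passed to
#'   [detect_translocation_blocks()].
#' @return List of class `map_validation`: `spearman_physical`,
#'   `spearman_genetic` (or NULL), `outliers` (per-marker data.frame),
#'   `fits` (per-chromosome adj. R2), `blocks`.
#' @export
validate_map <- function(gmap, positions, level = 0.95, min_block = 3L,
                         max_gap_cM = 10) {
  map <- if (inherits(gmap, "genetic_map")) gmap$map else gmap
  sp_phys <- spearman_by_chromosome(map, positions, "position_bp")
  sp_gen <- if ("position_cM_putative" %in% names(positions))
    spearman_by_chromosome(map, positions, "position_cM_putative") else NULL
  bp <- positions$position_bp[match(map$marker, positions$marker)]
  outs <- list(); fits <- list()
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    res <- tryCatch(
      polyfit_outliers(map$position_cM[idx], bp[idx], level = level),
      error = function(e) NULL)
    if (is.null(res)) next
    fits[[chr]] <- data.frame(chromosome = chr,
                              adj_r_squared = res$adj_r_squared,
                              outlier_fraction = res$outlier_fraction,
                              stringsAsFactors = FALSE)
    outs[[chr]] <- data.frame(marker = map$marker[idx], chromosome = chr,
                              outlier = res$outlier,
                              stringsAsFactors = FALSE)
  }
  blocks <- detect_translocation_blocks(map, positions, min_block,
                                        max_gap_cM)
  structure(list(spearman_physical = sp_phys, spearman_genetic = sp_gen,
                 outliers = do.call(rbind, outs) %||%
                   data.frame(marker = character(0),
                              chromosome = character(0),
                              outlier = logical(0)),
                 fits = do.call(rbind, fits) %||%
                   data.frame(chromosome = character(0),
                              adj_r_squared = numeric(0),
                              outlier_fraction = numeric(0)),
                 blocks = blocks),
            class = "map_validation")
}

#' @export
print.map_validation <- function(x, ...) {
  cat("Map validation\n")
  cat("  median Spearman rho (physical):",
      round(median(x$spearman_physical$rho, na.rm = TRUE), 3), "\n")
  if (!is.null(x$spearman_genetic))
    cat("  median Spearman rho (genetic): ",
        round(median(x$spearman_genetic$rho, na.rm = TRUE), 3), "\n")
  if (nrow(x$fits))
    cat("  outlier fraction (cubic band): ",
        round(mean(x$fits$outlier_fraction), 3), "\n")
  cat("  translocation-like blocks:", nrow(x$blocks), "\n")
  invisible(x)
}
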