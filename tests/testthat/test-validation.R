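make_map_df <- function(pos, chr = "1A", markers = NULL) {
  data.frame(marker = markers %||% sprintf("m%03d", seq_along(pos)),
             chromosome = chr, position_cM = pos)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Spearman correlations behave on collinear and reversed maps", {
  pos <- seq(0, 90, by = 10)
  map <- make_map_df(pos)
  fwd <- data.frame(marker = map$marker, position_bp = pos * 1e6 + 7)
  expect_equal(spearman_by_chromosome(map, fwd)$rho, 1)
  rev <- data.frame(marker = map$marker, position_bp = rev(pos) * 1e6)
  expect_equal(spearman_by_chromosome(map, rev)$rho, -1)
  ## one transposed pair: classic sum-of-squared-rank-differences formula
  y <- pos; y[2:3] <- y[3:2]
  tp <- data.frame(marker = map$marker, position_bp = y)
  d2 <- sum((rank(pos) - rank(y))^2)
  n <- length(pos)
  expect_equal(spearman_by_chromosome(map, tp)$rho,
               1 - 6 * d2 / (n * (n^2 - 1)))
  ## invariance under strictly monotone transforms
  expect_equal(spearman_by_chromosome(map, within(fwd, position_bp <-
                                                    exp(position_bp / 1e8)))$rho, 1)
  ## fewer than 3 usable markers: flagged, no value
  short <- make_map_df(c(0, 5))
  out <- spearman_by_chromosome(short,
                                data.frame(marker = short$marker,
                                           position_bp = c(1, 2)))
  expect_true(out$flagged)
  expect_true(is.na(out$rho))
})

test_that("cubic fit tags no outliers on noise-free cubic data", {
  x <- seq(1, 100, length.out = 40) * 1e6
  y <- 1e-22 * x^3 + 2e-14 * x^2 + 1e-6 * x
  res <- polyfit_outliers(y, x)
  expect_equal(res$adj_r_squared, 1, tolerance = 1e-6)
  expect_false(any(res$outlier))
  expect_error(polyfit_outliers(y[1:4], x[1:4]), "degree")
  expect_error(polyfit_outliers(rep(1, 10), rep(5, 10)), "degenerate")
})

test_that("planted gross displacements are tagged, null rate is calibrated", {
  set.seed(91)
  n <- 300
  x <- sort(runif(n, 0, 800)) * 1e6
  sig <- 150 / (1 + exp(-(x / 1e6 - 400) / 120))   # sigmoid truth
  y <- sig + rnorm(n, 0, 4)
  planted <- sample(n, 5)
  y[planted] <- y[planted] + sample(c(-1, 1), 5, TRUE) * 60
  res <- polyfit_outliers(y, x)
  expect_gte(sum(res$outlier[planted]), 4)
  ## null data: false-tag rate near 5%
  y0 <- sig + rnorm(n, 0, 4)
  res0 <- polyfit_outliers(y0, x)
  p <- mean(res0$outlier)
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("translocation blocks respect size, gap and homeolog rules", {
  pos <- seq(0, 95, by = 5)
  map <- make_map_df(pos, chr = "7A")
  asg <- data.frame(marker = map$marker, chromosome = "7A")
  ## 11 consecutive markers putatively on 4A
  asg$chromosome[5:15] <- "4A"
  bl <- detect_translocation_blocks(map, asg)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$putative_chromosome, "4A")
  expect_equal(bl$n_markers, 11)
  ## an isolated swapped marker is not a block
  asg2 <- data.frame(marker = map$marker, chromosome = "7A")
  asg2$chromosome[8] <- "4A"
  expect_equal(nrow(detect_translocation_blocks(map, asg2)), 0)
  ## homeologous hits never form a block
  asg3 <- data.frame(marker = map$marker, chromosome = "7B")
  expect_equal(nrow(detect_translocation_blocks(map, asg3)), 0)
  ## a large gap splits a would-be block below min_block
  map2 <- make_map_df(c(0, 2, 30, 32), chr = "7A")
  asg4 <- data.frame(marker = map2$marker, chromosome = "4A")
  expect_equal(nrow(detect_translocation_blocks(map2, asg4,
                                                min_block = 3,
                                                max_gap_cM = 10)), 0)
})

test_that("block detection depends only on map order, not input order", {
  set.seed(92)
  pos <- seq(0, 95, by = 5)
  map <- make_map_df(pos, chr = "2B")
  asg <- data.frame(marker = map$marker, chromosome = "2B")
  asg$chromosome[10:14] <- "6A"
  ref <- detect_translocation_blocks(map, asg)
  perm <- sample(nrow(map))
  got <- detect_translocation_blocks(map[perm, ], asg[sample(nrow(asg)), ])
  expect_equal(got, ref)
})

test_that("segment recombination rates are span ratios", {
  ## 49.5 cM over 90 Mb
  gen <- c(0, 10, 49.5)
  phys <- c(0, 30, 90) * 1e6
  expect_equal(segment_recomb_rate(gen, phys, c(0, 90e6)), 0.55)
  expect_equal(segment_recomb_rate(c(5, 5), c(0, 50e6), c(0, 90e6)), 0)
  expect_true(is.na(segment_recomb_rate(5, 50e6, c(0, 90e6))))
  ## uniform 1 cM/Mb map recovers its rate
  set.seed(93)
  x <- sort(runif(200, 0, 100)) * 1e6
  g <- x / 1e6 + rnorm(200, 0, 0.3)
  expect_equal(segment_recomb_rate(g, x, c(10e6, 90e6)), 1,
               tolerance = 0.05)
})

test_that("validate_map assembles a coherent report", {
  tr <- sim_truth_fixture(n_markers = 90, n_chr = 3, n_ind = 135, seed = 95)
  g <- tr$genotypes
  loci <- tr$map_spec$loci
  i <- match(sub("@.*", "", rownames(g)), loci$contig)
  asg <- data.frame(marker = rownames(g), chromosome = loci$chromosome[i],
                    position_bp = loci$position_bp[i],
                    position_cM_putative = loci$position_cM[i])
  gm <- build_genetic_map(g, asg, seed = 96)
  v <- validate_map(gm, asg)
  expect_s3_class(v, "map_validation")
  expect_true(all(abs(v$spearman_physical$rho) <= 1, na.rm = TRUE))
  expect_true(all(v$outliers$marker %in% gm$map$marker))
  expect_gte(min(abs(v$spearman_physical$rho), na.rm = TRUE), 0.9)
})
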