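test_that("reference generation validates its inputs", {
  expect_error(generate_reference(0), "n_contigs")
  expect_error(generate_reference(10, exon_length_distribution = "big"),
               "distribution")
  expect_error(generate_reference(10, exon_length_distribution = c(500, 100)),
               "invalid exon length")
})

test_that("reference generation is reproducible and sized as requested", {
  r1 <- generate_reference(100, seed = 42)
  r2 <- generate_reference(100, seed = 42)
  expect_identical(r1, r2)
  r3 <- generate_reference(100, seed = 43)
  expect_false(identical(r1$contigs, r3$contigs))
  expect_equal(sum(!grepl("_h$", names(r1$contigs))), 100)
  expect_equal(nrow(r1$snps), 100)
  ## every SNP inside its exon, alleles distinct
  with(merge(r1$snps, r1$exons), {
    expect_true(all(pos >= exon_start & pos <= exon_end))
  })
  expect_true(all(r1$snps$allele_dic2 != r1$snps$allele_silur))
})

test_that("homeolog count follows its binomial design rate", {
  r <- generate_reference(1000, seed = 7, homeolog_fraction = 0.3)
  k <- sum(r$snps$has_homeolog)
  expect_lt(abs(k - 300), 3 * sqrt(1000 * 0.3 * 0.7))
  expect_equal(nrow(r$bonus_sites), k)
})

test_that("map_spec rejects inconsistent geometry", {
  chrs <- data.frame(name = "1A", length_cM = 100)
  expect_error(map_spec(chrs, data.frame(contig = "a", chromosome = "1A",
                                         position_cM = 120,
                                         position_bp = 1)),
               "outside chromosome length")
  expect_error(map_spec(chrs, data.frame(contig = c("a", "a"),
                                         chromosome = "1A",
                                         position_cM = c(1, 2),
                                         position_bp = c(1, 2))),
               "unique")
})

test_that("residual heterozygosity after g selfings matches (1/2)^g", {
  ## one locus per chromosome: loci are independent across chromosomes
  chrs <- data.frame(name = paste0("c", 1:14), length_cM = 100)
  loci <- data.frame(contig = sprintf("m%02d", 1:14),
                     chromosome = chrs$name, position_cM = 50,
                     position_bp = 1e6)
  ms <- map_spec(chrs, loci)
  for (g in c(1, 3, 6)) {
    tr <- simulate_ril_population(ms, 800, g, seed = 20 + g)
    p_hat <- mean(tr$genotypes == "H")
    p <- 0.5^g
    n <- length(tr$genotypes)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n),
              label = sprintf("het frequency at g=%d (%.4f)", g, p_hat))
  }
})

test_that("recombinant-line fractions follow the Haldane-Waddington limit", {
  for (d in c(1, 10, 50)) {
    chrs <- data.frame(name = "1A", length_cM = d + 20)
    loci <- data.frame(contig = c("a", "b"), chromosome = "1A",
                       position_cM = c(10, 10 + d),
                       position_bp = c(1, 2) * 1e6)
    tr <- simulate_ril_population(map_spec(chrs, loci), 3000, 6,
                                  seed = 30 + d)
    g <- tr$genotypes
    ok <- g[1, ] != "H" & g[2, ] != "H"
    R_hat <- mean(g[1, ok] != g[2, ok])
    r <- (1 - exp(-2 * d / 100)) / 2
    R <- 2 * r / (1 + 2 * r)
    expect_lt(abs(R_hat - R), 3 * sqrt(R * (1 - R) / sum(ok)),
              label = sprintf("R at d=%g (%.4f vs %.4f)", d, R_hat, R))
  }
})

test_that("fully linked loci never recombine and truth is seed-stable", {
  chrs <- data.frame(name = "1A", length_cM = 50)
  loci <- data.frame(contig = c("a", "b"), chromosome = "1A",
                     position_cM = c(25, 25), position_bp = c(1e6, 1e6 + 1))
  tr <- simulate_ril_population(map_spec(chrs, loci), 500, 6, seed = 5)
  expect_true(all(tr$genotypes[1, ] == tr$genotypes[2, ]))
  tr2 <- simulate_ril_population(map_spec(chrs, loci), 500, 6, seed = 5)
  expect_identical(tr$genotypes, tr2$genotypes)
})

test_that("capture simulation conserves the read budget and honours the model", {
  tr <- sim_truth_fixture(n_markers = 120, n_ind = 50)
  model <- coverage_model(sequencing_error = 0)
  rc <- simulate_capture_readcounts(tr, model, seed = 9)
  expect_identical(rc$total_reads,
                   sum(rc$counts$reads_a + rc$counts$reads_b) +
                     sum(rc$sink$reads))
  expect_equal(nrow(rc$sink), model$sink_contig_count)
  ## error-free: homozygous A individuals never show B reads
  isA <- as.vector(tr$genotypes) == "A"
  flat <- rc$counts[order(match(rc$counts$individual,
                                colnames(tr$genotypes)),
                          match(rc$counts$locus,
                                rownames(tr$genotypes))), ]
  expect_true(all(flat$reads_b[isA] == 0))
  ## failed loci have zero reads everywhere
  if (length(rc$failed_loci)) {
    failed_rows <- flat$contig %in% rc$failed_loci
    expect_true(all(flat$reads_a[failed_rows] == 0) &&
                  all(flat$reads_b[failed_rows] == 0))
  }
  rc2 <- simulate_capture_readcounts(tr, model, seed = 9)
  expect_identical(rc, rc2)
})

test_that("bait dose doubles coverage and sinks take their read share", {
  snps <- data.frame(contig = sprintf("c%04d", 1:600), pos = 1L,
                     truly_polymorphic = TRUE)
  ms <- make_map_spec(snps, n_chromosomes = 6, chr_length_cM = 150,
                      seed = 77)
  ms$loci$bait_count <- rep(c(2L, 4L), length.out = 600)
  tr <- simulate_ril_population(ms, 40, 6, seed = 78)
  rc <- simulate_capture_readcounts(tr, coverage_model(), seed = 79)
  d <- rc$counts$reads_a + rc$counts$reads_b
  bc <- ms$loci$bait_count[match(rc$counts$contig, ms$loci$contig)]
  per_locus <- tapply(d, rc$counts$contig, mean)
  cls <- ms$loci$bait_count[match(names(per_locus), ms$loci$contig)]
  m4 <- per_locus[cls == 4]; m2 <- per_locus[cls == 2]
  ratio <- mean(m4) / mean(m2)
  se <- ratio * sqrt(var(m4) / (length(m4) * mean(m4)^2) +
                       var(m2) / (length(m2) * mean(m2)^2))
  expect_lt(abs(ratio - 2), 3 * se)
  share <- sum(rc$sink$reads) / rc$total_reads
  expect_lt(abs(share - 0.42), 0.005)
})
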