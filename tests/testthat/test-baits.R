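make_contig <- function(len, seed = 1) {
  set.seed(seed)
  random_seq(len)
}

test_that("target selection enforces the exon-length and one-per-contig rules", {
  contig <- make_contig(600)
  exons <- data.frame(contig = c("k1", "k2", "k3", "k3", "k3"),
                      exon_start = c(10, 10, 10, 200, 400),
                      exon_end = c(128, 159, 140, 340, 520))
  snps <- data.frame(contig = c("k1", "k2", "k3", "k3", "k3"),
                     pos = c(60, 80, 60, 260, 450),
                     allele_dic2 = "A", allele_silur = "C", origin = "DS")
  sel <- select_targets(snps, exons)
  ## 119 bp exon dropped; 150 bp exon kept as type 3
  expect_false(any(sel$targets$contig == "k1"))
  expect_equal(sel$report$reason[1], "exon shorter than 120 bp")
  k2 <- sel$targets[sel$targets$contig == "k2", ]
  expect_equal(k2$layout_type, 3)
  ## three eligible SNPs on k3: exactly one retained, longest exon wins
  k3 <- sel$targets[sel$targets$contig == "k3", ]
  expect_equal(nrow(k3), 1)
  expect_equal(k3$pos, 260)  # the 141 bp exon beats the 121 bp exons
  expect_equal(sum(sel$report$kept), 2)  # k2 and one k3 SNP
})

test_that("SNPs outside their contig are rejected rows, not errors", {
  exons <- data.frame(contig = "k1", exon_start = 1, exon_end = 300)
  snps <- data.frame(contig = "k1", pos = 500,
                     allele_dic2 = "A", allele_silur = "C", origin = "DS")
  sel <- select_targets(snps, exons, contig_lengths = c(k1 = 300))
  expect_equal(nrow(sel$targets), 0)
  expect_match(sel$report$reason, "outside contig")
})

test_that("bait layouts have the right geometry", {
  seqc <- make_contig(600, seed = 3)
  t1 <- list(contig = "c", pos = 300, allele_dic2 = "A",
             allele_silur = "C", exon_start = 100, exon_end = 500,
             layout_type = 1, origin = "DS")
  b1 <- design_baits(t1, seqc)
  expect_equal(nrow(b1), 4)
  expect_equal(sum(!is.na(b1$snp_offset_in_bait)), 2)
  expect_true(all(nchar(b1$sequence) == 120))
  ## allele pair differs at exactly one position
  pair <- b1$sequence[!is.na(b1$snp_offset_in_bait)]
  expect_equal(sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]]),
               1)
  ## flanking baits never contain the SNP position
  fl <- b1[b1$allele_status == "flanking", ]
  expect_true(all(t1$pos < fl$start | t1$pos > fl$start + 119))
  ## combined coverage reaches at least 100 bp each side of the SNP
  covered <- unlist(Map(seq, b1$start, b1$start + 119))
  expect_true(all((t1$pos - 100):(t1$pos + 100) %in% covered))

  t2 <- within(as.data.frame(t1), layout_type <- 2)
  b2 <- design_baits(t2, seqc)
  expect_equal(nrow(b2), 2)
  expect_true(all(!is.na(b2$snp_offset_in_bait)))
  expect_true(all(b2$snp_offset_in_bait %in% c(40, 80)))

  ## type 3 in an exactly 120 bp exon: forced placement, identical coords
  t3 <- list(contig = "c", pos = 160, allele_dic2 = "A", allele_silur = "C",
             exon_start = 101, exon_end = 220, layout_type = 3,
             origin = "DS")
  b3 <- design_baits(t3, seqc)
  expect_equal(nrow(b3), 2)
  expect_equal(unique(b3$start), 101)
  expect_equal(sum(strsplit(b3$sequence[1], "")[[1]] !=
                     strsplit(b3$sequence[2], "")[[1]]), 1)

  ## every bait matches the contig except at the allele position
  for (i in seq_len(nrow(b1))) {
    ref <- substr(seqc, b1$start[i], b1$start[i] + 119)
    diffs <- which(strsplit(ref, "")[[1]] !=
                     strsplit(b1$sequence[i], "")[[1]])
    off <- b1$snp_offset_in_bait[i]
    if (is.na(off)) expect_equal(length(diffs), 0)
    else expect_true(length(diffs) <= 1 && all(diffs == off))
  }
})

test_that("impossible layouts raise errors naming the constraint", {
  seqc <- make_contig(400, seed = 4)
  t1 <- list(contig = "c", pos = 150, allele_dic2 = "A", allele_silur = "C",
             exon_start = 100, exon_end = 310, layout_type = 1,
             origin = "DS")
  expect_error(design_baits(t1, seqc), "120 bp on both sides")
  t_tiny <- list(contig = "c", pos = 150, allele_dic2 = "A",
                 allele_silur = "C", exon_start = 100, exon_end = 215,
                 layout_type = 3, origin = "DS")
  expect_error(design_baits(t_tiny, seqc), "shorter than bait length")
})

test_that("bait counts per layout reconcile over a design set", {
  ref <- generate_reference(300, seed = 11)
  sel <- select_targets(ref$snps, ref$exons)
  ds <- design_bait_set(sel, ref$contigs)
  tab <- table(sel$targets$layout_type)
  expected <- sum(c(`1` = 4, `2` = 2, `3` = 2)[names(tab)] * tab)
  expect_equal(nrow(ds$baits), unname(expected))
  expect_true(all(ds$report$status == "ok"))
  ## names follow contig@pos|status|offset|type|origin
  expect_true(all(grepl("^[^@]+@\\d+\\|(Dic2|Silur|flanking)\\|(\\d+|NA)\\|[123]\\|(DS|EPO)$",
                        ds$baits$name)))
})

test_that("microsatellite screen flags the documented motifs", {
  set.seed(21)
  pad <- function(core) {
    left <- random_seq((120 - nchar(core)) %/% 2)
    paste0(left, core, random_seq(120 - nchar(core) - nchar(left)))
  }
  expect_true(screen_microsatellite(pad(strrep("AC", 7))))
  expect_true(screen_microsatellite(pad(strrep("ACG", 5))))
  expect_true(screen_microsatellite(strrep("T", 14)))  # homopolymer as (TT)x7
  expect_error(screen_microsatellite("ACGTN"), "non-ACGT")
  expect_error(screen_microsatellite(c("ACGT", "ACGT")), "single")
})

test_that("AC repeated six times is below the dinucleotide threshold", {
  ## brute-force scan over all phases confirms the max run is 6
  core <- strrep("AC", 6)
  expect_false(brute_tandem(core, 2, 7))
  expect_false(screen_microsatellite(core))
  ## one more copy tips it over
  expect_true(screen_microsatellite(paste0(core, "AC")))
})

test_that("the screen is reverse-complement invariant", {
  set.seed(23)
  for (i in 1:50) {
    s <- random_seq(120)
    if (i %% 5 == 0) {
      ins <- sample(c(strrep("GT", 7), strrep("CAG", 5)), 1)
      at <- sample(1:(120 - nchar(ins)), 1)
      substr(s, at, at + nchar(ins) - 1) <- ins
    }
    expect_identical(screen_microsatellite(s),
                     screen_microsatellite(revcomp(s)))
  }
})
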