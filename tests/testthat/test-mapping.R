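test_that("redundant markers merge exactly when calls agree where shared", {
  base <- rep(c("A", "B"), each = 20)
  g <- rbind(m1 = base, m2 = base,
             m3 = replace(base, 5, "B"),        # differs at one shared line
             m4 = replace(base, 1:15, NA))      # same where shared (25 > 30? no)
  rownames(g) <- c("m1", "m2", "m3", "m4")
  mr <- merge_redundant(g, min_shared = 30)
  bins <- split(mr$bins$marker, mr$bins$bin_id)
  expect_true(any(vapply(bins, function(b)
    setequal(b, c("m1", "m2")), TRUE)))
  expect_false(any(vapply(bins, function(b) "m3" %in% b && length(b) > 1,
                          TRUE)))
  ## m4 shares only 25 informative lines: below the sharing minimum
  expect_false(any(vapply(bins, function(b) "m4" %in% b && length(b) > 1,
                          TRUE)))
  ## at min_shared = 20, m4 links to m1/m2 AND to m3 (they agree where
  ## co-observed), so single-linkage closure pools all four
  mr2 <- merge_redundant(g, min_shared = 20)
  bins2 <- split(mr2$bins$marker, mr2$bins$bin_id)
  expect_true(any(vapply(bins2, function(b)
    setequal(b, c("m1", "m2", "m3", "m4")), TRUE)))
})

test_that("cosegregating pair with disjoint missingness is not merged", {
  full <- rep(c("A", "B"), each = 30)
  a <- replace(full, 1:40, NA)    # observed in lines 41..60
  b <- replace(full, 31:60, NA)   # observed in lines 1..30; share 0
  g <- rbind(p = a, q = b)
  mr <- merge_redundant(g, min_shared = 30)
  expect_equal(length(mr$representatives), 2)
})

test_that("group building is a partition with conjunctive criteria", {
  expect_equal(length(build_groups(matrix(character(0), 0, 0))$groups), 0)
  tr <- sim_truth_fixture(n_markers = 60, n_chr = 3, n_ind = 120)
  g <- tr$genotypes
  gr <- build_groups(g)
  all_m <- c(unlist(gr$groups), gr$singletons)
  expect_setequal(all_m, rownames(g))
  expect_equal(sum(duplicated(all_m)), 0)
  ## groups correspond to chromosomes
  chr_of <- tr$map_spec$loci$chromosome[
    match(sub("@.*", "", rownames(g)), tr$map_spec$loci$contig)]
  names(chr_of) <- rownames(g)
  purity <- vapply(gr$groups, function(grp)
    max(table(chr_of[grp])) / length(grp), 1)
  expect_true(all(purity == 1))
})

test_that("linkage requires both LOD and recombination criteria", {
  ## two markers sharing 100 lines, 20 recombinant: R = 0.2, LOD > 7
  c1 <- rep("A", 100)
  c2 <- c(rep("B", 20), rep("A", 80))
  tp <- two_point(c1, c2)
  expect_gt(tp$LOD, 7)
  expect_gt(tp$R_hat, 0.14)
  g <- rbind(`x@1` = c1, `y@1` = c2)
  gr <- build_groups(g, lod_min = 7, rf_max = 0.14)
  expect_equal(length(gr$groups), 0)
  expect_setequal(gr$singletons, c("x@1", "y@1"))
})

test_that("small groups are ordered to the exhaustive optimum", {
  set.seed(61)
  for (n in c(3, 5, 8)) {
    pos <- sort(runif(n, 0, 60))
    D <- abs(outer(pos, pos, "-")) + matrix(runif(n * n, 0, 0.5), n, n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("m", 1:n), paste0("m", 1:n))
    om <- order_markers(D, seed = 62)
    got <- capmapr:::sarf(D, match(om$marker, rownames(D)))
    expect_equal(got, brute_best_order(D), tolerance = 1e-9)
    ## cumulative positions are non-decreasing
    expect_true(all(diff(om$position_cM) >= 0))
  }
})

test_that("ordering criterion is reversal-invariant", {
  set.seed(63)
  n <- 12
  D <- as.matrix(dist(sort(runif(n, 0, 50))))
  dimnames(D) <- list(paste0("m", 1:n), paste0("m", 1:n))
  om <- order_markers(D, seed = 64)
  idx <- match(om$marker, rownames(D))
  expect_equal(capmapr:::sarf(D, idx), capmapr:::sarf(D, rev(idx)))
})

test_that("annealing recovers a known order for a dense group", {
  tr <- sim_truth_fixture(n_markers = 80, n_chr = 1, n_ind = 135,
                          len_cM = 120, seed = 71)
  g <- tr$genotypes
  tp <- capmapr:::two_point_matrix(g)
  D <- tp$D; D[!is.finite(D)] <- 200
  om <- order_markers(D, seed = 72)
  truth_pos <- tr$map_spec$loci$position_cM[
    match(sub("@.*", "", om$marker), tr$map_spec$loci$contig)]
  rho <- abs(cor(om$position_cM, truth_pos, method = "spearman"))
  expect_gte(rho, 0.95)
})

test_that("chromosome assignment takes the majority and reports swaps", {
  mk <- sprintf("m%02d", 1:20)
  asg <- data.frame(marker = mk,
                    chromosome = c(rep("2B", 16), rep("2A", 3), "5A"))
  a <- assign_chromosome(mk, asg)
  expect_equal(a$chromosome, "2B")
  expect_equal(a$frac_consistent, 0.8)
  expect_equal(a$frac_homeolog, 0.15)
  expect_equal(a$frac_other, 0.05)
  ## tie -> unassigned and flagged
  tie <- data.frame(marker = mk[1:4], chromosome = c("1A", "1A", "3B", "3B"))
  at <- assign_chromosome(mk[1:4], tie)
  expect_true(at$tie)
  expect_true(is.na(at$chromosome))
  ## no assignments at all
  a0 <- assign_chromosome(mk, data.frame(marker = "other",
                                         chromosome = "1A"))
  expect_true(is.na(a0$chromosome))
  expect_equal(a0$n_assigned, 0)
})

test_that("build_genetic_map yields ordered chromosomes and keeps bins together", {
  tr <- sim_truth_fixture(n_markers = 90, n_chr = 3, n_ind = 135, seed = 81)
  g <- tr$genotypes
  loci <- tr$map_spec$loci
  asg <- data.frame(marker = rownames(g),
                    chromosome = loci$chromosome[
                      match(sub("@.*", "", rownames(g)), loci$contig)],
                    position_bp = loci$position_bp[
                      match(sub("@.*", "", rownames(g)), loci$contig)])
  gm <- build_genetic_map(g, asg, seed = 82)
  expect_s3_class(gm, "genetic_map")
  m <- gm$map
  ## partition: no marker twice, all mapped markers known
  expect_equal(sum(duplicated(m$marker)), 0)
  for (chr in unique(m$chromosome)) {
    pos <- m$position_cM[m$chromosome == chr]
    expect_true(all(diff(sort(pos)) >= 0))
  }
  ## bins share one position
  pos_per_bin <- tapply(m$position_cM, paste(m$chromosome, m$bin_id),
                        function(x) length(unique(x)))
  expect_true(all(pos_per_bin == 1))
  ## summary output has the aggregate rows
  s <- summary(gm)
  expect_true(all(c("Mean", "Total") %in% s$chromosome))
})
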