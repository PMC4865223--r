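## Independent brute-force oracles used across the suite.  These are
## deliberately naive re-implementations kept free of any package
## internals.

## tandem-repeat scan: motif of size k repeated >= `need` times, any phase
brute_tandem <- function(s, k, need) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < k * need) return(FALSE)
  for (start in 1:(n - k + 1)) {
    reps <- 1
    while (start + (reps + 1) * k - 1 <= n &&
           all(ch[(start + reps * k):(start + (reps + 1) * k - 1)] ==
                 ch[start:(start + k - 1)])) {
      reps <- reps + 1
    }
    if (reps >= need) return(TRUE)
  }
  FALSE
}

brute_microsat <- function(s, di = 7, tri = 5) {
  brute_tandem(s, 2, di) || brute_tandem(s, 3, tri)
}

## expected heterozygosity / inbreeding coefficient recomputed from
## first principles on a call vector
brute_he_fis <- function(calls) {
  obs <- calls[!is.na(calls)]
  n_alleles <- 2 * length(obs)
  nA <- 2 * sum(obs == "A") + sum(obs == "H")
  p <- nA / n_alleles
  he <- 1 - p^2 - (1 - p)^2
  ho <- sum(obs == "H") / length(obs)
  list(he = he, fis = if (he > 0) 1 - ho / he else NA_real_)
}

## two-point likelihood oracle: numeric maximisation of the binomial
## log-likelihood of k recombinant lines out of n over R in [0, 0.5]
brute_two_point <- function(k, n) {
  ll <- function(R) {
    t1 <- if (k > 0) { if (R <= 0) -Inf else k * log(R) } else 0
    t2 <- if (n - k > 0) (n - k) * log(1 - R) else 0
    t1 + t2
  }
  opt <- optimize(function(R) -ll(R), c(1e-9, 0.5 - 1e-9), tol = 1e-12)
  cand <- c(0, opt$minimum, 0.5)
  vals <- vapply(cand, ll, 0)
  R_mle <- cand[which.max(vals)]
  lod <- (max(vals) - ll(0.5)) / log(10)
  list(R = R_mle, LOD = max(lod, 0))
}

## exhaustive best marker order for a distance matrix (orders canonical:
## first index < last index), returns the minimal criterion value
brute_best_order <- function(D) {
  n <- nrow(D)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    if (p[1] > p[n]) next
    cc <- sum(D[cbind(p[-n], p[-1])])
    best <- min(best, cc)
  }
  best
}

## random call vector with given composition
make_calls <- function(nA, nB, nH = 0, nNA = 0, shuffle = TRUE) {
  x <- c(rep("A", nA), rep("B", nB), rep("H", nH),
         rep(NA_character_, nNA))
  if (shuffle) sample(x) else x
}

## random 120-mer
random_seq <- function(n = 120) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## a small simulated population on `n_chr` chromosomes, error-free calls
sim_truth_fixture <- function(n_markers = 60, n_chr = 3, n_ind = 120,
                              len_cM = 120, seed = 101) {
  snps <- data.frame(contig = sprintf("c%04d", seq_len(n_markers)),
                     pos = 1L, truly_polymorphic = TRUE)
  ms <- make_map_spec(snps, n_chromosomes = n_chr, chr_length_cM = len_cM,
                      seed = seed)
  simulate_ril_population(ms, n_ind, 6L, seed = seed + 1L)
}
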