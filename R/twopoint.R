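## Two-point linkage statistics for selfed RIL genotypes.
##
## Lines are scored as recombinant/non-recombinant between two markers
## (heterozygous and missing calls excluded pairwise).  The observed
## recombinant-line fraction R relates to the meiotic recombination
## fraction r through the Haldane-Waddington limit for selfed lines,
## R = 2r / (1 + 2r); genetic distances are Haldane cM on the meiotic
## scale.

#' Haldane-Waddington conversions and Haldane distance
#'
#' `ril_R_to_r()` converts an observed recombinant-line fraction R in a
#' selfed RIL population to the meiotic recombination fraction
#' r = R / (2(1 - R)), capped at 0.5; `ril_r_to_R()` is the inverse
#' R = 2r / (1 + 2r); `haldane_cM()` maps r to Haldane map distance
#' d = -50 ln(1 - 2r).
#'
#' @param R,r Recombinant-line fraction / recombination fraction.
#' @return Numeric vector.
#' @export
ril_R_to_r <- function(R) pmin(R / (2 * (1 - R)), 0.5)

#' @rdname ril_R_to_r
#' @export
ril_r_to_R <- function(r) 2 * r / (1 + 2 * r)

#' @rdname ril_R_to_r
#' @export
haldane_cM <- function(r) ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))

twopoint_lod <- function(k, n, R = k / n) {
  R <- pmin(pmax(R, 0), 1)
  lod <- ifelse(R >= 0.5, 0,
                ifelse(k > 0, k * log10(R), 0) +
                  ifelse(n - k > 0, (n - k) * log10(1 - R), 0) +
                  n * log10(2))
  pmax(lod, 0)
}

#' Two-point linkage between two markers
#'
#' @param calls_1,calls_2 Call vectors ("A"/"B"/"H"/NA) over the same
#'   individuals; H is treated as missing.
#' @return List of class `two_point`: `R_hat` (recombinant-line
#'   fraction), `r` (meiotic, Haldane-Waddington corrected), `LOD`,
#'   `d_cM` (Haldane), `n_shared`, `n_recomb`; or NULL when no
#'   individual is informative for both markers.
#' @export
two_point <- function(calls_1, calls_2) {
  a <- ifelse(calls_1 %in% c("A", "B"), calls_1, NA)
  b <- ifelse(calls_2 %in% c("A", "B"), calls_2, NA)
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) return(NULL)
  k <- sum(a[ok] != b[ok])
  R <- k / n
  r <- ril_R_to_r(min(R, 0.5))
  structure(list(R_hat = R, r = r, LOD = twopoint_lod(k, n, min(R, 0.5)),
                 d_cM = haldane_cM(r), n_shared = n, n_recomb = k),
            class = "two_point")
}

## All-pairs two-point statistics, vectorised through cross-products.
## Returns matrices R (recombinant fraction), LOD, D (Haldane cM on the
## meiotic scale) and N (shared informative lines).
two_point_matrix <- function(genotypes) {
  X <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
              dimnames = dimnames(genotypes))
  X[genotypes == "A"] <- 0
  X[genotypes == "B"] <- 1
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  Y0 <- 1 - X; Y0[!M] <- 0
  storage.mode(M) <- "double"
  N <- tcrossprod(M)
  same <- tcrossprod(X0) + tcrossprod(Y0)
  K <- N - same
  R <- ifelse(N > 0, K / N, NA_real_)
  Rc <- pmin(R, 0.5)
  logR <- ifelse(K > 0, log10(Rc), 0)
  log1R <- ifelse(N - K > 0, log10(1 - Rc), 0)
  LOD <- ifelse(is.na(R) | R >= 0.5, 0,
                K * logR + (N - K) * log1R + N * log10(2))
  LOD <- pmax(LOD, 0)
  r <- ril_R_to_r(Rc)
  D <- haldane_cM(r)
  list(R = R, LOD = LOD, D = D, N = N)
}
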