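## De novo linkage map construction: redundant-marker merging, two-point
## grouping, chromosome assignment, and marker ordering by greedy
## insertion + simulated annealing + window flips on the sum of adjacent
## two-point distances (SARF criterion).

## union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union_pairs <- function(n, pairs) {
  parent <- uf_new(n)
  if (nrow(pairs)) for (p in seq_len(nrow(pairs))) {
    ri <- uf_find(parent, pairs[p, 1])
    rj <- uf_find(parent, pairs[p, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
}

#' Merge markers with redundant genotypes
#'
#' Markers are co-binned when their calls agree at every individual where
#' both are non-missing (H treated as a call here: vectors must be
#' identical where co-observed) and they share at least `min_shared`
#' co-genotyped individuals.  Binning is the transitive closure of that
#' pairwise relation.  One representative per bin: most genotyped
#' individuals, then lexicographically smallest name.
#'
#' @param genotypes Loci x individuals call matrix.
#' @param min_shared Minimum co-genotyped individuals for a merge
#'   (default 30).
#' @return List with `representatives` (character), `bins` (data.frame
#'   marker, bin_id, representative).
#' @export
merge_redundant <- function(genotypes, min_shared = 30L) {
  m <- nrow(genotypes)
  if (m == 0) return(list(representatives = character(0),
                          bins = data.frame(marker = character(0),
                                            bin_id = integer(0),
                                            representative = character(0))))
  ## code calls as integers for the cross-product trick; H is its own level
  X <- matrix(NA_real_, m, ncol(genotypes))
  X[genotypes == "A"] <- 0; X[genotypes == "B"] <- 1
  X[genotypes == "H"] <- 2
  M <- !is.na(X)
  storage.mode(M) <- "double"
  N <- tcrossprod(M)
  ## number of co-observed positions where the two markers differ
  A0 <- (X == 0) & M; B0 <- (X == 1) & M; H0 <- (X == 2) & M
  storage.mode(A0) <- storage.mode(B0) <- storage.mode(H0) <- "double"
  same <- tcrossprod(A0) + tcrossprod(B0) + tcrossprod(H0)
  diffn <- N - same
  link <- diffn == 0 & N >= min_shared
  link[lower.tri(link, diag = TRUE)] <- FALSE
  pairs <- which(link, arr.ind = TRUE)
  comp <- uf_union_pairs(m, pairs)
  ngeno <- rowSums(M)
  nm <- rownames(genotypes)
  reps <- vapply(split(seq_len(m), comp), function(idx) {
    idx[order(-ngeno[idx], nm[idx])][1]
  }, 0L)
  bin_id <- match(comp, sort(unique(comp)))
  bins <- data.frame(marker = nm, bin_id = bin_id,
                     representative = nm[reps[as.character(comp)]],
                     stringsAsFactors = FALSE)
  list(representatives = nm[sort(unique(reps))], bins = bins)
}

#' Assemble linkage groups from two-point statistics
#'
#' Single-linkage transitive closure over marker pairs with LOD >=
#' `lod_min` and recombinant-line fraction R <= `rf_max`.  Markers
#' linked to nothing become singleton groups.
#'
#' @param genotypes Loci x individuals call matrix (typically bin
#'   representatives).
#' @param lod_min Minimum two-point LOD (default 7).
#' @param rf_max Maximum two-point recombinant-line fraction
#'   (default 0.14).
#' @return List with `groups` (list of character vectors, largest
#'   first), `singletons` (markers in groups of size 1) and `tp` (the
#'   two-point matrices).
#' @export
build_groups <- function(genotypes, lod_min = 7, rf_max = 0.14) {
  m <- nrow(genotypes)
  if (m == 0) return(list(groups = list(), singletons = character(0),
                          tp = NULL))
  tp <- two_point_matrix(genotypes)
  link <- !is.na(tp$R) & tp$LOD >= lod_min & tp$R <= rf_max
  link[lower.tri(link, diag = TRUE)] <- FALSE
  pairs <- which(link, arr.ind = TRUE)
  comp <- uf_union_pairs(m, pairs)
  nm <- rownames(genotypes)
  groups <- split(nm, comp)
  names(groups) <- NULL
  sizes <- lengths(groups)
  singletons <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[order(-sizes)]
  list(groups = groups[lengths(groups) > 1], singletons = singletons,
       tp = tp)
}

## SARF criterion: sum of adjacent distances along an order.
sarf <- function(D, order) {
  if (length(order) < 2) return(0)
  sum(D[cbind(order[-length(order)], order[-1])])
}

## exhaustive best path for small groups (canonicalised: first < last)
order_exhaustive <- function(D) {
  n <- nrow(D)
  if (n <= 2) return(seq_len(n))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]),
                                                 function(p) c(v[i], p)))
    out
  }
  best <- NULL; best_c <- Inf
  for (p in perms(seq_len(n))) {
    if (p[1] > p[n]) next
    cc <- sarf(D, p)
    if (cc < best_c) { best_c <- cc; best <- p }
  }
  best
}

## greedy insertion: start from the closest pair, insert the remaining
## marker with the cheapest insertion cost at its best position
order_greedy <- function(D) {
  n <- nrow(D)
  if (n <= 2) return(seq_len(n))
  diag(D) <- Inf
  ij <- which(D == min(D), arr.ind = TRUE)[1, ]
  ord <- as.integer(ij)
  left <- setdiff(seq_len(n), ord)
  diag(D) <- 0
  while (length(left)) {
    best <- c(Inf, NA, NA)   # cost, marker, position
    for (mk in left) {
      ## insertion at every slot (0 = before first, length(ord) = after last)
      for (s in 0:length(ord)) {
        cost <- if (s == 0) D[mk, ord[1]]
        else if (s == length(ord)) D[ord[s], mk]
        else D[ord[s], mk] + D[mk, ord[s + 1]] - D[ord[s], ord[s + 1]]
        if (cost < best[1]) best <- c(cost, mk, s)
      }
    }
    s <- best[3]; mk <- best[2]
    ord <- append(ord, mk, after = s)
    left <- setdiff(left, mk)
  }
  ord
}

## simulated annealing on segment reversals with O(1) delta evaluation
order_anneal <- function(D, ord, n_iter = 30000L, t0 = 5, cooling = NULL) {
  n <- length(ord)
  if (n < 4) return(ord)
  if (is.null(cooling)) cooling <- exp(log(1e-3 / t0) / n_iter)
  temp <- t0
  cur <- sarf(D, ord)
  best <- ord; best_c <- cur
  for (it in seq_len(n_iter)) {
    i <- sample.int(n - 1L, 1L)
    j <- sample((i + 1L):n, 1L)
    d_new <- (if (i > 1) D[ord[i - 1L], ord[j]] else 0) +
      (if (j < n) D[ord[i], ord[j + 1L]] else 0)
    d_old <- (if (i > 1) D[ord[i - 1L], ord[i]] else 0) +
      (if (j < n) D[ord[j], ord[j + 1L]] else 0)
    delta <- d_new - d_old
    if (delta < 0 || runif(1) < exp(-delta / temp)) {
      ord[i:j] <- ord[j:i]
      cur <- cur + delta
      if (cur < best_c) { best_c <- cur; best <- ord }
    }
    temp <- temp * cooling
  }
  best
}

## exhaustive sliding-window reversals until no improvement
order_flips <- function(D, ord, max_window = 5L) {
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (w in 2:min(max_window, n)) {
      for (i in 1:(n - w + 1L)) {
        j <- i + w - 1L
        d_new <- (if (i > 1) D[ord[i - 1L], ord[j]] else 0) +
          (if (j < n) D[ord[i], ord[j + 1L]] else 0)
        d_old <- (if (i > 1) D[ord[i - 1L], ord[i]] else 0) +
          (if (j < n) D[ord[j], ord[j + 1L]] else 0)
        if (d_new < d_old - 1e-12) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Order the markers of a linkage group
#'
#' Minimises the sum of adjacent two-point Haldane distances (SARF).
#' Groups of up to `exact_max` markers are solved exhaustively; larger
#' groups use greedy insertion, simulated annealing on segment reversals
#' (geometric cooling) and exhaustive sliding-window flips until no
#' improvement.  The orientation of the order is arbitrary (reversal
#' leaves the criterion unchanged); positions are cumulative adjacent
#' Haldane distances starting at 0.
#'
#' @param D Symmetric matrix of two-point d_cM between group members
#'   (dimnames = marker names).
#' @param seed Integer seed for the annealing stage.
#' @param n_iter,t0 Annealing schedule: iterations and initial
#'   temperature.
#' @param max_window Flip-phase window size (default 5).
#' @param exact_max Largest group solved by exhaustive search
#'   (default 8).
#' @return data.frame: marker, position_cM (in inferred order).
#' @export
order_markers <- function(D, seed = 1L, n_iter = 30000L, t0 = 5,
                          max_window = 5L, exact_max = 8L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) return(data.frame(marker = rownames(D) %||% character(n),
                               position_cM = numeric(n)))
  ord <- if (n <= exact_max) order_exhaustive(D) else with_seed(seed, {
    o <- order_greedy(D)
    o <- order_anneal(D, o, n_iter = n_iter, t0 = t0)
    order_flips(D, o, max_window)
  })
  if (n > exact_max) ord <- order_flips(D, ord, max_window)
  adj <- D[cbind(ord[-n], ord[-1])]
  data.frame(marker = rownames(D)[ord],
             position_cM = c(0, cumsum(adj)),
             stringsAsFactors = FALSE)
}

#' Assign a linkage group to a chromosome
#'
#' The group is labelled with the modal putative chromosome among its
#' assigned members; ties leave the group unassigned (flagged).  The
#' consistency breakdown distinguishes members agreeing with the label,
#' members hitting the homeologous chromosome (same numeral, other
#' genome letter) and others.
#'
#' @param markers Character vector of group members.
#' @param assignments data.frame with columns `marker` and `chromosome`
#'   (missing markers allowed).
#' @return List: `chromosome` (label or NA), `tie` (logical),
#'   `n_assigned`, `frac_consistent`, `frac_homeolog`, `frac_other`.
#' @export
assign_chromosome <- function(markers, assignments) {
  chr <- assignments$chromosome[match(markers, assignments$marker)]
  chr <- chr[!is.na(chr)]
  if (!length(chr))
    return(list(chromosome = NA_character_, tie = FALSE, n_assigned = 0L,
                frac_consistent = NA_real_, frac_homeolog = NA_real_,
                frac_other = NA_real_))
  tab <- sort(table(chr), decreasing = TRUE)
  tie <- length(tab) > 1 && tab[1] == tab[2]
  label <- if (tie) NA_character_ else names(tab)[1]
  if (is.na(label))
    return(list(chromosome = NA_character_, tie = TRUE,
                n_assigned = length(chr), frac_consistent = NA_real_,
                frac_homeolog = NA_real_, frac_other = NA_real_))
  hom <- homeolog_of(label)
  list(chromosome = label, tie = FALSE, n_assigned = length(chr),
       frac_consistent = mean(chr == label),
       frac_homeolog = mean(chr == hom),
       frac_other = mean(chr != label & chr != hom))
}

## homeologous partner: same numeral, other genome letter (1A <-> 1B)
homeolog_of <- function(chr) {
  num <- sub("[AB]$", "", chr)
  letter <- sub("^.*?([AB])$", "\\1", chr)
  ifelse(grepl("[AB]$", chr), paste0(num, ifelse(letter == "A", "B", "A")),
         NA_character_)
}

#' Build a genetic map from clean genotypes
#'
#' Full chain: merge redundant markers into bins, assemble linkage
#' groups from two-point statistics, assign groups to chromosomes by
#' majority putative assignment (pooling groups assigned to the same
#' chromosome), and order each chromosome's bin representatives.
#' Positions are cumulative adjacent Haldane distances; all markers of a
#' bin share the representative's position.  Groups below `min_group`
#' markers and unlinked singletons are reported but excluded from the
#' map.
#'
#' @param genotypes Call matrix of the map-ready marker set.
#' @param assignments Optional putative assignment table (`marker`,
#'   `chromosome`); without it chromosomes are labelled LG1, LG2, ...
#' @param lod_min,rf_max Grouping thresholds (defaults 7 and 0.14).
#' @param min_shared Redundancy-merge sharing minimum (default 30).
#' @param min_group Minimum markers for a group to enter the map
#'   (default 3).
#' @param seed Seed for the annealing stage.
#' @param n_iter,t0 Annealing schedule.
#' @return Object of class `genetic_map`: list with `map` (data.frame
#'   marker, chromosome, position_cM, type, bin_id, representative),
#'   `groups` (per-group info), `bins`, `dropped` (small groups /
#'   singletons), `params`.
#' @export
build_genetic_map <- function(genotypes, assignments = NULL, lod_min = 7,
                              rf_max = 0.14, min_shared = 30L,
                              min_group = 3L, seed = 1L, n_iter = 30000L,
                              t0 = 5) {
  stopifnot(is.matrix(genotypes))
  mr <- merge_redundant(genotypes, min_shared)
  reps <- genotypes[mr$representatives, , drop = FALSE]
  grp <- build_groups(reps, lod_min, rf_max)
  ## chromosome labels: majority putative assignment (bins expanded)
  ginfo <- lapply(grp$groups, function(g) {
    members <- mr$bins$marker[mr$bins$representative %in% g]
    a <- if (is.null(assignments)) {
      list(chromosome = NA_character_, tie = FALSE, n_assigned = 0L,
           frac_consistent = NA_real_, frac_homeolog = NA_real_,
           frac_other = NA_real_)
    } else assign_chromosome(members, assignments)
    c(list(representatives = g, members = members), a)
  })
  labels <- vapply(ginfo, function(x) x$chromosome %||% NA_character_,
                   "")
  labels[is.na(labels)] <- paste0("LG", which(is.na(labels)))
  sizes <- vapply(ginfo, function(x) length(x$members), 0L)
  keep <- sizes >= min_group
  dropped <- list(
    small_groups = lapply(ginfo[!keep], `[[`, "members"),
    singletons = grp$singletons)
  ## pool kept groups by chromosome label, then order each chromosome
  pool <- split(seq_along(ginfo)[keep], labels[keep])
  tpD <- grp$tp$D
  rows <- list()
  for (chr in names(pool)) {
    g_reps <- unlist(lapply(ginfo[pool[[chr]]], `[[`, "representatives"),
                     use.names = FALSE)
    D <- tpD[g_reps, g_reps, drop = FALSE]
    ## unlinked pairs pooled from different groups: cap at a large finite
    ## distance so ordering still works
    D[!is.finite(D)] <- 200
    om <- order_markers(D, seed = derive_seed(seed, match(chr, names(pool))),
                        n_iter = n_iter, t0 = t0)
    ## orientation is arbitrary; align with putative coordinates if given
    if (!is.null(assignments)) {
      coord <- assignments$position_cM_putative %||% assignments$position_bp
      if (!is.null(coord)) {
        put <- coord[match(om$marker, assignments$marker)]
        s <- suppressWarnings(cor(om$position_cM, put,
                                  method = "spearman",
                                  use = "pairwise.complete.obs"))
        if (!is.na(s) && s < 0)
          om$position_cM <- max(om$position_cM) - om$position_cM
      }
    }
    members <- mr$bins[mr$bins$representative %in% g_reps, , drop = FALSE]
    pos <- om$position_cM[match(members$representative, om$marker)]
    rows[[chr]] <- data.frame(
      marker = members$marker, chromosome = chr, position_cM = pos,
      type = "mapped", bin_id = members$bin_id,
      representative = members$representative, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  if (!is.null(map)) {
    map <- map[order(map$chromosome, map$position_cM, map$marker), ]
    rownames(map) <- NULL
  } else {
    map <- data.frame(marker = character(0), chromosome = character(0),
                      position_cM = numeric(0), type = character(0),
                      bin_id = integer(0), representative = character(0))
  }
  structure(list(map = map, groups = ginfo, bins = mr$bins,
                 dropped = dropped,
                 params = list(lod_min = lod_min, rf_max = rf_max,
                               min_shared = min_shared,
                               min_group = min_group, seed = seed)),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  m <- x$map
  cat("Genetic map:", nrow(m), "markers on",
      length(unique(m$chromosome)), "chromosomes;",
      length(unique(paste(m$chromosome, m$bin_id))), "bins\n")
  cat("  total length:",
      round(sum(tapply(m$position_cM, m$chromosome, max)), 1), "cM\n")
  nd <- length(x$dropped$singletons) +
    sum(lengths(x$dropped$small_groups))
  if (nd) cat("  excluded:", nd, "markers (small groups / unlinked)\n")
  invisible(x)
}

#' Summarise a genetic map
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return See [summarize_map()].
#' @method summary genetic_map
#' @export
summary.genetic_map <- function(object, ...) {
  summarize_map(object)
}

#' Plot genetic vs physical (or rank) positions per chromosome
#'
#' @param x A `genetic_map`.
#' @param assignments Optional putative positions (`marker`,
#'   `position_bp`).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @method plot genetic_map
#' @export
plot.genetic_map <- function(x, assignments = NULL, ...) {
  m <- x$map
  chrs <- unique(m$chromosome)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(chrs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (chr in chrs) {
    mm <- m[m$chromosome == chr, ]
    if (!is.null(assignments) && "position_bp" %in% names(assignments)) {
      bp <- assignments$position_bp[match(mm$marker, assignments$marker)]
      plot(bp / 1e6, mm$position_cM, xlab = "physical position (Mb)",
           ylab = "genetic position (cM)", main = chr, pch = 20,
           cex = 0.5, ...)
    } else {
      plot(seq_len(nrow(mm)), mm$position_cM, xlab = "marker rank",
           ylab = "genetic position (cM)", main = chr, pch = 20,
           cex = 0.5, ...)
    }
  }
  invisible(x)
}
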