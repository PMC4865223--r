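## Allele-specific 120-mer bait design: one SNP per contig, single-exon
## placement, three layout types, and a tandem-microsatellite screen.

BAIT_LEN <- 120L

#' Select capture targets from a parental SNP table
#'
#' Retains SNPs that sit inside a single annotated exon of length >= 120 bp
#' (baits must not cross exon boundaries), keeps at most one SNP per contig
#' and assigns each target a bait layout type: exons >= 200 bp become
#' type 1 (four baits) or type 2 (two shifted baits) according to
#' `type1_fraction`; exons of 120--199 bp become type 3 (two aligned
#' baits).  Type 1 additionally needs the full four-bait footprint
#' (120 bp on each side of the SNP) inside the exon; targets where it does
#' not fit fall back to type 2.
#'
#' @param snps data.frame with columns `contig`, `pos` (1-based),
#'   `allele_dic2`, `allele_silur`, `origin` ("DS" or "EPO").
#' @param exons data.frame with columns `contig`, `exon_start`, `exon_end`
#'   (1-based inclusive).
#' @param max_per_contig Maximum targets per contig (default 1).  Ties are
#'   broken deterministically: longest exon, then smallest position.
#' @param type1_fraction Fraction of eligible >= 200 bp exon targets laid
#'   out as type 1 (default 3625/4133, the published design mix); the
#'   assignment is deterministic (every k-th eligible target becomes
#'   type 2).
#' @param contig_lengths Optional named vector of contig lengths; SNPs
#'   beyond their contig are rejected rows.
#' @return List with `targets` (selected SnpTarget rows: contig, pos,
#'   alleles, origin, exon_start, exon_end, layout_type) and `report`
#'   (every input row with `kept` and `reason`).
#' @export
select_targets <- function(snps, exons, max_per_contig = 1L,
                           type1_fraction = 3625 / 4133,
                           contig_lengths = NULL) {
  snps <- as.data.frame(snps)
  exons <- as.data.frame(exons)
  if (!is.null(snps$pos_1based) && is.null(snps$pos))
    names(snps)[names(snps) == "pos_1based"] <- "pos"
  stopifnot(all(c("contig", "pos") %in% names(snps)),
            all(c("contig", "exon_start", "exon_end") %in% names(exons)))
  if (any(exons$exon_start < 1 | exons$exon_end < exons$exon_start))
    stop_arg("invalid exon coordinates")
  reason <- character(nrow(snps))
  exon_start <- exon_end <- rep(NA_integer_, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    if (!is.null(contig_lengths)) {
      cl <- contig_lengths[[snps$contig[i]]]
      if (!is.null(cl) && !is.na(cl) && snps$pos[i] > cl) {
        reason[i] <- "position outside contig"
        next
      }
    }
    ex <- exons[exons$contig == snps$contig[i] &
                  exons$exon_start <= snps$pos[i] &
                  exons$exon_end >= snps$pos[i], , drop = FALSE]
    if (nrow(ex) == 0) { reason[i] <- "not in an annotated exon"; next }
    ex <- ex[which.max(ex$exon_end - ex$exon_start), , drop = FALSE]
    if (ex$exon_end - ex$exon_start + 1L < BAIT_LEN) {
      reason[i] <- "exon shorter than 120 bp"
      next
    }
    exon_start[i] <- ex$exon_start; exon_end[i] <- ex$exon_end
  }
  eligible <- reason == ""
  ## one SNP per contig: longest exon, then smallest position
  keep <- rep(FALSE, nrow(snps))
  for (ctg in unique(snps$contig[eligible])) {
    idx <- which(eligible & snps$contig == ctg)
    exlen <- exon_end[idx] - exon_start[idx] + 1L
    o <- order(-exlen, snps$pos[idx])
    sel <- idx[o][seq_len(min(max_per_contig, length(idx)))]
    keep[sel] <- TRUE
    reason[setdiff(idx, sel)] <- "another SNP selected on contig"
  }
  tg <- snps[keep, , drop = FALSE]
  tg$exon_start <- exon_start[keep]
  tg$exon_end <- exon_end[keep]
  exlen <- tg$exon_end - tg$exon_start + 1L
  type <- integer(nrow(tg))
  type[exlen < 200L] <- 3L
  big <- which(exlen >= 200L)
  ## type 1 requires [pos-120, pos+120] inside the exon
  fits1 <- (tg$pos[big] - BAIT_LEN) >= tg$exon_start[big] &
    (tg$pos[big] + BAIT_LEN) <= tg$exon_end[big]
  cand1 <- big[fits1]
  n1 <- round(length(cand1) * type1_fraction)
  ## deterministic split: first n1 candidates (input order) are type 1
  type[cand1] <- ifelse(seq_along(cand1) <= n1, 1L, 2L)
  type[big[!fits1]] <- 2L
  tg$layout_type <- type
  report <- snps
  report$kept <- keep
  report$reason <- ifelse(keep, "selected", reason)
  if (is.null(tg$origin)) tg$origin <- "DS"
  rownames(tg) <- NULL
  list(targets = tg, report = report)
}

bait_window <- function(seq, start) substr(seq, start, start + BAIT_LEN - 1L)

make_bait <- function(target, contig_seq, start, status, layout_type) {
  s <- bait_window(contig_seq, start)
  offset <- if (status == "flanking") NA_integer_ else
    as.integer(target$pos - start + 1L)
  if (!is.na(offset)) {
    allele <- if (status == "Dic2") target$allele_dic2 else target$allele_silur
    substr(s, offset, offset) <- allele
  }
  data.frame(name = paste0(marker_name(target$contig, target$pos), "|",
                           status, "|",
                           ifelse(is.na(offset), "NA", offset), "|",
                           layout_type, "|", target$origin %||% "DS"),
             contig = target$contig, snp_pos = target$pos,
             start = start, allele_status = status,
             snp_offset_in_bait = offset, layout_type = layout_type,
             sequence = s, stringsAsFactors = FALSE)
}

#' Design 120-mer baits for one target
#'
#' Emits the bait set for a selected SNP target according to its layout
#' type.  Type 1: two SNP-centred baits (one per parental allele) plus two
#' allele-invariant flanking baits immediately 5' and 3' of the SNP,
#' extending coverage to at least 100 bp on each side (200 bp around the
#' SNP).  Type 2: two shifted baits each containing the SNP (default at
#' 1/3 and 2/3 of the bait), one per allele.  Type 3: two baits at
#' identical coordinates differing only at the SNP.  Baits never cross
#' exon boundaries; an impossible layout is an error naming the violated
#' constraint.
#'
#' @param target One row of `select_targets()$targets` (data.frame or
#'   list with contig, pos, allele_dic2, allele_silur, exon_start,
#'   exon_end, layout_type, origin).
#' @param contig_seq Contig sequence (character scalar).
#' @param type2_offsets SNP offsets within the two type-2 baits (1-based,
#'   default c(40, 80)).
#' @return data.frame of baits: name (`contig@pos|status|offset|type|origin`),
#'   coordinates, allele status, SNP offset, layout type, sequence and
#'   `repeat_flagged` from [screen_microsatellite()].
#' @export
design_baits <- function(target, contig_seq, type2_offsets = c(40L, 80L)) {
  target <- as.list(target)
  pos <- target$pos
  es <- target$exon_start; ee <- target$exon_end
  type <- target$layout_type
  if (is.null(type)) stop_arg("target has no layout_type; run select_targets")
  if (ee - es + 1L < BAIT_LEN)
    stop_arg("exon shorter than bait length (120 bp)")
  baits <- switch(as.character(type),
    "1" = {
      if (pos - BAIT_LEN < es || pos + BAIT_LEN > ee)
        stop_arg("type 1 layout needs 120 bp on both sides of the SNP ",
                 "within the exon")
      centre <- pos - 59L
      rbind(make_bait(target, contig_seq, centre, "Dic2", 1L),
            make_bait(target, contig_seq, centre, "Silur", 1L),
            make_bait(target, contig_seq, pos - BAIT_LEN, "flanking", 1L),
            make_bait(target, contig_seq, pos + 1L, "flanking", 1L))
    },
    "2" = {
      starts <- pos - sort(as.integer(type2_offsets)) + 1L
      starts <- pmin(pmax(starts, es), ee - BAIT_LEN + 1L)
      if (any(pos < starts | pos > starts + BAIT_LEN - 1L))
        stop_arg("type 2 layout: SNP falls outside a shifted bait ",
                 "after clamping to the exon")
      rbind(make_bait(target, contig_seq, starts[2], "Dic2", 2L),
            make_bait(target, contig_seq, starts[1], "Silur", 2L))
    },
    "3" = {
      start <- min(max(es, pos - 59L), ee - BAIT_LEN + 1L)
      rbind(make_bait(target, contig_seq, start, "Dic2", 3L),
            make_bait(target, contig_seq, start, "Silur", 3L))
    },
    stop_arg("unknown layout type ", type))
  baits$repeat_flagged <- vapply(baits$sequence, screen_microsatellite,
                                 logical(1), USE.NAMES = FALSE)
  rownames(baits) <- NULL
  baits
}

#' Screen a sequence for tandem microsatellites
#'
#' Flags sequences containing a dinucleotide motif tandemly repeated at
#' least 7 times (>= 14 bp) or a trinucleotide motif repeated at least 5
#' times (>= 15 bp).  Homopolymer runs are flagged when they satisfy the
#' dinucleotide rule (14 identical bases are 7 tandem copies of a
#' dinucleotide).
#'
#' @param sequence Nucleotide string (ACGT only).
#' @param di_units Minimum tandem copies of a dinucleotide (default 7).
#' @param tri_units Minimum tandem copies of a trinucleotide (default 5).
#' @return TRUE if a qualifying tandem repeat is present.
#' @export
screen_microsatellite <- function(sequence, di_units = 7L, tri_units = 5L) {
  if (length(sequence) != 1 || !is.character(sequence))
    stop_arg("sequence must be a single character string")
  if (grepl("[^ACGTacgt]", sequence))
    stop_arg("sequence contains non-ACGT characters")
  s <- toupper(sequence)
  grepl(sprintf("([ACGT]{2})\\1{%d}", di_units - 1L), s, perl = TRUE) ||
    grepl(sprintf("([ACGT]{3})\\1{%d}", tri_units - 1L), s, perl = TRUE)
}

#' Design baits for a whole target set
#'
#' Applies [design_baits()] to every selected target and assembles the
#' bait table plus a design report (targets kept/dropped with reasons and
#' repeat flags).  Targets whose layout cannot be placed are dropped and
#' reported rather than aborting the run.
#'
#' @param selection Output of [select_targets()].
#' @param contigs Named character vector (or DNAStringSet) of contig
#'   sequences.
#' @return List with `baits` (data.frame), `report` (per-target status)
#'   and `bait_counts` (per contig: number of baits, for coverage
#'   modelling).
#' @export
design_bait_set <- function(selection, contigs) {
  contigs <- setNames(as.character(contigs), names(contigs))
  tg <- selection$targets
  out <- vector("list", nrow(tg))
  status <- character(nrow(tg))
  for (i in seq_len(nrow(tg))) {
    res <- tryCatch(design_baits(tg[i, ], contigs[[tg$contig[i]]]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      status[i] <- res
    } else {
      status[i] <- "ok"
      out[[i]] <- res
    }
  }
  baits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  report <- data.frame(contig = tg$contig, pos = tg$pos,
                       layout_type = tg$layout_type, status = status,
                       stringsAsFactors = FALSE)
  if (!is.null(baits)) {
    flag <- tapply(baits$repeat_flagged, baits$contig, any)
    report$repeat_flagged <- unname(flag[report$contig])
    bait_counts <- table(baits$contig)
  } else bait_counts <- table(character())
  list(baits = baits, report = report,
       bait_counts = setNames(as.integer(bait_counts), names(bait_counts)))
}

#' Write a bait set as FASTA
#'
#' @param baits Bait data.frame from [design_bait_set()] or
#'   [design_baits()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_baits <- function(baits, path) {
  x <- Biostrings::DNAStringSet(setNames(baits$sequence, baits$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
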