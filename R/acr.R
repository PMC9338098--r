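# ACR taxonomy: fold-enrichment filtering, genic/intergenic split,
# midpoint-based feature annotation, three-way overlap classes, differential
# enrichment between genotypes, pileup deciles and histone-mark clusters.

#' Filter peaks by fold enrichment
#'
#' Retains peaks with fold enrichment strictly greater than the cutoff
#' (default 3.4); the retained peaks are the accessible chromatin regions
#' (ACRs) used everywhere downstream.
#'
#' @param peaks peak table with a `fold_enrichment` column.
#' @param min_fe strict lower cutoff.
#' @return The retained subset, rownames reset.
#' @export
filter_acrs <- function(peaks, min_fe = 3.4) {
  if (is.null(peaks$fold_enrichment))
    stop("peaks lack a fold_enrichment column")
  if (anyNA(peaks$fold_enrichment))
    stop("fold_enrichment contains missing values")
  out <- peaks[peaks$fold_enrichment > min_fe, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify ACRs as genic or intergenic
#'
#' An ACR is genic (gACR) iff it overlaps any gene span (TSS to TTS) by at
#' least 1 bp, intergenic (iACR) otherwise.
#'
#' @param acrs ACR table.
#' @param genes gene-model table.
#' @return character vector `"gACR"`/`"iACR"`, one per ACR.
#' @export
classify_genic_intergenic <- function(acrs, genes) {
  ov <- overlap_query(acrs, genes)
  flag <- rep("iACR", nrow(acrs))
  flag[unique(ov$query)] <- "gACR"
  flag
}

.FEATURES <- c("promoter_1kb", "promoter_1_2kb", "promoter_2_3kb",
               "five_prime_UTR", "three_prime_UTR", "exon", "intron",
               "downstream_300bp", "distal_intergenic")

#' Annotate ACRs with a genomic feature and an associated gene
#'
#' The ACR midpoint is assigned to the highest-priority overlapping feature:
#' tiered promoters (0-1, 1-2, 2-3 kb upstream of the TSS, strand-aware) >
#' 5'/3' UTR (only when a UTR table is supplied) > exon > intron (introns
#' only distinguishable when an exon table is supplied; otherwise any
#' midpoint inside a gene span is "exon") > within 300 bp downstream of the
#' TTS > distal intergenic. The associated gene is the feature's owner, or
#' for distal ACRs the nearest TSS within `distal_cap` bp (NA beyond it).
#' Ties at equal priority go to the gene with the nearest TSS.
#'
#' @param acrs ACR table.
#' @param genes gene-model table.
#' @param exons optional data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param utrs optional data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `side` ("five_prime"/"three_prime").
#' @param distal_cap association cap (bp) for distal ACRs.
#' @return data.frame with `feature` and `associated_gene` per ACR.
#' @export
annotate_features <- function(acrs, genes, exons = NULL, utrs = NULL,
                              distal_cap = 10000L) {
  mid <- (acrs$start + acrs$end) %/% 2L
  tss <- tss_position(genes)
  tts <- tts_position(genes)
  n <- nrow(acrs)
  feature <- rep("distal_intergenic", n)
  gene_of <- rep(NA_character_, n)
  prio <- setNames(seq_along(.FEATURES), .FEATURES)
  best_prio <- rep(prio["distal_intergenic"], n)
  best_dist <- rep(Inf, n)

  consider <- function(i, f, g_idx) {
    d <- abs(mid[i] - tss[g_idx])
    better <- prio[f] < best_prio[i] |
      (prio[f] == best_prio[i] & d < best_dist[i])
    i <- i[better]; g_idx <- g_idx[better]; d <- d[better]
    if (length(i)) {
      feature[i] <<- f
      gene_of[i] <<- genes$gene_id[g_idx]
      best_prio[i] <<- prio[f]
      best_dist[i] <<- d
    }
  }

  midi <- data.frame(chrom = acrs$chrom, start = mid, end = mid + 1L)
  # promoter tiers: strand-aware upstream windows of the TSS
  for (tier in 1:3) {
    lo <- (tier - 1L) * 1000L; hi <- tier * 1000L
    ps <- ifelse(genes$strand == "+", genes$start - hi, genes$end + lo)
    pe <- ifelse(genes$strand == "+", genes$start - lo, genes$end + hi)
    pw <- data.frame(chrom = genes$chrom, start = pmax(ps, 0L), end = pe)
    keep <- pw$start < pw$end
    ov <- overlap_query(midi, pw[keep, , drop = FALSE])
    f <- c("promoter_1kb", "promoter_1_2kb", "promoter_2_3kb")[tier]
    if (nrow(ov)) consider(ov$query, f, which(keep)[ov$subject])
  }
  if (!is.null(utrs) && nrow(utrs)) {
    for (side in c("five_prime", "three_prime")) {
      u <- utrs[utrs$side == side, , drop = FALSE]
      if (!nrow(u)) next
      ov <- overlap_query(midi, u)
      if (nrow(ov))
        consider(ov$query, paste0(side, "_UTR"),
                 match(u$gene_id[ov$subject], genes$gene_id))
    }
  }
  # gene body: exon vs intron
  ov <- overlap_query(midi, genes)
  if (nrow(ov)) {
    if (is.null(exons) || !nrow(exons)) {
      consider(ov$query, "exon", ov$subject)
    } else {
      in_exon <- rep(FALSE, nrow(ov))
      ove <- overlap_query(midi, exons)
      if (nrow(ove)) {
        key <- paste(ove$query, exons$gene_id[ove$subject])
        in_exon <- paste(ov$query, genes$gene_id[ov$subject]) %in% key
      }
      if (any(in_exon)) consider(ov$query[in_exon], "exon",
                                 ov$subject[in_exon])
      if (any(!in_exon)) consider(ov$query[!in_exon], "intron",
                                  ov$subject[!in_exon])
    }
  }
  # downstream: within 300 bp past the TTS, strand-aware
  ds <- ifelse(genes$strand == "+", genes$end, genes$start - 300L)
  de <- ifelse(genes$strand == "+", genes$end + 300L, genes$start)
  dw <- data.frame(chrom = genes$chrom, start = pmax(ds, 0L), end = de)
  keep <- dw$start < dw$end
  ov <- overlap_query(midi, dw[keep, , drop = FALSE])
  if (nrow(ov)) consider(ov$query, "downstream_300bp", which(keep)[ov$subject])

  # distal association: nearest TSS within the cap
  distal <- which(feature == "distal_intergenic")
  if (length(distal)) {
    win <- data.frame(chrom = acrs$chrom[distal],
                      start = pmax(mid[distal] - distal_cap, 0L),
                      end = mid[distal] + distal_cap + 1L)
    tw <- data.frame(chrom = genes$chrom, start = tss, end = tss + 1L)
    ov <- overlap_query(win, tw)
    if (nrow(ov)) {
      d <- abs(mid[distal][ov$query] - tss[ov$subject])
      dt <- data.table::data.table(q = ov$query, g = ov$subject, d = d)
      best <- dt[, .SD[which.min(d)], by = q]
      gene_of[distal[best$q]] <- genes$gene_id[best$g]
    }
  }
  data.frame(feature = factor(feature, levels = .FEATURES),
             associated_gene = gene_of, stringsAsFactors = FALSE)
}

#' Three-way common/specific overlap classes
#'
#' For each genotype's ACR set, an ACR is `common_all3` if it overlaps at
#' least one ACR in each of the other two genotypes, `genotype_specific` if
#' it overlaps none, otherwise `shared_2way`.
#'
#' @param acr_sets named list of exactly three ACR tables.
#' @param min_overlap_bp minimum overlap to count (default 1).
#' @return list with `classes` (per-genotype character vectors) and `counts`
#'   (genotype x class table as a data.frame).
#' @export
find_overlap_classes <- function(acr_sets, min_overlap_bp = 1L) {
  stopifnot(length(acr_sets) == 3L, !is.null(names(acr_sets)))
  gts <- names(acr_sets)
  classes <- list()
  for (g in gts) {
    others <- setdiff(gts, g)
    hit <- sapply(others, function(o) {
      ov <- overlap_query(acr_sets[[g]], acr_sets[[o]], min_overlap_bp)
      seq_len(nrow(acr_sets[[g]])) %in% ov$query
    })
    nhit <- rowSums(matrix(hit, ncol = 2L))
    classes[[g]] <- c("genotype_specific", "shared_2way",
                      "common_all3")[nhit + 1L]
  }
  counts <- do.call(rbind, lapply(gts, function(g) {
    tb <- table(factor(classes[[g]],
                       levels = c("common_all3", "shared_2way",
                                  "genotype_specific")))
    data.frame(genotype = g, class = names(tb), n = as.integer(tb))
  }))
  list(classes = classes, counts = counts)
}

# internal: pooled-variance two-sample t with a zero-variance guard
# (perfect separation -> p = 0, identical constant groups -> p = 1)
.pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}

# internal: Welch t with a zero-variance guard (perfect separation -> p = 0,
# identical constant groups -> p = 1); returns two-sided p
.welch_p <- function(x, y) {
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * pt(-abs(t), df)
}

#' Differential enrichment test on a signal matrix
#'
#' Core test behind [call_deas()]: two-sided pooled-variance t test on
#' log2(value + 1) per feature (the log transform stabilizes variances, and
#' the pooled t keeps the type-I error at its nominal level at 3 replicates,
#' where the Welch correction is noticeably conservative), with the fold
#' change taken as the ratio of group means. A feature with zero signal in
#' every replicate of both groups is not tested.
#'
#' @param x,y numeric matrices (features x replicates) of depth-normalized
#'   signal, >= 2 columns each.
#' @param lfc_cut,p_cut thresholds: differential iff `|log2FC| >= lfc_cut`
#'   and `p < p_cut`.
#' @return data.frame `log2fc`, `p`, `status` (`enriched_in_x`,
#'   `enriched_in_y`, `ns`, `not_tested`).
#' @export
dea_test <- function(x, y, lfc_cut = 1, p_cut = 0.05) {
  if (ncol(x) < 2L || ncol(y) < 2L)
    stop("at least 2 replicates per genotype are required")
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  log2fc <- p <- rep(NA_real_, n)
  status <- rep("not_tested", n)
  for (i in seq_len(n)) {
    xi <- x[i, ]; yi <- y[i, ]
    if (all(xi == 0) && all(yi == 0)) next
    log2fc[i] <- log2(mean(xi) / mean(yi))
    p[i] <- .pooled_t_p(log2(xi + 1), log2(yi + 1))
    status[i] <- if (!is.na(p[i]) && abs(log2fc[i]) >= lfc_cut &&
                     p[i] < p_cut) {
      if (log2fc[i] > 0) "enriched_in_x" else "enriched_in_y"
    } else "ns"
  }
  data.frame(log2fc = log2fc, p = p, status = status,
             stringsAsFactors = FALSE)
}

#' Call differentially enriched ACRs between two genotypes
#'
#' Tests the ACRs common to two genotypes: overlapping peak calls from both
#' genotypes are merged into one tested region, per-replicate signal is the
#' track value summed over that region normalized to depth (per million
#' mapped reads), and [dea_test()] supplies the statistic. Differential iff
#' `|log2FC| >= 1` and `p < 0.05`.
#'
#' @param acrs_x,acrs_y filtered ACR tables of the two genotypes.
#' @param tracks_x,tracks_y lists of replicate [signal_track()]s.
#' @param min_overlap_bp minimum peak overlap defining "common".
#' @param lfc_cut,p_cut thresholds passed to [dea_test()].
#' @return data.frame: tested region (`chrom`, `start`, `end`), `log2fc`,
#'   `p`, `status` (`enriched_in_x` meaning more accessible in genotype X).
#' @export
call_deas <- function(acrs_x, acrs_y, tracks_x, tracks_y,
                      min_overlap_bp = 1L, lfc_cut = 1, p_cut = 0.05) {
  if (length(tracks_x) < 2L || length(tracks_y) < 2L)
    stop("at least 2 replicate tracks per genotype are required")
  ov <- overlap_query(acrs_x, acrs_y, min_overlap_bp)
  if (!nrow(ov))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), log2fc = numeric(), p = numeric(),
                      status = character()))
  common <- rbind(acrs_x[unique(ov$query), c("chrom", "start", "end")],
                  acrs_y[unique(ov$subject), c("chrom", "start", "end")])
  regions <- merge_intervals(common)
  sig <- function(tracks) {
    m <- sapply(tracks, function(tr) {
      v <- vapply(seq_len(nrow(regions)), function(i)
        .track_sum(tr, regions$chrom[i], regions$start[i], regions$end[i]),
        0)
      v / tr$total_mapped_reads * 1e6
    })
    matrix(m, nrow = nrow(regions))
  }
  res <- dea_test(sig(tracks_x), sig(tracks_y), lfc_cut, p_cut)
  cbind(regions, res)
}

#' Rank ACRs into pileup deciles
#'
#' Sorts by pileup ascending (ties broken by chromosome then start, for
#' determinism) and splits into 10 groups as equal as possible; when the
#' count is not divisible by 10 the first (lowest-pileup) groups take the
#' extra members.
#'
#' @param acrs ACR table with `pileup`.
#' @return integer decile (1 = least accessible) per input row.
#' @export
rank_deciles <- function(acrs) {
  n <- nrow(acrs)
  if (n < 10L) stop("need at least 10 ACRs to form deciles")
  o <- order(acrs$pileup, acrs$chrom, acrs$start)
  sizes <- rep(n %/% 10L, 10L)
  r <- n %% 10L
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  dec <- integer(n)
  dec[o] <- rep(1:10, sizes)
  dec
}

#' Assign ACRs to histone-association clusters
#'
#' A mark is "present" iff the ACR overlaps (>= 1 bp) a peak of that mark.
#' Clusters: 1 = H3K27me3 only, 2 = H3K4me3 only, 3 = H3K27ac only,
#' 4 = H3K27me3 + H3K4me3, 5 = H3K4me3 + H3K27ac, 6 = H3K27me3 + H3K27ac.
#' ACRs with no mark or all three are left unassigned (NA).
#'
#' @param acrs ACR table.
#' @param histone_peaks named list with interval tables for `H3K4me3`,
#'   `H3K27ac`, `H3K27me3`.
#' @param min_overlap_bp minimum overlap to count a mark as present.
#' @return integer vector of clusters (1-6, NA = unassigned).
#' @export
assign_histone_clusters <- function(acrs, histone_peaks,
                                    min_overlap_bp = 1L) {
  stopifnot(all(.MARKS %in% names(histone_peaks)))
  pres <- sapply(.MARKS, function(m) {
    ov <- overlap_query(acrs, histone_peaks[[m]], min_overlap_bp)
    seq_len(nrow(acrs)) %in% ov$query
  })
  pres <- matrix(pres, ncol = 3L, dimnames = list(NULL, .MARKS))
  key <- apply(pres, 1L, function(z)
    paste(sort(.MARKS[z]), collapse = "+"))
  map <- c("H3K27me3" = 1L, "H3K4me3" = 2L, "H3K27ac" = 3L,
           "H3K27me3+H3K4me3" = 4L, "H3K27ac+H3K4me3" = 5L,
           "H3K27ac+H3K27me3" = 6L)
  map_key <- vapply(names(map), function(k)
    paste(sort(strsplit(k, "+", fixed = TRUE)[[1]]), collapse = "+"), "")
  unname(map[match(key, map_key)])
}
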