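# In silico 'hybrid' construction: progenitor datasets live on disjoint
# subgenomes of the shared coordinate system, so mixing is concatenation plus
# depth rescaling. ATAC/ChIP/RNA are mixed 1:1 (each parent's contribution
# equalized); methylation coverage is split in proportion to parental genome
# sizes.

#' Mix parental coverage tracks and peak sets into the hybrid
#'
#' Replicate i of each parent becomes hybrid replicate i. Each parent's track
#' values and pileups are rescaled so the two effective contributed read
#' totals are equal (the 1:1 mix); the hybrid library size is the sum of the
#' scaled parental totals, and the hybrid peak set is the union of the scaled
#' parental peak sets.
#'
#' @param rapa,oleracea lists with elements `tracks` (list of
#'   [signal_track()], one per replicate) and `peaks` (peak table). Tracks
#'   must cover disjoint chromosome sets.
#' @param genotype label for the mixed genotype.
#' @return list with `tracks` (per replicate), `peaks`, and the per-parent
#'   `scale` factors used.
#' @export
mix_tracks_and_peaks <- function(rapa, oleracea, genotype = "A_C") {
  if (length(rapa$tracks) != length(oleracea$tracks))
    stop("replicate count mismatch between parents")
  shared <- intersect(unique(rapa$tracks[[1]]$steps$chrom),
                      unique(oleracea$tracks[[1]]$steps$chrom))
  if (length(shared))
    stop("parental coverage overlaps on chromosome(s): ",
         paste(shared, collapse = ", "),
         " (parents must map to disjoint subgenomes)")
  tracks <- vector("list", length(rapa$tracks))
  sc <- matrix(NA_real_, length(tracks), 2,
               dimnames = list(NULL, c("rapa", "oleracea")))
  for (i in seq_along(tracks)) {
    tr <- rapa$tracks[[i]]; to <- oleracea$tracks[[i]]
    if (tr$assay != to$assay) stop("assay mismatch between parents")
    tgt <- min(tr$total_mapped_reads, to$total_mapped_reads)
    fr <- tgt / tr$total_mapped_reads
    fo <- tgt / to$total_mapped_reads
    sc[i, ] <- c(fr, fo)
    sr <- tr$steps; sr$value <- sr$value * fr
    so <- to$steps; so$value <- so$value * fo
    tracks[[i]] <- signal_track(rbind(sr, so), assay = tr$assay,
                                genotype = genotype,
                                replicate = tr$replicate,
                                total_mapped_reads = 2 * tgt)
  }
  pr <- rapa$peaks; po <- oleracea$peaks
  # peak pileups scaled with the replicate-averaged factor of their parent
  pr$pileup <- pr$pileup * mean(sc[, "rapa"])
  po$pileup <- po$pileup * mean(sc[, "oleracea"])
  peaks <- rbind(pr, po)
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  rownames(peaks) <- NULL
  list(tracks = tracks, peaks = peaks, scale = sc)
}

#' Mix parental expression matrices into the hybrid
#'
#' Parental count matrices (disjoint gene sets, one per subgenome) are
#' concatenated after per-replicate library-size equalization, and TPM is
#' recomputed on the combined gene set.
#'
#' @param rapa,oleracea count matrices (genes x replicates) with disjoint
#'   rownames.
#' @param gene_length named vector covering both gene sets.
#' @return list with `counts` and `tpm` for the hybrid.
#' @export
mix_expression <- function(rapa, oleracea, gene_length) {
  if (ncol(rapa) != ncol(oleracea))
    stop("replicate count mismatch between parents")
  if (length(intersect(rownames(rapa), rownames(oleracea))))
    stop("parental gene sets must be disjoint by subgenome")
  counts <- matrix(0, nrow(rapa) + nrow(oleracea), ncol(rapa),
                   dimnames = list(c(rownames(rapa), rownames(oleracea)),
                                   paste0("A_C_rep", seq_len(ncol(rapa)))))
  for (i in seq_len(ncol(rapa))) {
    lr <- sum(rapa[, i]); lo <- sum(oleracea[, i])
    tgt <- min(lr, lo)
    counts[, i] <- c(rapa[, i] * tgt / lr, oleracea[, i] * tgt / lo)
  }
  tpm <- compute_tpm(counts, gene_length[rownames(counts)])
  list(counts = counts, tpm = tpm)
}

#' Mix parental methylomes in proportion to genome size
#'
#' Site tables are concatenated; per-site coverage is rescaled (and rounded
#' to integers, preserving each site's methylation level up to rounding) so
#' that the hybrid's total coverage splits across subgenomes in proportion to
#' the parental genome sizes.
#'
#' @param rapa,oleracea site tables on disjoint chromosome sets.
#' @param genome_sizes numeric length-2 vector `c(rapa = , oleracea = )` of
#'   parental genome sizes in bp.
#' @return Combined site table.
#' @export
mix_methylome <- function(rapa, oleracea, genome_sizes) {
  stopifnot(all(c("rapa", "oleracea") %in% names(genome_sizes)))
  cr <- sum(rapa$total_reads); co <- sum(oleracea$total_reads)
  if (cr == 0 || co == 0) stop("a parental methylome has zero coverage")
  # ratio the scaled coverages must satisfy; scale down the over-represented
  # parent only, so no site's coverage is inflated
  r <- (genome_sizes[["rapa"]] / genome_sizes[["oleracea"]]) / (cr / co)
  fr <- min(1, r); fo <- min(1, 1 / r)
  rescale <- function(tab, f) {
    if (f == 1) return(tab)
    lvl <- ifelse(tab$total_reads > 0, tab$meth_reads / tab$total_reads, 0)
    tot <- as.integer(round(tab$total_reads * f))
    tab$total_reads <- tot
    tab$meth_reads <- pmin(as.integer(round(lvl * tot)), tot)
    tab
  }
  out <- rbind(rescale(rapa, fr), rescale(oleracea, fo))
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Build the full in silico hybrid from a simulated dataset
#'
#' Convenience wrapper applying [mix_tracks_and_peaks()] per assay,
#' [mix_expression()] and [mix_methylome()] to the progenitor slices of a
#' [simulate_dataset()] result, yielding the "A_C" genotype.
#'
#' @param sim output of [simulate_dataset()].
#' @return list with `peaks`, `histone_peaks`, `tracks`, `counts`, `tpm`,
#'   `methylome` for genotype "A_C".
#' @export
build_hybrid <- function(sim) {
  cfg <- sim$config
  layout <- sim$genome$layout
  gsize <- c(rapa = sum(layout$length[layout$subgenome == "A"]),
             oleracea = sum(layout$length[layout$subgenome == "C"]))
  pick_tracks <- function(g, assay)
    lapply(seq_len(cfg$n_replicates), function(r)
      sim$accessibility$tracks[[paste(g, assay, r, sep = ".")]])

  atac <- mix_tracks_and_peaks(
    list(tracks = pick_tracks("rapa", "ATAC"),
         peaks = sim$accessibility$peaks$rapa),
    list(tracks = pick_tracks("oleracea", "ATAC"),
         peaks = sim$accessibility$peaks$oleracea))
  tracks <- setNames(atac$tracks,
                     paste("A_C", "ATAC", seq_len(cfg$n_replicates),
                           sep = "."))
  histone_peaks <- list()
  for (m in .MARKS) {
    hm <- mix_tracks_and_peaks(
      list(tracks = pick_tracks("rapa", m),
           peaks = cbind(sim$accessibility$histone_peaks$rapa[[m]],
                         pileup = 1)),
      list(tracks = pick_tracks("oleracea", m),
           peaks = cbind(sim$accessibility$histone_peaks$oleracea[[m]],
                         pileup = 1)))
    for (r in seq_len(cfg$n_replicates))
      tracks[[paste("A_C", m, r, sep = ".")]] <- hm$tracks[[r]]
    histone_peaks[[m]] <- hm$peaks[, c("chrom", "start", "end", "locus_id")]
  }
  expr <- mix_expression(sim$expression$counts$rapa,
                         sim$expression$counts$oleracea,
                         sim$expression$gene_length)
  meth <- lapply(seq_len(cfg$n_replicates), function(r)
    mix_methylome(sim$methylome$rapa[[r]], sim$methylome$oleracea[[r]],
                  gsize))
  list(peaks = atac$peaks, histone_peaks = histone_peaks, tracks = tracks,
       counts = expr$counts, tpm = expr$tpm, methylome = meth,
       scale = atac$scale)
}
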