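# Synthetic multi-omic dataset with known ground truth.
#
# The generator emulates the study design downstream code assumes: an
# allopolyploid coordinate system with A and C subgenomes; diploid progenitors
# ("rapa" on A, "oleracea" on C) whose data are later mixed into the in silico
# hybrid "A_C"; and two allopolyploids ("RAC" resynthesized, "NAC" natural).
# ACR loci, differential enrichment, histone-mark combinations, methylation
# depletion inside ACRs, DEGs and homeolog expression bias are all planted and
# recorded in truth tables.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_dataset()]. Defaults are
#' sized for fast desk-scale generation (2 chromosomes of 1 Mb per subgenome,
#' 200 genes, 300 ACRs per genotype) while keeping every downstream analysis
#' non-degenerate.
#'
#' @param seed integer; fully determines the dataset.
#' @param n_chroms_per_subgenome chromosomes per subgenome.
#' @param chrom_length chromosome length in bp.
#' @param n_homeolog_pairs homeolog gene pairs (one A + one C gene each).
#' @param n_unique_genes_per_subgenome subgenome-unique genes per subgenome.
#' @param dup_class_proportions named proportions over the six duplicate
#'   classes; must sum to 1.
#' @param n_acrs_per_genotype planted ACRs per genotype (before the
#'   sub-threshold fold-enrichment decoys are added).
#' @param frac_common,frac_specific,frac_dea fractions of each genotype's
#'   ACRs that are common to all three genotypes, genotype-specific, or
#'   common with planted differential enrichment; must sum to <= 1 (the
#'   remainder is shared by exactly two genotypes).
#' @param dea_log2fc planted log2 pileup/coverage difference for DEA loci.
#' @param frac_low_fe extra decoy peaks (fraction of
#'   `n_acrs_per_genotype`) with fold enrichment <= 3.4, which the ACR filter
#'   must remove.
#' @param acr_tss_fraction fraction of ACR loci anchored just upstream of a
#'   gene TSS (the rest are intergenic).
#' @param acr_tss_offset bp between the TSS and the summit of TSS-anchored
#'   ACRs (summit upstream of the TSS).
#' @param peak_width_mean mean ACR width in bp (widths vary +/- 25%).
#' @param pileup_mean,pileup_log2_sd lognormal pileup model for planted ACRs.
#' @param track_bin bin width (bp) of generated coverage tracks.
#' @param background_rate background per-base read rate of tracks.
#' @param track_bg_log_sd log-sd of the slowly varying per-bin background
#'   profile; the profile is drawn once per genotype and assay and shared by
#'   its replicates (as local accessibility structure is in real libraries),
#'   which is what makes replicate rank correlations informative.
#' @param peak_enrichment mean in-peak rate as a multiple of
#'   `background_rate`.
#' @param noise "poisson" for sampled tracks/counts, "none" for expected
#'   values (used to verify exact truth recovery).
#' @param meth_base_rate named per-context (CG/CHG/CHH) methylation rates.
#' @param acr_meth_depletion multiplier applied to methylation rates inside
#'   ACRs.
#' @param cytosine_spacing average bp between simulated cytosines.
#' @param meth_coverage_mean mean per-site bisulfite coverage (Poisson; some
#'   sites fall below the coverage-3 rule by design).
#' @param nb_mean,nb_dispersion negative-binomial expression model
#'   (`var = mu + dispersion * mu^2`).
#' @param deg_fraction,deg_log2fc fraction of genes planted as DEGs and
#'   their log2 fold change.
#' @param beg_fraction,beg_log2fc fraction of homeolog pairs planted with
#'   biased expression and the bias magnitude.
#' @param n_replicates biological replicates per genotype and assay.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms_per_subgenome = 2L,
                       chrom_length = 1e6,
                       n_homeolog_pairs = 60L,
                       n_unique_genes_per_subgenome = 40L,
                       dup_class_proportions = c(singleton = 0.40, WGD = 0.25,
                                                 TD = 0.10, TRD = 0.10,
                                                 DSD = 0.10, PD = 0.05),
                       n_acrs_per_genotype = 300L,
                       frac_common = 0.3,
                       frac_specific = 0.5,
                       frac_dea = 0.2,
                       dea_log2fc = 2,
                       frac_low_fe = 0.1,
                       acr_tss_fraction = 0.3,
                       acr_tss_offset = 100L,
                       peak_width_mean = 400L,
                       pileup_mean = 50,
                       pileup_log2_sd = 0.5,
                       track_bin = 100L,
                       background_rate = 0.2,
                       track_bg_log_sd = 0.5,
                       peak_enrichment = 20,
                       noise = c("poisson", "none"),
                       meth_base_rate = c(CG = 0.60, CHG = 0.30, CHH = 0.08),
                       acr_meth_depletion = 0.2,
                       cytosine_spacing = 40L,
                       meth_coverage_mean = 8,
                       nb_mean = 100,
                       nb_dispersion = 0.05,
                       deg_fraction = 0.1,
                       deg_log2fc = 3,
                       beg_fraction = 0.2,
                       beg_log2fc = 2,
                       n_replicates = 3L) {
  noise <- match.arg(noise)
  cfg <- as.list(environment())
  fr <- c(frac_common, frac_specific, frac_dea)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12)
    stop("ACR fractions must lie in [0,1] and sum to <= 1")
  if (abs(sum(dup_class_proportions) - 1) > 1e-8)
    stop("dup_class_proportions must sum to 1")
  if (!setequal(names(dup_class_proportions),
                c("singleton", "WGD", "TD", "TRD", "DSD", "PD")))
    stop("dup_class_proportions must name the six duplicate classes")
  if (!setequal(names(meth_base_rate), c("CG", "CHG", "CHH")))
    stop("meth_base_rate must name contexts CG, CHG, CHH")
  stopifnot(chrom_length > 0, n_replicates >= 2, peak_enrichment > 0,
            background_rate >= 0, acr_meth_depletion >= 0,
            all(meth_base_rate >= 0), all(meth_base_rate <= 1))
  structure(cfg, class = "sim_config")
}

.GENOTYPES <- c("A_C", "RAC", "NAC")
.PARENT_OF <- c(A = "rapa", C = "oleracea")
.MARKS <- c("H3K4me3", "H3K27ac", "H3K27me3")

# combos defining the six histone-association clusters (plus none / all three)
.HISTONE_COMBOS <- list(
  none = character(), c1 = "H3K27me3", c2 = "H3K4me3", c3 = "H3K27ac",
  c4 = c("H3K27me3", "H3K4me3"), c5 = c("H3K4me3", "H3K27ac"),
  c6 = c("H3K27me3", "H3K27ac"),
  all3 = c("H3K4me3", "H3K27ac", "H3K27me3"))
.COMBO_CLUSTER <- c(none = NA_integer_, c1 = 1L, c2 = 2L, c3 = 3L, c4 = 4L,
                    c5 = 5L, c6 = 6L, all3 = NA_integer_)

# deterministic apportionment of n among round(p*n) with remainder to largest
.apportion <- function(n, p) {
  k <- floor(p * n)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(p * n - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

#' Generate the genome layout and gene annotation
#'
#' Places non-overlapping genes on a two-subgenome chromosome set, links
#' homeolog pairs across subgenomes and assigns duplicate classes in the
#' configured proportions.
#'
#' @param config a [sim_config()].
#' @return list with `layout` (genome layout) and `genes` (gene-model table
#'   including `length` and the placement unit used internally).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  n_chr <- config$n_chroms_per_subgenome
  layout <- genome_layout(
    chrom = c(paste0("A", seq_len(n_chr)), paste0("C", seq_len(n_chr))),
    length = rep(config$chrom_length, 2L * n_chr),
    subgenome = rep(c("A", "C"), each = n_chr))
  unit <- 5000L
  units_per_chrom <- floor(config$chrom_length / unit)
  all_units <- data.frame(
    chrom = rep(layout$chrom, each = units_per_chrom),
    u = rep(seq_len(units_per_chrom) - 1L, times = nrow(layout)))
  all_units$subgenome <- layout$subgenome[match(all_units$chrom,
                                                layout$chrom)]

  n_per_sub <- config$n_homeolog_pairs + config$n_unique_genes_per_subgenome
  pick <- function(sub, n) {
    idx <- which(all_units$subgenome == sub)
    if (n > length(idx))
      stop("genes cannot fit without overlap; increase chrom_length or ",
           "n_chroms_per_subgenome")
    sample(idx, n)
  }
  a_units <- pick("A", n_per_sub)
  c_units <- pick("C", n_per_sub)

  mk_genes <- function(units_idx, sub, ids) {
    n <- length(units_idx)
    len <- as.integer(round(runif(n, 1000, 3000)))
    start <- all_units$u[units_idx] * unit + 1500L
    data.frame(gene_id = ids, chrom = all_units$chrom[units_idx],
               start = start, end = start + len,
               strand = sample(c("+", "-"), n, replace = TRUE),
               subgenome = sub, homeolog_partner = NA_character_,
               origin_class = "subgenome_unique",
               dup_class = NA_character_, length = len,
               stringsAsFactors = FALSE)
  }
  np <- config$n_homeolog_pairs
  a_ids <- sprintf("gene_A%04d", seq_len(n_per_sub))
  c_ids <- sprintf("gene_C%04d", seq_len(n_per_sub))
  ga <- mk_genes(a_units, "A", a_ids)
  gc <- mk_genes(c_units, "C", c_ids)
  if (np > 0) {
    ga$homeolog_partner[seq_len(np)] <- c_ids[seq_len(np)]
    gc$homeolog_partner[seq_len(np)] <- a_ids[seq_len(np)]
    ga$origin_class[seq_len(np)] <- "homeolog"
    gc$origin_class[seq_len(np)] <- "homeolog"
  }
  genes <- rbind(ga, gc)
  classes <- names(config$dup_class_proportions)
  counts <- .apportion(nrow(genes), config$dup_class_proportions)
  genes$dup_class <- sample(rep(classes, counts))
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  validate_genes(genes, layout)
  list(layout = layout, genes = genes, unit = unit,
       units_per_chrom = units_per_chrom)
}

# internal: choose coordinates for every ACR locus; returns the locus truth
# table shared by the accessibility, methylome and track generators
.plan_acr_loci <- function(config, genome) {
  n <- config$n_acrs_per_genotype
  n_common <- round(config$frac_common * n)
  n_dea <- round(config$frac_dea * n)
  n_spec <- round(config$frac_specific * n)
  n_two <- n - n_common - n_dea - n_spec
  if (n_two < 0L) { n_spec <- n_spec + n_two; n_two <- 0L }
  # membership patterns over (A_C, RAC, NAC); shared loci appear once,
  # genotype-specific and two-way loci are planted per genotype/pair so each
  # genotype ends up with exactly n ACRs
  pat <- list()
  add <- function(members, kind, k) {
    if (k > 0)
      pat[[length(pat) + 1L]] <<- data.frame(
        kind = kind, members = paste(members, collapse = ","),
        n = k, stringsAsFactors = FALSE)
  }
  add(.GENOTYPES, "common", n_common)
  add(.GENOTYPES, "dea", n_dea)
  for (g in .GENOTYPES) add(g, "specific", n_spec)
  # each genotype sits in two of the three pairs, so planting n_two/2 loci
  # per pair gives every genotype ~n_two two-way ACRs
  pairs <- list(c("A_C", "RAC"), c("RAC", "NAC"), c("A_C", "NAC"))
  for (pr in pairs) add(pr, "shared_2way", n_two %/% 2L)
  pat <- do.call(rbind, pat)
  loci <- pat[rep(seq_len(nrow(pat)), pat$n), c("kind", "members")]
  n_loci <- nrow(loci)
  loci$locus_id <- sprintf("acr_%04d", seq_len(n_loci))
  rownames(loci) <- NULL

  # placement: a fraction at gene TSSs, the rest centered in gene-free units
  n_tss <- round(config$acr_tss_fraction * n_loci)
  genes <- genome$genes
  if (n_tss > nrow(genes)) n_tss <- nrow(genes)
  at_tss <- sample(c(rep(TRUE, n_tss), rep(FALSE, n_loci - n_tss)))
  width <- as.integer(round(runif(n_loci, 0.75, 1.25) *
                            config$peak_width_mean))
  tss_genes <- sample(nrow(genes), n_tss)
  gene_unit_key <- paste(genes$chrom, (genes$start - 1500L) %/% genome$unit)
  free <- expand.grid(chrom = genome$layout$chrom,
                      u = seq_len(genome$units_per_chrom) - 1L,
                      stringsAsFactors = FALSE)
  free <- free[!(paste(free$chrom, free$u) %in% gene_unit_key), ]
  n_free <- n_loci - n_tss
  if (n_free > nrow(free))
    stop("too many ACR loci for the genome size; increase chrom_length")
  free <- free[sample(nrow(free), n_free), ]

  loci$chrom <- NA_character_
  loci$summit <- NA_integer_
  gi <- 0L; fi <- 0L
  for (i in seq_len(n_loci)) {
    if (at_tss[i]) {
      gi <- gi + 1L
      g <- genes[tss_genes[gi], ]
      tss <- tss_position(g)
      dir <- if (g$strand == "+") -1L else 1L
      loci$chrom[i] <- g$chrom
      loci$summit[i] <- tss + dir * config$acr_tss_offset
    } else {
      fi <- fi + 1L
      loci$chrom[i] <- free$chrom[fi]
      loci$summit[i] <- as.integer(free$u[fi] * genome$unit +
                                   genome$unit %/% 2L)
    }
  }
  loci$start <- as.integer(loci$summit - width %/% 2L)
  loci$end <- loci$start + width
  loci$start <- pmax(loci$start, 0L)
  chr_len <- genome$layout$length[match(loci$chrom, genome$layout$chrom)]
  loci$end <- pmin(loci$end, chr_len)
  loci$anchored_tss <- at_tss

  # planted differential enrichment: each DEA locus is up in one genotype
  loci$dea_up_in <- NA_character_
  is_dea <- loci$kind == "dea"
  loci$dea_up_in[is_dea] <- sample(.GENOTYPES, sum(is_dea), replace = TRUE)
  # histone-mark combination (shared across genotypes); all six clusters
  # guaranteed non-empty among common loci
  combo_p <- c(none = 0.18, c1 = 0.12, c2 = 0.12, c3 = 0.12, c4 = 0.12,
               c5 = 0.12, c6 = 0.12, all3 = 0.10)
  loci$combo <- sample(names(combo_p), n_loci, replace = TRUE,
                       prob = combo_p)
  ci <- which(loci$kind %in% c("common", "dea"))
  loci$combo[ci[seq_len(6L)]] <- paste0("c", 1:6)
  loci$cluster <- .COMBO_CLUSTER[loci$combo]
  # pileup baseline per locus (shared across genotypes so only DEA differs)
  loci$base_pileup <- config$pileup_mean *
    2^rnorm(n_loci, 0, config$pileup_log2_sd)
  loci
}

.locus_members <- function(loci) strsplit(loci$members, ",", fixed = TRUE)

#' Generate ACRs, histone peak sets and coverage tracks
#'
#' Plants common, genotype-specific, two-way-shared and differentially
#' enriched ACR loci; builds per-genotype peak records (plus sub-threshold
#' fold-enrichment decoys), per-genotype histone peak sets realizing the six
#' cluster-defining mark combinations, and per-replicate binned coverage
#' tracks (Poisson background plus a triangular enrichment kernel over each
#' peak). Progenitor data ("rapa"/"oleracea") cover only their own subgenome
#' and carry the loci assigned to the in silico hybrid.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @return list with `peaks` (per genotype), `histone_peaks` (genotype ->
#'   mark), `tracks` (list of [signal_track()]), and `truth` (per-locus
#'   table).
#' @export
generate_accessibility <- function(config, genome) {
  set.seed(config$seed + 1L)
  loci <- .plan_acr_loci(config, genome)
  members <- .locus_members(loci)

  geno_sets <- c("rapa", "oleracea", "RAC", "NAC")
  sub_of <- setNames(genome$layout$subgenome, genome$layout$chrom)
  has_locus <- function(g) {
    if (g %in% c("rapa", "oleracea")) {
      sub <- names(.PARENT_OF)[.PARENT_OF == g]
      vapply(members, function(m) "A_C" %in% m, TRUE) &
        sub_of[loci$chrom] == sub
    } else {
      vapply(members, function(m) g %in% m, TRUE)
    }
  }
  dea_mult <- function(g, idx) {
    eff <- loci$dea_up_in[idx]
    gg <- if (g %in% c("rapa", "oleracea")) "A_C" else g
    ifelse(!is.na(eff) & eff == gg, 2^config$dea_log2fc, 1)
  }

  peaks <- list()
  for (g in geno_sets) {
    idx <- which(has_locus(g))
    pu <- loci$base_pileup[idx] * dea_mult(g, idx)
    n <- length(idx)
    pk <- data.frame(
      chrom = loci$chrom[idx], start = loci$start[idx], end = loci$end[idx],
      name = paste0(g, "_", loci$locus_id[idx]), pileup = pu,
      strand = rep(".", n),
      fold_enrichment = runif(n, 4, 15),
      pvalue = 10^(-runif(n, 5, 50)),
      qvalue = 10^(-runif(n, 4, 40)),
      summit_offset = loci$summit[idx] - loci$start[idx],
      locus_id = loci$locus_id[idx], stringsAsFactors = FALSE)
    # sub-threshold decoys the fold-enrichment filter must drop
    n_lo <- round(config$frac_low_fe * config$n_acrs_per_genotype)
    if (n_lo > 0) {
      chr <- if (g == "rapa") genome$layout$chrom[genome$layout$subgenome == "A"]
             else if (g == "oleracea")
               genome$layout$chrom[genome$layout$subgenome == "C"]
             else genome$layout$chrom
      st <- as.integer(runif(n_lo, 0, config$chrom_length - 500))
      lo <- data.frame(
        chrom = sample(chr, n_lo, replace = TRUE), start = st,
        end = st + 300L, name = paste0(g, "_lowfe_", seq_len(n_lo)),
        pileup = runif(n_lo, 1, 10), strand = ".",
        fold_enrichment = runif(n_lo, 1, 3.4),
        pvalue = 10^(-runif(n_lo, 2, 5)), qvalue = 10^(-runif(n_lo, 1, 4)),
        summit_offset = 150L, locus_id = NA_character_,
        stringsAsFactors = FALSE)
      pk <- rbind(pk, lo)
    }
    pk <- pk[order(pk$chrom, pk$start), ]
    rownames(pk) <- NULL
    peaks[[g]] <- pk
  }

  histone_peaks <- list()
  for (g in geno_sets) {
    idx <- which(has_locus(g))
    hp <- list()
    for (m in .MARKS) {
      has_m <- vapply(loci$combo[idx],
                      function(cb) m %in% .HISTONE_COMBOS[[cb]], TRUE)
      sel <- idx[has_m]
      hp[[m]] <- data.frame(chrom = loci$chrom[sel],
                            start = pmax(loci$start[sel] - 100L, 0L),
                            end = loci$end[sel] + 100L,
                            locus_id = loci$locus_id[sel],
                            stringsAsFactors = FALSE)
    }
    histone_peaks[[g]] <- hp
  }

  tracks <- .generate_tracks(config, genome, loci, peaks, histone_peaks)

  truth <- loci[, c("locus_id", "kind", "members", "chrom", "start", "end",
                    "summit", "anchored_tss", "dea_up_in", "combo",
                    "cluster", "base_pileup")]
  list(peaks = peaks, histone_peaks = histone_peaks, tracks = tracks,
       truth = truth)
}

# internal: binned coverage tracks for every genotype x assay x replicate
.generate_tracks <- function(config, genome, loci, peaks, histone_peaks) {
  bw <- config$track_bin
  bg <- config$background_rate
  amp0 <- bg * (config$peak_enrichment - 1)  # mean extra rate over a peak
  sub_of <- setNames(genome$layout$subgenome, genome$layout$chrom)
  chroms_for <- function(g) {
    if (g == "rapa") genome$layout$chrom[genome$layout$subgenome == "A"]
    else if (g == "oleracea")
      genome$layout$chrom[genome$layout$subgenome == "C"]
    else genome$layout$chrom
  }
  tracks <- list()
  for (g in c("rapa", "oleracea", "RAC", "NAC")) {
    chroms <- chroms_for(g)
    grid <- do.call(rbind, lapply(chroms, function(ch) {
      len <- genome$layout$length[genome$layout$chrom == ch]
      nb <- floor(len / bw)
      data.frame(chrom = ch, start = (seq_len(nb) - 1L) * bw,
                 end = seq_len(nb) * bw, stringsAsFactors = FALSE)
    }))
    mid <- (grid$start + grid$end) / 2
    for (assay in c("ATAC", .MARKS)) {
      # replicate-shared background structure for this genotype/assay
      lam <- bg * exp(rnorm(nrow(grid), 0, config$track_bg_log_sd) -
                        config$track_bg_log_sd^2 / 2)
      if (assay == "ATAC") {
        pk <- peaks[[g]]
        pk <- pk[!is.na(pk$locus_id), ]  # decoys carry no real enrichment
        amp <- amp0 * pk$pileup /
          mean(loci$base_pileup)  # track enrichment scales with pileup
      } else {
        pk <- histone_peaks[[g]][[assay]]
        amp <- rep(amp0, nrow(pk))
      }
      if (nrow(pk)) {
        ov <- overlap_query(grid, pk[, c("chrom", "start", "end")])
        if (nrow(ov)) {
          i <- ov$query; j <- ov$subject
          ctr <- (pk$start[j] + pk$end[j]) / 2
          half <- (pk$end[j] - pk$start[j]) / 2
          w <- pmax(0, 2 * (1 - abs(mid[i] - ctr) / half))  # mean 1 over peak
          extra <- tapply(amp[j] * w, i, sum)
          lam[as.integer(names(extra))] <- lam[as.integer(names(extra))] +
            as.numeric(extra)
        }
      }
      for (r in seq_len(config$n_replicates)) {
        reads <- if (config$noise == "poisson") rpois(length(lam), lam * bw)
                 else lam * bw
        steps <- data.frame(chrom = grid$chrom, start = grid$start,
                            end = grid$end, value = reads / bw,
                            stringsAsFactors = FALSE)
        tracks[[paste(g, assay, r, sep = ".")]] <-
          signal_track(steps, assay = assay, genotype = g, replicate = r,
                       total_mapped_reads = max(sum(reads), 1))
      }
    }
  }
  tracks
}

#' Generate per-cytosine methylation tables
#'
#' Simulates cytosines on a jittered grid with Poisson coverage (some sites
#' below the coverage-3 missing-data rule by design) and binomial methylated
#' counts at context-specific base rates, multiplied by
#' `acr_meth_depletion` inside the genotype's ACRs.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @param peaks per-genotype peak tables (e.g. from
#'   [generate_accessibility()]).
#' @return named list: genotype -> replicate -> site table (`chrom`, `pos`,
#'   `strand`, `context`, `meth_reads`, `total_reads`).
#' @export
generate_methylome <- function(config, genome, peaks) {
  set.seed(config$seed + 2L)
  out <- list()
  for (g in names(peaks)) {
    chroms <- unique(peaks[[g]]$chrom)
    if (g %in% c("rapa", "oleracea")) {
      sub <- names(.PARENT_OF)[.PARENT_OF == g]
      chroms <- genome$layout$chrom[genome$layout$subgenome == sub]
    } else chroms <- genome$layout$chrom
    sites <- do.call(rbind, lapply(chroms, function(ch) {
      len <- genome$layout$length[genome$layout$chrom == ch]
      pos <- seq(1L, len - 1L, by = config$cytosine_spacing)
      data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
    }))
    n <- nrow(sites)
    sites$strand <- sample(c("+", "-"), n, replace = TRUE)
    sites$context <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE,
                            prob = c(0.25, 0.25, 0.5))
    rate <- config$meth_base_rate[sites$context]
    acr <- merge_intervals(peaks[[g]][, c("chrom", "start", "end")])
    si <- data.frame(chrom = sites$chrom, start = sites$pos,
                     end = sites$pos + 1L)
    ov <- overlap_query(si, acr)
    in_acr <- logical(n)
    in_acr[unique(ov$query)] <- TRUE
    rate[in_acr] <- rate[in_acr] * config$acr_meth_depletion
    for (r in seq_len(config$n_replicates)) {
      tot <- rpois(n, config$meth_coverage_mean)
      mr <- rbinom(n, tot, rate)
      tab <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        strand = sites$strand, context = sites$context,
                        meth_reads = mr, total_reads = tot,
                        stringsAsFactors = FALSE)
      out[[g]][[r]] <- tab
    }
  }
  out
}

#' Generate expression count matrices with planted DEGs and homeolog bias
#'
#' Homeolog partners share a baseline mean so expression bias is attributable
#' to the planted BEG effect alone; DEG genes are shifted by `deg_log2fc` in
#' one designated genotype (progenitors inherit shifts designated for the in
#' silico hybrid). TPM is computed from counts and gene lengths.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @return list with `counts`/`tpm` (per genotype: genes x replicates),
#'   `gene_length`, and `truth` (per-gene `deg_up_in`, `beg_class`).
#' @export
generate_expression <- function(config, genome) {
  set.seed(config$seed + 3L)
  genes <- genome$genes
  n <- nrow(genes)
  base <- setNames(config$nb_mean * 2^rnorm(n, 0, 1.2), genes$gene_id)
  # homeolog partners share the baseline (A copy's value wins)
  paired <- !is.na(genes$homeolog_partner) & genes$subgenome == "C"
  base[genes$gene_id[paired]] <- base[genes$homeolog_partner[paired]]
  # a slice of subgenome-unique genes is silenced to exercise the "none"
  # expression class (pairs keep both copies expressed so homeolog-bias
  # truth stays attributable to the planted BEG effect alone)
  uniq <- which(is.na(genes$homeolog_partner))
  silent <- sample(uniq, round(0.05 * n))
  base[silent] <- 0

  # planted DEGs: up in one designated genotype; a shift planted on one copy
  # of a homeolog pair is applied to both copies so it does not masquerade
  # as expression bias within a genotype
  deg_up_in <- setNames(rep(NA_character_, n), genes$gene_id)
  expressed <- which(base > 0)
  n_deg <- round(config$deg_fraction * n)
  deg_idx <- sample(expressed, min(n_deg, length(expressed)))
  deg_up_in[deg_idx] <- sample(.GENOTYPES, length(deg_idx), replace = TRUE)
  partner <- genes$homeolog_partner[deg_idx]
  has_p <- !is.na(partner)
  deg_up_in[partner[has_p]] <- deg_up_in[deg_idx][has_p]

  # planted BEGs among homeolog pairs (pair identified by its A-subgenome id)
  a_paired <- genes$gene_id[!is.na(genes$homeolog_partner) &
                            genes$subgenome == "A"]
  beg_class <- setNames(rep(NA_character_, n), genes$gene_id)
  beg_class[a_paired] <- "no_BEG"
  n_beg <- round(config$beg_fraction * length(a_paired))
  beg_pairs <- sample(a_paired, n_beg)
  beg_class[beg_pairs] <- sample(c("A_BEG", "C_BEG"), n_beg, replace = TRUE)

  mu_for <- function(g) {
    mu <- base
    gg <- if (g %in% c("rapa", "oleracea")) "A_C" else g
    up <- !is.na(deg_up_in) & deg_up_in == gg
    mu[up] <- mu[up] * 2^config$deg_log2fc
    for (a_id in a_paired) {
      cls <- beg_class[a_id]
      c_id <- genes$homeolog_partner[genes$gene_id == a_id]
      if (cls == "A_BEG") mu[a_id] <- mu[a_id] * 2^config$beg_log2fc
      if (cls == "C_BEG") mu[c_id] <- mu[c_id] * 2^config$beg_log2fc
    }
    mu
  }
  gene_length <- setNames(genes$length, genes$gene_id)
  counts <- list(); tpm <- list()
  for (g in c("rapa", "oleracea", "RAC", "NAC")) {
    ids <- if (g == "rapa") genes$gene_id[genes$subgenome == "A"]
           else if (g == "oleracea") genes$gene_id[genes$subgenome == "C"]
           else genes$gene_id
    mu <- mu_for(g)[ids]
    m <- matrix(0, length(ids), config$n_replicates,
                dimnames = list(ids, paste0(g, "_rep",
                                            seq_len(config$n_replicates))))
    for (r in seq_len(config$n_replicates)) {
      m[, r] <- if (config$noise == "poisson")
        rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
      else mu
    }
    counts[[g]] <- m
    tpm[[g]] <- compute_tpm(m, gene_length[ids])
  }
  truth <- data.frame(gene_id = genes$gene_id,
                      deg_up_in = unname(deg_up_in[genes$gene_id]),
                      beg_class = unname(beg_class[genes$gene_id]),
                      stringsAsFactors = FALSE)
  list(counts = counts, tpm = tpm, gene_length = gene_length, truth = truth)
}

#' Generate the full synthetic dataset
#'
#' Runs the genome, accessibility, methylome and expression generators under
#' one seed. The result is fully determined by the configuration.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genome`, `accessibility`, `methylome`,
#'   `expression`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- generate_genome(config)
  acc <- generate_accessibility(config, genome)
  meth <- generate_methylome(config, genome, acc$peaks)
  expr <- generate_expression(config, genome)
  list(config = config, genome = genome, accessibility = acc,
       methylome = meth, expression = expr)
}
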