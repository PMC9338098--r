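# Orchestration: simulate -> hybrid -> acr -> profiles -> methylation ->
# expression -> report, as resumable stages over one in-memory state, with
# flat TSV outputs and a JSON manifest (parameters + md5 of every file) per
# stage. Reruns with the same configuration are byte-identical.

.STAGES <- c("simulate", "hybrid", "acr", "profiles", "methylation",
             "expression", "report")
.COMPARISONS <- list(c("A_C", "RAC"), c("A_C", "NAC"), c("RAC", "NAC"))

#' Merge replicate tracks into one
#'
#' Sums step values (tracks must share the same step grid) and library
#' sizes; the result carries replicate id "merged".
#'
#' @param tracks list of [signal_track()]s of one genotype/assay.
#' @return A merged [signal_track()].
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  base <- tracks[[1L]]
  steps <- base$steps
  if (length(tracks) > 1L) {
    for (tr in tracks[-1L]) {
      if (!identical(dim(tr$steps), dim(steps)) ||
          !identical(tr$steps$start, steps$start))
        stop("replicate tracks must share the same step grid")
      steps$value <- steps$value + tr$steps$value
    }
  }
  signal_track(steps, assay = base$assay, genotype = base$genotype,
               replicate = "merged",
               total_mapped_reads = sum(vapply(tracks, function(t)
                 t$total_mapped_reads, 0)))
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

.manifest <- function(outdir, stage, files, params) {
  md5 <- as.list(tools::md5sum(files))
  names(md5) <- basename(files)
  jsonlite::write_json(
    list(stage = stage, params = params, files = md5),
    file.path(outdir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in order. Each stage writes its result
#' tables and a manifest to `outdir`; the returned state carries every
#' in-memory object so stages can be rerun or inspected. All randomness is
#' governed by `config$seed`, and reruns with an unchanged configuration
#' produce byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param stages subset of `c("simulate", "hybrid", "acr", "profiles",
#'   "methylation", "expression", "report")`; dependencies must be included
#'   or already present in `state`.
#' @param state optional state from a previous call (for resuming).
#' @param quiet suppress per-stage progress messages.
#' @return The pipeline state (named list), invisibly.
#' @export
run_pipeline <- function(config = sim_config(), outdir, stages = .STAGES,
                         state = list(), quiet = FALSE) {
  stages <- match.arg(stages, .STAGES, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- config[!vapply(config, is.function, TRUE)]
  note <- function(...) if (!quiet) message(sprintf(...))
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop(sprintf("stage '%s' requires stage '%s' to have run", stage,
                   what))
  }
  t0 <- proc.time()[["elapsed"]]

  if ("simulate" %in% stages) {
    note("[simulate] generating synthetic dataset (seed %d)", config$seed)
    state$simulate <- simulate_dataset(config)
    sim <- state$simulate
    files <- c(
      .write_tsv(sim$genome$layout, file.path(outdir, "genome_layout.tsv")),
      .write_tsv(sim$genome$genes, file.path(outdir, "genes.tsv")),
      .write_tsv(sim$accessibility$truth,
                 file.path(outdir, "truth_acr.tsv")),
      .write_tsv(sim$expression$truth,
                 file.path(outdir, "truth_gene.tsv")),
      vapply(c("rapa", "oleracea", "RAC", "NAC"), function(g)
        write_intervals(sim$accessibility$peaks[[g]],
                        file.path(outdir, paste0("peaks_", g, ".narrowPeak")),
                        "narrowPeak"), ""))
    .manifest(outdir, "simulate", files, params)
  }

  if ("hybrid" %in% stages) {
    need("simulate", "hybrid")
    note("[hybrid] mixing progenitors into the in silico hybrid")
    state$hybrid <- build_hybrid(state$simulate)
    files <- c(
      write_intervals(state$hybrid$peaks,
                      file.path(outdir, "peaks_A_C.narrowPeak"),
                      "narrowPeak"),
      .write_tsv(data.frame(replicate = seq_len(nrow(state$hybrid$scale)),
                            state$hybrid$scale),
                 file.path(outdir, "hybrid_scale_factors.tsv")))
    .manifest(outdir, "hybrid", files, params)
  }

  if ("acr" %in% stages) {
    need("simulate", "acr"); need("hybrid", "acr")
    note("[acr] filtering, annotating and comparing ACRs")
    sim <- state$simulate
    genes <- sim$genome$genes
    raw <- list(A_C = state$hybrid$peaks,
                RAC = sim$accessibility$peaks$RAC,
                NAC = sim$accessibility$peaks$NAC)
    hist_pk <- list(A_C = state$hybrid$histone_peaks,
                    RAC = sim$accessibility$histone_peaks$RAC,
                    NAC = sim$accessibility$histone_peaks$NAC)
    acrs <- lapply(raw, filter_acrs)
    ovc <- find_overlap_classes(acrs)
    ann <- list()
    for (g in names(acrs)) {
      a <- acrs[[g]]
      feat <- annotate_features(a, genes)
      a$genotype <- g
      a$genic_flag <- classify_genic_intergenic(a, genes)
      a$feature <- as.character(feat$feature)
      a$associated_gene <- feat$associated_gene
      a$overlap_class <- ovc$classes[[g]]
      a$decile <- rank_deciles(a)
      a$histone_cluster <- assign_histone_clusters(a, hist_pk[[g]])
      ann[[g]] <- partition_by_subgenome(a, sim$genome$layout)
    }
    tracks_of <- function(g) {
      src <- if (g == "A_C") state$hybrid$tracks else sim$accessibility$tracks
      lapply(seq_len(config$n_replicates), function(r)
        src[[paste(g, "ATAC", r, sep = ".")]])
    }
    deas <- list()
    for (cmp in .COMPARISONS) {
      nm <- paste0(cmp[1], "_vs_", cmp[2])
      deas[[nm]] <- call_deas(ann[[cmp[1]]], ann[[cmp[2]]],
                              tracks_of(cmp[1]), tracks_of(cmp[2]))
    }
    state$acr <- list(acrs = ann, venn = ovc$counts, deas = deas,
                      histone_peaks = hist_pk)
    files <- c(
      vapply(names(ann), function(g)
        .write_tsv(ann[[g]], file.path(outdir, paste0("acr_", g, ".tsv"))),
        ""),
      .write_tsv(ovc$counts, file.path(outdir, "acr_venn_counts.tsv")),
      vapply(names(deas), function(nm)
        .write_tsv(deas[[nm]], file.path(outdir, paste0("dea_", nm, ".tsv"))),
        ""))
    .manifest(outdir, "acr", files, params)
  }

  if ("profiles" %in% stages) {
    need("simulate", "profiles"); need("acr", "profiles")
    note("[profiles] TSS and peak-center meta-profiles, replicate QC")
    sim <- state$simulate
    genes <- sim$genome$genes
    tss_anchors <- data.frame(region_id = genes$gene_id,
                              chrom = genes$chrom,
                              anchor = tss_position(genes),
                              strand = genes$strand)
    curves <- list(); spear <- list()
    for (g in c("A_C", "RAC", "NAC")) {
      src <- if (g == "A_C") state$hybrid$tracks else sim$accessibility$tracks
      reps <- lapply(seq_len(config$n_replicates), function(r)
        src[[paste(g, "ATAC", r, sep = ".")]])
      merged <- merge_tracks(reps)
      tssm <- compute_matrix(merged, tss_anchors)
      a <- state$acr$acrs[[g]]
      ctr_anchors <- data.frame(region_id = a$name, chrom = a$chrom,
                                anchor = a$start + a$summit_offset,
                                strand = ".")
      ctrm <- compute_matrix(merged, ctr_anchors)
      curves[[g]] <- data.frame(
        genotype = g, bin_rel = tssm$bin_rel,
        tss_rpkm = profile_mean(tssm)$curve,
        acr_center_rpkm = profile_mean(ctrm)$curve)
      sp <- replicate_spearman(reps)
      spear[[g]] <- data.frame(genotype = g,
                               pair = apply(expand.grid(rownames(sp),
                                                        colnames(sp)), 1,
                                            paste, collapse = "_"),
                               rho = as.vector(sp))
    }
    state$profiles <- list(curves = curves, spearman = spear)
    files <- c(
      .write_tsv(do.call(rbind, curves),
                 file.path(outdir, "profiles_atac.tsv")),
      .write_tsv(do.call(rbind, spear),
                 file.path(outdir, "replicate_spearman.tsv")))
    .manifest(outdir, "profiles", files, params)
  }

  if ("methylation" %in% stages) {
    need("simulate", "methylation"); need("acr", "methylation")
    note("[methylation] weighted levels in ACRs and around peak centers")
    sim <- state$simulate
    meth_of <- function(g) {
      if (g == "A_C") state$hybrid$methylome[[1L]]
      else sim$methylome[[g]][[1L]]
    }
    lev_rows <- list(); prof_rows <- list()
    for (g in c("A_C", "RAC", "NAC")) {
      a <- state$acr$acrs[[g]]
      tab <- meth_of(g)
      ctr <- data.frame(chrom = a$chrom, anchor = a$start + a$summit_offset,
                        strand = ".")
      for (ctx in c("CG", "CHG", "CHH")) {
        lv <- region_level(tab, a, context = ctx)
        lev_rows[[paste(g, ctx)]] <- data.frame(
          genotype = g, context = ctx, n_acrs = sum(!is.na(lv)),
          mean_acr_level = mean(lv, na.rm = TRUE))
        pr <- methylation_profile(tab, ctr, context = ctx)
        pr$genotype <- g; pr$context <- ctx
        prof_rows[[paste(g, ctx)]] <- pr
      }
    }
    state$methylation <- list(acr_levels = do.call(rbind, lev_rows),
                              profiles = do.call(rbind, prof_rows))
    rownames(state$methylation$acr_levels) <- NULL
    files <- c(
      .write_tsv(state$methylation$acr_levels,
                 file.path(outdir, "methylation_acr_levels.tsv")),
      .write_tsv(state$methylation$profiles,
                 file.path(outdir, "methylation_profiles.tsv")))
    .manifest(outdir, "methylation", files, params)
  }

  if ("expression" %in% stages) {
    need("simulate", "expression"); need("hybrid", "expression")
    need("acr", "expression")
    note("[expression] TPM, DEGs, BEGs and ACR x DEG overlap")
    sim <- state$simulate
    counts <- list(A_C = state$hybrid$counts,
                   RAC = sim$expression$counts$RAC,
                   NAC = sim$expression$counts$NAC)
    tpm <- list(A_C = state$hybrid$tpm, RAC = sim$expression$tpm$RAC,
                NAC = sim$expression$tpm$NAC)
    genes <- sim$genome$genes
    cls <- do.call(rbind, lapply(names(tpm), function(g)
      data.frame(genotype = g, gene_id = rownames(tpm[[g]]),
                 mean_tpm = rowMeans(tpm[[g]]),
                 class = as.character(classify_expression(
                   rowMeans(tpm[[g]]))),
                 stringsAsFactors = FALSE)))
    rownames(cls) <- NULL
    degs <- list()
    for (cmp in .COMPARISONS) {
      nm <- paste0(cmp[1], "_vs_", cmp[2])
      degs[[nm]] <- call_degs(counts[[cmp[1]]], counts[[cmp[2]]])
    }
    pairs <- data.frame(
      a_gene = genes$gene_id[genes$subgenome == "A" &
                             !is.na(genes$homeolog_partner)],
      stringsAsFactors = FALSE)
    pairs$c_gene <- genes$homeolog_partner[match(pairs$a_gene,
                                                 genes$gene_id)]
    begs <- lapply(counts, classify_begs, pairs = pairs)
    # genotype-enriched ACR-associated genes vs genotype-enriched DEGs
    enr_genes <- function(g, dea, side) {
      a <- state$acr$acrs[[g]]
      spec <- a$associated_gene[a$overlap_class == "genotype_specific"]
      dea_enr <- dea[dea$status == side, c("chrom", "start", "end")]
      dg <- if (nrow(dea_enr))
        annotate_features(dea_enr, genes)$associated_gene else character()
      unique(na.omit(c(spec, dg)))
    }
    ovl_rows <- list()
    for (cmp in .COMPARISONS) {
      nm <- paste0(cmp[1], "_vs_", cmp[2])
      dea <- state$acr$deas[[nm]]
      deg <- degs[[nm]]
      for (side in 1:2) {
        g <- cmp[side]
        st <- c("enriched_in_x", "enriched_in_y")[side]
        dst <- c("up_in_x", "up_in_y")[side]
        res <- acr_deg_overlap(enr_genes(g, dea, st),
                               deg$gene_id[deg$status == dst])
        ovl_rows[[paste(nm, g)]] <- data.frame(
          comparison = nm, genotype = g, n_overlap = res$n_overlap,
          n_enriched_degs = res$n_degs, percent = res$percent)
      }
    }
    ovl <- do.call(rbind, ovl_rows)
    rownames(ovl) <- NULL
    state$expression <- list(counts = counts, tpm = tpm, classes = cls,
                             degs = degs, begs = begs, acr_deg = ovl)
    files <- c(
      .write_tsv(cls, file.path(outdir, "expression_classes.tsv")),
      vapply(names(degs), function(nm)
        .write_tsv(degs[[nm]], file.path(outdir, paste0("deg_", nm, ".tsv"))),
        ""),
      vapply(names(begs), function(g)
        .write_tsv(begs[[g]], file.path(outdir, paste0("beg_", g, ".tsv"))),
        ""),
      .write_tsv(ovl, file.path(outdir, "acr_deg_overlap.tsv")))
    .manifest(outdir, "expression", files, params)
  }

  if ("report" %in% stages) {
    need("acr", "report"); need("expression", "report")
    note("[report] consolidated subgenome asymmetry comparisons")
    sim <- state$simulate
    genes <- sim$genome$genes
    acr_tab <- do.call(rbind, lapply(state$acr$acrs, function(a)
      a[, c("genotype", "subgenome", "pileup", "genic_flag")]))
    cls <- state$expression$classes
    gene_tab <- cls
    gi <- match(gene_tab$gene_id, genes$gene_id)
    gene_tab$subgenome <- genes$subgenome[gi]
    gene_tab$origin_class <- genes$origin_class[gi]
    gene_tab$dup_class <- genes$dup_class[gi]
    rep <- asymmetry_report(acr_tab, gene_tab)
    state$report <- rep
    files <- .write_tsv(rep, file.path(outdir, "asymmetry_report.tsv"))
    .manifest(outdir, "report", files, params)
  }

  note("pipeline finished in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(state)
}
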