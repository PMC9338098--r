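# ACR taxonomy: filtering, genic/intergenic, feature annotation, overlap
# classes, differential enrichment, deciles, histone clusters

toy_genes <- function() {
  data.frame(
    gene_id = c("gPlus", "gMinus"), chrom = c("A1", "A1"),
    start = c(10000L, 40000L), end = c(12000L, 42000L),
    strand = c("+", "-"), subgenome = "A",
    homeolog_partner = NA_character_, origin_class = "subgenome_unique",
    dup_class = "singleton", stringsAsFactors = FALSE)
}

acr_at <- function(mid, w = 200L) {
  data.frame(chrom = "A1", start = mid - w %/% 2L, end = mid + w %/% 2L)
}

test_that("fold-enrichment filter is strict at the 3.4 boundary", {
  pk <- data.frame(fold_enrichment = c(3.5, 3.4, 3.41, 0.2, 12))
  expect_equal(filter_acrs(pk)$fold_enrichment, c(3.5, 3.41, 12))
  expect_equal(nrow(filter_acrs(pk[0, , drop = FALSE])), 0L)
  expect_error(filter_acrs(data.frame(x = 1)), "fold_enrichment")
})

test_that("genic/intergenic flags partition the set and use any-overlap", {
  genes <- toy_genes()
  acrs <- rbind(acr_at(9000L),            # fully upstream -> iACR
                data.frame(chrom = "A1", start = 9900L, end = 10001L),
                acr_at(11000L),           # inside -> gACR
                acr_at(20000L))           # far intergenic
  fl <- classify_genic_intergenic(acrs, genes)
  expect_equal(fl, c("iACR", "gACR", "gACR", "iACR"))
  set.seed(77)
  racr <- random_intervals(50, chroms = "A1", max_pos = 50000L)
  rfl <- classify_genic_intergenic(racr, genes)
  expect_equal(sum(rfl == "gACR") + sum(rfl == "iACR"), nrow(racr))
})

test_that("midpoint feature annotation follows the tiered priority", {
  genes <- toy_genes()
  cases <- list(
    list(acr_at(9500L), "promoter_1kb", "gPlus"),     # 500 bp upstream, +
    list(acr_at(8500L), "promoter_1_2kb", "gPlus"),
    list(acr_at(7500L), "promoter_2_3kb", "gPlus"),
    list(acr_at(42500L), "promoter_1kb", "gMinus"),   # upstream of - gene
    list(acr_at(11000L), "exon", "gPlus"),            # gene body
    list(acr_at(12200L), "downstream_300bp", "gPlus"),
    list(acr_at(39800L), "downstream_300bp", "gMinus"),
    list(acr_at(25000L), "distal_intergenic", NA))    # 13 kb from gPlus TSS
  for (cs in cases) {
    ann <- annotate_features(cs[[1]], genes)
    expect_equal(as.character(ann$feature), cs[[2]])
    if (is.na(cs[[3]])) expect_true(is.na(ann$associated_gene))
    else expect_equal(ann$associated_gene, cs[[3]])
  }
  # distal but within the 10 kb cap associates with the nearest TSS
  ann <- annotate_features(acr_at(18000L), genes)
  expect_equal(as.character(ann$feature), "distal_intergenic")
  expect_equal(ann$associated_gene, "gPlus")
})

test_that("UTR and intron features require the extra annotation tables", {
  genes <- toy_genes()
  exons <- data.frame(gene_id = "gPlus", chrom = "A1",
                      start = c(10000L, 11500L), end = c(10400L, 12000L))
  utrs <- data.frame(gene_id = "gPlus", chrom = "A1", start = 10000L,
                     end = 10150L, side = "five_prime")
  a_utr <- acr_at(10100L)
  a_intron <- acr_at(11000L)
  ann <- annotate_features(rbind(a_utr, a_intron), genes, exons = exons,
                           utrs = utrs)
  expect_equal(as.character(ann$feature), c("five_prime_UTR", "intron"))
  # without the tables both fall back to the gene body
  ann0 <- annotate_features(rbind(a_utr, a_intron), genes)
  expect_equal(as.character(ann0$feature), c("exon", "exon"))
})

test_that("feature assignment partitions every ACR set", {
  sim <- simulate_dataset(tiny_config())
  acrs <- filter_acrs(sim$accessibility$peaks$RAC)
  ann <- annotate_features(acrs, sim$genome$genes)
  expect_false(anyNA(ann$feature))
  pct <- 100 * table(ann$feature) / nrow(acrs)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("three-way overlap classes recover identical and disjoint sets", {
  a <- data.frame(chrom = "A1", start = c(0L, 100L), end = c(50L, 150L))
  sets <- list(A_C = a, RAC = a, NAC = a)
  oc <- find_overlap_classes(sets)
  expect_true(all(unlist(oc$classes) == "common_all3"))
  sets2 <- list(A_C = a,
                RAC = data.frame(chrom = "A1", start = 300L, end = 400L),
                NAC = data.frame(chrom = "A1", start = 600L, end = 700L))
  oc2 <- find_overlap_classes(sets2)
  expect_true(all(oc2$classes$RAC == "genotype_specific"))
  expect_true(all(oc2$classes$A_C == "genotype_specific"))
})

test_that("planted overlap classes are recovered exactly", {
  sim <- simulate_dataset(tiny_config())
  hyb <- build_hybrid(sim)
  sets <- list(A_C = filter_acrs(hyb$peaks),
               RAC = filter_acrs(sim$accessibility$peaks$RAC),
               NAC = filter_acrs(sim$accessibility$peaks$NAC))
  oc <- find_overlap_classes(sets)
  truth <- sim$accessibility$truth
  for (g in names(sets)) {
    got <- oc$classes[[g]]
    want_kind <- truth$kind[match(sets[[g]]$locus_id, truth$locus_id)]
    want <- ifelse(want_kind %in% c("common", "dea"), "common_all3",
            ifelse(want_kind == "specific", "genotype_specific",
                   "shared_2way"))
    expect_equal(got, want)
  }
})

test_that("dea_test handles identities and degenerate inputs", {
  x <- matrix(rep(c(8, 8, 8), each = 2), 2, byrow = FALSE)
  r <- dea_test(x, x)
  expect_equal(r$log2fc, c(0, 0))
  expect_equal(r$status, c("ns", "ns"))
  z <- matrix(0, 1, 3)
  expect_equal(dea_test(z, z)$status, "not_tested")
  expect_error(dea_test(matrix(1, 1, 1), matrix(1, 1, 3)), "2 replicates")
  # zero-variance separation is called with p = 0
  a <- matrix(8, 1, 3); b <- matrix(2, 1, 3)
  r2 <- dea_test(a, b)
  expect_equal(r2$status, "enriched_in_x")
  expect_equal(r2$log2fc, 2)
})

test_that("planted 4-fold differences are detected with correct direction", {
  set.seed(88)
  n <- 200
  base <- matrix(rnorm(n * 3, 100, 5), n)
  up <- matrix(rnorm(n * 3, 400, 20), n)
  r <- dea_test(up, base)
  expect_gte(mean(r$status == "enriched_in_x"), 0.95)
  expect_equal(sum(r$status == "enriched_in_y"), 0L)
})

test_that("dea caller type-I error is near nominal on null data", {
  set.seed(99)
  n <- 2000
  x <- matrix(exp(rnorm(n * 3, log(100), 0.1)), n)
  y <- matrix(exp(rnorm(n * 3, log(100), 0.1)), n)
  r <- dea_test(x, y)
  rate <- mean(r$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("call_deas recovers planted differential ACRs from tracks", {
  sim <- simulate_dataset(tiny_config(noise = "none"))
  hyb <- build_hybrid(sim)
  acrs <- list(A_C = filter_acrs(hyb$peaks),
               RAC = filter_acrs(sim$accessibility$peaks$RAC))
  tr <- function(g) {
    src <- if (g == "A_C") hyb$tracks else sim$accessibility$tracks
    lapply(1:3, function(r) src[[paste(g, "ATAC", r, sep = ".")]])
  }
  res <- call_deas(acrs$A_C, acrs$RAC, tr("A_C"), tr("RAC"))
  truth <- sim$accessibility$truth
  dea <- truth[truth$kind == "dea" & truth$dea_up_in %in% c("A_C", "RAC"), ]
  # map planted loci onto tested regions by overlap
  ov <- overlap_query(dea, res)
  expect_equal(nrow(ov), nrow(dea))
  got <- res$status[ov$subject]
  want <- ifelse(dea$dea_up_in == "A_C", "enriched_in_x", "enriched_in_y")
  expect_equal(got, want)
  # non-differential common loci are not called
  com <- truth[truth$kind == "common", ]
  ovc <- overlap_query(com, res)
  expect_true(all(res$status[ovc$subject] == "ns"))
})

test_that("decile ranking follows the remainder rule and sort order", {
  acrs <- data.frame(chrom = "A1", start = seq_len(20L) * 100L,
                     end = seq_len(20L) * 100L + 50L,
                     pileup = runif(20))
  d <- rank_deciles(acrs)
  expect_equal(as.integer(table(d)), rep(2L, 10))
  acrs23 <- data.frame(chrom = "A1", start = seq_len(23L),
                       end = seq_len(23L) + 1L, pileup = runif(23))
  d23 <- rank_deciles(acrs23)
  expect_equal(as.integer(table(d23)), c(3L, 3L, 3L, rep(2L, 7)))
  # ordering: max pileup of group k <= min of group k+1
  for (k in 1:9)
    expect_lte(max(acrs23$pileup[d23 == k]), min(acrs23$pileup[d23 == k + 1]))
  expect_error(rank_deciles(acrs[1:5, ]), "at least 10")
})

test_that("histone clusters map mark combinations as defined", {
  acr <- function(s) data.frame(chrom = "A1", start = s, end = s + 100L)
  acrs <- do.call(rbind, lapply(0:7 * 1000L, acr))
  mk <- function(rows) {
    if (!length(rows)) return(data.frame(chrom = character(),
                                         start = integer(),
                                         end = integer()))
    acrs[rows, , drop = FALSE]
  }
  hp <- list(H3K27me3 = mk(c(2, 5, 7, 8)), H3K4me3 = mk(c(3, 5, 6, 8)),
             H3K27ac = mk(c(4, 6, 7, 8)))
  cl <- assign_histone_clusters(acrs, hp)
  expect_equal(cl, c(NA, 1L, 2L, 3L, 4L, 5L, 6L, NA))
})

test_that("planted histone clusters are recovered exactly", {
  sim <- simulate_dataset(tiny_config())
  acrs <- filter_acrs(sim$accessibility$peaks$RAC)
  cl <- assign_histone_clusters(acrs, sim$accessibility$histone_peaks$RAC)
  truth <- sim$accessibility$truth
  want <- truth$cluster[match(acrs$locus_id, truth$locus_id)]
  # decoy peaks have no planted locus: they overlap no histone peak
  expect_equal(cl[!is.na(acrs$locus_id)], want[!is.na(acrs$locus_id)])
  expect_true(all(is.na(cl[is.na(acrs$locus_id)])))
})
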