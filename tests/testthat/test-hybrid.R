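# in silico hybrid construction: 1:1 mixing contracts, genome-size
# proportional methylation mixing, subgenome-restriction identities

make_parent <- function(chrom, total, values = c(2, 4), genotype = "p") {
  steps <- data.frame(chrom = chrom, start = c(0L, 100L),
                      end = c(100L, 200L), value = values)
  list(tracks = list(signal_track(steps, "ATAC", genotype, 1, total)),
       peaks = data.frame(chrom = chrom, start = 10L, end = 60L,
                          name = paste0(genotype, "_pk"), pileup = 20,
                          strand = ".", fold_enrichment = 5,
                          pvalue = 1e-10, qvalue = 1e-8,
                          summit_offset = 25L))
}

test_that("equal parental totals mix with unit scale factors", {
  r <- make_parent("A1", 1000, genotype = "rapa")
  o <- make_parent("C1", 1000, genotype = "oleracea")
  h <- mix_tracks_and_peaks(r, o)
  expect_equal(unname(h$scale[1, ]), c(1, 1))
  # hybrid restricted to the A subgenome is identical to the rapa track
  hs <- h$tracks[[1]]$steps
  expect_equal(hs[hs$chrom == "A1", ], r$tracks[[1]]$steps)
  expect_equal(h$tracks[[1]]$total_mapped_reads, 2000)
  expect_equal(nrow(h$peaks), 2L)
})

test_that("unbalanced totals 2N and N equalize to factors 0.5 and 1", {
  r <- make_parent("A1", 2000, genotype = "rapa")
  o <- make_parent("C1", 1000, genotype = "oleracea")
  h <- mix_tracks_and_peaks(r, o)
  expect_equal(unname(h$scale[1, ]), c(0.5, 1))
  hs <- h$tracks[[1]]$steps
  expect_equal(hs$value[hs$chrom == "A1"], c(1, 2))  # rescaled by 0.5
  expect_equal(hs$value[hs$chrom == "C1"], c(2, 4))
  expect_equal(h$peaks$pileup, c(10, 20))
})

test_that("overlapping parental chromosomes are rejected", {
  r <- make_parent("A1", 1000)
  o <- make_parent("A1", 1000)
  expect_error(mix_tracks_and_peaks(r, o), "disjoint")
})

test_that("mixing a hybrid with itself returns it up to rescaling", {
  r <- make_parent("A1", 1500, genotype = "rapa")
  o <- make_parent("C1", 1000, genotype = "oleracea")
  h <- mix_tracks_and_peaks(r, o)
  # split the hybrid back into its subgenome halves and remix
  halves <- lapply(c("A1", "C1"), function(ch) {
    st <- h$tracks[[1]]$steps
    st <- st[st$chrom == ch, ]
    rownames(st) <- NULL
    list(tracks = list(signal_track(st, "ATAC", "h", 1,
                                    h$tracks[[1]]$total_mapped_reads / 2)),
         peaks = h$peaks[h$peaks$chrom == ch, ])
  })
  h2 <- mix_tracks_and_peaks(halves[[1]], halves[[2]])
  expect_equal(h2$tracks[[1]]$steps$value, h$tracks[[1]]$steps$value)
})

test_that("expression mixing equalizes library sizes and recomputes TPM", {
  ra <- matrix(c(10, 20, 30, 40), 2,
               dimnames = list(c("gA1", "gA2"), NULL))
  ol <- matrix(c(30, 30, 90, 30), 2,
               dimnames = list(c("gC1", "gC2"), NULL))
  gl <- c(gA1 = 1000, gA2 = 2000, gC1 = 1000, gC2 = 1000)
  h <- mix_expression(ra, ol, gl)
  # rep 1: libraries 30 vs 60 -> oleracea scaled by 0.5
  expect_equal(unname(h$counts[, 1]), c(10, 20, 15, 15))
  expect_equal(unname(colSums(h$tpm)), rep(1e6, 2))
  # closed-form check of the A-subgenome TPM share in replicate 1:
  # rates 10, 10, 15, 15 -> A share = 20/50
  expect_equal(sum(h$tpm[c("gA1", "gA2"), 1]) / 1e6, 0.4)
  expect_error(mix_expression(ra, ol[, 1, drop = FALSE], gl), "mismatch")
})

test_that("identical parental counts mix to themselves under equal sizes", {
  ra <- matrix(c(50, 50), 1, dimnames = list("gA1", NULL))
  ol <- matrix(c(50, 50), 1, dimnames = list("gC1", NULL))
  h <- mix_expression(ra, ol, c(gA1 = 1000, gC1 = 1000))
  expect_equal(unname(h$counts), matrix(50, 2, 2))
})

test_that("methylome mixing splits coverage by genome size, keeps levels", {
  set.seed(55)
  mk <- function(chrom, n, cov) {
    tot <- rpois(n, cov) + 3L
    data.frame(chrom = chrom, pos = seq_len(n) * 50L, strand = "+",
               context = "CG", meth_reads = rbinom(n, tot, 0.4),
               total_reads = tot)
  }
  ra <- mk("A1", 400, 20)
  ol <- mk("C1", 400, 20)
  # equal sizes, equal depth: identity
  h0 <- mix_methylome(ra, ol, c(rapa = 1e6, oleracea = 1e6))
  expect_equal(sum(h0$total_reads), sum(ra$total_reads) +
                 sum(ol$total_reads))
  # genome sizes 529:630 -> coverage split within 1%
  h <- mix_methylome(ra, ol, c(rapa = 529e6, oleracea = 630e6))
  got <- sum(h$total_reads[h$chrom == "A1"]) /
    sum(h$total_reads[h$chrom == "C1"])
  expect_lt(abs(got - 529 / 630), 0.01 * 529 / 630)
  # per-site levels preserved within rounding
  hA <- h[h$chrom == "A1", ]
  m <- match(hA$pos, ra$pos)
  lv0 <- ra$meth_reads[m] / ra$total_reads[m]
  lv1 <- ifelse(hA$total_reads > 0, hA$meth_reads / hA$total_reads, lv0)
  expect_true(all(abs(lv1 - lv0) <= 1 / pmax(hA$total_reads, 1) + 1e-12))
})

test_that("full hybrid build restricts to parents up to rescaling", {
  sim <- simulate_dataset(tiny_config())
  hyb <- build_hybrid(sim)
  expect_equal(nrow(hyb$peaks),
               nrow(sim$accessibility$peaks$rapa) +
                 nrow(sim$accessibility$peaks$oleracea))
  tr <- hyb$tracks[["A_C.ATAC.1"]]
  pr <- sim$accessibility$tracks[["rapa.ATAC.1"]]
  a_steps <- tr$steps[startsWith(tr$steps$chrom, "A"), ]
  rownames(a_steps) <- NULL
  f <- hyb$scale[1, "rapa"]
  expect_equal(a_steps$value, pr$steps$value * f, tolerance = 1e-12)
  expect_equal(unname(colSums(hyb$tpm)), rep(1e6, 3), tolerance = 1e-6)
})
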