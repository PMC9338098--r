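# TPM, expression classes, NB differential expression, BEG classification

test_that("TPM matches the closed form and sums to 1e6", {
  cnt <- matrix(c(100, 100), 2, dimnames = list(c("g1", "g2"), NULL))
  tpm <- compute_tpm(cnt, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  one <- compute_tpm(matrix(7, 1, 1, dimnames = list("g", NULL)),
                     c(g = 500))
  expect_equal(unname(one[1, 1]), 1e6)
  set.seed(41)
  cnt2 <- matrix(rpois(30, 50), 10)
  tpm2 <- compute_tpm(cnt2, runif(10, 500, 3000))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 3), tolerance = 1e-6)
  expect_error(compute_tpm(matrix(0, 2, 1), c(1000, 1000)), "zero total")
})

test_that("expression classes use the stated boundaries and partition", {
  x <- c(0, 0.5, 1, 5, 10, 10.1, 200)
  cls <- classify_expression(x)
  expect_equal(as.character(cls),
               c("none", "low", "med", "med", "med", "high", "high"))
  expect_false(anyNA(cls))
  expect_error(classify_expression(-1), "non-negative")
})

test_that("identical count matrices yield zero DEGs", {
  set.seed(42)
  cnt <- matrix(rnbinom(600, mu = 100, size = 20), 200)
  r <- call_degs(cnt, cnt)
  expect_true(all(r$status == "ns"))
  expect_true(all(abs(r$log2fc) < 1e-12))
})

test_that("planted 8-fold DEGs are recovered with correct direction", {
  set.seed(43)
  n <- 400; n_deg <- 60
  mu <- rep(100, n); mu[seq_len(n_deg)] <- 800
  cx <- matrix(rnbinom(n * 3, mu = mu, size = 20), n)
  cy <- matrix(rnbinom(n * 3, mu = 100, size = 20), n)
  r <- call_degs(cx, cy)
  expect_gte(mean(r$status[seq_len(n_deg)] == "up_in_x"), 0.9)
  expect_equal(sum(r$status[seq_len(n_deg)] == "up_in_y"), 0L)
})

test_that("null simulation keeps the BH-adjusted false call rate nominal", {
  set.seed(44)
  n <- 2000
  cx <- matrix(rnbinom(n * 3, mu = 100, size = 20), n)
  cy <- matrix(rnbinom(n * 3, mu = 100, size = 20), n)
  r <- call_degs(cx, cy)
  # p-value calibration at 0.05
  expect_lt(abs(mean(r$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # with no true positives, BH keeps false discoveries at padj<=0.001 rare
  expect_lte(sum(r$padj <= 0.001), 3L)
})

test_that("DEG calls are invariant under per-sample depth scaling", {
  set.seed(45)
  n <- 300
  cx <- matrix(rnbinom(n * 3, mu = 200, size = 20), n)
  cy <- matrix(rnbinom(n * 3, mu = 200, size = 20), n)
  cy[1:30, ] <- cy[1:30, ] * 8L
  r1 <- call_degs(cx, cy)
  scale <- c(3L, 1L, 2L)
  r2 <- call_degs(sweep(cx, 2, scale, "*"), cy)
  expect_equal(r1$status, r2$status)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 0.02)
})

test_that("replicate requirements are enforced", {
  cnt <- matrix(1:6, 3)
  expect_error(call_degs(cnt[, 1, drop = FALSE], cnt), "2 replicates")
})

test_that("BEG classes: equal copies, planted bias, label antisymmetry", {
  set.seed(46)
  n_pairs <- 40
  a_ids <- sprintf("a%02d", seq_len(n_pairs))
  c_ids <- sprintf("c%02d", seq_len(n_pairs))
  mu <- rep(200, n_pairs)
  a_cnt <- matrix(rnbinom(n_pairs * 3, mu = mu * c(rep(4, 10), rep(1, 30)),
                          size = 50), n_pairs)
  c_cnt <- matrix(rnbinom(n_pairs * 3, mu = mu, size = 50), n_pairs)
  counts <- rbind(a_cnt, c_cnt)
  rownames(counts) <- c(a_ids, c_ids)
  pairs <- data.frame(a_gene = a_ids, c_gene = c_ids)
  r <- classify_begs(counts, pairs)
  expect_gte(mean(r$beg_class[1:10] == "A_BEG"), 0.9)
  expect_true(all(r$beg_class[11:40] %in% c("no_BEG")))
  # swapping the copy labels swaps A_BEG and C_BEG exactly
  swapped <- classify_begs(counts, data.frame(a_gene = c_ids,
                                              c_gene = a_ids))
  map <- c(A_BEG = "C_BEG", C_BEG = "A_BEG", no_BEG = "no_BEG")
  expect_equal(unname(map[r$beg_class]), swapped$beg_class)
  expect_equal(r$log2fc, -swapped$log2fc)
  # identical copies are never biased
  same <- rbind(a_cnt, a_cnt)
  rownames(same) <- c(a_ids, c_ids)
  r0 <- classify_begs(same, pairs)
  expect_true(all(r0$beg_class == "no_BEG"))
})

test_that("unpaired genes are skipped with a warning", {
  counts <- matrix(10, 2, 3, dimnames = list(c("a1", "c1"), NULL))
  pairs <- data.frame(a_gene = c("a1", "a9"), c_gene = c("c1", "c9"))
  expect_warning(r <- classify_begs(counts, pairs), "skipped")
  expect_equal(nrow(r), 1L)
})

test_that("acr/deg overlap statistics handle edge cases", {
  expect_equal(acr_deg_overlap(c("g1", "g2"), c("g3"))$percent, 0)
  full <- acr_deg_overlap(c("g1", "g2", "g3"), c("g1", "g3"))
  expect_equal(full$percent, 100)
  expect_equal(full$n_overlap, 2L)
  hand <- acr_deg_overlap(sprintf("g%d", 1:10), sprintf("g%d", 6:20))
  expect_equal(hand$n_overlap, 5L)
  expect_equal(hand$percent, 100 * 5 / 15)
  expect_equal(acr_deg_overlap(character(), character())$percent, 0)
})

test_that("planted truth: DEGs and BEGs recovered from the simulator", {
  sim <- simulate_dataset(tiny_config(noise = "none"))
  cnt <- sim$expression$counts
  truth <- sim$expression$truth
  r <- call_degs(cnt$RAC, cnt$NAC)
  want_up_x <- truth$gene_id[!is.na(truth$deg_up_in) &
                             truth$deg_up_in == "RAC"]
  want_up_y <- truth$gene_id[!is.na(truth$deg_up_in) &
                             truth$deg_up_in == "NAC"]
  expect_setequal(r$gene_id[r$status == "up_in_x"], want_up_x)
  expect_setequal(r$gene_id[r$status == "up_in_y"], want_up_y)
  genes <- sim$genome$genes
  pairs <- data.frame(
    a_gene = genes$gene_id[genes$subgenome == "A" &
                           !is.na(genes$homeolog_partner)])
  pairs$c_gene <- genes$homeolog_partner[match(pairs$a_gene,
                                               genes$gene_id)]
  rb <- classify_begs(cnt$RAC, pairs)
  want <- truth$beg_class[match(rb$a_gene, truth$gene_id)]
  expect_equal(rb$beg_class, want)
})
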