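# shared fixtures: tiny configurations and brute-force oracles

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 11L, n_chroms_per_subgenome = 1L, chrom_length = 3e5,
         n_homeolog_pairs = 10L, n_unique_genes_per_subgenome = 5L,
         n_acrs_per_genotype = 40L, cytosine_spacing = 80L),
    list(...))
  do.call(sim_config, args)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 100L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(20L, n, replace = TRUE))
}

# O(n*m) all-pairs overlap oracle
brute_overlap <- function(a, b, min_overlap_bp = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap_bp)
        out[[length(out) + 1L]] <- data.frame(query = i, subject = j,
                                              overlap_bp = ov)
    }
  }
  if (!length(out))
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  do.call(rbind, out)
}

# per-base boolean union oracle for interval merging
brute_merge <- function(x, max_gap = 0L) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, ]
    lim <- max(xi$end) + 1L
    covered <- logical(lim)
    for (i in seq_len(nrow(xi)))
      covered[(xi$start[i] + 1L):xi$end[i]] <- TRUE
    if (max_gap > 0) {  # bridge gaps of <= max_gap uncovered bases
      r <- rle(covered)
      gap <- !r$values & r$lengths <= max_gap
      inner <- which(gap & seq_along(gap) > 1 & seq_along(gap) < length(gap))
      r$values[inner] <- TRUE
      covered <- inverse.rle(r)
    }
    r <- rle(covered)
    pos <- cumsum(c(0L, r$lengths))
    runs <- which(r$values)
    for (k in runs)
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            start = pos[k],
                                            end = pos[k + 1L])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

sort_pairs <- function(p) {
  p <- p[order(p$query, p$subject), , drop = FALSE]
  rownames(p) <- NULL
  p
}
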