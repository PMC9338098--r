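# Site- and region-level DNA methylation. The site level is methylated reads
# over coverage; sites with coverage below 3 are missing data and excluded
# everywhere. The region level is weighted by coverage: summed methylated
# reads over summed coverage of the qualifying sites (never a mean of site
# levels).

#' Per-site methylation levels with the minimum-coverage rule
#'
#' @param table site table (`chrom`, `pos`, `strand`, `context`,
#'   `meth_reads`, `total_reads`).
#' @param min_coverage sites with `total_reads < min_coverage` are flagged
#'   missing (default 3).
#' @return The table with `level` (NA when missing) and `missing` columns.
#' @export
site_levels <- function(table, min_coverage = 3L) {
  if (any(table$meth_reads > table$total_reads))
    stop("meth_reads exceeds total_reads at some site")
  missing <- table$total_reads < min_coverage
  level <- ifelse(missing, NA_real_, table$meth_reads / table$total_reads)
  cbind(table, level = level, missing = missing)
}

#' Weighted methylation level of regions
#'
#' For each region and context, the level is the sum of methylated reads
#' divided by the sum of coverage over the qualifying (non-missing, matching
#' context) sites inside the region. Regions with no qualifying site are NA,
#' never 0.
#'
#' @param table site table.
#' @param regions interval data.frame (`chrom`, `start`, `end`).
#' @param context one of "CG", "CHG", "CHH", or NULL for all contexts.
#' @param min_coverage minimum site coverage (default 3).
#' @return Numeric vector, one weighted level (or NA) per region.
#' @export
region_level <- function(table, regions, context = NULL, min_coverage = 3L) {
  keep <- table$total_reads >= min_coverage
  if (!is.null(context)) keep <- keep & table$context == context
  tab <- table[keep, , drop = FALSE]
  out <- rep(NA_real_, nrow(regions))
  if (!nrow(tab)) return(out)
  sites <- data.frame(chrom = tab$chrom, start = tab$pos,
                      end = tab$pos + 1L)
  ov <- overlap_query(sites, regions)
  if (!nrow(ov)) return(out)
  dt <- data.table::data.table(region = ov$subject,
                               m = tab$meth_reads[ov$query],
                               t = tab$total_reads[ov$query])
  agg <- dt[, list(m = sum(m), t = sum(t)), by = "region"]
  out[agg$region] <- agg$m / agg$t
  out
}

#' Methylation meta-profile around anchors
#'
#' Bins the flanks of each anchor and reports, per bin, the weighted level
#' pooled over all anchors (summed methylated reads over summed coverage of
#' qualifying sites assigned to that bin; strand-aware, minus-strand anchors
#' flipped). Bins with no qualifying site are NA.
#'
#' @param table site table.
#' @param anchors data.frame with `chrom`, `anchor`, `strand`.
#' @param context context filter, or NULL for all.
#' @param upstream,downstream flank extents in bp.
#' @param bin_width bin width in bp; must divide both extents.
#' @param min_coverage minimum site coverage.
#' @return data.frame with `bin_rel` (bp offset of the bin start), `level`,
#'   `n_sites`.
#' @export
methylation_profile <- function(table, anchors, context = NULL,
                                upstream = 1000L, downstream = 1000L,
                                bin_width = 50L, min_coverage = 3L) {
  if (upstream %% bin_width != 0L || downstream %% bin_width != 0L)
    stop("bin_width must divide the upstream and downstream extents")
  keep <- table$total_reads >= min_coverage
  if (!is.null(context)) keep <- keep & table$context == context
  tab <- table[keep, , drop = FALSE]
  nb <- (upstream + downstream) %/% bin_width
  res <- data.frame(bin_rel = seq(-upstream, downstream - bin_width,
                                  by = bin_width),
                    level = NA_real_, n_sites = 0L)
  if (!nrow(tab) || !nrow(anchors)) return(res)
  wins <- data.frame(chrom = anchors$chrom,
                     start = pmax(anchors$anchor - upstream, 0L),
                     end = anchors$anchor + downstream)
  sites <- data.frame(chrom = tab$chrom, start = tab$pos,
                      end = tab$pos + 1L)
  ov <- overlap_query(sites, wins)
  if (!nrow(ov)) return(res)
  pos <- tab$pos[ov$query]
  a <- anchors$anchor[ov$subject]
  rel <- ifelse(anchors$strand[ov$subject] == "-", a - pos - 1L, pos - a)
  bin <- (rel + upstream) %/% bin_width + 1L
  ok <- bin >= 1L & bin <= nb
  dt <- data.table::data.table(bin = bin[ok],
                               m = tab$meth_reads[ov$query][ok],
                               t = tab$total_reads[ov$query][ok])
  agg <- dt[, list(m = sum(m), t = sum(t), n = .N), by = "bin"]
  res$level[agg$bin] <- agg$m / agg$t
  res$n_sites[agg$bin] <- agg$n
  res
}
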