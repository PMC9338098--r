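#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats p.adjust dnorm pnorm pt rbinom rnbinom rnorm rpois runif
#'   setNames cor sd var median quantile na.omit
#' @importFrom utils combn head tail
NULL

# All interval coordinates in this package are 0-based half-open [start, end),
# BED-style. GFF3 (1-based closed) is converted at the read/write boundary.

#' Define a genome layout
#'
#' A genome layout is the chromosome-level scaffold every other object is
#' placed on: chromosome names, lengths and the subgenome ("A" or "C") each
#' chromosome belongs to.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @param subgenome character vector, one of "A"/"C" per chromosome.
#' @return A `data.frame` with columns `chrom`, `length`, `subgenome`.
#' @export
genome_layout <- function(chrom, length, subgenome) {
  stopifnot(base::length(chrom) == base::length(length),
            base::length(chrom) == base::length(subgenome))
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (!all(subgenome %in% c("A", "C")))
    stop("subgenome labels must be 'A' or 'C'")
  data.frame(chrom = as.character(chrom), length = as.integer(length),
             subgenome = as.character(subgenome), stringsAsFactors = FALSE)
}

#' Validate a gene-model table
#'
#' Gene models carry the attributes the allopolyploid analyses key on:
#' subgenome, homeolog partner (symmetric, across subgenomes) and duplicate
#' class (singleton/WGD/TD/TRD/DSD/PD).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `subgenome`, `homeolog_partner` (NA if none), `origin_class`,
#'   `dup_class`.
#' @param layout optional genome layout; chromosomes are checked against it.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_genes <- function(genes, layout = NULL) {
  req <- c("gene_id", "chrom", "start", "end", "strand", "subgenome",
           "homeolog_partner", "origin_class", "dup_class")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(layout) && !all(genes$chrom %in% layout$chrom))
    stop("gene table references chromosomes absent from the genome layout")
  has_partner <- !is.na(genes$homeolog_partner)
  if (!all(genes$origin_class[has_partner] == "homeolog") ||
      !all(genes$origin_class[!has_partner] == "subgenome_unique"))
    stop("origin_class must be 'homeolog' iff homeolog_partner is set")
  idx <- match(genes$homeolog_partner[has_partner], genes$gene_id)
  if (anyNA(idx)) stop("homeolog_partner references unknown gene_id")
  back <- genes$homeolog_partner[idx]
  if (!identical(back, genes$gene_id[has_partner]))
    stop("homeolog_partner links must be symmetric")
  if (any(genes$subgenome[idx] == genes$subgenome[has_partner]))
    stop("homeolog partners must lie on different subgenomes")
  invisible(genes)
}

#' Strand-aware TSS and TTS positions
#'
#' TSS is `start` for + strand genes and `end - 1` for - strand genes (the
#' last covered base under half-open coordinates); TTS is the symmetric
#' opposite anchor.
#'
#' @param genes gene-model table.
#' @return Integer vector of anchor positions.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @rdname tss_position
#' @export
tts_position <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

# internal: interval data.frame (0-based half-open) -> GRanges (1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Find overlapping interval pairs
#'
#' Reports every pair (i in `a`, j in `b`) whose intervals share at least
#' `min_overlap_bp` bases under half-open semantics. Backed by the
#' IRanges/GenomicRanges overlap engine.
#'
#' @param a,b interval data.frames with `chrom`, `start`, `end`.
#' @param min_overlap_bp minimum overlap in bp (>= 1).
#' @return data.frame with columns `query` (row in `a`), `subject` (row in
#'   `b`), `overlap_bp`.
#' @export
overlap_query <- function(a, b, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1L)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  ga <- .as_granges(a)
  gb <- .as_granges(b)
  # disjoint chromosome sets are a legitimate empty result, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb,
                                minoverlap = as.integer(min_overlap_bp)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  data.frame(query = qi, subject = si, overlap_bp = as.integer(ov))
}

#' Merge intervals into a disjoint set
#'
#' Intervals closer than or equal to `max_gap` bp apart (0 merges adjacent
#' half-open intervals such as [0,5) and [5,8)) are unioned.
#'
#' @param x interval data.frame.
#' @param max_gap maximum gap in bp bridged by a merge (>= 0).
#' @return Sorted, disjoint interval data.frame with `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(x, max_gap = 0L) {
  stopifnot(max_gap >= 0L)
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  red <- GenomicRanges::reduce(.as_granges(x),
                               min.gapwidth = as.integer(max_gap) + 1L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# format doubles so that read-back reproduces the identical double
.fmt_dbl <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

.check_chroms <- function(x, genome, path) {
  if (!is.null(genome)) {
    bad <- setdiff(unique(x$chrom), genome$chrom)
    if (length(bad))
      stop(sprintf("%s: unknown chromosome(s) not in genome layout: %s",
                   path, paste(bad, collapse = ", ")))
  }
  x
}

.bad_line <- function(path, i, what) {
  stop(sprintf("%s: malformed line %d: %s", path, i, what), call. = FALSE)
}

#' Read genomic intervals from standard text formats
#'
#' Supported dialects: `bed` (3 or 6 columns), `narrowPeak` (10 columns; the
#' p/q-value columns are -log10-encoded on disk and converted to raw
#' probabilities on read, -1 meaning unavailable), `gff3` (1-based closed,
#' converted to half-open), `bedgraph`, and `tsv` (header line, `chrom`,
#' `start`, `end` plus arbitrary columns). All coordinates are returned
#' 0-based half-open.
#'
#' @param path file to read.
#' @param format one of `"bed"`, `"narrowPeak"`, `"gff3"`, `"bedgraph"`,
#'   `"tsv"`.
#' @param genome optional genome layout; unknown chromosomes raise an error.
#' @return data.frame of intervals; columns depend on the dialect.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "gff3",
                                            "bedgraph", "tsv"),
                           genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    x <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
    if (!all(c("chrom", "start", "end") %in% names(x)))
      stop(path, ": tsv interval file must have chrom/start/end columns")
    return(.check_chroms(x, genome, path))
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer())
    return(empty)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- switch(format, bed = 3L, narrowPeak = 10L, gff3 = 9L,
                 bedgraph = 4L)
  bad <- which(nf < need)
  if (length(bad))
    .bad_line(path, lineno[bad[1L]],
              sprintf("expected >= %d tab-separated fields, found %d",
                      need, nf[bad[1L]]))
  get <- function(k) vapply(fields, `[[`, "", k)
  num <- function(k, nm) {
    v <- suppressWarnings(as.numeric(get(k)))
    if (anyNA(v))
      .bad_line(path, lineno[which(is.na(v))[1L]],
                sprintf("non-numeric %s field", nm))
    v
  }
  x <- switch(format,
    bed = {
      out <- data.frame(chrom = get(1), start = as.integer(num(2, "start")),
                        end = as.integer(num(3, "end")))
      if (all(nf >= 6L)) {
        out$name <- get(4)
        out$score <- num(5, "score")
        out$strand <- get(6)
      }
      out
    },
    narrowPeak = {
      to_p <- function(v) ifelse(v < 0, NA_real_, 10^(-v))
      data.frame(chrom = get(1), start = as.integer(num(2, "start")),
                 end = as.integer(num(3, "end")), name = get(4),
                 pileup = num(5, "pileup"), strand = get(6),
                 fold_enrichment = num(7, "fold_enrichment"),
                 pvalue = to_p(num(8, "pvalue")),
                 qvalue = to_p(num(9, "qvalue")),
                 summit_offset = as.integer(num(10, "summit")))
    },
    gff3 = {
      data.frame(chrom = get(1), source = get(2), type = get(3),
                 start = as.integer(num(4, "start")) - 1L,
                 end = as.integer(num(5, "end")), score = get(6),
                 strand = get(7), phase = get(8), attributes = get(9))
    },
    bedgraph = {
      data.frame(chrom = get(1), start = as.integer(num(2, "start")),
                 end = as.integer(num(3, "end")), value = num(4, "value"))
    })
  bad <- which(x$start >= x$end)
  if (length(bad))
    .bad_line(path, lineno[bad[1L]], "interval start must be < end")
  .check_chroms(x, genome, path)
}

#' Write genomic intervals in standard text formats
#'
#' The matching counterpart of [read_intervals()]: tab-separated,
#' newline-terminated, no trailing whitespace. Doubles are written with
#' enough digits that a read-back reproduces them exactly; narrowPeak p/q
#' columns are written as -log10 values (NA as -1).
#'
#' @param x interval data.frame in the column layout the dialect expects.
#' @param path output file.
#' @param format dialect, as in [read_intervals()].
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "narrowPeak", "gff3",
                                                "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    y <- x
    for (j in seq_along(y)) if (is.double(y[[j]])) y[[j]] <- .fmt_dbl(y[[j]])
    data.table::fwrite(y, path, sep = "\t", quote = FALSE, na = "NA")
    return(invisible(path))
  }
  rows <- switch(format,
    bed = if (!is.null(x$strand))
      cbind(x$chrom, x$start, x$end, x$name, .fmt_dbl(x$score), x$strand)
    else cbind(x$chrom, x$start, x$end),
    narrowPeak = {
      from_p <- function(p) ifelse(is.na(p), -1, -log10(p))
      nm <- if (is.null(x$name)) sprintf("peak_%d", seq_len(nrow(x))) else x$name
      st <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
      qv <- if (is.null(x$qvalue)) rep(NA_real_, nrow(x)) else x$qvalue
      cbind(x$chrom, x$start, x$end, nm, .fmt_dbl(x$pileup), st,
            .fmt_dbl(x$fold_enrichment), .fmt_dbl(from_p(x$pvalue)),
            .fmt_dbl(from_p(qv)), x$summit_offset)
    },
    gff3 = cbind(x$chrom, x$source, x$type, x$start + 1L, x$end, x$score,
                 x$strand, x$phase, x$attributes),
    bedgraph = cbind(x$chrom, x$start, x$end, .fmt_dbl(x$value)))
  writeLines(apply(rows, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Construct a signal track
#'
#' A signal track is stepwise per-base coverage for one assay, genotype and
#' replicate, plus the library's total mapped reads (used for depth
#' normalization). Steps must be sorted and non-overlapping per chromosome.
#'
#' @param steps data.frame with `chrom`, `start`, `end`, `value` (>= 0).
#' @param assay one of "ATAC", "H3K4me3", "H3K27ac", "H3K27me3".
#' @param genotype genotype label.
#' @param replicate replicate id, or "merged".
#' @param total_mapped_reads positive library size.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(steps, assay, genotype, replicate,
                         total_mapped_reads) {
  stopifnot(assay %in% c("ATAC", "H3K4me3", "H3K27ac", "H3K27me3"),
            total_mapped_reads > 0, all(is.finite(steps$value)),
            all(steps$value >= 0))
  o <- order(steps$chrom, steps$start)
  steps <- steps[o, , drop = FALSE]
  rownames(steps) <- NULL
  by_chr <- split(seq_len(nrow(steps)), steps$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L &&
        any(steps$start[idx][-1L] < steps$end[idx][-length(idx)]))
      stop("signal track steps overlap within a chromosome")
  }
  structure(list(steps = steps, assay = assay, genotype = genotype,
                 replicate = as.character(replicate),
                 total_mapped_reads = as.numeric(total_mapped_reads)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s / %s / rep %s: %d steps, %.3g mapped reads\n",
              x$assay, x$genotype, x$replicate, nrow(x$steps),
              x$total_mapped_reads))
  invisible(x)
}

# internal: per-base coverage vector for [from, to) on one chromosome
.track_window <- function(track, chrom, from, to) {
  n <- to - from
  out <- numeric(n)
  s <- track$steps
  idx <- which(s$chrom == chrom & s$end > from & s$start < to)
  for (i in idx) {
    a <- max(s$start[i], from) - from + 1L
    b <- min(s$end[i], to) - from
    out[a:b] <- s$value[i]
  }
  out
}

# internal: sum of value*bp over [from, to) for one chromosome
.track_sum <- function(track, chrom, from, to) {
  s <- track$steps
  idx <- which(s$chrom == chrom & s$end > from & s$start < to)
  if (!length(idx)) return(0)
  sum(s$value[idx] * (pmin(s$end[idx], to) - pmax(s$start[idx], from)))
}
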