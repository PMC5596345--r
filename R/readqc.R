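#' Expected number of errors of a read
#'
#' Sums the per-base error probabilities implied by the Phred scores:
#' EE = sum_b 10^(-Q_b / 10).  Reads with EE > 1 are conventionally
#' discarded during amplicon quality control.
#'
#' @param qualities integer Phred scores, or a Phred+33 quality string.
#' @return nonnegative expected error count.
#' @export
expected_error <- function(qualities) {
  if (is.character(qualities)) {
    if (length(qualities) != 1) {
      return(vapply(qualities, expected_error, numeric(1), USE.NAMES = FALSE))
    }
    qualities <- utf8ToInt(qualities) - 33L
  }
  if (length(qualities) == 0) stop("empty quality vector")
  if (any(qualities < 0)) stop("Phred scores must be >= 0")
  sum(10^(-qualities / 10))
}

#' Filter reads on expected error and length
#'
#' Applies the standard amplicon QC rules: discard reads with expected
#' error > `max_ee`, then discard reads with length outside
#' `[min_len, max_len]` (bounds inclusive; the amplified V5-V7 region is
#' expected at 369 bases).  Expected-error failure takes precedence over
#' length failure in the report, and every input read is tallied exactly
#' once.
#'
#' @param reads a `read_set` data frame (columns `id`, `sequence`,
#'   `quality`, optionally `sample`).
#' @param max_ee maximum expected error.
#' @param min_len,max_len inclusive length bounds (bases).
#' @return list with `retained` (a `read_set`) and `report` (a `qc_report`
#'   data frame per sample: input, failed_ee, failed_length, spike,
#'   retained; spike is filled by [remove_spikes()]).
#' @export
filter_reads <- function(reads, max_ee = 1, min_len = 350L,
                         max_len = 380L) {
  if (!all(c("sequence", "quality") %in% names(reads)))
    stop("malformed read set: need sequence and quality columns")
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    bad <- which(nchar(reads$sequence) != nchar(reads$quality))[1]
    stop("malformed record ", bad, ": sequence/quality length mismatch")
  }
  samp <- if ("sample" %in% names(reads) && !all(is.na(reads$sample)))
    reads$sample else rep("all", nrow(reads))
  ee <- vapply(reads$quality, expected_error, numeric(1), USE.NAMES = FALSE)
  len <- nchar(reads$sequence)
  fail_ee <- ee > max_ee
  fail_len <- !fail_ee & (len < min_len | len > max_len)
  keep <- !fail_ee & !fail_len
  lev <- unique(samp)
  tab <- function(flag) {
    as.integer(vapply(lev, function(s) sum(flag[samp == s]), numeric(1)))
  }
  report <- data.frame(sample = lev,
                       input = tab(rep(TRUE, length(samp))),
                       failed_ee = tab(fail_ee),
                       failed_length = tab(fail_len),
                       spike = 0L,
                       retained = tab(keep),
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  retained <- reads[keep, , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- c("read_set", "data.frame")
  list(retained = retained, report = report)
}

#' Identify and remove spike-in reads
#'
#' A read is classified as spike if and only if its sequence equals one of
#' the spike sequences exactly over the spike's full length; a single
#' mismatch makes it a putative 16S read.
#'
#' @param reads a `read_set` (normally the retained stream of
#'   [filter_reads()]).
#' @param spike_seqs the three spike sequences.
#' @param report optional `qc_report` from [filter_reads()] to update
#'   (spike and retained columns).
#' @return list with `reads` (16S stream), `spike_counts` (per-sample x 3
#'   matrix), and updated `report` (when given).
#' @export
remove_spikes <- function(reads, spike_seqs, report = NULL) {
  if (length(spike_seqs) != 3) stop("exactly three spike sequences required")
  hit <- match(reads$sequence, spike_seqs)
  samp <- if ("sample" %in% names(reads) && !all(is.na(reads$sample)))
    reads$sample else rep("all", nrow(reads))
  lev <- unique(samp)
  spike_counts <- t(vapply(lev, function(s)
    vapply(1:3, function(k)
      sum(!is.na(hit) & hit == k & samp == s), numeric(1)),
    numeric(3)))
  dimnames(spike_counts) <- list(lev, paste0("spike", 1:3))
  out <- reads[is.na(hit), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  if (!is.null(report)) {
    i <- match(lev, report$sample)
    report$spike[i] <- as.integer(rowSums(spike_counts))
    report$retained[i] <- report$retained[i] - report$spike[i]
  }
  list(reads = out, spike_counts = spike_counts, report = report)
}

#' Full read-level QC pipeline
#'
#' Fixed filter order: expected error, then length, then exact spike
#' identification.  Every input read lands in exactly one tally of the
#' report (input = failed_ee + failed_length + spike + retained).
#'
#' @inheritParams filter_reads
#' @inheritParams remove_spikes
#' @return list with `reads` (retained 16S stream), `spike_counts`, and
#'   `report`.
#' @export
qc_reads <- function(reads, spike_seqs, max_ee = 1, min_len = 350L,
                     max_len = 380L) {
  f <- filter_reads(reads, max_ee = max_ee, min_len = min_len,
                    max_len = max_len)
  remove_spikes(f$retained, spike_seqs, report = f$report)
}

#' Sample depth filter with seeded subsampling
#'
#' Clustering methods tolerate only limited variation in read depth:
#' samples with fewer than `min_depth` total counts are removed, samples
#' exceeding `cap` are subsampled without replacement to exactly `cap`
#' counts (seeded), and samples in between are left untouched.  The
#' operation is idempotent on its own output.
#'
#' @param table a `phylotype_table`.
#' @param min_depth minimum total counts to keep a sample.
#' @param cap maximum total counts; larger samples are rarefied to this.
#' @param seed integer seed recorded in the result's `subsample_seed`
#'   attribute.
#' @return filtered/subsampled `phylotype_table`.
#' @export
depth_filter_subsample <- function(table, min_depth = 5000L,
                                   cap = 20000L, seed = NULL) {
  stopifnot(inherits(table, "phylotype_table"))
  if (any(table$counts < 0)) stop("negative counts")
  if (!is.null(seed)) set.seed(seed)
  tot <- rowSums(table$counts)
  keep <- tot >= min_depth
  counts <- table$counts[keep, , drop = FALSE]
  tot <- tot[keep]
  for (i in which(tot > cap)) {
    v <- rep(seq_len(ncol(counts)), counts[i, ])
    sub <- sample(v, cap)
    counts[i, ] <- tabulate(sub, nbins = ncol(counts))
  }
  out <- table
  out$counts <- counts
  if (!is.null(out$meta))
    out$meta <- out$meta[out$meta$sample %in% rownames(counts), ,
                         drop = FALSE]
  attr(out, "subsample_seed") <- seed
  out
}

#' Analysis-stage depth filter
#'
#' Removes samples with fewer than `min_depth` total counts before
#' dissimilarity analysis.
#'
#' @param table a `phylotype_table`.
#' @param min_depth minimum total counts (default 1000).
#' @return filtered `phylotype_table`.
#' @export
analysis_depth_filter <- function(table, min_depth = 1000L) {
  stopifnot(inherits(table, "phylotype_table"))
  keep <- rowSums(table$counts) >= min_depth
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  if (!is.null(out$meta))
    out$meta <- out$meta[out$meta$sample %in% rownames(out$counts), ,
                         drop = FALSE]
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read QC report (filter order: expected error, length, spike)\n")
  NextMethod()
}
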