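#' Spike-in control sequences
#'
#' Three unique synthetic 350-base sequences, deterministically generated
#' from a seed, standing in for the spike-in DNAs added at three log-spaced
#' concentrations before library preparation.  Being of known sequence they
#' can be identified exactly and removed during quality control.
#'
#' @param seed integer seed fixing the sequences.
#' @param length spike length in bases.
#' @return character vector of three DNA sequences.
#' @export
spike_sequences <- function(seed = 350L, length = 350L) {
  set.seed(seed)
  vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

phred_string <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
}

#' Simulate spiked amplicon reads from a phylotype table
#'
#' Emits, per sample, 16S reads (lengths centred at 369 bases, drawn from
#' per-phylotype reference sequences) and spike reads, under a fixed total
#' sequencer depth per sample.  Spike DNA competes with the sample's 16S
#' load for that fixed depth, so samples with more 16S material yield fewer
#' spike reads: spike and 16S read counts are anticorrelated across
#' samples.  A configurable fraction of reads is emitted with poor base
#' qualities or truncated lengths to exercise the QC filters.
#'
#' @param table a `phylotype_table`.
#' @param spike_seqs exactly three spike sequences (350 bases each);
#'   defaults to [spike_sequences()].  Use fractions of zero in `config`
#'   to disable spikes.
#' @param config an [effect_config()] (fields `read_depth`,
#'   `spike_fractions`, `read_length_sd`, `frac_low_quality`,
#'   `frac_short`).
#' @param seed integer seed; identical seeds give byte-identical FASTQ.
#' @param spike_fractions override of the three expected spike read
#'   fractions; `c(0, 0, 0)` produces no spike reads.
#' @return data frame of class `"read_set"` with columns `id`, `sample`,
#'   `sequence`, `quality` (Phred+33 string); attributes `spike_draws`
#'   (samples x 3 matrix of true spike read counts) and `n16s_draws`.
#' @export
simulate_reads <- function(table, spike_seqs = spike_sequences(),
                           config = effect_config(), seed = NULL,
                           spike_fractions = NULL) {
  stopifnot(inherits(table, "phylotype_table"))
  if (length(spike_seqs) != 3) stop("exactly three spike sequences required")
  if (any(nchar(spike_seqs) != 350))
    stop("spike sequences must be exactly 350 bases")
  if (!is.null(seed)) set.seed(seed)
  fr <- if (is.null(spike_fractions)) config$spike_fractions
        else spike_fractions
  counts <- table$counts
  n <- nrow(counts)
  refs <- rand_dna(ncol(counts), 380L)
  load <- rowSums(counts)
  # spike weights calibrated so that at the mean 16S load the expected
  # spike read fractions equal `fr`
  w <- if (all(fr == 0)) c(0, 0, 0)
       else fr / (1 - sum(fr)) * mean(load)
  out <- vector("list", n)
  spike_draws <- matrix(0L, n, 3,
                        dimnames = list(rownames(counts), NULL))
  n16s <- integer(n)
  for (i in seq_len(n)) {
    alloc <- stats::rmultinom(1, config$read_depth,
                              c(load[i], w) / (load[i] + sum(w)))[, 1]
    k16 <- alloc[1]
    spike_draws[i, ] <- alloc[2:4]
    n16s[i] <- k16
    phylo <- if (k16 > 0)
      stats::rmultinom(1, k16, counts[i, ] / load[i])[, 1] else integer(0)
    idx <- rep(seq_along(phylo), phylo)
    lens <- as.integer(round(stats::rnorm(k16, 369, config$read_length_sd)))
    lens <- pmin(pmax(lens, 350L), 380L)
    short <- stats::runif(k16) < config$frac_short
    lens[short] <- sample(300:349, sum(short), replace = TRUE)
    seqs <- substr(refs[idx], 1L, lens)
    low <- stats::runif(k16) < config$frac_low_quality
    quals <- vapply(seq_len(k16), function(r) {
      q <- if (low[r]) sample(10:15, lens[r], replace = TRUE)
           else sample(33:40, lens[r], replace = TRUE)
      phred_string(q)
    }, character(1))
    sp_idx <- rep(1:3, spike_draws[i, ])
    sp_seqs <- spike_seqs[sp_idx]
    sp_quals <- vapply(seq_along(sp_idx), function(r)
      phred_string(sample(33:40, 350L, replace = TRUE)), character(1))
    sid <- rownames(counts)[i]
    nr <- k16 + length(sp_idx)
    out[[i]] <- data.frame(
      id = sprintf("%s_read%05d", sid, seq_len(nr)),
      sample = sid,
      sequence = c(seqs, sp_seqs),
      quality = c(quals, sp_quals),
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  class(reads) <- c("read_set", "data.frame")
  attr(reads, "spike_draws") <- spike_draws
  attr(reads, "n16s_draws") <- n16s
  reads
}

#' Read / write FASTQ
#'
#' Standard 4-line FASTQ with Phred+33 qualities, via Biostrings.
#'
#' @param file FASTQ path.
#' @return `read_fastq()` returns a `read_set` data frame (id, sequence,
#'   quality).
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq",
                                    with.qualities = TRUE)
  reads <- data.frame(id = names(x),
                      sample = NA_character_,
                      sequence = as.character(x),
                      quality = as.character(S4Vectors::mcols(x)$qualities),
                      stringsAsFactors = FALSE)
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' @param reads a `read_set` data frame.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, file, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(file)
}
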