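#' Specify haplotype blocks for gene dropping
#'
#' SNPs are transmitted in blocks (haplotypes): within a block a parent
#' passes on one of its two haplotypes intact, with no recombination.  The
#' number of blocks controls the Mendelian sampling variance of realized
#' relatedness — few large blocks give noisy realized kinship, many small
#' blocks approach the pedigree expectation.
#'
#' @param n_blocks number of independently segregating blocks.
#' @param loci_per_block number of biallelic loci per block.
#' @param founder_allele_freqs optional vector of per-locus founder allele
#'   frequencies (length `n_blocks * loci_per_block`, all strictly inside
#'   (0, 1)); drawn uniformly from `freq_range` when omitted.
#' @param freq_range range for randomly drawn founder frequencies.
#' @param seed integer seed for the random frequencies.
#' @return list of class `"haplotype_blocks"` with elements `n_blocks`,
#'   `loci_per_block`, `freqs` and `block_of_locus`.
#' @export
haplotype_blocks <- function(n_blocks, loci_per_block = 1,
                             founder_allele_freqs = NULL,
                             freq_range = c(0.1, 0.9), seed = NULL) {
  if (n_blocks < 1 || loci_per_block < 1)
    stop("n_blocks and loci_per_block must be positive")
  n_loci <- n_blocks * loci_per_block
  if (is.null(founder_allele_freqs)) {
    if (!is.null(seed)) set.seed(seed)
    founder_allele_freqs <- stats::runif(n_loci, freq_range[1], freq_range[2])
  }
  if (length(founder_allele_freqs) != n_loci)
    stop("founder_allele_freqs must have length n_blocks * loci_per_block")
  if (any(founder_allele_freqs <= 0 | founder_allele_freqs >= 1))
    stop("founder allele frequencies must be strictly inside (0, 1)")
  structure(list(n_blocks = as.integer(n_blocks),
                 loci_per_block = as.integer(loci_per_block),
                 freqs = founder_allele_freqs,
                 block_of_locus = rep(seq_len(n_blocks),
                                      each = loci_per_block)),
            class = "haplotype_blocks")
}

#' Drop genotypes through a pedigree
#'
#' Founders draw two haplotypes per block from the founder allele
#' frequencies; each meiosis transmits, per block, exactly one of the
#' parent's two haplotypes chosen with equal probability (no within-block
#' recombination).  Every offspring therefore carries exactly one maternal
#' and one paternal allele at every locus — parents always transmit exactly
#' half their genome, while the *realized* sharing between two relatives
#' scatters around the pedigree expectation (Mendelian sampling).
#'
#' @param ped a pedigree data frame ([sim_pedigree()]).
#' @param blocks a [haplotype_blocks()] specification.
#' @param seed integer seed.
#' @param keep_haplotypes keep the per-parent haplotype matrices (needed to
#'   trace parental origin of alleles).
#' @param founder_pool number of distinct ancestral haplotypes per block
#'   that founders draw from.  The default (`Inf`) makes founders
#'   mutually unrelated; a finite pool emulates an endogamous community in
#'   which even individuals marrying into the family share ancestry, so
#'   their realized kinship scatters around a positive background instead
#'   of zero.
#' @return list of class `"genotype_matrix"`: `counts` (individuals x loci
#'   allele-count matrix, entries 0/1/2), `block_of_locus`, `freqs`, and,
#'   when requested, `paternal` / `maternal` 0/1 haplotype matrices.
#' @export
gene_drop <- function(ped, blocks, seed = NULL, keep_haplotypes = FALSE,
                      founder_pool = Inf) {
  stopifnot(inherits(blocks, "haplotype_blocks"))
  ped <- topological_order(ped)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  L <- length(blocks$freqs)
  bl <- blocks$block_of_locus
  pool <- NULL
  if (is.finite(founder_pool)) {
    # ancestral haplotype pool per block: founders draw with replacement,
    # so any two founders share haplotypes at rate 1 / founder_pool
    H <- as.integer(founder_pool)
    if (H < 2) stop("founder_pool must be >= 2")
    pool <- matrix(stats::rbinom(H * L, 1L, rep(blocks$freqs, each = H)),
                   H, L)
  }
  draw_founder_haplotype <- function() {
    if (is.null(pool)) return(stats::rbinom(L, 1L, blocks$freqs))
    picks <- sample.int(nrow(pool), blocks$n_blocks, replace = TRUE)
    pool[cbind(picks[bl], seq_len(L))]
  }
  pat <- matrix(0L, n, L, dimnames = list(ped$id, NULL))
  mat <- matrix(0L, n, L, dimnames = list(ped$id, NULL))
  for (i in seq_len(n)) {
    if (is.na(ped$father[i])) {
      pat[i, ] <- draw_founder_haplotype()
      mat[i, ] <- draw_founder_haplotype()
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      if (is.na(fi) || is.na(mi)) stop("parent missing from pedigree")
      # per block, pick which of the parent's two haplotypes is transmitted
      pick_f <- sample(c(TRUE, FALSE), blocks$n_blocks, replace = TRUE)[bl]
      pick_m <- sample(c(TRUE, FALSE), blocks$n_blocks, replace = TRUE)[bl]
      pat[i, ] <- ifelse(pick_f, pat[fi, ], mat[fi, ])
      mat[i, ] <- ifelse(pick_m, pat[mi, ], mat[mi, ])
    }
  }
  counts <- pat + mat
  colnames(counts) <- sprintf("L%04d", seq_len(L))
  out <- list(counts = counts, block_of_locus = bl, freqs = blocks$freqs)
  if (keep_haplotypes) {
    out$paternal <- pat
    out$maternal <- mat
  }
  structure(out, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci (%d blocks)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$block_of_locus))))
  invisible(x)
}

#' Read / write genotype matrices
#'
#' Tab-delimited allele-count matrix (rows = individuals, columns = loci,
#' entries 0/1/2) plus a companion block-map file (locus, block).
#'
#' @param file path to the matrix file.
#' @param block_file path to the locus-to-block map.
#' @return `read_genotypes()` returns a `genotype_matrix` list.
#' @export
read_genotypes <- function(file, block_file = NULL) {
  m <- as.matrix(utils::read.delim(file, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (any(!m %in% 0:2)) stop("allele counts must be 0, 1 or 2")
  bl <- if (!is.null(block_file)) {
    bm <- utils::read.delim(block_file, stringsAsFactors = FALSE)
    bm$block[match(colnames(m), bm$locus)]
  } else rep(1L, ncol(m))
  structure(list(counts = m, block_of_locus = bl, freqs = NULL),
            class = "genotype_matrix")
}

#' @param geno genotype matrix to write.
#' @rdname read_genotypes
#' @export
write_genotypes <- function(geno, file, block_file = NULL) {
  out <- data.frame(id = rownames(geno$counts), geno$counts,
                    check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(block_file))
    utils::write.table(
      data.frame(locus = colnames(geno$counts),
                 block = geno$block_of_locus),
      block_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read diploid genotypes from a VCF file
#'
#' Maps the GT field of a diploid VCF to allele counts (0/1/2); phased and
#' unphased separators are accepted, missing calls become NA.
#'
#' @param file VCF path (plain text or bgzipped).
#' @return a `genotype_matrix` (individuals x loci).
#' @export
read_vcf_genotypes <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  m <- t(apply(gt, c(1, 2), alt_count))
  structure(list(counts = m, block_of_locus = rep(1L, ncol(m)),
                 freqs = NULL),
            class = "genotype_matrix")
}
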