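#' Relative abundances from a count table
#'
#' @param table a `phylotype_table` or a samples x taxa count matrix.
#' @return matrix of row-normalized relative abundances (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "phylotype_table")) table$counts else
    as.matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "),
         " (remove them with analysis_depth_filter first)")
  m / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' For relative-abundance rows a and b (each summing to 1) the Bray-Curtis
#' dissimilarity reduces to d(a, b) = 1 - sum_j min(a_j, b_j): 0 for
#' identical compositions, 1 for disjoint ones.
#'
#' @param compositions samples x taxa matrix of relative abundances (rows
#'   sum to 1), e.g. from [relative_abundance()]; a `phylotype_table` is
#'   converted automatically.
#' @return symmetric distance matrix with zero diagonal, entries in [0, 1]
#'   and attribute `metric_name = "bray_curtis"`.
#' @export
bray_curtis <- function(compositions) {
  if (inherits(compositions, "phylotype_table"))
    compositions <- relative_abundance(compositions)
  m <- as.matrix(compositions)
  if (any(abs(rowSums(m) - 1) > 1e-8))
    stop("rows must sum to 1 (use relative_abundance)")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    # min(a, b) summed over taxa, vectorized over the remaining rows
    rest <- (i + 1):n
    shared <- pmin(m[rest, , drop = FALSE],
                   matrix(m[i, ], length(rest), ncol(m), byrow = TRUE))
    D[i, rest] <- D[rest, i] <- 1 - rowSums(shared)
  }
  attr(D, "metric_name") <- "bray_curtis"
  D
}

#' Within-genus (subgenus) composition
#'
#' Restricts the count table to the phylotypes of one genus and
#' renormalizes rows, giving the fine-scale composition *within* that
#' genus.  Samples with zero counts for the genus carry no information
#' about its internal composition; they are excluded and listed in the
#' `excluded` attribute.
#'
#' @param table a `phylotype_table`.
#' @param genus genus name (must exist in the taxonomy).
#' @return relative-abundance matrix over the genus's phylotypes for the
#'   retained samples; attribute `excluded` lists dropped samples.
#' @export
subgenus_composition <- function(table, genus) {
  stopifnot(inherits(table, "phylotype_table"))
  cols <- table$taxonomy$phylotype[table$taxonomy$genus == genus]
  cols <- intersect(cols, colnames(table$counts))
  if (length(cols) == 0) stop("unknown genus: ", genus)
  sub <- table$counts[, cols, drop = FALSE]
  tot <- rowSums(sub)
  excl <- rownames(sub)[tot == 0]
  sub <- sub[tot > 0, , drop = FALSE]
  out <- sub / rowSums(sub)
  attr(out, "genus") <- genus
  attr(out, "excluded") <- excl
  out
}

#' Most abundant genera
#'
#' Ranks genera by their mean relative abundance across samples (ties
#' broken lexicographically); spouse subgenus contrasts conventionally use
#' the top 12.
#'
#' @param table a `phylotype_table`.
#' @param k number of genera to return (all if fewer exist).
#' @return character vector of genus names, most abundant first.
#' @export
top_genera <- function(table, k = 12) {
  stopifnot(inherits(table, "phylotype_table"))
  ra <- relative_abundance(table)
  gmap <- table$taxonomy$genus[match(colnames(ra), table$taxonomy$phylotype)]
  gmean <- vapply(split(seq_len(ncol(ra)), gmap),
                  function(j) mean(rowSums(ra[, j, drop = FALSE])),
                  numeric(1))
  ord <- order(-gmean, names(gmean))
  utils::head(names(gmean)[ord], k)
}
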