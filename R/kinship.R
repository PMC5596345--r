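#' Pedigree-expected kinship matrix
#'
#' Computes kinship coefficients (the probability that two alleles sampled
#' at random, one from each individual, are identical by descent) by the
#' recursive tabular method, processing individuals in topological order:
#' founders are mutually unrelated and non-inbred, phi(i,i) =
#' (1 + phi(father_i, mother_i)) / 2, and phi(i,j) =
#' (phi(father_i, j) + phi(mother_i, j)) / 2 for any j defined before i.
#' Inbreeding (e.g. cousin marriages) is handled exactly.
#'
#' @param ped a pedigree data frame ([sim_pedigree()]).
#' @return symmetric kinship matrix with individual ids as dimnames and
#'   attribute `flavor = "pedigree"`.  Non-inbred diagonal is 0.5;
#'   parent-offspring 0.25; first cousins 0.0625.
#' @export
pedigree_kinship <- function(ped) {
  ped <- topological_order(ped)
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (is.na(ped$father[i])) {
      K[i, i] <- 0.5
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      if (i > 1) {
        j <- seq_len(i - 1L)
        K[i, j] <- 0.5 * (K[fi, j] + K[mi, j])
        K[j, i] <- K[i, j]
      }
      K[i, i] <- 0.5 * (1 + K[fi, mi])
    }
  }
  attr(K, "flavor") <- "pedigree"
  K
}

#' SNP-realized kinship matrix
#'
#' Standardized allele-sharing estimator: each locus is centred by twice its
#' allele frequency and scaled by sqrt(2p(1-p)); cross-products are averaged
#' over loci and halved to the kinship scale (so full sibs average 0.25).
#' By default the off-diagonal entries are then shifted by a constant so
#' their mean is exactly zero, giving relative genetic similarity within the
#' cohort; the raw estimator is available with `normalize = FALSE` (the
#' scale needed to compare realized kinship against pedigree expectations).
#'
#' @param geno a `genotype_matrix` ([gene_drop()]) or a plain individuals x
#'   loci allele-count matrix with entries 0/1/2.
#' @param normalize shift off-diagonals to mean zero (diagonal untouched)?
#' @param allele_freq optional per-locus allele frequencies (e.g. the known
#'   founder frequencies); estimated from the sample when omitted.
#' @return symmetric kinship matrix with attribute `flavor = "snp"`.
#' @export
snp_kinship <- function(geno, normalize = TRUE, allele_freq = NULL) {
  m <- if (inherits(geno, "genotype_matrix")) geno$counts else as.matrix(geno)
  if (nrow(m) < 2) stop("need at least two individuals")
  p <- if (is.null(allele_freq)) colMeans(m) / 2 else allele_freq
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci")
  m <- m[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(m, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z) / 2
  if (normalize) {
    off <- row(K) != col(K)
    K[off] <- K[off] - mean(K[off])
  }
  attr(K, "flavor") <- "snp"
  K
}

#' Convert a kinship matrix to Euclidean distances
#'
#' The kinship matrix is treated as an inner-product (similarity) matrix:
#' after a positive-semidefinite repair (negative eigenvalues clipped at
#' zero), d(i,j) = sqrt(k(i,i) + k(j,j) - 2 k(i,j)).  The result is a valid
#' Euclidean distance matrix, suitable for metric MDS; double-centring its
#' squared entries recovers the centred repaired kinship (Gower).
#'
#' @param kinship symmetric kinship matrix.
#' @return labelled distance matrix; attribute `clipped` records the total
#'   magnitude of clipped negative eigenvalues.
#' @export
kinship_to_distance <- function(kinship) {
  K <- as.matrix(kinship)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kinship must be symmetric")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  neg <- pmin(e$values, 0)
  Kp <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d2 <- outer(diag(Kp), diag(Kp), "+") - 2 * Kp
  D <- sqrt(pmax(d2, 0))
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- dimnames(K)
  attr(D, "metric_name") <- "kinship_euclidean"
  attr(D, "clipped") <- sum(abs(neg))
  D
}

#' Metric (classical) multidimensional scaling of a distance matrix
#'
#' Gower double-centring of -squared distances / 2, eigendecomposition, and
#' scaling of the top axes by the square root of their eigenvalues.  A
#' deterministic sign convention (first nonzero loading of each axis
#' positive) makes the axes reproducible across platforms, so they can be
#' used as model covariates.  If fewer positive eigenvalues than requested
#' axes exist, the remaining axes are zero-padded with a warning.
#'
#' @param distances symmetric distance matrix (or `dist`).
#' @param n_axes number of axes to return (the family-microbiome analyses
#'   use five kinship-MDS axes as host-genetic covariates).
#' @return list of class `"mds_axes"`: `points` (n x n_axes matrix, columns
#'   MDS1..MDSk), `eig` (their eigenvalues), `ids`.
#' @export
classical_mds <- function(distances, n_axes = 5) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < n_axes + 1)
    stop("need at least n_axes + 1 individuals")
  B <- gower_center(D)
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
  k <- min(length(pos), n_axes)
  pts <- matrix(0, n, n_axes,
                dimnames = list(rownames(D), paste0("MDS", seq_len(n_axes))))
  eigs <- numeric(n_axes)
  if (k > 0) {
    V <- e$vectors[, seq_len(k), drop = FALSE]
    lam <- e$values[seq_len(k)]
    for (a in seq_len(k)) {
      v <- V[, a]
      nz <- which(abs(v) > 1e-12)[1]
      if (!is.na(nz) && v[nz] < 0) v <- -v
      pts[, a] <- v * sqrt(lam[a])
    }
    eigs[seq_len(k)] <- lam
  }
  if (k < n_axes)
    warning(sprintf("only %d positive eigenvalues; padding %d axes with 0",
                    k, n_axes - k))
  structure(list(points = pts, eig = eigs, ids = rownames(D)),
            class = "mds_axes")
}

#' @export
print.mds_axes <- function(x, ...) {
  cat(sprintf("Metric MDS: %d points, %d axes; eigenvalues: %s\n",
              nrow(x$points), ncol(x$points),
              paste(signif(x$eig, 4), collapse = ", ")))
  invisible(x)
}

#' Gower double-centring
#'
#' Converts a distance matrix into the centred inner-product (Gower) matrix
#' G = -J D^2 J / 2 with J = I - 11'/n, the shared backbone of metric MDS
#' and distance-based analysis of variance.
#'
#' @param D symmetric distance matrix.
#' @return centred inner-product matrix.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  G <- A - matrix(rm_, n, n) - matrix(rm_, n, n, byrow = TRUE) + mean(A)
  (G + t(G)) / 2
}

#' Read / write labelled square matrices
#'
#' Tab-delimited with row and column labels (first column = ids); used for
#' kinship and distance matrices.
#'
#' @param file path.
#' @return `read_square_matrix()` returns a labelled numeric matrix.
#' @export
read_square_matrix <- function(file) {
  m <- as.matrix(utils::read.delim(file, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  m
}

#' @param m labelled matrix to write.
#' @rdname read_square_matrix
#' @export
write_square_matrix <- function(m, file) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write MDS axes as a covariate table
#'
#' @param axes an `mds_axes` object.
#' @param file path.
#' @export
write_mds_axes <- function(axes, file) {
  utils::write.table(data.frame(id = axes$ids, axes$points,
                                check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
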