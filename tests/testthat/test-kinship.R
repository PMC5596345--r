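test_that("pedigree kinship reproduces textbook coefficients", {
  K <- pedigree_kinship(ped_cousin_marriage())
  expect_equal(K["P1", "P1"], 0.5)        # non-inbred self
  expect_equal(K["G1", "P1"], 0.25)       # parent-offspring
  expect_equal(K["P1", "P2"], 0.25)       # full sibs
  expect_equal(K["X", "Y"], 0.0625)       # first cousins
  expect_equal(K["G1", "G2"], 0)          # unrelated founders
  # child of first-cousin parents: self-kinship (1 + 1/16)/2
  expect_equal(K["Z", "Z"], 0.53125)
})

test_that("recursive kinship equals the path-counting oracle exactly", {
  for (s in 1:20) {
    ped <- sim_pedigree(n_generations = sample(2:4, 1),
                        mean_children = 2, n_founder_couples = 2,
                        seed = 1000 + s)
    K <- pedigree_kinship(ped)
    O <- oracle_kinship(topological_order(ped))
    expect_equal(K, O[rownames(K), colnames(K)], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # and on the inbred fixture, where path counting must handle loops
  ped <- ped_cousin_marriage()
  expect_equal(pedigree_kinship(ped),
               oracle_kinship(ped)[rownames(pedigree_kinship(ped)),
                                   rownames(pedigree_kinship(ped))],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pedigree kinship is invariant to row order", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 2, seed = 17)
  K1 <- pedigree_kinship(ped)
  set.seed(1)
  shuffled <- ped[sample(nrow(ped)), , drop = FALSE]
  class(shuffled) <- c("fam_pedigree", "data.frame")
  K2 <- pedigree_kinship(shuffled)
  ids <- rownames(K1)
  expect_equal(K1, K2[ids, ids], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("SNP kinship: normalization, duplicates, hand-worked value", {
  ped <- ped_sib_pairs(30)
  bl <- haplotype_blocks(80, 2, seed = 3)
  g <- gene_drop(ped, bl, seed = 4)
  K <- snp_kinship(g)
  off <- K[row(K) != col(K)]
  expect_lt(abs(mean(off)), 1e-12)

  # duplicated individual: pairwise entry equals the shared diagonal
  m <- rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L),
             c = c(2L, 1L, 0L, 1L))
  Kd <- snp_kinship(m, normalize = FALSE)
  expect_equal(Kd["a", "b"], Kd["a", "a"])

  # two individuals, two loci, p = 0.5 at both:
  # genotypes (0,2) and (2,0); standardized scores (-1,1)/sqrt(0.5) and
  # (1,-1)/sqrt(0.5); mean cross-product / 2 = -1, self = +1
  m2 <- rbind(u = c(0L, 2L), v = c(2L, 0L))
  K2 <- snp_kinship(m2, normalize = FALSE, allele_freq = c(0.5, 0.5))
  expect_equal(K2["u", "v"], -1)
  expect_equal(K2["u", "u"], 1)

  expect_error(snp_kinship(rbind(c(2L, 2L), c(2L, 2L))), "polymorphic")
})

test_that("kinship-to-distance is a Euclidean map with Gower inverse", {
  # identical twins: equal rows and diagonal -> distance 0
  Kt <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
               dimnames = list(c("t1", "t2"), c("t1", "t2")))
  expect_equal(kinship_to_distance(Kt)["t1", "t2"], 0)

  K <- matrix(c(0.5, 0.25, 0.25, 0.5), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  D <- kinship_to_distance(K)
  expect_equal(D["a", "b"], sqrt(0.5), tolerance = 1e-12)

  # double-centring the squared distances recovers the centred
  # PSD-repaired kinship
  ped <- sim_pedigree(n_generations = 3, mean_children = 2, seed = 8)
  Kp <- pedigree_kinship(ped)
  Dp <- kinship_to_distance(Kp)
  n <- nrow(Kp)
  J <- diag(n) - matrix(1 / n, n, n)
  e <- eigen((Kp + t(Kp)) / 2, symmetric = TRUE)
  Kpsd <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  expect_equal(gower_center(Dp), J %*% Kpsd %*% J, tolerance = 1e-8,
               ignore_attr = TRUE)
  # triangle inequality on all triples
  for (i in 1:min(n, 8)) for (j in 1:min(n, 8)) for (k in 1:min(n, 8))
    expect_lte(Dp[i, j], Dp[i, k] + Dp[k, j] + 1e-12)
})

test_that("classical MDS embeds distances faithfully", {
  # two points at distance d -> coordinates +/- d/2 on one axis
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  ax <- suppressWarnings(classical_mds(D2, n_axes = 1))
  expect_equal(sort(ax$points[, 1]), c(-1.5, 1.5), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a known 5-d configuration round-trips through the embedding
  set.seed(42)
  X <- matrix(rnorm(12 * 5), 12, 5,
              dimnames = list(paste0("i", 1:12), NULL))
  D <- as.matrix(dist(X))
  ax5 <- classical_mds(D, n_axes = 5)
  expect_equal(ncol(ax5$points), 5L)
  Dhat <- as.matrix(dist(ax5$points))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-8)

  # agreement with stats::cmdscale up to per-axis sign
  cmd <- stats::cmdscale(D, k = 5)
  expect_equal(abs(unname(ax5$points)), abs(unname(cmd)),
               tolerance = 1e-8)

  # deterministic sign convention: first nonzero loading positive
  for (a in 1:5) {
    v <- ax5$points[, a]
    expect_gt(v[which(abs(v) > 1e-12)[1]], 0)
  }

  # degenerate rank: padding with zero axes and a warning
  expect_warning(axp <- classical_mds(D2, n_axes = 1 + 0), NA)
  Dflat <- as.matrix(dist(cbind(1:7)))
  expect_warning(axf <- classical_mds(Dflat, n_axes = 5), "padding")
  expect_true(all(axf$points[, 2:5] == 0))
})
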