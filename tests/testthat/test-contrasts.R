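test_that("within/between household means match hand arithmetic", {
  # two households of two; distances set by hand
  D <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  D["s1", "s2"] <- D["s2", "s1"] <- 0.2   # within H1
  D["s3", "s4"] <- D["s4", "s3"] <- 0.4   # within H2
  D["s1", "s3"] <- D["s3", "s1"] <- 0.7
  D["s1", "s4"] <- D["s4", "s1"] <- 0.8
  D["s2", "s3"] <- D["s3", "s2"] <- 0.6
  D["s2", "s4"] <- D["s4", "s2"] <- 0.9
  g <- c(s1 = "H1", s2 = "H1", s3 = "H2", s4 = "H2")
  res <- group_dissimilarity_ttest(D, g)
  expect_equal(res$mean_within, 0.3)
  expect_equal(res$mean_between, 0.75)
  expect_equal(res$n_within, 2L)
  expect_equal(res$n_between, 4L)
  expect_equal(res$sd_within, sd(c(0.2, 0.4)))
  expect_true(res$caveat_nonindependence)

  # all-identical compositions: both classes of distances are zero
  Z <- matrix(0, 4, 4, dimnames = dimnames(D))
  rz <- suppressWarnings(group_dissimilarity_ttest(Z, g))
  expect_equal(rz$mean_within, 0)
  expect_equal(rz$mean_between, 0)

  # an empty class errors
  expect_error(group_dissimilarity_ttest(D, c(s1 = "H", s2 = "H",
                                              s3 = "H", s4 = "H")),
               "each class")
})

test_that("a planted household effect yields within < between with a
           small p", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 3, seed = 13)
  cfg <- effect_config(sigma_household = 1.2, sigma_city = 0,
                       sigma_genetic = 0, beta_age = 0,
                       sigma_residual = 0.5, n_phylotypes = 60,
                       depth_law = list(type = "fixed", depth = 4000))
  tab <- simulate_composition(ped, config = cfg, seed = 14)
  D <- bray_curtis(relative_abundance(tab))
  res <- group_dissimilarity_ttest(
    D, stats::setNames(tab$meta$household, tab$meta$sample))
  expect_lt(res$mean_within, res$mean_between)
  expect_lt(res$p_value, 0.05)
})

test_that("spousal subgenus contrast: extreme case gives -1 per genus", {
  # two couples; within the genus, spouses identical, non-spouses disjoint
  counts <- rbind(
    h1a = c(10L, 0L, 5L), h1b = c(10L, 0L, 5L),
    h2a = c(0L, 10L, 5L), h2b = c(0L, 10L, 5L))
  colnames(counts) <- c("gA1", "gA2", "out1")
  tax <- data.frame(phylotype = colnames(counts),
                    genus = c("Alpha", "Alpha", "Other"),
                    phylum = "x", stringsAsFactors = FALSE)
  tab <- phylotype_table(counts, tax)
  pairs <- data.frame(partner1 = c("h1a", "h2a"),
                      partner2 = c("h1b", "h2b"))
  res <- spouse_subgenus_contrast(tab, pairs, genera = "Alpha")
  expect_equal(res$per_genus$difference, -1)
  expect_equal(res$per_genus$mean_spousal, 0)
  expect_equal(res$per_genus$mean_nonspousal, 1)

  # non-disjoint pairs are rejected
  bad <- data.frame(partner1 = c("h1a", "h1a"),
                    partner2 = c("h1b", "h2b"))
  expect_error(spouse_subgenus_contrast(tab, bad, genera = "Alpha"),
               "disjoint")
})

test_that("pairs lost to zero genus counts are dropped and reported", {
  counts <- rbind(
    h1a = c(4L, 6L), h1b = c(5L, 5L),
    h2a = c(0L, 10L), h2b = c(3L, 7L))
  colnames(counts) <- c("gA1", "other")
  tax <- data.frame(phylotype = colnames(counts),
                    genus = c("Alpha", "Other"), phylum = "x")
  tab <- phylotype_table(counts, tax)
  pairs <- data.frame(partner1 = c("h1a", "h2a"),
                      partner2 = c("h1b", "h2b"))
  res <- spouse_subgenus_contrast(tab, pairs, genera = "Alpha")
  expect_equal(res$per_genus$dropped_pairs, 1L)
  expect_equal(res$per_genus$n_pairs_used, 1L)
})

test_that("no planted spousal resemblance: cross-genus difference is
           near zero", {
  set.seed(15)
  n <- 16
  counts <- matrix(rpois(n * 20, 30), n, 20,
                   dimnames = list(sprintf("i%02d", 1:n),
                                   sprintf("p%02d", 1:20)))
  tax <- data.frame(phylotype = colnames(counts),
                    genus = rep(c("A", "B", "C", "D"), each = 5),
                    phylum = "x")
  tab <- phylotype_table(counts, tax)
  pairs <- data.frame(partner1 = sprintf("i%02d", seq(1, 15, 2)),
                      partner2 = sprintf("i%02d", seq(2, 16, 2)))
  res <- spouse_subgenus_contrast(tab, pairs,
                                  genera = c("A", "B", "C", "D"))
  expect_lt(abs(res$mean_difference), 2 * res$se_difference + 0.05)
})
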