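bray_fixture <- function(seed = 31, n_phylotypes = 60) {
  ped <- sim_pedigree(n_generations = 3, mean_children = 3, seed = seed)
  kin <- pedigree_kinship(ped)
  cfg <- effect_config(n_phylotypes = n_phylotypes,
                       depth_law = list(type = "fixed", depth = 3000))
  tab <- simulate_composition(ped, kin, cfg, seed = seed + 1)
  cov <- tab$meta
  rownames(cov) <- cov$sample
  cov$age <- as.numeric(cov$age)
  list(D = bray_curtis(relative_abundance(tab)), cov = cov)
}

test_that("Euclidean one-factor pseudo-F equals classical ANOVA F", {
  set.seed(21)
  y <- rnorm(24)
  g <- factor(rep(c("a", "b", "c"), each = 8))
  D <- as.matrix(dist(y))
  fit <- permanova(D ~ g, data.frame(g = g), permutations = 99, seed = 1)
  Fclassic <- anova(lm(y ~ g))[["F value"]][1]
  expect_equal(fit$tab$F[1], Fclassic, tolerance = 1e-10)

  # two groups: pseudo-F equals the squared pooled-variance t statistic
  g2 <- factor(rep(c("a", "b"), each = 12))
  fit2 <- permanova(D ~ g2, data.frame(g2 = g2), permutations = 99,
                    seed = 1)
  tstat <- t.test(y ~ g2, var.equal = TRUE)$statistic
  expect_equal(fit2$tab$F[1], unname(tstat^2), tolerance = 1e-10)
})

test_that("sums of squares are additive and R2 sums to one", {
  fx <- bray_fixture()
  fit <- permanova(fx$D ~ plate + gender + age + city + household,
                   fx$cov, permutations = 49, seed = 2)
  tab <- fit$tab
  k <- nrow(tab) - 1L
  expect_equal(sum(tab$R2[1:(k - 1)]) + tab$R2[k], 1, tolerance = 1e-8)
  expect_equal(sum(tab$SumOfSqs[1:(k - 1)]),
               tab$SumOfSqs[k + 1] - tab$SumOfSqs[k],
               tolerance = 1e-8)
  expect_equal(sum(tab$Df[1:k]), fit$n - 1L)
})

test_that("sequential decomposition matches vegan::adonis2 term by term", {
  fx <- bray_fixture()
  fit <- permanova(fx$D ~ plate + gender + age + city + household,
                   fx$cov, permutations = 19, seed = 3)
  v <- vegan::adonis2(as.dist(fx$D) ~ plate + gender + age + city +
                        household,
                      data = fx$cov, permutations = 19, by = "terms")
  k <- length(fit$term_labels)
  expect_equal(fit$tab$SumOfSqs[1:(k + 1)], v$SumOfSqs[1:(k + 1)],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$tab$R2[1:(k + 1)], v$R2[1:(k + 1)], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$tab$F[1:k], v$F[1:k], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$tab$Df[1:(k + 1)], v$Df[1:(k + 1)],
               ignore_attr = TRUE)
})

test_that("exhaustive enumeration matches the brute-force oracle, and
           sampled p lands in its binomial band", {
  set.seed(77)
  y <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- c("a", "a", "a", "b", "b", "b")
  cov <- data.frame(g = g, row.names = rownames(D))

  fit_ex <- permanova(D ~ g, cov, permutations = "exact")
  expect_true(fit_ex$exact)
  expect_equal(fit_ex$permutations, factorial(6))
  p_oracle <- oracle_onefactor_exact_p(D, g)
  expect_equal(fit_ex$tab$p[1], p_oracle, tolerance = 1e-12)
  # the oracle's F must agree too
  expect_equal(fit_ex$tab$F[1], oracle_onefactor_F(D, g),
               tolerance = 1e-10)

  fit_s <- permanova(D ~ g, cov, permutations = 999, seed = 5)
  band <- binom_band(p_oracle, 999)
  expect_gte(fit_s$tab$p[1], band[1])
  expect_lte(fit_s$tab$p[1], band[2])
})

test_that("strata restrict permutations to within-city shuffles", {
  strata <- factor(rep(c("I", "II", "III"), times = c(4, 3, 3)))
  perms <- build_permutations(10, 200, strata = strata, seed = 9)
  for (p in seq_len(ncol(perms)))
    expect_identical(as.character(strata[perms[, p]]),
                     as.character(strata))
  # exact strata mode enumerates the product of within-stratum groups
  ex <- build_permutations(6, "exact",
                           strata = factor(c(1, 1, 1, 2, 2, 2)))
  expect_equal(ncol(ex), factorial(3)^2)
  expect_true(attr(ex, "exact"))
  # all columns distinct
  expect_equal(anyDuplicated(t(ex)), 0L)
})

test_that("stratified fits keep city fixed and still decompose fully", {
  fx <- bray_fixture()
  fit <- suppressWarnings(
    permanova(fx$D ~ age + city + household, fx$cov,
              permutations = 99, strata = "city", seed = 4))
  tab <- fit$tab
  expect_equal(sum(tab$R2[1:(nrow(tab) - 1)]), 1, tolerance = 1e-8)
  expect_true(all(tab$p[1:3] > 0 & tab$p[1:3] <= 1))
})

test_that("rank-deficient terms get zero df and a warning", {
  fx <- bray_fixture()
  fx$cov$city_copy <- fx$cov$city
  expect_warning(
    fit <- permanova(fx$D ~ city + city_copy, fx$cov,
                     permutations = 29, seed = 6),
    "rank-deficient")
  i <- match("city_copy", fit$tab$term)
  expect_equal(fit$tab$Df[i], 0L)
  expect_true(is.na(fit$tab$F[i]) && is.na(fit$tab$p[i]))
})

test_that("permanova methods expose the fit the standard way", {
  fx <- bray_fixture()
  fit <- permanova(fx$D ~ age + household, fx$cov, permutations = 29,
                   seed = 7)
  r2 <- coef(fit)
  expect_named(r2, c("age", "household"))
  expect_equal(unname(sum(r2)), sum(fit$tab$R2[1:2]))
  df <- as.data.frame(fit)
  expect_s3_class(df, "data.frame")
  expect_output(print(fit), "Sequential permutational")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_permanova(fit, f)
  back <- read.delim(f)
  expect_equal(back$R2[1:2], unname(r2), tolerance = 1e-12)
})
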