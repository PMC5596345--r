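test_that("counts conserve the drawn depth and reproduce under a seed", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 2, seed = 4)
  cfg <- effect_config(depth_law = list(type = "fixed", depth = 3000),
                       n_phylotypes = 80)
  kin <- pedigree_kinship(ped)
  t1 <- simulate_composition(ped, kin, cfg, seed = 9)
  t2 <- simulate_composition(ped, kin, cfg, seed = 9)
  expect_identical(t1$counts, t2$counts)
  expect_true(all(rowSums(t1$counts) == 3000))
  expect_equal(nrow(t1$counts), nrow(ped))
  expect_equal(ncol(t1$counts), 80L)
  # every phylotype has a taxonomy entry
  expect_setequal(colnames(t1$counts), t1$taxonomy$phylotype)
})

test_that("null model is exchangeable across households", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 3, seed = 6)
  cfg <- effect_config(sigma_household = 0, sigma_spouse = 0,
                       sigma_city = 0, sigma_genetic = 0, beta_age = 0,
                       sigma_residual = 0.8, n_phylotypes = 60,
                       depth_law = list(type = "fixed", depth = 4000))
  tab <- simulate_composition(ped, config = cfg, seed = 7)
  D <- bray_curtis(relative_abundance(tab))
  hh <- stats::setNames(tab$meta$household, tab$meta$sample)
  same <- outer(hh[rownames(D)], hh[rownames(D)], "==")
  ut <- upper.tri(D)
  within <- D[ut & same]; between <- D[ut & !same]
  se <- sqrt(stats::var(within) / length(within) +
               stats::var(between) / length(between))
  expect_lt(abs(mean(within) - mean(between)), 4 * se)
})

test_that("a dominant household effect makes housemates more similar", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 3, seed = 6)
  cfg <- effect_config(sigma_household = 1.2, sigma_city = 0,
                       sigma_genetic = 0, beta_age = 0,
                       sigma_residual = 0.5, n_phylotypes = 60,
                       depth_law = list(type = "fixed", depth = 4000))
  tab <- simulate_composition(ped, config = cfg, seed = 8)
  D <- bray_curtis(relative_abundance(tab))
  hh <- stats::setNames(tab$meta$household, tab$meta$sample)
  same <- outer(hh[rownames(D)], hh[rownames(D)], "==")
  ut <- upper.tri(D)
  expect_lt(mean(D[ut & same]), mean(D[ut & !same]))
})

test_that("with no effects and multinomial sampling, proportions
           converge to the softmax baseline", {
  ped <- sim_pedigree(n_generations = 2, mean_children = 0,
                      n_founder_couples = 4, seed = 1)
  cfg <- effect_config(sigma_household = 0, sigma_spouse = 0,
                       sigma_city = 0, sigma_genetic = 0, beta_age = 0,
                       sigma_residual = 0,
                       overdispersion_theta = Inf, n_phylotypes = 40,
                       depth_law = list(type = "fixed", depth = 2e5))
  tab <- simulate_composition(ped, config = cfg, seed = 2)
  mu <- default_taxonomy(40)$mu
  target <- exp(mu - max(mu)); target <- target / sum(target)
  props <- colMeans(tab$counts / rowSums(tab$counts))
  expect_lt(max(abs(props - target)), 4 * sqrt(max(target) / (2e5 * 8)) + 1e-3)
})

test_that("genetic effects require and respect the kinship labels", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 2, seed = 3)
  cfg <- effect_config(sigma_genetic = 0.5, n_phylotypes = 30)
  expect_error(simulate_composition(ped, NULL, cfg, seed = 1), "kinship")
  kin <- pedigree_kinship(ped)[1:3, 1:3]
  expect_error(simulate_composition(ped, kin, cfg, seed = 1),
               "missing individuals")
})

test_that("effect_config rejects invalid settings", {
  expect_error(effect_config(sigma_household = -1), ">= 0")
  expect_error(effect_config(spike_fractions = c(0.1, 0.2, 0.3)),
               "decreasing")
  expect_error(effect_config(spike_fractions = c(0.5, 0.4, 0.3)),
               "sum < 1")
})

test_that("default taxonomy leads with the expected salivary genera", {
  base <- default_taxonomy(271)
  expect_equal(nrow(base$taxonomy), 271L)
  expect_equal(length(base$mu), 271L)
  p <- exp(base$mu); p <- p / sum(p)
  by_genus <- tapply(p, base$taxonomy$genus, sum)
  ord <- names(sort(by_genus, decreasing = TRUE))
  expect_equal(ord[1], "Streptococcus")
  expect_true(all(c("Rothia", "Neisseria", "Prevotella") %in% ord[2:4]))
  expect_equal(unname(by_genus["Streptococcus"]), 0.304, tolerance = 0.01)
})

test_that("simulated reads: spikes compete with 16S load", {
  ped <- sim_pedigree(n_generations = 3, mean_children = 2, seed = 10)
  cfg <- effect_config(read_depth = 600, n_phylotypes = 30,
                       sigma_genetic = 0,
                       spike_fractions = c(0.08, 0.02, 0.005),
                       depth_law = list(type = "lognormal",
                                        meanlog = log(3000), sdlog = 1))
  tab <- simulate_composition(ped, config = cfg, seed = 11)
  sp <- spike_sequences()
  reads <- simulate_reads(tab, sp, cfg, seed = 12)
  spikes <- rowSums(attr(reads, "spike_draws"))
  n16 <- attr(reads, "n16s_draws")
  expect_true(all(spikes + n16 == cfg$read_depth))
  expect_lt(stats::cor(spikes, n16), 0)

  # no spikes when the fractions are zero
  none <- simulate_reads(tab, sp, cfg, seed = 12,
                         spike_fractions = c(0, 0, 0))
  expect_equal(sum(attr(none, "spike_draws")), 0)
  expect_false(any(none$sequence %in% sp))

  # byte-identical FASTQ under the same seed
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(tab, sp, cfg, seed = 99), f1)
  write_fastq(simulate_reads(tab, sp, cfg, seed = 99), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(simulate_reads(tab, sp[1:2], cfg, seed = 1), "three")
  expect_error(simulate_reads(tab, c(sp[1:2], "ACGT"), cfg, seed = 1),
               "350")
})
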