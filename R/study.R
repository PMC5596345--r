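#' Configuration for a full synthetic family-microbiome study
#'
#' Bundles the generator settings (pedigree, haplotype blocks, effect
#' scales) and the analysis settings (permutations, MDS axes, robustness
#' procedure) for [run_study()].  Defaults are sized so that a full run
#' completes in minutes on one CPU while retaining the structure of a
#' multigenerational, multi-city family cohort.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_generations,mean_children,n_cities,n_founder_couples pedigree
#'   generator settings (see [sim_pedigree()]); the defaults build a
#'   five-generation family of several hundred members.
#' @param n_blocks,loci_per_block haplotype-block structure for gene
#'   dropping (see [haplotype_blocks()]).
#' @param founder_pool ancestral haplotype pool size emulating community
#'   endogamy (see [gene_drop()]); `Inf` for unrelated founders.
#' @param recruitment household-wise recruitment settings passed to
#'   [recruit_samples()] (a list with `n_pair_households`,
#'   `n_family_households`, `members_per_family`, `n_singletons`), or
#'   `NULL` to sample every family member.
#' @param effects an [effect_config()].
#' @param permutations permutations for the main PERMANOVA fits.
#' @param mds_axes number of kinship-MDS covariate axes.
#' @param run_robustness run the variable-order robustness procedure?
#' @param robustness_orderings,robustness_permutations settings of that
#'   procedure.
#' @return list of class `"study_config"`.
#' @export
study_config <- function(seed = 1, n_generations = 5, mean_children = 3.2,
                         n_cities = 4, n_founder_couples = 6,
                         n_blocks = 300, loci_per_block = 2,
                         founder_pool = 24,
                         recruitment = list(n_pair_households = 8,
                                            n_family_households = 5,
                                            members_per_family = 3,
                                            n_singletons = 100),
                         effects = effect_config(),
                         permutations = 999, mds_axes = 5,
                         run_robustness = TRUE,
                         robustness_orderings = 30,
                         robustness_permutations = 199) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the full family-microbiome variance-partitioning study
#'
#' Executes the whole pipeline on a synthetic cohort: pedigree simulation,
#' gene dropping, pedigree and SNP kinship, kinship-MDS covariates,
#' Dirichlet-multinomial phylotype counts, depth filtering, Bray-Curtis
#' dissimilarities, and the analysis sequence of a family study —
#' exploratory Mantel test of genetic kinship against microbiome
#' dissimilarity, within- vs between-household t-test, the cohabiting
#' cohort models (city-only, household-only, nested city + household with
#' city-stratified permutations), the ever-cohabited cohort model, the
#' cities model, the pedigree-vs-SNP kinship comparison with parental
#' household, spouse-pair analyses, and variable-order robustness.
#' Identical configuration and seed reproduce the bundle exactly.
#'
#' @param config a [study_config()].
#' @param output_dir optional directory; when given, all tables are also
#'   written as tab-delimited files.
#' @return list of class `"family_study"` with elements `pedigree`,
#'   `genotypes`, `kinship` (pedigree/snp/snp_raw), `mds`
#'   (snp/pedigree), `table` (filtered `phylotype_table`), `bray`,
#'   `cohorts`, `covariates`, `analyses`, `provenance`.
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- as.integer(config$seed)

  ped <- sim_pedigree(config$n_generations, config$mean_children,
                      config$n_cities,
                      n_founder_couples = config$n_founder_couples,
                      seed = seed)
  sampled <- if (is.null(config$recruitment)) ped$id else
    do.call(recruit_samples,
            c(list(ped = ped, seed = seed + 4L), config$recruitment))
  sped <- subset_pedigree(ped, sampled)
  blocks <- haplotype_blocks(config$n_blocks, config$loci_per_block,
                             seed = seed + 1L)
  geno <- gene_drop(ped, blocks, seed = seed + 2L,
                    founder_pool = config$founder_pool)
  kin_ped <- pedigree_kinship(ped)[sampled, sampled]
  kin_snp_raw <- snp_kinship(geno$counts[sampled, ], normalize = FALSE)
  kin_snp <- snp_kinship(geno$counts[sampled, ], normalize = TRUE)

  # generative genetic covariance follows the realized (SNP) relatedness
  tab <- simulate_composition(sped, kinship = kin_snp_raw,
                              config = config$effects, seed = seed + 3L)
  tab <- analysis_depth_filter(tab, 1000L)
  bray <- bray_curtis(relative_abundance(tab))

  mds_snp <- classical_mds(kinship_to_distance(kin_snp), config$mds_axes)
  mds_ped <- classical_mds(kinship_to_distance(kin_ped), config$mds_axes)

  samples <- rownames(tab$counts)
  cohorts <- select_cohorts(ped, samples = samples,
                            genotyped = sampled)
  hh_now <- attr(cohorts, "household_now")
  hh_ever <- attr(cohorts, "household_ever")

  cov <- tab$meta
  cov$household_now <- unname(hh_now[cov$sample])
  cov$household_ever <- unname(hh_ever[cov$sample])
  child_hh <- stats::setNames(ped$childhood_household, ped$id)
  par_hh <- ifelse(is.na(child_hh[cov$sample]),
                   cov$household, child_hh[cov$sample])
  cov$parental_household <- unname(par_hh)
  cov$age <- as.numeric(cov$age)
  for (a in seq_len(config$mds_axes)) {
    cov[[paste0("MDS", a)]] <- mds_snp$points[cov$sample, a]
    cov[[paste0("pedMDS", a)]] <- mds_ped$points[cov$sample, a]
  }
  rownames(cov) <- cov$sample

  mds_terms <- paste0("MDS", seq_len(config$mds_axes))
  base_terms <- c("plate", "gender", "age", mds_terms)
  P <- config$permutations

  sub_fit <- function(ids, terms, strata = NULL, perm_seed) {
    ids <- intersect(ids, samples)
    d <- bray[ids, ids]
    cv <- cov[ids, , drop = FALSE]
    f <- stats::as.formula(paste(".D ~", paste(terms, collapse = " + ")))
    env <- new.env(parent = environment())
    assign(".D", d, envir = env)
    environment(f) <- env
    permanova(f, cv, permutations = P, strata = strata,
              seed = perm_seed)
  }

  gen_ids <- cohorts$genetics$sample_ids
  now_ids <- cohorts$cohabiting_now$sample_ids
  ever_ids <- cohorts$ever_cohabited$sample_ids
  city_ids <- cohorts$cities$sample_ids

  analyses <- list()

  # exploratory Mantel: genetic distance vs community dissimilarity
  gdist <- kinship_to_distance(kin_snp)[gen_ids, gen_ids]
  analyses$mantel <- mantel_test(gdist, bray[gen_ids, gen_ids],
                                 n_permutations = P, seed = seed + 10L)

  # within- vs between-household community dissimilarity
  analyses$household_ttest <- group_dissimilarity_ttest(
    bray[now_ids, now_ids],
    stats::setNames(cov[now_ids, "household_now"], now_ids))

  # cohabiting cohort: city-only, household-only, nested city + household
  analyses$cohabiting <- list(
    city_only = sub_fit(now_ids, c(base_terms, "city"),
                        perm_seed = seed + 11L),
    household_only = sub_fit(now_ids, c(base_terms, "household_now"),
                             perm_seed = seed + 12L),
    city_household = sub_fit(now_ids,
                             c(base_terms, "city", "household_now"),
                             strata = "city", perm_seed = seed + 13L))

  # ever-cohabited cohort
  analyses$ever_cohabited <- list(
    city_only = sub_fit(ever_ids, c(base_terms, "city"),
                        perm_seed = seed + 14L),
    household_only = sub_fit(ever_ids, c(base_terms, "household_ever"),
                             perm_seed = seed + 15L),
    city_household = sub_fit(ever_ids,
                             c(base_terms, "city", "household_ever"),
                             strata = "city", perm_seed = seed + 16L))

  # cities cohort: geography without requiring cohabitation
  analyses$cities <- sub_fit(city_ids, c(base_terms, "city"),
                             perm_seed = seed + 17L)

  # host-genetics comparison: pedigree vs SNP kinship MDS axes, with
  # parental household as the environmental term
  analyses$kinship_comparison <- list(
    pedigree = sub_fit(gen_ids,
                       c("plate", "gender", "age",
                         paste0("pedMDS", seq_len(config$mds_axes)),
                         "parental_household"),
                       perm_seed = seed + 18L),
    snp = sub_fit(gen_ids, c(base_terms, "parental_household"),
                  perm_seed = seed + 19L))

  # spouse pairs: spousal-household variance share and subgenus contrast
  sp <- spouse_pairs(sped)
  sp <- sp[sp$partner1 %in% samples & sp$partner2 %in% samples, ,
           drop = FALSE]
  if (nrow(sp) >= 2) {
    sp_ids <- c(sp$partner1, sp$partner2)
    spcov <- cov[sp_ids, , drop = FALSE]
    spcov$spouse_household <- rep(paste0("couple", seq_len(nrow(sp))), 2)
    dsp <- bray[sp_ids, sp_ids]
    fsp <- stats::as.formula(".Dsp ~ spouse_household")
    envsp <- new.env(parent = environment())
    assign(".Dsp", dsp, envir = envsp)
    environment(fsp) <- envsp
    analyses$spouse <- list(
      permanova = permanova(fsp, spcov, permutations = P,
                            seed = seed + 20L),
      contrast = spouse_subgenus_contrast(tab, sp))
  } else {
    analyses$spouse <- NULL
  }

  if (isTRUE(config$run_robustness)) {
    rids <- intersect(ever_ids, samples)
    analyses$robustness <- order_robustness(
      bray[rids, rids], cov[rids, , drop = FALSE],
      terms = c(base_terms, "city", "household_ever"),
      n_orderings = config$robustness_orderings,
      permutations = config$robustness_permutations,
      seed = seed + 21L)
  }

  bundle <- structure(list(
    pedigree = ped, genotypes = geno,
    kinship = list(pedigree = kin_ped, snp = kin_snp,
                   snp_raw = kin_snp_raw),
    mds = list(snp = mds_snp, pedigree = mds_ped),
    table = tab, bray = bray, cohorts = cohorts, covariates = cov,
    analyses = analyses,
    provenance = list(seed = seed, config = config,
                      package_version =
                        as.character(utils::packageVersion("salivafam")))),
    class = "family_study")
  if (!is.null(output_dir)) write_study(bundle, output_dir)
  bundle
}

#' @export
print.family_study <- function(x, ...) {
  a <- x$analyses
  cat("Synthetic family-microbiome study\n")
  cat(sprintf("  pedigree: %d individuals; samples analysed: %d\n",
              nrow(x$pedigree), nrow(x$table$counts)))
  cat(sprintf("  cohorts: cohabiting %d, ever-cohabited %d, cities %d, genetics %d\n",
              length(x$cohorts$cohabiting_now$sample_ids),
              length(x$cohorts$ever_cohabited$sample_ids),
              length(x$cohorts$cities$sample_ids),
              length(x$cohorts$genetics$sample_ids)))
  cat(sprintf("  Mantel (kinship vs Bray-Curtis): r = %.3f, p = %.4g\n",
              a$mantel$statistic, a$mantel$p_value))
  tt <- a$household_ttest
  cat(sprintf("  household dissimilarity: within %.3f +/- %.3f vs between %.3f +/- %.3f (p = %.3g)\n",
              tt$mean_within, tt$sd_within, tt$mean_between,
              tt$sd_between, tt$p_value))
  hh <- a$cohabiting$household_only$tab
  i <- match("household_now", hh$term)
  cat(sprintf("  cohabiting cohort, household-only model: household R2 = %.3f, p = %.4g\n",
              hh$R2[i], hh$p[i]))
  if (!is.null(a$robustness))
    cat(sprintf("  order robustness: household always q < %g: %s\n",
                a$robustness$alpha,
                a$robustness$always_significant[["household_ever"]]))
  invisible(x)
}

#' Write a study bundle to tab-delimited files
#'
#' Emits the pedigree, genotype matrix, count table and taxonomy, kinship
#' matrices, MDS covariates, every fitted PERMANOVA table, and a summary
#' of the scalar results into `dir`.
#'
#' @param bundle a `family_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_pedigree(bundle$pedigree, fp("pedigree.tsv"))
  write_genotypes(bundle$genotypes, fp("genotypes.tsv"),
                  fp("blocks.tsv"))
  write_phylotype_table(bundle$table, fp("phylotype_counts.tsv"),
                        fp("taxonomy.tsv"))
  write_square_matrix(bundle$kinship$pedigree, fp("kinship_pedigree.tsv"))
  write_square_matrix(bundle$kinship$snp, fp("kinship_snp.tsv"))
  write_square_matrix(bundle$bray, fp("bray_curtis.tsv"))
  write_mds_axes(bundle$mds$snp, fp("mds_snp.tsv"))
  write_mds_axes(bundle$mds$pedigree, fp("mds_pedigree.tsv"))
  a <- bundle$analyses
  fits <- list(cohab_city_only = a$cohabiting$city_only,
               cohab_household_only = a$cohabiting$household_only,
               cohab_city_household = a$cohabiting$city_household,
               ever_city_only = a$ever_cohabited$city_only,
               ever_household_only = a$ever_cohabited$household_only,
               ever_city_household = a$ever_cohabited$city_household,
               cities = a$cities,
               kinship_pedigree = a$kinship_comparison$pedigree,
               kinship_snp = a$kinship_comparison$snp)
  if (!is.null(a$spouse)) fits$spouse <- a$spouse$permanova
  for (nm in names(fits))
    write_permanova(fits[[nm]], fp(paste0("permanova_", nm, ".tsv")))
  tt <- a$household_ttest
  summ <- data.frame(
    quantity = c("mantel_r", "mantel_p", "within_household_mean",
                 "within_household_sd", "between_household_mean",
                 "between_household_sd", "household_ttest_p", "seed"),
    value = c(a$mantel$statistic, a$mantel$p_value, tt$mean_within,
              tt$sd_within, tt$mean_between, tt$sd_between, tt$p_value,
              bundle$provenance$seed))
  utils::write.table(summ, fp("summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
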