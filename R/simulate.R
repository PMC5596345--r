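#' Configuration of the synthetic-cohort generative model
#'
#' Collects the variance components and sampling parameters of the
#' synthetic microbiome generator.  Latent log abundances receive
#' independent zero-mean normal household, city and residual effects, a
#' per-phylotype age slope, and a genetic effect whose covariance across
#' individuals follows the kinship matrix; counts are drawn by a
#' Dirichlet-multinomial around the softmax of the latent scores.
#'
#' Default scales are chosen to emulate a cohort in which the shared
#' household dominates (explaining on the order of a fifth to a third of
#' community variance), city and host genetics are weak, and
#' interindividual residual variation is large.
#'
#' @param sigma_household,sigma_city,sigma_genetic,sigma_residual standard
#'   deviations of the latent log-scale effects.
#' @param sigma_spouse extra shared effect for cohabiting spouse pairs, on
#'   top of the household effect: frequent direct contact makes spouses
#'   considerably more similar than other housemates.
#' @param beta_age scale (SD) of the per-phylotype age slope, per year of
#'   age (centred).
#' @param sigma_plate,sigma_gender optional batch (sequencing plate) and
#'   gender effect scales, default 0.
#' @param n_plates number of sequencing plates samples are spread over.
#' @param n_phylotypes number of phylotypes in the community.
#' @param overdispersion_theta Dirichlet-multinomial concentration
#'   multiplier; `Inf` gives plain multinomial sampling.
#' @param depth_law list describing the per-sample read-depth distribution:
#'   `list(type = "lognormal", meanlog=, sdlog=)` or
#'   `list(type = "fixed", depth=)`.
#' @param spike_fractions three strictly decreasing expected read fractions
#'   in (0,1), summing to < 1, for the three spike-in tiers (log-spaced
#'   concentrations).
#' @param read_depth fixed total sequencer reads per sample when simulating
#'   raw reads (spikes compete with 16S reads within this total).
#' @param read_length_sd SD of simulated 16S read length around 369 bases.
#' @param frac_low_quality,frac_short fractions of reads simulated with
#'   poor base quality / truncated length (exercise the QC filters).
#' @return list of class `"effect_config"`.
#' @export
effect_config <- function(sigma_household = 0.3, sigma_spouse = 0.6,
                          sigma_city = 0.1,
                          sigma_genetic = 0.4, sigma_residual = 1.2,
                          beta_age = 0.01, sigma_plate = 0,
                          sigma_gender = 0, n_plates = 2,
                          n_phylotypes = 271,
                          overdispersion_theta = 200,
                          depth_law = list(type = "lognormal",
                                           meanlog = log(15000),
                                           sdlog = 0.5),
                          spike_fractions = c(0.02, 0.002, 4e-04),
                          read_depth = 5000, read_length_sd = 4,
                          frac_low_quality = 0.05, frac_short = 0.02) {
  sc <- c(sigma_household = sigma_household, sigma_spouse = sigma_spouse,
          sigma_city = sigma_city,
          sigma_genetic = sigma_genetic, sigma_residual = sigma_residual,
          beta_age = beta_age, sigma_plate = sigma_plate,
          sigma_gender = sigma_gender)
  if (any(sc < 0)) stop("all scale parameters must be >= 0")
  if (n_phylotypes < 1) stop("n_phylotypes must be positive")
  if (overdispersion_theta < 0) stop("overdispersion_theta must be >= 0")
  if (length(spike_fractions) != 3)
    stop("spike_fractions must have length 3")
  if (any(diff(spike_fractions) >= 0) ||
      any(spike_fractions <= 0 | spike_fractions >= 1) ||
      sum(spike_fractions) >= 1)
    stop("spike_fractions must be strictly decreasing, in (0,1), sum < 1")
  structure(list(sigma_household = sigma_household,
                 sigma_spouse = sigma_spouse, sigma_city = sigma_city,
                 sigma_genetic = sigma_genetic,
                 sigma_residual = sigma_residual, beta_age = beta_age,
                 sigma_plate = sigma_plate, sigma_gender = sigma_gender,
                 n_plates = as.integer(n_plates),
                 n_phylotypes = as.integer(n_phylotypes),
                 overdispersion_theta = overdispersion_theta,
                 depth_law = depth_law, spike_fractions = spike_fractions,
                 read_depth = as.integer(read_depth),
                 read_length_sd = read_length_sd,
                 frac_low_quality = frac_low_quality,
                 frac_short = frac_short),
            class = "effect_config")
}

# salivary genus profile used for the default baseline: leading genera and
# their approximate mean relative abundances (%), remainder spread over
# rarer genera
salivary_genus_profile <- function() {
  data.frame(
    genus = c("Streptococcus", "Rothia", "Neisseria", "Prevotella",
              "Leptotrichia", "Haemophilus", "Veillonella",
              "Fusobacterium", "Porphyromonas", "Granulicatella",
              "Actinomyces", "Gemella", "Capnocytophaga",
              "Campylobacter", "unclassified"),
    phylum = c("Firmicutes", "Actinobacteria", "Proteobacteria",
               "Bacteroidetes", "Fusobacteria", "Proteobacteria",
               "Firmicutes", "Fusobacteria", "Bacteroidetes",
               "Firmicutes", "Actinobacteria", "Firmicutes",
               "Bacteroidetes", "Proteobacteria", "unclassified"),
    target = c(30.4, 18.5, 17.1, 17.1, 3.5, 3.0, 2.5, 2.0, 1.5, 1.2,
               1.0, 0.8, 0.6, 0.5, 0.3) / 100,
    stringsAsFactors = FALSE
  )
}

#' Default phylotype taxonomy and baseline log abundances
#'
#' Deterministically assigns `n_phylotypes` phylotypes to a realistic set
#' of salivary genera (Streptococcus, Rothia, Neisseria, Prevotella
#' leading) and splits each genus's target mean abundance across its
#' phylotypes geometrically, yielding the baseline log-abundance vector of
#' the generator.
#'
#' @param n_phylotypes number of phylotypes.
#' @return list with `taxonomy` (data frame: phylotype, genus, phylum) and
#'   `mu` (baseline log abundances).
#' @export
default_taxonomy <- function(n_phylotypes = 271) {
  prof <- salivary_genus_profile()
  # phylotypes per genus: proportional to sqrt(target) (abundant genera are
  # phylotype-rich but not linearly so), at least one each
  w <- sqrt(prof$target)
  n_g <- pmax(1L, as.integer(round(w / sum(w) * n_phylotypes)))
  while (sum(n_g) != n_phylotypes) {
    i <- if (sum(n_g) > n_phylotypes) which.max(n_g) else which.max(w)
    n_g[i] <- n_g[i] + sign(n_phylotypes - sum(n_g))
  }
  tax <- data.frame(phylotype = character(0), genus = character(0),
                    phylum = character(0), stringsAsFactors = FALSE)
  mu <- numeric(0)
  for (g in seq_len(nrow(prof))) {
    k <- n_g[g]
    split <- 0.7^(seq_len(k) - 1)
    split <- split / sum(split) * prof$target[g]
    tax <- rbind(tax, data.frame(
      phylotype = sprintf("P%03d_%s", length(mu) + seq_len(k),
                          substr(prof$genus[g], 1, 4)),
      genus = prof$genus[g], phylum = prof$phylum[g],
      stringsAsFactors = FALSE))
    mu <- c(mu, log(split))
  }
  list(taxonomy = tax, mu = mu)
}

#' Simulate a phylotype count table over a pedigree
#'
#' Draws, for every individual in the pedigree, a latent log-abundance
#' vector eta_ij = mu_j + household_j + city_j + plate_j + gender_j +
#' beta_j (age_i - mean age) + genetic_ij + residual_ij, converts it to
#' relative abundances by softmax, and draws integer counts by a
#' Dirichlet-multinomial with concentration `overdispersion_theta *
#' abundance` at a per-sample depth from the configured depth law
#' (`theta = Inf` gives plain multinomial).  The genetic effect vector for
#' each phylotype is drawn zero-mean with covariance `sigma_genetic^2`
#' times the relatedness matrix (2 x kinship, eigenvalue-clipped to be
#' positive semidefinite).
#'
#' @param ped a pedigree data frame; one sample per individual.
#' @param kinship kinship matrix covering all pedigree individuals
#'   (required when `sigma_genetic > 0`).
#' @param config an [effect_config()].
#' @param seed integer seed.
#' @return list of class `"phylotype_table"`: `counts` (samples x
#'   phylotypes integer matrix), `taxonomy` (phylotype, genus, phylum),
#'   `meta` (per-sample covariates: individual, household, city, age,
#'   gender, plate).
#' @export
simulate_composition <- function(ped, kinship = NULL,
                                 config = effect_config(), seed = NULL) {
  stopifnot(inherits(config, "effect_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  J <- config$n_phylotypes
  base <- default_taxonomy(J)
  mu <- base$mu

  hh <- ped$household
  hh[is.na(hh)] <- paste0("solo_", ped$id[is.na(hh)])
  city <- ped$city
  age <- ped$age - mean(ped$age)
  plate <- sprintf("plate%d", 1 + (seq_len(n) - 1L) %% config$n_plates)

  eta <- matrix(mu, n, J, byrow = TRUE,
                dimnames = list(ped$id, base$taxonomy$phylotype))
  add_factor <- function(eta, f, sigma) {
    if (sigma <= 0) return(eta)
    lev <- unique(f)
    eff <- matrix(stats::rnorm(length(lev) * J, 0, sigma), length(lev), J,
                  dimnames = list(lev, NULL))
    eta + eff[f, , drop = FALSE]
  }
  eta <- add_factor(eta, hh, config$sigma_household)
  if (config$sigma_spouse > 0) {
    # cohabiting spouse pairs share an extra effect beyond the household
    # one: direct frequent contact homogenizes their communities most
    cp <- spouse_pairs(ped)
    cp <- cp[cp$partner1 %in% ped$id & cp$partner2 %in% ped$id, ,
             drop = FALSE]
    hh_of <- stats::setNames(hh, ped$id)
    cp <- cp[!is.na(hh_of[cp$partner1]) &
               hh_of[cp$partner1] == hh_of[cp$partner2], , drop = FALSE]
    if (nrow(cp) > 0) {
      eff <- matrix(stats::rnorm(nrow(cp) * J, 0, config$sigma_spouse),
                    nrow(cp), J)
      i1 <- match(cp$partner1, ped$id)
      i2 <- match(cp$partner2, ped$id)
      eta[i1, ] <- eta[i1, ] + eff
      eta[i2, ] <- eta[i2, ] + eff
    }
  }
  eta <- add_factor(eta, city, config$sigma_city)
  eta <- add_factor(eta, plate, config$sigma_plate)
  eta <- add_factor(eta, ped$sex, config$sigma_gender)
  if (config$beta_age > 0) {
    beta <- stats::rnorm(J, 0, config$beta_age)
    eta <- eta + outer(age, beta)
  }
  if (config$sigma_genetic > 0) {
    if (is.null(kinship)) stop("kinship required when sigma_genetic > 0")
    miss <- setdiff(ped$id, rownames(kinship))
    if (length(miss) > 0)
      stop("kinship is missing individuals: ", paste(miss, collapse = ", "))
    A <- 2 * kinship[ped$id, ped$id]
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    M <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
    eta <- eta + config$sigma_genetic * (M %*%
             matrix(stats::rnorm(n * J), n, J))
  }
  if (config$sigma_residual > 0)
    eta <- eta + matrix(stats::rnorm(n * J, 0, config$sigma_residual), n, J)

  # softmax rows -> relative abundances
  pmat <- exp(eta - apply(eta, 1, max))
  pmat <- pmat / rowSums(pmat)

  depth <- switch(config$depth_law$type,
    lognormal = pmax(1L, as.integer(round(stats::rlnorm(
      n, config$depth_law$meanlog, config$depth_law$sdlog)))),
    fixed = rep(as.integer(config$depth_law$depth), n),
    stop("unknown depth_law type"))

  counts <- matrix(0L, n, J, dimnames = dimnames(eta))
  theta <- config$overdispersion_theta
  for (i in seq_len(n)) {
    pr <- if (is.finite(theta)) {
      g <- stats::rgamma(J, shape = theta * pmat[i, ])
      if (sum(g) == 0) pmat[i, ] else g / sum(g)
    } else pmat[i, ]
    counts[i, ] <- stats::rmultinom(1, depth[i], pr)[, 1]
  }

  meta <- data.frame(sample = ped$id, individual = ped$id,
                     household = hh, city = city, age = ped$age,
                     gender = ped$sex, plate = plate,
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, taxonomy = base$taxonomy, meta = meta),
            class = "phylotype_table")
}

#' @export
print.phylotype_table <- function(x, ...) {
  cat(sprintf(
    "Phylotype table: %d samples x %d phylotypes (%d genera); depth %d-%d\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$taxonomy$genus)),
    min(rowSums(x$counts)), max(rowSums(x$counts))))
  invisible(x)
}

#' Construct a phylotype table from components
#'
#' @param counts samples x phylotypes integer matrix (dimnames required).
#' @param taxonomy data frame with columns phylotype, genus, phylum; a
#'   single "unclassified" genus is assumed when omitted.
#' @param meta optional per-sample covariate data frame (column `sample`).
#' @return a `phylotype_table`.
#' @export
phylotype_table <- function(counts, taxonomy = NULL, meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(taxonomy))
    taxonomy <- data.frame(phylotype = colnames(counts),
                           genus = "unclassified",
                           phylum = "unclassified",
                           stringsAsFactors = FALSE)
  miss <- setdiff(colnames(counts), taxonomy$phylotype)
  if (length(miss) > 0)
    stop("taxonomy missing phylotypes: ", paste(miss, collapse = ", "))
  structure(list(counts = counts, taxonomy = taxonomy, meta = meta),
            class = "phylotype_table")
}

#' Read / write phylotype count tables
#'
#' Count matrix: tab-delimited, rows = samples, columns = phylotypes.
#' Taxonomy: tab-delimited with columns phylotype, genus, phylum.
#'
#' @param file count-matrix path.
#' @param taxonomy_file taxonomy path (optional on read).
#' @return `read_phylotype_table()` returns a `phylotype_table`.
#' @export
read_phylotype_table <- function(file, taxonomy_file = NULL) {
  m <- as.matrix(utils::read.delim(file, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  tax <- if (!is.null(taxonomy_file))
    utils::read.delim(taxonomy_file, stringsAsFactors = FALSE) else NULL
  phylotype_table(m, tax)
}

#' @param table phylotype table to write.
#' @rdname read_phylotype_table
#' @export
write_phylotype_table <- function(table, file, taxonomy_file = NULL) {
  utils::write.table(data.frame(sample = rownames(table$counts),
                                table$counts, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_file))
    utils::write.table(table$taxonomy, taxonomy_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(file)
}
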