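#' Simulate a multigenerational family pedigree with households and cities
#'
#' Generates an extended family of the kind used in family microbiome
#' cohorts: a set of founder couples, each starting a household in a city,
#' whose descendants marry unrelated individuals, found new households
#' (usually in the same city), and have children of their own.  Children
#' live in their parents' household until they marry and move out; ages are
#' assigned per generation so that the youngest generation is mostly still
#' at home.
#'
#' @param n_generations total number of generations including the founders
#'   (>= 2; with \code{mean_children = 0} only founders are produced).
#' @param mean_children mean number of children per couple (Poisson).
#' @param n_cities number of cities households can be located in.
#' @param marry_age typical age (years) at which individuals marry and leave
#'   the parental household; used when assigning ages and move-out status.
#' @param n_founder_couples number of founding couples (branches of the
#'   family).
#' @param p_marry probability that an adult descendant marries (and so
#'   founds a new household with a married-in, unrelated spouse).
#' @param p_same_city probability a new household is founded in the parental
#'   city rather than a uniformly chosen other city.
#' @param seed integer seed; the same seed reproduces the pedigree exactly.
#'
#' @return A data frame of class \code{"fam_pedigree"} with one row per
#'   individual and columns \code{id}, \code{father}, \code{mother}
#'   (\code{NA} for founders), \code{sex} ("female"/"male"),
#'   \code{age} (years), \code{household} (current household id, may be
#'   \code{NA}), \code{city}, \code{moved_out} (logical, \code{NA} =
#'   unknown), \code{childhood_household} (parental household id, \code{NA}
#'   for founders), and \code{generation} (0 for founders).  Couples
#'   (including childless ones) are recorded in \code{attr(x, "couples")}.
#' @export
sim_pedigree <- function(n_generations = 3, mean_children = 3, n_cities = 4,
                         marry_age = 21, n_founder_couples = 3,
                         p_marry = 0.8, p_same_city = 0.7, seed = NULL) {
  if (n_generations < 2) stop("n_generations must be >= 2")
  if (n_cities < 1) stop("n_cities must be >= 1")
  if (mean_children < 0) stop("mean_children must be >= 0")
  if (n_founder_couples < 1) stop("n_founder_couples must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  couples <- list()
  next_id <- 1L
  next_hh <- 1L
  new_id <- function() {
    id <- sprintf("I%03d", next_id)
    next_id <<- next_id + 1L
    id
  }
  cities <- sprintf("city%d", seq_len(n_cities))

  # age model: generation g (0 = founders) is centred gen_gap years older
  # than generation g + 1; the last generation are children
  gen_gap <- marry_age + 6
  base_age <- function(gen) {
    # capped so deep pedigrees keep realistic lifespans
    centre <- min(10 + gen_gap * (n_generations - 1 - gen), 88)
    max(0L, as.integer(round(centre + stats::runif(1, -4, 6))))
  }

  add_person <- function(id, father, mother, sex, age, household, city,
                         moved_out, childhood_household, generation) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex, age = age,
      household = household, city = city, moved_out = moved_out,
      childhood_household = childhood_household, generation = generation,
      stringsAsFactors = FALSE
    )
  }

  # queue of couples still to reproduce: list(f = id, m = id, hh, city, gen)
  queue <- list()
  for (b in seq_len(n_founder_couples)) {
    hh <- sprintf("H%03d", next_hh); next_hh <- next_hh + 1L
    city <- cities[((b - 1L) %% n_cities) + 1L]
    fa <- new_id(); mo <- new_id()
    age <- base_age(0L)
    add_person(fa, NA_character_, NA_character_, "male", age, hh, city,
               TRUE, NA_character_, 0L)
    add_person(mo, NA_character_, NA_character_, "female",
               max(0L, age + sample(-3:3, 1)), hh, city, TRUE,
               NA_character_, 0L)
    couples[[length(couples) + 1L]] <- data.frame(
      partner1 = fa, partner2 = mo, household = hh, stringsAsFactors = FALSE)
    queue[[length(queue) + 1L]] <- list(f = fa, m = mo, hh = hh,
                                        city = city, gen = 0L)
  }

  while (length(queue) > 0L) {
    cpl <- queue[[1L]]; queue <- queue[-1L]
    if (cpl$gen + 1L > n_generations - 1L) next
    n_kids <- stats::rpois(1L, mean_children)
    if (n_kids == 0L) next
    child_gen <- cpl$gen + 1L
    last_gen <- child_gen == n_generations - 1L
    for (k in seq_len(n_kids)) {
      kid <- new_id()
      sex <- sample(c("female", "male"), 1L)
      age <- base_age(child_gen)
      if (last_gen) {
        # youngest generation: children at home, a few young adults
        if (age <= 18L) {
          add_person(kid, cpl$f, cpl$m, sex, age, cpl$hh, cpl$city,
                     FALSE, cpl$hh, child_gen)
        } else if (age >= 25L) {
          hh <- sprintf("H%03d", next_hh); next_hh <- next_hh + 1L
          add_person(kid, cpl$f, cpl$m, sex, age, hh, cpl$city,
                     TRUE, cpl$hh, child_gen)
        } else {
          # 19-24: move-out status genuinely unknown
          add_person(kid, cpl$f, cpl$m, sex, age, NA_character_,
                     cpl$city, NA, cpl$hh, child_gen)
        }
      } else {
        # adult generation: may marry a founder spouse and found a household
        if (stats::runif(1) < p_marry) {
          sp <- new_id()
          sp_sex <- if (sex == "female") "male" else "female"
          city <- if (stats::runif(1) < p_same_city || n_cities == 1L)
            cpl$city else sample(setdiff(cities, cpl$city), 1L)
          hh <- sprintf("H%03d", next_hh); next_hh <- next_hh + 1L
          add_person(kid, cpl$f, cpl$m, sex, age, hh, city, TRUE,
                     cpl$hh, child_gen)
          add_person(sp, NA_character_, NA_character_, sp_sex,
                     max(0L, age + sample(-3:3, 1)), hh, city, TRUE,
                     NA_character_, child_gen)
          couples[[length(couples) + 1L]] <- data.frame(
            partner1 = kid, partner2 = sp, household = hh,
            stringsAsFactors = FALSE)
          pair <- if (sex == "female") list(f = sp, m = kid)
                  else list(f = kid, m = sp)
          queue[[length(queue) + 1L]] <- list(f = pair$f, m = pair$m,
                                              hh = hh, city = city,
                                              gen = child_gen)
        } else {
          hh <- sprintf("H%03d", next_hh); next_hh <- next_hh + 1L
          add_person(kid, cpl$f, cpl$m, sex, age, hh, cpl$city, TRUE,
                     cpl$hh, child_gen)
        }
      }
    }
  }

  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  attr(ped, "couples") <- do.call(rbind, couples)
  class(ped) <- c("fam_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks the structural invariants of a pedigree table: unique ids, parents
#' either both present or both absent, parents defined before use, no
#' individual its own ancestor, nonnegative ages.
#'
#' @param ped a pedigree data frame (see [sim_pedigree()]).
#' @return the pedigree, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "father", "mother", "sex", "age")
  miss <- setdiff(req, names(ped))
  if (length(miss) > 0)
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  both <- is.na(ped$father) == is.na(ped$mother)
  if (!all(both))
    stop("individuals must have both parents or neither (founders)")
  nonf <- !is.na(ped$father)
  if (!all(ped$father[nonf] %in% ped$id) ||
      !all(ped$mother[nonf] %in% ped$id))
    stop("parent id not present in pedigree")
  if (any(ped$age < 0, na.rm = TRUE)) stop("ages must be nonnegative")
  # acyclicity via generation indexing (errors internally on a cycle)
  generation_index(ped)
  invisible(ped)
}

#' Generation index of each individual
#'
#' Founders get index 0; every non-founder gets 1 + the maximum of its
#' parents' indices.  Computed by an iterative topological pass, so a cyclic
#' "pedigree" is detected and rejected.
#'
#' @param ped a pedigree data frame.
#' @return named integer vector of generation indices.
#' @export
generation_index <- function(ped) {
  n <- nrow(ped)
  gi <- ifelse(is.na(ped$father), 0L, NA_integer_)
  names(gi) <- ped$id
  repeat {
    todo <- which(is.na(gi))
    if (length(todo) == 0L) break
    progressed <- FALSE
    for (i in todo) {
      gf <- gi[ped$father[i]]; gm <- gi[ped$mother[i]]
      if (!is.na(gf) && !is.na(gm)) {
        gi[i] <- 1L + max(gf, gm)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cycle detected in pedigree")
  }
  gi
}

#' Reorder a pedigree so parents precede children
#'
#' @param ped a pedigree data frame.
#' @return the pedigree sorted by generation index (stable within
#'   generation).
#' @export
topological_order <- function(ped) {
  gi <- generation_index(ped)
  out <- ped[order(gi[ped$id]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.fam_pedigree <- function(x, ...) {
  gi <- generation_index(x)
  cat(sprintf(
    "Family pedigree: %d individuals, %d founders, %d generations\n",
    nrow(x), sum(is.na(x$father)), max(gi) + 1L))
  cat(sprintf("  households: %d, cities: %d\n",
              length(unique(stats::na.omit(x$household))),
              length(unique(stats::na.omit(x$city)))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read / write pedigree tables
#'
#' Tab-delimited, one row per individual, header required; founder parents
#' written as "0".  Columns: id, father, mother, sex, age, household, city,
#' moved_out (true/false/unknown), childhood_household, generation.
#'
#' @param file path to a tab-delimited pedigree file.
#' @return `read_pedigree()` returns a `fam_pedigree` data frame.
#' @export
read_pedigree <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (col in c("father", "mother"))
    d[[col]][!is.na(d[[col]]) & d[[col]] == "0"] <- NA_character_
  if ("moved_out" %in% names(d) && is.character(d$moved_out)) {
    mo <- tolower(d$moved_out)
    d$moved_out <- ifelse(mo == "true", TRUE,
                          ifelse(mo == "false", FALSE, NA))
  }
  class(d) <- c("fam_pedigree", "data.frame")
  validate_pedigree(d)
  d
}

#' @param ped pedigree to write.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, file) {
  out <- as.data.frame(ped)
  for (col in c("father", "mother"))
    out[[col]][is.na(out[[col]])] <- "0"
  if ("moved_out" %in% names(out))
    out$moved_out <- ifelse(is.na(out$moved_out), "unknown",
                            ifelse(out$moved_out, "true", "false"))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Subset a pedigree to a set of individuals
#'
#' Keeps the rows for the given ids (e.g. the sampled members of a larger
#' family) along with the couples attribute restricted to couples whose
#' both partners remain.  Parent links pointing outside the subset are
#' kept as identifiers; the result is intended for covariate/sampling use,
#' not for kinship recursion.
#'
#' @param ped a pedigree data frame.
#' @param ids individual ids to keep.
#' @return subsetted pedigree data frame (class preserved).
#' @export
subset_pedigree <- function(ped, ids) {
  cp <- spouse_pairs(ped)
  out <- ped[ped$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "couples") <- cp[cp$partner1 %in% ids & cp$partner2 %in% ids, ,
                             drop = FALSE]
  class(out) <- c("fam_pedigree", "data.frame")
  out
}

#' Emulate household-based recruitment of a family cohort
#'
#' Family microbiome cohorts are typically recruited household-wise: whole
#' households volunteer together while most of the extended family
#' contributes at most one member.  This helper draws a sample of
#' individuals accordingly: both members of a number of two-person
#' (empty-nest spouse) households, a few members each from larger family
#' households, and single representatives of other households.  The
#' resulting cohabiting cohort is dominated by spouse pairs with a
#' minority of parent-child households, the structure family studies
#' report.
#'
#' @param ped a pedigree data frame.
#' @param n_pair_households number of two-person households sampled whole.
#' @param n_family_households number of larger (>= 4 member) households.
#' @param members_per_family how many members to sample from each family
#'   household.
#' @param n_singletons number of additional households contributing one
#'   member each.
#' @param seed integer seed.
#' @return character vector of sampled individual ids.
#' @export
recruit_samples <- function(ped, n_pair_households = 8,
                            n_family_households = 5,
                            members_per_family = 3,
                            n_singletons = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hh_tab <- table(ped$household)
  pair_hh <- names(hh_tab)[hh_tab == 2]
  fam_hh <- names(hh_tab)[hh_tab >= 4]
  if (length(pair_hh) < n_pair_households ||
      length(fam_hh) < n_family_households)
    stop("pedigree does not contain enough households of the ",
         "requested sizes")
  pick_pairs <- sample(pair_hh, n_pair_households)
  pick_fams <- sample(fam_hh, n_family_households)
  members <- ped$id[!is.na(ped$household) & ped$household %in% pick_pairs]
  for (h in pick_fams) {
    m <- ped$id[!is.na(ped$household) & ped$household == h]
    members <- c(members, sample(m, min(members_per_family, length(m))))
  }
  other_hh <- setdiff(names(hh_tab), c(pick_pairs, pick_fams))
  n_single <- min(n_singletons, length(other_hh))
  singles <- vapply(sample(other_hh, n_single), function(h) {
    m <- ped$id[!is.na(ped$household) & ped$household == h]
    m[sample.int(length(m), 1)]
  }, character(1))
  sort(unique(c(members, singles)))
}

#' Spouse pairs recorded in a pedigree
#'
#' Couples are taken from the pedigree's couples attribute when present
#' (this includes childless couples) and otherwise reconstructed as the
#' distinct (father, mother) pairs of the recorded children.
#'
#' @param ped a pedigree data frame.
#' @return data frame with columns partner1, partner2 (ids).
#' @export
spouse_pairs <- function(ped) {
  cp <- attr(ped, "couples")
  if (!is.null(cp)) return(cp[, c("partner1", "partner2")])
  kids <- ped[!is.na(ped$father), , drop = FALSE]
  u <- unique(kids[, c("father", "mother")])
  data.frame(partner1 = u$father, partner2 = u$mother,
             stringsAsFactors = FALSE)
}
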