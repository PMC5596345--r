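#' Infer household status from age
#'
#' In communities where individuals marry and leave the family home around
#' a known median age, household membership can be inferred when not
#' directly recorded: individuals aged `cohabit_max_age` or younger are
#' assumed to live with their parents, individuals aged `moved_min_age` or
#' older are assumed to have moved out, and those in between are left
#' unknown.  An explicit move-out flag, when present, overrides the
#' inference; missing age and missing flag give "unknown", never an error.
#'
#' @param age age in years (vector allowed).
#' @param moved_out explicit flag (TRUE/FALSE/NA), recycled.
#' @param cohabit_max_age oldest age assumed still living with parents.
#' @param moved_min_age youngest age assumed moved out.
#' @return character vector in \{"cohabiting_with_parents", "moved_out",
#'   "unknown"\}.
#' @export
infer_household_status <- function(age, moved_out = NA,
                                   cohabit_max_age = 18,
                                   moved_min_age = 25) {
  k <- max(length(age), length(moved_out))
  age <- rep_len(age, k)
  moved_out <- rep_len(moved_out, k)
  out <- rep("unknown", k)
  out[!is.na(moved_out) & moved_out] <- "moved_out"
  out[!is.na(moved_out) & !moved_out] <- "cohabiting_with_parents"
  idx <- is.na(moved_out) & !is.na(age)
  out[idx & age <= cohabit_max_age] <- "cohabiting_with_parents"
  out[idx & age >= moved_min_age] <- "moved_out"
  out
}

#' Assemble the nested analysis cohorts
#'
#' Builds the four nested sample selections of the family analysis:
#' \describe{
#'   \item{cohabiting_now}{individuals currently sharing a household with
#'     at least one other sampled individual (households of >= 2 sampled
#'     members; individuals of unknown status are excluded).}
#'   \item{ever_cohabited}{the above plus individuals who grew up in a
#'     household with at least one other sampled individual but have since
#'     moved out.}
#'   \item{cities}{individuals with a known city (not necessarily
#'     cohabiting).}
#'   \item{genetics}{individuals with genotype data available.}
#' }
#' Households enter the household analyses only with two or more sampled
#' members, so the household term never measures pure interindividual
#' variation.
#'
#' @param ped a pedigree data frame.
#' @param samples sample ids available (default: everyone in the
#'   pedigree).
#' @param genotyped ids with genotype data (default: all samples).
#' @return named list of `cohort_selection` lists (`name`, `sample_ids`,
#'   `rationale`), plus attributes `household_now` and `household_ever`
#'   (named vectors giving the household variable used for each cohort).
#' @export
select_cohorts <- function(ped, samples = ped$id, genotyped = samples) {
  ped <- as.data.frame(ped)
  ped <- ped[ped$id %in% samples, , drop = FALSE]
  status <- infer_household_status(ped$age, ped$moved_out)
  # explicit household always known for moved-out adults with own homes;
  # unknown-status individuals have no usable current household
  cur_hh <- ped$household
  cur_hh[status == "unknown" & is.na(cur_hh)] <- NA

  hh_sizes <- table(cur_hh)
  multi <- names(hh_sizes)[hh_sizes >= 2]
  cohab_now <- ped$id[!is.na(cur_hh) & cur_hh %in% multi]

  child_hh <- if ("childhood_household" %in% names(ped))
    ped$childhood_household else rep(NA_character_, nrow(ped))
  ever_hh <- ifelse(ped$id %in% cohab_now, cur_hh, child_hh)
  names(ever_hh) <- ped$id
  ever_sizes <- table(ever_hh)
  ever_multi <- names(ever_sizes)[ever_sizes >= 2]
  ever <- ped$id[!is.na(ever_hh) & ever_hh %in% ever_multi &
                   status != "unknown"]
  ever <- union(cohab_now, ever)

  cities <- ped$id[!is.na(ped$city)]
  gen <- intersect(ped$id, genotyped)

  sel <- list(
    cohabiting_now = list(
      name = "cohabiting_now", sample_ids = cohab_now,
      rationale = "currently sharing a household of >= 2 sampled members"),
    ever_cohabited = list(
      name = "ever_cohabited", sample_ids = ever,
      rationale = "shared a household of >= 2 sampled members now or while growing up"),
    cities = list(
      name = "cities", sample_ids = cities,
      rationale = "known city of residence"),
    genetics = list(
      name = "genetics", sample_ids = gen,
      rationale = "host genotype data available"))
  for (nm in names(sel)) class(sel[[nm]]) <- "cohort_selection"
  if (length(cohab_now) == 0)
    warning("cohabiting_now selection is empty (all households singletons)")
  hh_now <- stats::setNames(cur_hh, ped$id)
  attr(sel, "household_now") <- hh_now
  attr(sel, "household_ever") <- ever_hh
  sel
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d samples (%s)\n", x$name,
              length(x$sample_ids), x$rationale))
  invisible(x)
}
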