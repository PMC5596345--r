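#' Within- versus between-group dissimilarity t-test
#'
#' Partitions all unordered sample pairs into same-group (e.g. same
#' household) and different-group sets and compares the two sets of
#' dissimilarities with a two-sided t-test (Welch by default).  Pairwise
#' dissimilarities sharing a sample are not independent, so the p-value is
#' descriptive/exploratory; a caveat flag is always attached.
#'
#' @param distances distance matrix over samples.
#' @param grouping group label per sample: a named vector (names = sample
#'   ids) or a vector aligned with the distance labels.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return object of class `"dissim_ttest"`: means, SDs and pair counts of
#'   the two classes, the t statistic, two-sided p-value, and
#'   `caveat_nonindependence = TRUE`.
#' @export
group_dissimilarity_ttest <- function(distances, grouping,
                                      var_equal = FALSE) {
  D <- as.matrix(distances)
  g <- grouping
  if (!is.null(names(g)) && !is.null(rownames(D)))
    g <- g[rownames(D)]
  if (length(g) != nrow(D)) stop("grouping does not match distance matrix")
  same <- outer(g, g, "==")
  ut <- upper.tri(D)
  within <- D[ut & same]
  between <- D[ut & !same]
  if (length(within) < 2 || length(between) < 2)
    stop("need at least 2 pairs in each class")
  tt <- stats::t.test(within, between, var.equal = var_equal)
  structure(list(
    mean_within = mean(within), sd_within = stats::sd(within),
    n_within = length(within),
    mean_between = mean(between), sd_between = stats::sd(between),
    n_between = length(between),
    t = unname(tt$statistic), p_value = tt$p.value,
    welch = !var_equal, caveat_nonindependence = TRUE),
    class = "dissim_ttest")
}

#' @export
print.dissim_ttest <- function(x, ...) {
  cat(sprintf("Within-group:  %.3f +/- %.3f (%d pairs)\n",
              x$mean_within, x$sd_within, x$n_within))
  cat(sprintf("Between-group: %.3f +/- %.3f (%d pairs)\n",
              x$mean_between, x$sd_between, x$n_between))
  cat(sprintf("%s t = %.3f, two-sided p = %.4g\n",
              if (x$welch) "Welch" else "Pooled", x$t, x$p_value))
  cat("Note: pairwise dissimilarities are not independent;",
      "treat p as descriptive.\n")
  invisible(x)
}

#' Spousal subgenus composition contrast
#'
#' For each genus, computes the within-genus (subgenus) phylotype
#' composition, the Bray-Curtis dissimilarities among all retained samples
#' of the involved individuals, and the difference between the mean
#' spousal and mean non-spousal dissimilarity (negative = spouses more
#' similar).  Reports the per-genus difference with a two-sided Welch
#' t-test, and the mean and standard error of the differences across
#' genera with a one-sample t-test of the cross-genus mean against zero.
#' Samples with zero counts for a genus are excluded for that genus; a
#' spouse pair losing a member this way is dropped for that genus and
#' recorded.
#'
#' @param table a `phylotype_table`.
#' @param spouse_pairs data frame with columns `partner1`, `partner2`
#'   (sample ids); pairs must be disjoint.
#' @param genera genus names to analyse (default: [top_genera()] top 12).
#' @return object of class `"spouse_contrast"`: per-genus table (genus,
#'   mean_spousal, mean_nonspousal, difference, t, p, n_pairs_used,
#'   dropped_pairs), cross-genus `mean_difference`, `se_difference`,
#'   `t`, `p_value`.
#' @export
spouse_subgenus_contrast <- function(table, spouse_pairs, genera = NULL) {
  stopifnot(inherits(table, "phylotype_table"))
  if (is.null(genera)) genera <- top_genera(table, 12)
  ids <- unique(c(spouse_pairs$partner1, spouse_pairs$partner2))
  if (anyDuplicated(c(spouse_pairs$partner1, spouse_pairs$partner2)))
    stop("spouse pairs must be disjoint")
  missing_ids <- setdiff(ids, rownames(table$counts))
  if (length(missing_ids) > 0)
    stop("spouse pair member(s) not in the table: ",
         paste(missing_ids, collapse = ", "))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  spouse_keys <- key(spouse_pairs$partner1, spouse_pairs$partner2)

  rows <- lapply(genera, function(g) {
    comp <- subgenus_composition(table, g)
    keep <- intersect(ids, rownames(comp))
    dropped <- sum(!(spouse_pairs$partner1 %in% keep &
                       spouse_pairs$partner2 %in% keep))
    if (length(keep) < 3) {
      return(data.frame(genus = g, mean_spousal = NA_real_,
                        mean_nonspousal = NA_real_, difference = NA_real_,
                        t = NA_real_, p = NA_real_, n_pairs_used = 0L,
                        dropped_pairs = dropped, stringsAsFactors = FALSE))
    }
    D <- bray_curtis(comp[keep, , drop = FALSE])
    ut <- which(upper.tri(D), arr.ind = TRUE)
    pair_keys <- key(rownames(D)[ut[, 1]], rownames(D)[ut[, 2]])
    is_sp <- pair_keys %in% spouse_keys
    d <- D[upper.tri(D)]
    sp <- d[is_sp]; nonsp <- d[!is_sp]
    if (length(sp) < 1 || length(nonsp) < 2)
      return(data.frame(genus = g, mean_spousal = mean(sp),
                        mean_nonspousal = mean(nonsp),
                        difference = mean(sp) - mean(nonsp),
                        t = NA_real_, p = NA_real_,
                        n_pairs_used = length(sp),
                        dropped_pairs = dropped, stringsAsFactors = FALSE))
    tt <- if (length(sp) >= 2 && stats::var(c(sp, nonsp)) > 0)
      tryCatch(stats::t.test(sp, nonsp), error = function(e) NULL)
    else NULL
    data.frame(genus = g, mean_spousal = mean(sp),
               mean_nonspousal = mean(nonsp),
               difference = mean(sp) - mean(nonsp),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               n_pairs_used = length(sp), dropped_pairs = dropped,
               stringsAsFactors = FALSE)
  })
  per_genus <- do.call(rbind, rows)
  diffs <- per_genus$difference[!is.na(per_genus$difference)]
  ctt <- if (length(diffs) >= 2 && stats::sd(diffs) > 0)
    stats::t.test(diffs) else NULL
  structure(list(per_genus = per_genus,
                 mean_difference = mean(diffs),
                 se_difference = stats::sd(diffs) / sqrt(length(diffs)),
                 n_genera = length(diffs),
                 t = if (is.null(ctt)) NA_real_ else unname(ctt$statistic),
                 p_value = if (is.null(ctt)) NA_real_ else ctt$p.value),
            class = "spouse_contrast")
}

#' @export
print.spouse_contrast <- function(x, digits = 3, ...) {
  cat("Spousal vs non-spousal subgenus Bray-Curtis contrast\n")
  tab <- x$per_genus
  tab[, 2:6] <- lapply(tab[, 2:6], signif, digits)
  print(tab, row.names = FALSE, na.print = "")
  cat(sprintf(
    "Cross-genus mean difference (spousal - non-spousal): %.3f +/- %.3f (SE, %d genera); p = %.4g\n",
    x$mean_difference, x$se_difference, x$n_genera, x$p_value))
  invisible(x)
}
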