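#' Sequential permutational multivariate analysis of variance
#'
#' Distance-based ANOVA with sequential (Type-I) sums of squares and
#' permutation p-values, the workhorse for partitioning community variance
#' between ordered covariates (e.g. sequencing plate, gender, age, host
#' genetic MDS axes, city, household).  The distance matrix is
#' Gower-centred into an inner-product matrix G; each term's sum of squares
#' is tr((H_j - H_{j-1}) G) for the cumulative hat matrices of the ordered
#' design, so terms are assessed after everything listed before them and
#' the R-squared column (terms plus residual) sums to exactly 1.
#' Significance is assessed by permuting the sample labels of the distance
#' matrix with the design held fixed; permutations can be restricted to
#' shuffle only within levels of a stratifying covariate (e.g. households
#' tested within cities).
#'
#' For Euclidean distances on a univariate response the pseudo-F of a
#' single factor equals the classical ANOVA F statistic exactly.
#'
#' @param formula left-hand side evaluates to a distance matrix (a `dist`
#'   or a symmetric matrix); right-hand side lists the model terms in the
#'   order they should enter (e.g. `d ~ plate + gender + age + MDS1 + city +
#'   household`).
#' @param data data frame of covariates; rows are matched to the distance
#'   labels via a `sample` column or row names when present, otherwise
#'   taken in order.
#' @param permutations number of label permutations (default 9999), or
#'   `"exact"` to enumerate every permutation (small n; respects strata as
#'   the product of within-stratum permutation groups).
#' @param strata name of a column in `data` (or a vector) whose levels
#'   restrict permutations: labels are shuffled only within strata.
#' @param seed integer seed for the permutation stream.
#' @return object of class `"permanova"`: a list with `tab` (term, Df,
#'   SumOfSqs, R2, F, p), `call`, `n`, `permutations`, `strata`, `seed`,
#'   `term_labels`.  Methods: `print`, `summary`, `coef` (R-squared per
#'   term), `as.data.frame`, `plot`.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(40), 20, 2)
#' g <- rep(c("a", "b"), each = 10)
#' d <- as.matrix(dist(y))
#' fit <- permanova(d ~ g, data.frame(g = g), permutations = 199, seed = 1)
#' coef(fit)
#' @export
permanova <- function(formula, data, permutations = 9999, strata = NULL,
                      seed = NULL) {
  cl <- match.call()
  D <- eval(formula[[2]], data, environment(formula))
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("left-hand side must be a distance matrix")
  n <- nrow(D)
  labs <- rownames(D)
  data <- align_covariates(data, labs, n)
  term_labels <- attr(stats::terms(formula), "term.labels")
  if (length(term_labels) == 0) stop("model must contain at least one term")

  strata_vec <- resolve_strata(strata, data, n)

  G <- gower_center(D)
  ss_tot <- sum(diag(G))

  # cumulative hat matrices for the ordered design
  hats <- vector("list", length(term_labels))
  ranks <- integer(length(term_labels))
  for (j in seq_along(term_labels)) {
    f <- stats::reformulate(term_labels[seq_len(j)])
    X <- stats::model.matrix(f, data)
    qr_ <- qr(X)
    Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    ranks[j] <- qr_$rank
  }
  df <- diff(c(1L, ranks))
  if (any(df == 0))
    warning("rank-deficient term(s) with 0 df: ",
            paste(term_labels[df == 0], collapse = ", "))
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("no residual degrees of freedom")

  hdiff <- vector("list", length(term_labels))
  prev <- tcrossprod(rep(1 / sqrt(n), n))  # intercept-only hat matrix
  for (j in seq_along(hats)) {
    hdiff[[j]] <- hats[[j]] - prev
    prev <- hats[[j]]
  }
  H_full <- hats[[length(hats)]]

  ss <- vapply(hdiff, function(H) sum(H * G), numeric(1))
  ss_res <- ss_tot - sum(H_full * G)
  Fobs <- ifelse(df > 0, (ss / pmax(df, 1)) / (ss_res / df_res), NA_real_)

  perms <- build_permutations(n, permutations, strata_vec, seed)
  P <- ncol(perms)
  exact <- attr(perms, "exact")
  count <- numeric(length(term_labels))
  tol <- 1e-10
  for (p in seq_len(P)) {
    idx <- perms[, p]
    Gp <- G[idx, idx]
    ss_res_p <- ss_tot - sum(H_full * Gp)
    for (j in seq_along(hdiff)) {
      if (df[j] == 0) next
      Fp <- (sum(hdiff[[j]] * Gp) / df[j]) / (ss_res_p / df_res)
      if (Fp >= Fobs[j] - tol * max(1, abs(Fobs[j])))
        count[j] <- count[j] + 1
    }
  }
  pval <- if (exact) count / P else (1 + count) / (1 + P)
  pval[df == 0] <- NA_real_

  tab <- data.frame(
    term = c(term_labels, "Residuals", "Total"),
    Df = c(df, df_res, n - 1L),
    SumOfSqs = c(ss, ss_res, ss_tot),
    R2 = c(ss, ss_res, ss_tot) / ss_tot,
    F = c(Fobs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(tab = tab, call = cl, n = n,
                 permutations = if (exact) P else P,
                 exact = exact,
                 strata = if (is.null(strata_vec)) NULL else strata_vec,
                 strata_name = if (is.character(strata) &&
                                   length(strata) == 1) strata else NULL,
                 seed = seed, term_labels = term_labels),
            class = "permanova")
}

align_covariates <- function(data, labs, n) {
  data <- as.data.frame(data)
  if (!is.null(labs)) {
    if ("sample" %in% names(data) &&
        all(labs %in% data$sample)) {
      data <- data[match(labs, data$sample), , drop = FALSE]
    } else if (all(labs %in% rownames(data))) {
      data <- data[labs, , drop = FALSE]
    }
  }
  if (nrow(data) != n)
    stop("covariate table does not match the distance matrix")
  data
}

resolve_strata <- function(strata, data, n) {
  if (is.null(strata)) return(NULL)
  s <- if (is.character(strata) && length(strata) == 1) {
    if (!strata %in% names(data))
      stop("strata column '", strata, "' not found")
    data[[strata]]
  } else strata
  if (length(s) != n) stop("strata length must equal the number of samples")
  s <- as.factor(s)
  if (any(table(s) == 1))
    warning("singleton strata level(s): those labels are fixed under ",
            "permutation")
  s
}

#' Generate a permutation stream (optionally strata-restricted)
#'
#' @param n number of samples.
#' @param permutations integer count, or `"exact"` for exhaustive
#'   enumeration (product of within-stratum permutation groups when strata
#'   are given; capped at 500000).
#' @param strata optional factor restricting shuffles to within levels.
#' @param seed integer seed.
#' @return n x P integer matrix of permutation indices; attribute `exact`
#'   says whether the columns enumerate the full group (including the
#'   identity).
#' @export
build_permutations <- function(n, permutations, strata = NULL,
                               seed = NULL) {
  if (identical(permutations, "exact")) {
    perms <- if (is.null(strata)) all_perms(n) else strata_perms(strata)
    attr(perms, "exact") <- TRUE
    return(perms)
  }
  if (!is.null(seed)) set.seed(seed)
  P <- as.integer(permutations)
  out <- matrix(0L, n, P)
  if (is.null(strata)) {
    for (p in seq_len(P)) out[, p] <- sample.int(n)
  } else {
    idx_by <- split(seq_len(n), strata)
    for (p in seq_len(P)) {
      idx <- integer(n)
      for (g in idx_by) idx[g] <- if (length(g) > 1) g[sample.int(length(g))] else g
      out[, p] <- idx
    }
  }
  attr(out, "exact") <- FALSE
  out
}

all_perms <- function(n, cap = 500000L) {
  if (factorial(n) > cap) stop("too many permutations to enumerate")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1, cap)
  # insert n at every position of every permutation of 1..(n-1)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (cc in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[, k] <- append(sub[, cc], n, after = pos - 1L)
    }
  }
  out
}

strata_perms <- function(strata, cap = 500000L) {
  strata <- as.factor(strata)
  n <- length(strata)
  idx_by <- split(seq_len(n), strata)
  sizes <- lengths(idx_by)
  total <- prod(factorial(sizes))
  if (total > cap) stop("too many permutations to enumerate")
  grp_perms <- lapply(idx_by, function(g) {
    pg <- all_perms(length(g))
    matrix(g[pg], nrow = length(g))
  })
  out <- matrix(seq_len(n), n, total)
  # fill by cycling each group's permutations (mixed-radix enumeration)
  block <- total
  for (k in seq_along(grp_perms)) {
    pg <- grp_perms[[k]]
    m <- ncol(pg)
    block <- block / m
    sel <- rep(rep(seq_len(m), each = block), length.out = total)
    out[idx_by[[k]], ] <- pg[, sel]
  }
  out
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("Sequential permutational multivariate ANOVA\n")
  cat(sprintf("n = %d samples; %s permutations%s%s\n", x$n,
              if (x$exact) paste0("exact (", x$permutations, ")")
              else format(x$permutations),
              if (!is.null(x$strata)) ", stratified" else "",
              if (!is.null(x$strata_name))
                paste0(" by ", x$strata_name) else ""))
  tab <- x$tab
  tab$SumOfSqs <- signif(tab$SumOfSqs, digits)
  tab$R2 <- round(tab$R2, 3)
  tab$F <- signif(tab$F, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE, na.print = "")
  invisible(x)
}

#' @method summary permanova
#' @export
summary.permanova <- function(object, ...) {
  print(object)
  invisible(object$tab)
}

#' @method coef permanova
#' @export
coef.permanova <- function(object, ...) {
  k <- length(object$term_labels)
  stats::setNames(object$tab$R2[seq_len(k)], object$term_labels)
}

#' @method as.data.frame permanova
#' @export
as.data.frame.permanova <- function(x, ...) x$tab

#' @method plot permanova
#' @export
plot.permanova <- function(x, ...) {
  k <- length(x$term_labels) + 1L
  r2 <- x$tab$R2[seq_len(k)]
  names(r2) <- x$tab$term[seq_len(k)]
  p <- x$tab$p[seq_len(k)]
  graphics::barplot(r2, las = 2, ylab = expression(R^2),
                    col = ifelse(!is.na(p) & p <= 0.05, "firebrick",
                                 "grey70"), ...)
  invisible(x)
}

#' Write a fitted PERMANOVA table to a tab-delimited file
#'
#' @param fit a `permanova` object.
#' @param file path.
#' @export
write_permanova <- function(fit, file) {
  utils::write.table(fit$tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
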