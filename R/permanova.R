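# Feature standardisation and a from-scratch one-way PERMANOVA on
# Euclidean distances, used for every season contrast in the pipeline.

#' Standardise feature columns to zero mean and unit variance
#'
#' Each numeric column is centred on its mean and divided by its sample
#' standard deviation. Zero-variance columns are an error (named), since
#' they cannot be standardised.
#'
#' @param x A numeric matrix or a data.frame of numeric feature columns.
#' @return Object of the same type with every column at mean 0, sd 1.
#' @export
standardize_features <- function(x) {
  is_df <- is.data.frame(x)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("features must be numeric")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  sds <- apply(m, 2, stats::sd)
  if (any(!is.finite(sds) | sds == 0))
    stop("zero-variance feature column(s): ",
         paste(colnames(m)[!is.finite(sds) | sds == 0], collapse = ", "))
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (is_df) as.data.frame(out) else out
}

#' One-way PERMANOVA on Euclidean distances
#'
#' Permutational analysis of variance for a one-way design: with squared
#' Euclidean distances \eqn{d^2_{ij}},
#' \eqn{SS_{total} = \sum_{i<j} d^2_{ij} / N} and
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d^2_{ij} / n_g}; the
#' pseudo-F is \eqn{((SS_{total}-SS_{within})/(a-1)) / (SS_{within}/(N-a))}
#' and its p-value is obtained by unrestricted permutation of the group
#' labels, \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})}, so p
#' is never 0 and its resolution is \eqn{1/(n_{perm}+1)}. For a univariate
#' response this pseudo-F is algebraically identical to the classical
#' one-way ANOVA F.
#'
#' The default interface is a model formula, `response ~ group`, where the
#' response may be a single variable, a matrix, or `cbind(...)` of
#' features.
#'
#' @param x A formula (`y ~ group` / `cbind(a, b) ~ group`), or a numeric
#'   matrix/data.frame of features for the default method.
#' @param ... Passed between methods.
#' @return An object of class `"permanova"` with elements `pseudo_f`,
#'   `df_between`, `df_within`, `p_value`, `n_perm`, `seed`, `ss_total`,
#'   `ss_within`, `group_means`, `call`.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = c(rnorm(20), rnorm(20, 2)),
#'                 season = rep(c("a", "b"), each = 20))
#' permanova(y ~ season, data = d, n_perm = 199, seed = 9)
#' @export
permanova <- function(x, ...) UseMethod("permanova")

#' @rdname permanova
#' @param data Data.frame in which to evaluate the formula.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation stream (the caller's RNG
#'   state is preserved).
#' @param scale Standardise the feature columns first (see
#'   [standardize_features()])?
#' @export
permanova.formula <- function(x, data, n_perm = 999, seed = NULL,
                              scale = FALSE, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  g <- mf[[2L]]
  out <- permanova.default(as.matrix(y), g, n_perm = n_perm, seed = seed,
                           scale = scale)
  out$call <- match.call()
  out
}

#' @rdname permanova
#' @param group Group label per row (coerced to factor; at least 2 groups
#'   of at least 2 rows each).
#' @export
permanova.default <- function(x, group, n_perm = 999, seed = NULL,
                              scale = FALSE, ...) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("features must be numeric")
  if (anyNA(m)) stop("features contain missing values")
  g <- factor(group)
  if (length(g) != nrow(m)) stop("`group` length must match rows of `x`")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 rows")
  if (scale) m <- standardize_features(m)
  d2 <- as.matrix(stats::dist(m))^2
  n <- nrow(m)
  a <- nlevels(g)
  ss_total <- sum(d2) / (2 * n)
  ss_w <- function(gg) {
    s <- 0
    for (lev in levels(gg)) {
      idx <- which(gg == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_within <- ss_w(g)
  f_stat <- function(ssw)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- if (ss_within > 0) f_stat(ss_within) else Inf
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    ssw <- ss_w(factor(g[sample.int(n)], levels = levels(g)))
    if (ssw > 0) f_stat(ssw) else Inf
  }, numeric(1)))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  gm <- if (ncol(m) == 1L)
    tapply(m[, 1L], g, mean) else NULL
  structure(list(pseudo_f = f_obs, df_between = a - 1L, df_within = n - a,
                 p_value = p, n_perm = n_perm, seed = seed,
                 ss_total = ss_total, ss_within = ss_within,
                 group_means = gm, n = n, call = match.call()),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("One-way PERMANOVA (Euclidean distance, ", x$n_perm,
      " permutations)\n", sep = "")
  cat(sprintf("  pseudo-F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$pseudo_f, x$p_value))
  if (!is.null(x$group_means)) {
    cat("  group means: ",
        paste(sprintf("%s = %.3g", names(x$group_means), x$group_means),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.permanova <- function(object, ...) {
  ss_b <- object$ss_total - object$ss_within
  tab <- data.frame(
    df = c(object$df_between, object$df_within, object$df_between + object$df_within),
    SumOfSqs = c(ss_b, object$ss_within, object$ss_total),
    pseudo_F = c(object$pseudo_f, NA, NA),
    p = c(object$p_value, NA, NA),
    row.names = c("between", "within", "total"))
  structure(list(table = tab, n_perm = object$n_perm, call = object$call),
            class = "summary.permanova")
}

#' @export
print.summary.permanova <- function(x, ...) {
  cat("PERMANOVA table (", x$n_perm, " permutations)\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}
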