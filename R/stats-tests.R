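# Hypothesis tests linking shape scores to use-wear factors and size.
#
# Pillai's trace is the MANOVA statistic throughout: with k response
# variables, g groups and N specimens its F approximation uses
#   s  = min(k, g - 1)
#   m  = (|k - g + 1| - 1) / 2
#   nn = (N - g - k - 1) / 2
#   df1 = s (2m + s + 1),  df2 = s (2nn + s + 1)
#   F  = [(2nn + s + 1) / (2m + s + 1)] * V / (s - V)
# which is exactly what stats::summary.manova computes; the closed form is
# kept here as an independent cross-check. p-values are reported unadjusted
# (no multiple-testing correction is applied anywhere).

#' Closed-form Pillai trace degrees of freedom
#'
#' @param k number of response variables (PC scores used).
#' @param g number of groups.
#' @param N total number of specimens.
#' @return named vector `c(num = df1, den = df2)`.
#' @export
pillai_df <- function(k, g, N) {
  s <- min(k, g - 1)
  m <- (abs(k - g + 1) - 1) / 2
  nn <- (N - g - k - 1) / 2
  c(num = s * (2 * m + s + 1), den = s * (2 * nn + s + 1))
}

test_result <- function(name, statistic, df_factor, df_num, df_den,
                        F_value, p_value, k, group_sizes = NULL) {
  structure(list(name = name, statistic = unname(statistic),
                 df_factor = unname(df_factor), df_num = unname(df_num),
                 df_den = unname(df_den), F_value = unname(F_value),
                 p_value = unname(p_value), k = k,
                 group_sizes = group_sizes),
            class = "tool_test")
}

#' @export
print.tool_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, F = %.4f (Df = %s; num/denDf = %g/%g), p = %.4g [k = %d]\n",
              x$name, x$statistic, x$F_value,
              paste(x$df_factor, collapse = ","), x$df_num, x$df_den,
              x$p_value, x$k))
  if (!is.null(x$group_sizes))
    cat("  group sizes:", paste(sprintf("%s=%d", names(x$group_sizes),
                                        x$group_sizes), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tool_test <- function(x, ...) {
  data.frame(test = x$name, statistic = x$statistic, df_factor = x$df_factor,
             df_num = x$df_num, df_den = x$df_den, F_value = x$F_value,
             p_value = x$p_value, k = x$k,
             groups = if (is.null(x$group_sizes)) "" else
               paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                     collapse = ";"),
             stringsAsFactors = FALSE)
}

prepare_scores <- function(scores, k) {
  Y <- as.matrix(scores)
  if (is.null(k)) k <- ncol(Y)
  k <- as.integer(k)
  if (k < 1L || k > ncol(Y)) stop("'k' must be between 1 and ", ncol(Y))
  Y[, seq_len(k), drop = FALSE]
}

#' Pillai-trace MANOVA of shape scores against a factor
#'
#' Individual classes may be smaller than k (the paper-style exclusion rule
#' for under-sampled factors is applied at pipeline level, not here), but the
#' residual degrees of freedom `N - g` must be at least `k`.
#'
#' @param scores specimens x axes matrix of PC scores.
#' @param f factor (or vector coercible to one), one label per specimen.
#' @param k number of leading PCs to test (default: all columns).
#' @param name label for the result.
#' @return a `tool_test` result.
#' @export
manova_pillai <- function(scores, f, k = NULL, name = "MANOVA (Pillai)") {
  f <- droplevels(factor(f))
  g <- nlevels(f)
  if (g < 2L) stop("the factor must have at least 2 classes")
  Y <- prepare_scores(scores, k)
  k <- ncol(Y)
  N <- nrow(Y)
  if (length(f) != N) stop("'f' length must match the number of specimens")
  if (N - g < k)
    stop(sprintf("insufficient residual df: N - g = %d < k = %d", N - g, k))
  fit <- stats::manova(Y ~ f)
  st <- summary(fit, test = "Pillai")$stats
  test_result(name, statistic = st["f", "Pillai"], df_factor = g - 1L,
              df_num = st["f", "num Df"], df_den = st["f", "den Df"],
              F_value = st["f", "approx F"], p_value = st["f", "Pr(>F)"],
              k = k, group_sizes = c(table(f)))
}

#' Multivariate regression of shape scores on a size covariate
#'
#' Tests allometry: the k PC scores are regressed on a single size covariate
#' and the regression term is tested with Pillai's trace (df1 = k,
#' df2 = N - k - 1).
#'
#' @param scores specimens x axes matrix of PC scores.
#' @param size positive size values (centroid size in mm or volume in mm^3).
#' @param k number of leading PCs (default: all).
#' @param transform transform applied to `size` before the regression:
#'   `"log"` (for centroid size), `"cuberoot"` (for a volume) or
#'   `"identity"`.
#' @param name label for the result.
#' @return a `tool_test` result.
#' @export
size_shape_regression <- function(scores, size, k = NULL,
                                  transform = c("log", "cuberoot", "identity"),
                                  name = "shape ~ size (Pillai)") {
  transform <- match.arg(transform)
  size <- as.numeric(size)
  if (any(!is.finite(size))) stop("non-finite size values")
  if (transform != "identity" && any(size <= 0))
    stop("size values must be positive before the '", transform, "' transform")
  x <- switch(transform, log = log(size), cuberoot = size^(1 / 3), identity = size)
  if (stats::var(x) <= 0) stop("constant size vector")
  Y <- prepare_scores(scores, k)
  k <- ncol(Y)
  N <- nrow(Y)
  if (length(x) != N) stop("'size' length must match the number of specimens")
  if (N - 1L - k < 1L) stop("insufficient residual df for ", k, " variables")
  fit <- stats::manova(Y ~ x)
  st <- summary(fit, test = "Pillai")$stats
  test_result(paste0(name, " [", transform, "]"),
              statistic = st["x", "Pillai"], df_factor = 1L,
              df_num = st["x", "num Df"], df_den = st["x", "den Df"],
              F_value = st["x", "approx F"], p_value = st["x", "Pr(>F)"],
              k = k)
}

#' Correlation between centroid size and volume
#'
#' The headline statistic pairs centroid size (mm) with the cube root of the
#' volume (mm), the two size estimators on commensurate linear scales; the
#' log-size vs cube-root and log-size vs log-volume pairings are reported
#' alongside.
#'
#' @param cs centroid sizes (mm, positive).
#' @param vol volumes (mm^3, positive).
#' @return list with `r_squared`, `p_value` (Pearson, two-sided) and a
#'   `variants` data.frame with all three pairings.
#' @export
size_volume_correlation <- function(cs, vol) {
  cs <- as.numeric(cs); vol <- as.numeric(vol)
  if (length(cs) != length(vol)) stop("'cs' and 'vol' lengths differ")
  if (length(cs) < 3L) stop("at least 3 specimens are required")
  if (any(cs <= 0) || any(vol <= 0)) stop("sizes and volumes must be positive")
  if (stats::var(cs) <= 0 || stats::var(vol) <= 0) stop("zero variance input")
  pair <- function(x, y) {
    ct <- stats::cor.test(x, y, method = "pearson")
    c(r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
  }
  v1 <- pair(cs, vol^(1 / 3))
  v2 <- pair(log(cs), vol^(1 / 3))
  v3 <- pair(log(cs), log(vol))
  variants <- data.frame(
    pairing = c("cs~vol^(1/3)", "log(cs)~vol^(1/3)", "log(cs)~log(vol)"),
    r_squared = c(v1[1L], v2[1L], v3[1L]),
    p_value = c(v1[2L], v2[2L], v3[2L]))
  list(r_squared = unname(v1[1L]), p_value = unname(v1[2L]), variants = variants)
}

#' One-way ANOVA of size across factor classes
#'
#' @param size numeric size values.
#' @param f factor, one label per specimen.
#' @param name label for the result.
#' @return a `tool_test` result.
#' @export
size_by_factor_anova <- function(size, f, name = "size ~ factor (ANOVA)") {
  f <- droplevels(factor(f))
  if (nlevels(f) < 2L) stop("the factor must have at least 2 classes")
  if (any(table(f) < 2L)) stop("every class needs at least 2 members")
  size <- as.numeric(size)
  a <- stats::anova(stats::lm(size ~ f))
  test_result(name, statistic = a$`F value`[1L], df_factor = a$Df[1L],
              df_num = a$Df[1L], df_den = a$Df[2L],
              F_value = a$`F value`[1L], p_value = a$`Pr(>F)`[1L],
              k = 1L, group_sizes = c(table(f)))
}

# ---- discriminant analysis ---------------------------------------------------

#' Linear discriminant analysis of shape scores
#'
#' Fisher/canonical variates over the first k PCs (pooled within-group
#' covariance, priors proportional to class sizes, via [MASS::lda()]).
#' The number of axes is `min(k, g - 1)`.
#'
#' @param scores specimens x axes matrix of PC scores.
#' @param f factor, one label per specimen.
#' @param k number of leading PCs (default: all).
#' @return object of class `"discriminant_space"`: `loadings` (k x axes,
#'   over the PCs), `df_scores` (specimens x axes), `group_means` (in DF
#'   space), the underlying `lda` fit and the factor.
#' @export
lda_fit <- function(scores, f, k = NULL) {
  f <- droplevels(factor(f))
  if (nlevels(f) < 2L) stop("the factor must have at least 2 classes")
  Y <- prepare_scores(scores, k)
  k <- ncol(Y)
  if (nrow(Y) - nlevels(f) < k)
    stop(sprintf("insufficient residual df: N - g = %d < k = %d; use fewer PCs",
                 nrow(Y) - nlevels(f), k))
  fit <- tryCatch(MASS::lda(Y, grouping = f),
                  error = function(e)
                    stop("within-group scatter is singular on these PCs; ",
                         "use fewer PCs (", conditionMessage(e), ")",
                         call. = FALSE))
  dfs <- stats::predict(fit)$x
  gm <- rowsum(dfs, f) / as.vector(table(f))
  structure(list(loadings = fit$scaling, df_scores = dfs, group_means = gm,
                 lda = fit, factor = f, k = k),
            class = "discriminant_space")
}

#' @export
print.discriminant_space <- function(x, ...) {
  cat(sprintf("discriminant space: %d axes over %d PCs, %d groups\n",
              ncol(x$loadings), x$k, nlevels(x$factor)))
  invisible(x)
}

#' Outline reconstructions at the extremes of a discriminant axis
#'
#' The DF loadings (a direction in PC-score space) are mapped back through
#' the PC eigenvectors into coefficient space, and outlines are reconstructed
#' at DF scores of +/- `sd_mult` standard deviations of the observed DF
#' scores (a zero-length direction returns the mean shape twice).
#' Back-projecting a reconstructed outline's coefficients recovers its DF
#' score exactly.
#'
#' @param d a [lda_fit()] result.
#' @param space the [pca_fit()] shape space the scores came from.
#' @param axis discriminant axis index.
#' @param sd_mult extremity in DF-score standard deviations (default 2).
#' @param n_points points per reconstructed outline.
#' @return list with elements `negative`, `positive` (outline matrices) and
#'   `df_scores` (the two scores used).
#' @export
df_extreme_shapes <- function(d, space, axis = 1L, sd_mult = 2, n_points = 196L) {
  stopifnot(inherits(d, "discriminant_space"), inherits(space, "shape_space"))
  axis <- as.integer(axis)
  if (axis < 1L || axis > ncol(d$loadings)) stop("'axis' out of range")
  w <- d$loadings[, axis]
  wn2 <- sum(w^2)
  E <- space$rotation[, seq_len(d$k), drop = FALSE]
  s <- sd_mult * stats::sd(d$df_scores[, axis])
  shape_at <- function(df_score) {
    if (wn2 == 0) return(mean_shape(space, n_points))
    pc_dev <- numeric(ncol(space$rotation))
    pc_dev[seq_len(d$k)] <- df_score * w / wn2
    reconstruct_coef(space, as.vector(space$rotation %*% pc_dev), n_points)
  }
  list(negative = shape_at(-s), positive = shape_at(s), df_scores = c(-s, s))
}
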