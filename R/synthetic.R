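# Synthetic assemblages of 3D triangular tool-like outlines with known shape
# parameters, factor labels with controllable shape-factor effect sizes,
# digitization noise and analytic volumes. Every pipeline stage and
# statistical property can be exercised against this generator without any
# museum data.

#' Shape parameters of a synthetic convergent tool outline
#'
#' The template is a rounded-corner triangle (apex = tip = L1 at the top,
#' base corners L2/L3, traversed clockwise) built at unit base width and then
#' scaled to millimetres:
#'
#' * `elongation`: height / base-width ratio.
#' * `asymmetry`: signed horizontal offset of the base (fraction of width);
#'   shears the proximal part left or right of the tip.
#' * `ventral_bow`: amplitude of the out-of-plane (z) bowing as a fraction of
#'   the scale; applied as `ventral_bow * scale * sin(pi * s)` with s the
#'   normalized arc position from L1.
#' * `tip_angle`: apex wedge angle in degrees (5-120).
#' * `corner_radius`: corner rounding as a fraction of adjacent edge length
#'   (0 to 0.3).
#' * `base_convexity`: signed bulge of the proximal edge (fraction of width;
#'   positive = convex).
#' * `scale`: base width in mm.
#'
#' @param elongation,asymmetry,ventral_bow,tip_angle,corner_radius,base_convexity,scale
#'   see Details.
#' @return object of class `"shape_params"`.
#' @export
shape_params <- function(elongation = 1.3, asymmetry = 0, ventral_bow = 0.05,
                         tip_angle = 45, corner_radius = 0.08,
                         base_convexity = 0, scale = 38) {
  p <- list(elongation = elongation, asymmetry = asymmetry,
            ventral_bow = ventral_bow, tip_angle = tip_angle,
            corner_radius = corner_radius, base_convexity = base_convexity,
            scale = scale)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  if (p$elongation <= 0) stop("parameter 'elongation' must be > 0")
  if (p$tip_angle <= 5 || p$tip_angle >= 120)
    stop("parameter 'tip_angle' must be in (5, 120) degrees")
  if (p$corner_radius < 0 || p$corner_radius >= 0.3)
    stop("parameter 'corner_radius' must be in [0, 0.3)")
  if (p$scale <= 0) stop("parameter 'scale' must be > 0")
  structure(p, class = "shape_params")
}

rot2 <- function(v, ang) {
  c(cos(ang) * v[1L] - sin(ang) * v[2L],
    sin(ang) * v[1L] + cos(ang) * v[2L])
}

# sample a quadratic Bezier (excluding the end point) as m points
qbezier <- function(p0, p1, p2, m, include_end = FALSE) {
  t <- if (include_end) seq(0, 1, length.out = m) else seq(0, 1 - 1 / m, length.out = m)
  cbind((1 - t)^2 %o% p0[1L] + 2 * t * (1 - t) %o% p1[1L] + t^2 %o% p2[1L],
        (1 - t)^2 %o% p0[2L] + 2 * t * (1 - t) %o% p1[2L] + t^2 %o% p2[2L])
}

seg <- function(p0, p1, m) {                    # half-open straight segment
  t <- seq(0, 1 - 1 / m, length.out = m)
  cbind(p0[1L] + t * (p1[1L] - p0[1L]), p0[2L] + t * (p1[2L] - p0[2L]))
}

# replace the neighbourhood of the polyline vertex at index i (arc clip length
# len on each side) by a quadratic Bezier with the vertex as control point
round_polyline_corner <- function(pts, i, len, m = 24L) {
  k <- nrow(pts)
  arc_at <- function(j0, dir) {                 # walk from vertex, return point at arc len
    acc <- 0; j <- j0
    repeat {
      jn <- ((j - 1L + dir) %% k) + 1L
      step <- sqrt(sum((pts[jn, ] - pts[j, ])^2))
      if (acc + step >= len) {
        f <- (len - acc) / step
        return(list(pt = pts[j, ] + f * (pts[jn, ] - pts[j, ]), last = j, nxt = jn))
      }
      acc <- acc + step; j <- jn
    }
  }
  fwd <- arc_at(i, +1L); bwd <- arc_at(i, -1L)
  bez <- qbezier(bwd$pt, pts[i, ], fwd$pt, m, include_end = TRUE)
  # indices strictly inside the replaced arc (assumes clip spans < k/3 points)
  inside <- integer(0L)
  j <- bwd$last
  while (j != fwd$nxt) { inside <- c(inside, j); j <- (j %% k) + 1L }
  keep <- setdiff(seq_len(k), inside)
  # stitch: points before the corner, bezier, points after
  before <- keep[keep < i]; after <- keep[keep > i]
  out <- rbind(pts[before, , drop = FALSE], bez, pts[after, , drop = FALSE])
  list(pts = out, corner_index = length(before) + (m + 1L) %/% 2L)
}

#' Generate one synthetic convergent-tool outline
#'
#' Deterministic for a fixed `(p, seed)` pair: a rounded-corner triangle is
#' built in the x-y plane (apex up, clockwise traversal starting at the tip),
#' sheared by `asymmetry`, its proximal edge bowed by `base_convexity`, bowed
#' out of plane by `ventral_bow`, scaled to mm, perturbed by Gaussian
#' coordinate noise, and finally resampled to `n_points` equally spaced
#' pseudo-landmarks. The three anchors are taken at the curvature maxima of
#' the construction (the tip and the two rounded base corners); L1 is the
#' first contour point exactly.
#'
#' @param p a [shape_params()] object.
#' @param n_points pseudo-landmarks on the returned contour (default 196).
#' @param noise_sd Gaussian digitization noise SD in mm (per coordinate).
#' @param seed optional integer seed (set when `noise_sd > 0` for
#'   reproducibility).
#' @param id specimen identifier.
#' @return an [outline()] with attributes `params` and `area_mm2` (shoelace
#'   area of the noiseless planform, used for the analytic volume proxy).
#' @export
generate_outline <- function(p, n_points = 196L, noise_sd = 0, seed = NULL,
                             id = "synthetic") {
  stopifnot(inherits(p, "shape_params"))
  if (!is.null(seed)) set.seed(seed)
  h <- p$elongation
  A <- c(0, h)
  B <- c(0.5 + p$asymmetry, 0)
  C <- c(-0.5 + p$asymmetry, 0)
  th <- p$tip_angle * pi / 180
  u <- c(p$asymmetry, 0) - A; u <- u / sqrt(sum(u^2))   # apex -> base midpoint
  dR <- rot2(u, +th / 2)
  dL <- rot2(u, -th / 2)
  wd <- 0.18 * h                                  # wedge depth below the tip
  PR <- A + wd * dR
  PL <- A + wd * dL
  # clockwise: tip wedge right, blend to B, base B->C (with convexity bulge),
  # blend from C up to the left wedge, wedge back to the tip
  QR <- PR + dR * (0.45 * sqrt(sum((B - PR)^2)))
  QL <- PL + dL * (0.45 * sqrt(sum((C - PL)^2)))
  base <- seg(B, C, 64L)
  tb <- seq(0, 1 - 1 / 64, length.out = 64L)
  base[, 2L] <- base[, 2L] - p$base_convexity * sin(pi * tb)
  pts <- rbind(seg(A, PR, 16L), qbezier(PR, QR, B, 56L), base,
               qbezier(C, QL, PL, 56L), seg(PL, A, 16L))
  iA <- 1L
  iB <- 16L + 56L + 1L                            # first base point = corner B
  iC <- 16L + 56L + 64L + 1L                      # first left-blend point = corner C
  if (p$corner_radius > 0) {
    edge_len <- sqrt(sum((C - B)^2))
    clip <- p$corner_radius * edge_len
    rC <- round_polyline_corner(pts, iC, clip)    # later index first: keeps iB valid
    pts <- rC$pts; iC <- rC$corner_index
    nb <- nrow(pts)
    rB <- round_polyline_corner(pts, iB, clip)
    pts <- rB$pts; iB <- rB$corner_index
    iC <- iC + (nrow(pts) - nb)                   # C sits after the replaced B region
  }
  # out-of-plane bowing by arc position from the tip
  d <- sqrt(rowSums((rbind(pts[-1L, ], pts[1L, ]) - pts)^2))
  s <- c(0, cumsum(d))[seq_len(nrow(pts))] / sum(d)
  m3 <- cbind(pts, z = p$ventral_bow * sin(pi * s))
  m3 <- m3 * p$scale
  area <- abs(polygon_area_xy(m3))
  if (noise_sd > 0)
    m3 <- m3 + matrix(stats::rnorm(length(m3), sd = noise_sd), nrow(m3), 3L)
  anchors <- m3[c(iA, iB, iC), , drop = FALSE]
  contour <- arc_length_resample(m3, n_points)
  out <- outline(id, rbind(contour[1L, ], anchors[2:3, , drop = FALSE]), contour)
  attr(out, "params") <- p
  attr(out, "area_mm2") <- area
  out
}

# shoelace area of the x-y projection of a closed 3D polygon
polygon_area_xy <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

default_factor_specs <- function() {
  list(
    material = list(probs = c(SH = 0.60, H = 0.25, IND = 0.15), shifts = NULL),
    trace_side = list(probs = c(R = 0.30, L = 0.30, LR = 0.40),
                      shifts = list(R = c(asymmetry = +0.05),
                                    L = c(asymmetry = -0.05))),
    localization = list(probs = c("edges" = 0.45, "edges+point" = 0.55),
                        shifts = list("edges+point" = c(tip_angle = -7))),
    action = list(probs = c(T = 0.30, L = 0.40, P = 0.30),
                  shifts = list(T = c(corner_radius = +0.03),
                                P = c(tip_angle = -9, elongation = +0.12))))
}

#' Configuration of a synthetic assemblage
#'
#' Defaults emulate a level-sized assemblage of 37 convergent flint tools:
#' 37 specimens, triangular planforms around elongation 1.3 and tip angle 45
#' degrees, base widths around 38 mm (so centroid sizes span the range seen
#' on real flakes), digitization noise of 0.3 mm per coordinate, four
#' use-wear factors drawn by the configured class probabilities, and modest
#' additive parameter shifts per class as the ground-truth shape-factor
#' effects. Set `null_effects = TRUE` to zero every shift (shape independent
#' of all factors), the configuration used for type-I-error calibration.
#'
#' @param n_specimens number of tools (>= 2).
#' @param seed mandatory integer seed; all randomness flows from it
#'   (R's default Mersenne-Twister generator).
#' @param param_means,param_sds named lists overriding the per-parameter
#'   means / SDs of [shape_params()].
#' @param factors named list of factor specs (`probs`, optional `shifts` =
#'   named per-class additive shifts on shape parameters).
#' @param noise_sd digitization noise SD in mm.
#' @param n_points pseudo-landmarks per contour.
#' @param null_effects zero all class shifts?
#' @return object of class `"assemblage_config"`.
#' @export
assemblage_config <- function(n_specimens = 37L, seed, param_means = list(),
                              param_sds = list(), factors = default_factor_specs(),
                              noise_sd = 0.3, n_points = 196L,
                              null_effects = FALSE) {
  if (missing(seed)) stop("'seed' is mandatory")
  n_specimens <- as.integer(n_specimens)
  if (n_specimens < 2L) stop("'n_specimens' must be >= 2")
  means <- utils::modifyList(unclass(shape_params()), param_means)
  sds <- utils::modifyList(list(elongation = 0.22, asymmetry = 0.07,
                                ventral_bow = 0.03, tip_angle = 9,
                                corner_radius = 0.035, base_convexity = 0.04,
                                scale = 8), param_sds)
  for (f in names(factors)) {
    pr <- factors[[f]]$probs
    if (abs(sum(pr) - 1) > 1e-8) stop("class probabilities of '", f, "' must sum to 1")
    if (null_effects) factors[[f]]$shifts <- NULL
    for (cls in names(factors[[f]]$shifts)) {
      sh <- factors[[f]]$shifts[[cls]]
      trial <- means; for (nm in names(sh)) trial[[nm]] <- trial[[nm]] + sh[[nm]]
      ok <- tryCatch({ do.call(shape_params, trial); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok))
        stop("infeasible class shift for factor '", f, "', class '", cls, "': ", ok)
    }
  }
  structure(list(n_specimens = n_specimens, seed = as.integer(seed),
                 param_means = means, param_sds = sds, factors = factors,
                 noise_sd = noise_sd, n_points = as.integer(n_points)),
            class = "assemblage_config")
}

# parameter bounds used to clip random draws to the valid domain
param_bounds <- list(elongation = c(0.3, 4), asymmetry = c(-0.35, 0.35),
                     ventral_bow = c(-0.25, 0.25), tip_angle = c(6, 119),
                     corner_radius = c(0.005, 0.29),
                     base_convexity = c(-0.25, 0.25), scale = c(5, Inf))

#' Generate a synthetic assemblage
#'
#' Draws per-specimen shape parameters from the configured normal
#' distributions (clipped to the valid parameter domain), assigns factor
#' classes by the configured probabilities, applies the per-class parameter
#' shifts, generates each outline with [generate_outline()], and computes
#' sizes: the centroid size of the 3 + n_points configuration and the
#' analytic volume proxy `planform area x 0.15 scale`. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg an [assemblage_config()].
#' @return object of class `"assemblage"`: `outlines` (an `outline_set`),
#'   `factors` (a `factor_table`), `sizes` (a `size_table`) and `params`
#'   (data.frame of the true per-specimen shape parameters).
#' @export
generate_assemblage <- function(cfg) {
  stopifnot(inherits(cfg, "assemblage_config"))
  set.seed(cfg$seed)
  n <- cfg$n_specimens
  ids <- sprintf("SYN%03d", seq_len(n))
  pnames <- names(cfg$param_means)
  params <- sapply(pnames, function(nm)
    stats::rnorm(n, cfg$param_means[[nm]], cfg$param_sds[[nm]]))
  colnames(params) <- pnames
  fac <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (f in names(cfg$factors)) {
    spec <- cfg$factors[[f]]
    lev <- names(spec$probs)
    draw <- sample(lev, n, replace = TRUE, prob = spec$probs)
    fac[[f]] <- factor(draw, levels = factor_vocabulary[[f]] %||% lev)
    for (cls in names(spec$shifts)) {
      sh <- spec$shifts[[cls]]
      hit <- draw == cls
      for (nm in names(sh)) params[hit, nm] <- params[hit, nm] + sh[[nm]]
    }
  }
  for (nm in pnames)
    params[, nm] <- pmin(pmax(params[, nm], param_bounds[[nm]][1L]),
                         param_bounds[[nm]][2L])
  outs <- vector("list", n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- do.call(shape_params, as.list(params[i, ]))
    outs[[i]] <- generate_outline(p, n_points = cfg$n_points,
                                  noise_sd = cfg$noise_sd, id = ids[i])
    area[i] <- attr(outs[[i]], "area_mm2")
  }
  outlines <- outline_set(outs)
  cs <- vapply(outlines, function(o) centroid_size(full_config(o)), numeric(1L))
  sizes <- data.frame(id = ids, centroid_size_mm = unname(cs),
                      volume_mm3 = area * 0.15 * params[, "scale"],
                      stringsAsFactors = FALSE)
  class(sizes) <- c("size_table", "data.frame")
  class(fac) <- c("factor_table", "data.frame")
  structure(list(outlines = outlines, factors = fac, sizes = sizes,
                 params = data.frame(id = ids, params, stringsAsFactors = FALSE),
                 config = cfg),
            class = "assemblage")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("synthetic assemblage: %d specimens, seed %d\n",
              length(x$outlines), x$config$seed))
  invisible(x)
}

# resample -> anchor GPA -> tangent projection -> EFA -> PCA, the shared
# analysis core used by the calibration harness and the pipeline
shape_scores <- function(outlines, n_points = 196L, n_harmonics = 12L,
                         include_anchors = FALSE, scale_ref = "anchors",
                         efa_method = "trapezoid", tangent = TRUE,
                         drop_constants = TRUE) {
  res <- resample_outline(outlines, n = n_points)
  fit <- gpa_anchors(res, scale_ref = scale_ref)
  ali <- align_outlines(fit, res)
  if (tangent) ali <- tangent_project(ali)
  coef <- efa_matrix(ali, n_harmonics = n_harmonics,
                     include_anchors = include_anchors, method = efa_method)
  space <- pca_fit(coef, drop_constants = drop_constants)
  list(gpa = fit, aligned = ali, coef = coef, space = space)
}

#' Type-I error / power calibration of the shape MANOVA
#'
#' Repeatedly generates fresh assemblages from `cfg` (varying only the seed:
#' replicate r uses `cfg$seed + r`), runs the full shape pipeline
#' (resampling, anchor Procrustes, tangent projection, 12-harmonic EFA, PCA)
#' and the Pillai MANOVA of the first `k` PC scores against `factor_name`,
#' and returns the fraction of replicates rejecting at `alpha`. With a
#' null-effects configuration this measures the empirical type-I error of
#' the whole pipeline; with class shifts it measures power.
#'
#' @param cfg an [assemblage_config()].
#' @param reps number of replicates (>= 100).
#' @param alpha significance level.
#' @param k PCs entering the MANOVA.
#' @param factor_name which factor to test (default `"action"`).
#' @return rejection rate, with attribute `"p_values"`.
#' @export
manova_calibration <- function(cfg, reps = 2000L, alpha = 0.05, k = 9L,
                               factor_name = "action") {
  stopifnot(inherits(cfg, "assemblage_config"))
  reps <- as.integer(reps)
  if (reps < 100L) stop("'reps' must be at least 100")
  if (!(alpha >= 0 && alpha <= 1)) stop("'alpha' must be in [0, 1]")
  pv <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    a <- generate_assemblage(cfg_r)
    sc <- shape_scores(a$outlines, n_points = cfg$n_points)
    pv[r] <- manova_pillai(sc$space$scores, a$factors[[factor_name]], k = k)$p_value
  }
  rate <- mean(pv < alpha)
  attr(rate, "p_values") <- pv
  rate
}
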