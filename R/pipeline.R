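# End-to-end orchestration: ingest (or simulate) -> resample -> anchor
# Procrustes -> tangent projection -> 3D EFA -> PCA -> factor and size tests
# -> reconstructions -> report bundle on disk.

#' Pipeline configuration
#'
#' @param outlines an `outline_set`, a path to a coordinate table, or `NULL`
#'   when `synthetic` is given.
#' @param factors a `factor_table`, a path, or `NULL`.
#' @param sizes a `size_table`, a path, or `NULL` (centroid sizes are always
#'   recomputed from the coordinates; volumes come from this table or from
#'   the synthetic generator).
#' @param synthetic an [assemblage_config()] used when `outlines` is `NULL`.
#' @param out_dir output directory for the report bundle (`NULL` = do not
#'   write files).
#' @param n_points pseudo-landmarks per contour (default 196).
#' @param n_harmonics harmonics retained for the analysis (default 12), or
#'   `"auto"` to pick the smallest count whose cumulative power reaches
#'   `power_threshold` for every specimen.
#' @param power_threshold cumulative power threshold for `"auto"` (0.99).
#' @param pcs named integer vector: PCs entering the MANOVA/LDA of each
#'   factor (defaults: action 9, trace_side 5, localization 15, material 9).
#' @param k_allometry PCs entering the size-shape regressions (default 9).
#' @param include_anchors interleave L2/L3 into the Fourier input curve?
#' @param scale_ref Procrustes scale reference, see [gpa_anchors()].
#' @param efa_method forward estimator, see [efa_forward()].
#' @param tangent apply tangent-space projection (default TRUE)?
#' @param gpa_tol,gpa_max_iter Procrustes convergence controls.
#' @param sd_mult extremity (in SD) for reconstructed extreme shapes.
#' @param seed seed forwarded to the synthetic generator (overrides the
#'   seed inside `synthetic` when given).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outlines = NULL, factors = NULL, sizes = NULL,
                            synthetic = NULL, out_dir = NULL,
                            n_points = 196L, n_harmonics = 12L,
                            power_threshold = 0.99,
                            pcs = c(action = 9L, trace_side = 5L,
                                    localization = 15L, material = 9L),
                            k_allometry = 9L, include_anchors = FALSE,
                            scale_ref = c("anchors", "full"),
                            efa_method = c("trapezoid", "projection"),
                            tangent = TRUE, gpa_tol = 1e-10,
                            gpa_max_iter = 100L, sd_mult = 2, seed = NULL) {
  if (is.null(outlines) && is.null(synthetic))
    stop("provide either 'outlines' or a 'synthetic' assemblage configuration")
  cfg <- list(outlines = outlines, factors = factors, sizes = sizes,
              synthetic = synthetic, out_dir = out_dir,
              n_points = as.integer(n_points), n_harmonics = n_harmonics,
              power_threshold = power_threshold, pcs = pcs,
              k_allometry = as.integer(k_allometry),
              include_anchors = isTRUE(include_anchors),
              scale_ref = match.arg(scale_ref),
              efa_method = match.arg(efa_method), tangent = isTRUE(tangent),
              gpa_tol = gpa_tol, gpa_max_iter = as.integer(gpa_max_iter),
              sd_mult = sd_mult, seed = seed)
  structure(cfg, class = "pipeline_config")
}

ingest_inputs <- function(cfg, log) {
  if (!is.null(cfg$outlines)) {
    outlines <- if (inherits(cfg$outlines, "outline_set")) cfg$outlines
      else read_outline_table(cfg$outlines, layout = "generic_csv")
    factors <- if (is.null(cfg$factors)) NULL
      else if (inherits(cfg$factors, "data.frame")) cfg$factors
      else read_factor_table(cfg$factors, quiet = TRUE)
    sizes <- if (is.null(cfg$sizes)) NULL
      else if (inherits(cfg$sizes, "data.frame")) cfg$sizes
      else read_size_table(cfg$sizes)
  } else {
    syn <- cfg$synthetic
    if (!is.null(cfg$seed)) syn$seed <- as.integer(cfg$seed)
    log("synthetic assemblage: ", syn$n_specimens, " specimens, seed ", syn$seed)
    a <- generate_assemblage(syn)
    outlines <- a$outlines; factors <- a$factors; sizes <- a$sizes
  }
  if (!is.null(factors)) {
    ids <- names(outlines)
    extra <- setdiff(factors$id, ids)
    missing <- setdiff(ids, factors$id)
    if (length(extra))
      warning("factor table specimens absent from outlines: ",
              paste(extra, collapse = ", "))
    if (length(missing))
      warning("outlines without factor data: ", paste(missing, collapse = ", "))
    common <- intersect(ids, factors$id)
    if (length(common) == 0L) stop("no specimens shared between outlines and factor table")
    if (length(common) < length(ids)) {
      log("using the ", length(common), "-specimen intersection of outlines and factors")
      outlines <- outline_set(outlines[common])
      if (!is.null(sizes)) sizes <- sizes[match(common, sizes$id), , drop = FALSE]
    }
    factors <- factors[match(names(outlines), factors$id), , drop = FALSE]
  }
  if (!is.null(sizes)) sizes <- sizes[match(names(outlines), sizes$id), , drop = FALSE]
  list(outlines = outlines, factors = factors, sizes = sizes)
}

#' Run the full outline-shape analysis pipeline
#'
#' Stages: ingest (or simulate) the assemblage; resample every contour to
#' equally spaced pseudo-landmarks; generalized Procrustes fit on the three
#' anchors with propagation to the full configurations; tangent projection;
#' 3D elliptic Fourier analysis; PCA of the coefficients; Pillai MANOVA and
#' discriminant analysis per use-wear factor (factors with any class smaller
#' than the number of variables are excluded and logged); allometry tests
#' (shape ~ log centroid size and ~ cube-root volume), size-volume
#' correlation and size-by-factor ANOVAs; mean/extreme shape reconstructions.
#' Every stage is a pure function of the inputs plus the configuration, so a
#' re-run with the same config and seed is byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages (the run log is always kept in
#'   the returned bundle and written to `run_log.txt`).
#' @return a report bundle (list) with the aligned set, coefficient matrix,
#'   shape space, eigen table, test results, size summary, reconstructions,
#'   harmonic power attainment and the run log. Written to `cfg$out_dir`
#'   when set.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character(0L)
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  log("lithomorph ", as.character(utils::packageVersion("lithomorph")),
      " pipeline run")
  dat <- ingest_inputs(cfg, log)
  outlines <- dat$outlines
  n <- length(outlines)
  log("specimens: ", n, "; pseudo-landmarks: ", cfg$n_points)

  res <- resample_outline(outlines, n = cfg$n_points)
  fit <- gpa_anchors(res, tol = cfg$gpa_tol, max_iter = cfg$gpa_max_iter,
                     scale_ref = cfg$scale_ref)
  log("anchor Procrustes converged in ", fit$iterations,
      " iterations (scale reference: ", cfg$scale_ref, ")")
  ali <- align_outlines(fit, res)
  if (cfg$tangent) ali <- tangent_project(ali)

  # harmonic power accounting on the analysis-ready configurations
  max_h <- (cfg$n_points - 1L) %/% 2L
  full_coef <- efa_matrix(ali, n_harmonics = max_h,
                          include_anchors = cfg$include_anchors,
                          method = cfg$efa_method)
  powers <- lapply(seq_len(n), function(i)
    harmonic_power(efa_from_vector(full_coef[i, ])))
  n_harm <- if (identical(cfg$n_harmonics, "auto"))
    choose_harmonics(powers, cfg$power_threshold, quiet = TRUE)
  else as.integer(cfg$n_harmonics)
  cum12 <- vapply(powers, function(p) p$cumulative_fraction[n_harm], numeric(1L))
  log(sprintf("harmonics retained: %d (cumulative power %.4f..%.4f across specimens)",
              n_harm, min(cum12), max(cum12)))
  keep_cols <- seq_len(3L + 6L * n_harm)
  coef <- full_coef[, keep_cols, drop = FALSE]

  space <- pca_fit(coef, drop_constants = TRUE)
  eig <- eigen_table(space, n_axes = min(15L, length(space$eigenvalues)))
  log(sprintf("PCA: first 3 axes explain %.2f%% of coefficient variance",
              space$cumulative_pct[min(3L, length(space$cumulative_pct))]))

  cs <- vapply(outlines, function(o) centroid_size(full_config(o)), numeric(1L))
  cs_table <- data.frame(id = names(outlines), centroid_size_mm = unname(cs))

  tests <- list()
  ldas <- list()
  recon <- list(mean = mean_shape(space, cfg$n_points))
  for (ax in 1:min(3L, ncol(space$rotation))) {
    sdv <- cfg$sd_mult * sqrt(space$eigenvalues[ax])
    recon[[paste0("PC", ax, "_neg")]] <- reconstruct_at(space, ax, -sdv, cfg$n_points)
    recon[[paste0("PC", ax, "_pos")]] <- reconstruct_at(space, ax, +sdv, cfg$n_points)
  }

  if (!is.null(dat$factors)) {
    for (f in intersect(names(cfg$pcs), names(dat$factors))) {
      fv <- droplevels(factor(dat$factors[[f]]))
      k <- min(cfg$pcs[[f]], ncol(space$scores))
      counts <- table(fv)
      if (nlevels(fv) < 2L) {
        log("factor ", f, ": fewer than 2 observed classes, skipped")
        next
      }
      if (any(counts < k)) {
        log(sprintf("factor %s excluded: class sizes (%s) below the %d variables",
                    f, paste(sprintf("%s=%d", names(counts), counts),
                             collapse = " "), k))
        next
      }
      tst <- manova_pillai(space$scores, fv, k = k,
                           name = paste0("shape ~ ", f, " (Pillai)"))
      log(sprintf("MANOVA %s: F = %.4f, num/denDf = %g/%g, p = %.4f [k = %d]",
                  f, tst$F_value, tst$df_num, tst$df_den, tst$p_value, k))
      tests[[paste0("manova_", f)]] <- tst
      ld <- lda_fit(space$scores, fv, k = k)
      ldas[[f]] <- ld
      ext <- df_extreme_shapes(ld, space, axis = 1L, sd_mult = cfg$sd_mult,
                               n_points = cfg$n_points)
      recon[[paste0("DF1_", f, "_neg")]] <- ext$negative
      recon[[paste0("DF1_", f, "_pos")]] <- ext$positive
    }
  }

  k_allo <- min(cfg$k_allometry, ncol(space$scores), n - 2L)
  tests$allometry_logcs <- size_shape_regression(
    space$scores, cs, k = k_allo, transform = "log",
    name = "shape ~ centroid size (Pillai)")
  size_summary <- NULL
  if (!is.null(dat$sizes) && all(is.finite(dat$sizes$volume_mm3))) {
    vol <- dat$sizes$volume_mm3
    tests$allometry_volume <- size_shape_regression(
      space$scores, vol, k = k_allo, transform = "cuberoot",
      name = "shape ~ volume (Pillai)")
    corr <- size_volume_correlation(cs, vol)
    log(sprintf("size-volume correlation: r^2 = %.4f (p = %.3g)",
                corr$r_squared, corr$p_value))
    if (!is.null(dat$factors))
      for (f in intersect(names(cfg$pcs), names(dat$factors))) {
        fv <- droplevels(factor(dat$factors[[f]]))
        if (nlevels(fv) >= 2L && all(table(fv) >= 2L))
          tests[[paste0("size_anova_", f)]] <-
            size_by_factor_anova(cs, fv, name = paste0("size ~ ", f, " (ANOVA)"))
      }
    size_summary <- data.frame(
      quantity = c("centroid_size_mm", "volume_mm3"),
      n = n,
      mean = c(mean(cs), mean(vol)),
      sd = c(stats::sd(cs), stats::sd(vol)),
      min = c(min(cs), min(vol)),
      max = c(max(cs), max(vol)))
    size_summary$size_volume_r2 <- corr$r_squared
  } else {
    size_summary <- data.frame(
      quantity = "centroid_size_mm", n = n, mean = mean(cs),
      sd = stats::sd(cs), min = min(cs), max = max(cs),
      size_volume_r2 = NA_real_)
    corr <- NULL
  }
  log(sprintf("mean centroid size: %.2f mm", mean(cs)))

  power_table <- data.frame(
    id = names(outlines),
    cumulative_power = vapply(powers, function(p)
      p$cumulative_fraction[n_harm], numeric(1L)))

  bundle <- list(config = cfg, outlines = outlines, gpa = fit, aligned = ali,
                 coefficients = coef, space = space, eigen_table = eig,
                 scores = space$scores, tests = tests, ldas = ldas,
                 size_volume = corr, size_summary = size_summary,
                 centroid_sizes = cs_table, harmonic_power = power_table,
                 n_harmonics = n_harm, reconstructions = recon,
                 factors = dat$factors, sizes = dat$sizes, log = log_lines)
  class(bundle) <- "pipeline_bundle"

  if (!is.null(cfg$out_dir)) {
    tabs <- list(coefficients = coef, scores = space$scores,
                 eigen_table = eig, centroid_sizes = cs_table,
                 harmonic_power = power_table, size_summary = size_summary,
                 tests = do.call(rbind, lapply(tests, as.data.frame)))
    for (nm in names(recon)) {
      rc <- recon[[nm]]
      tabs[[paste0("reconstruction_", nm)]] <-
        data.frame(point = seq_len(nrow(rc)), rc)
    }
    if (!is.null(dat$factors)) tabs$factor_table <- as.data.frame(dat$factors)
    if (!is.null(dat$sizes)) tabs$size_table <- as.data.frame(dat$sizes)
    paths <- write_results(tabs, cfg$out_dir)
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
    bundle$paths <- c(paths, file.path(cfg$out_dir, "run_log.txt"))
    log("wrote ", length(bundle$paths), " files to ", cfg$out_dir)
  }
  invisible(bundle)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline bundle:", length(x$outlines), "specimens,",
      x$n_harmonics, "harmonics\n")
  k <- min(3L, length(x$space$pct_variance))
  cat("  ", paste(sprintf("PC%d %.2f%%", seq_len(k),
                          x$space$pct_variance[seq_len(k)]), collapse = ", "), "\n")
  for (t in x$tests) print(t)
  invisible(x)
}

#' Run the pipeline under the alternative under-specified configurations
#'
#' Two analysis choices are not fixed by the study design: whether the anchor
#' landmarks are interleaved into the Fourier input curve, and whether the
#' Procrustes scale reference is the anchor triangle or the full
#' configuration. This helper runs all four combinations on the same inputs
#' and tabulates the leading eigen percentages and test statistics so the
#' variants can be compared against published values.
#'
#' @param outlines,factors,sizes inputs as in [pipeline_config()].
#' @param out_dir optional directory; each variant writes to a subdirectory.
#' @param ... further arguments passed to [pipeline_config()].
#' @return list with `summary` (one row per variant) and `bundles`.
#' @export
compare_variants <- function(outlines, factors = NULL, sizes = NULL,
                             out_dir = NULL, ...) {
  grid <- expand.grid(include_anchors = c(FALSE, TRUE),
                      scale_ref = c("anchors", "full"),
                      stringsAsFactors = FALSE)
  bundles <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tag <- sprintf("anchors%s_scale-%s",
                   if (grid$include_anchors[i]) "-in" else "-out",
                   grid$scale_ref[i])
    cfg <- pipeline_config(
      outlines = outlines, factors = factors, sizes = sizes,
      out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, tag),
      include_anchors = grid$include_anchors[i],
      scale_ref = grid$scale_ref[i], ...)
    b <- run_pipeline(cfg, quiet = TRUE)
    bundles[[i]] <- b
    pct <- b$space$pct_variance
    rows[[i]] <- data.frame(
      variant = tag,
      include_anchors = grid$include_anchors[i],
      scale_ref = grid$scale_ref[i],
      pc1_pct = pct[1L], pc2_pct = pct[2L], pc3_pct = pct[3L],
      mean_cs = mean(b$centroid_sizes$centroid_size_mm),
      size_volume_r2 = if (is.null(b$size_volume)) NA_real_
        else b$size_volume$r_squared)
  }
  names(bundles) <- vapply(rows, `[[`, character(1L), "variant")
  list(summary = do.call(rbind, rows), bundles = bundles)
}
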