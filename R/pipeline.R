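#' Configuration of an end-to-end simulated experiment
#'
#' Collects every setting of a full pipeline run: phantom generation,
#' acquisition protocol, noise, masking and statistical analysis.
#' Either construct programmatically or load from YAML with
#' [load_run_config()].
#'
#' @param protocol A protocol preset name (`"exp1" ... "exp4"`) or an
#'   [asl_protocol()].
#' @param n_pairs Label/control pairs to simulate (overrides the
#'   preset's count).
#' @param shape Phantom voxel counts.
#' @param tissue A [tissue_config()].
#' @param kinetics A [kinetic_params()].
#' @param noise A [noise_config()].
#' @param masks A [mask_config()].
#' @param alpha Primary significance level (one-tailed).
#' @param curve_step Grid thinning for curve/histogram outputs: every
#'   `curve_step` pairs.  Time-to-significance always uses every pair.
#' @param bins Histogram bin count over \[-10, 50\].
#' @param seed Integer master seed for all randomness.
#' @param outdir Output directory.
#' @param make_plots Also write convenience PDF figures (all numbers
#'   live in the CSV/JSON outputs regardless).
#' @return A list of class `run_config`.
#' @export
run_config <- function(protocol = "exp3", n_pairs = 400L,
                       shape = c(32L, 32L, 8L),
                       tissue = tissue_config(),
                       kinetics = kinetic_params(),
                       noise = noise_config(),
                       masks = mask_config(),
                       alpha = 0.05, curve_step = 5L, bins = 60L,
                       seed = 1L, outdir = "aslpower_out",
                       make_plots = FALSE) {
  if (is.character(protocol)) protocol <- protocol_preset(protocol,
                                                          n_pairs)
  else {
    stopifnot(inherits(protocol, "asl_protocol"))
    protocol$n_pairs <- as.integer(n_pairs)
  }
  structure(list(protocol = protocol, shape = as.integer(shape),
                 tissue = tissue, kinetics = kinetics, noise = noise,
                 masks = masks, alpha = alpha,
                 curve_step = as.integer(curve_step),
                 bins = as.integer(bins), seed = as.integer(seed),
                 outdir = outdir, make_plots = isTRUE(make_plots)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()]; the nested `tissue`, `kinetics`, `noise` and
#' `masks` blocks override individual defaults of the corresponding
#' constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, block)
    if (is.null(block)) fn() else do.call(fn, block)
  run_config(
    protocol = if (is.null(y$protocol)) "exp3" else y$protocol,
    n_pairs = if (is.null(y$n_pairs)) 400L else y$n_pairs,
    shape = if (is.null(y$shape)) c(32L, 32L, 8L) else unlist(y$shape),
    tissue = build(tissue_config, y$tissue),
    kinetics = build(kinetic_params, y$kinetics),
    noise = build(noise_config, y$noise),
    masks = build(mask_config, y$masks),
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    curve_step = if (is.null(y$curve_step)) 5L else y$curve_step,
    bins = if (is.null(y$bins)) 60L else y$bins,
    seed = if (is.null(y$seed)) 1L else y$seed,
    outdir = if (is.null(y$outdir)) "aslpower_out" else y$outdir,
    make_plots = isTRUE(y$make_plots))
}

write_table <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a full simulated experiment end to end
#'
#' Executes simulate -> subtract -> mask -> significance -> response
#' models and writes all outputs under `config$outdir`: per-threshold
#' and per-sub-mask significant-fraction tables (CSV), a
#' time-to-significance map and non-responder mask (NIfTI), the four
#' masks (NIfTI), t-histogram and skewness tables (CSV), the response
#' and sqrt-law fits (JSON), and a provenance record (JSON) listing
#' every output with its MD5 hash.  Identical configuration and seed
#' give byte-identical CSV/JSON outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with the in-memory results and
#'   `files` (named paths of everything written).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  proto <- config$protocol
  np <- proto$n_pairs

  # 1. simulate
  tmap <- sample_tissue_map(config$shape, config$tissue, config$seed)
  sim <- simulate_series(tmap, proto, config$kinetics, config$noise,
                         seed = config$seed + 1L)
  diff <- split_and_subtract(sim$series)

  # 2. masks from the SIR volume
  ms <- build_masks(sim$sir, config$masks)
  for (nm in c("full_wm", "periventricular", "peripheral", "deep"))
    files[paste0("mask_", nm)] <- write_volume(
      ms[[nm]] * 1, file.path(outdir, paste0("mask_", nm, ".nii.gz")),
      tmap$voxel_size)

  # 3. t-curves: thinned grid for curves/histograms, full for TTS
  curve_grid <- unique(pmax(2L, seq(config$curve_step, np,
                                    by = config$curve_step)))
  curves <- t_curves(diff, curve_grid, mask = ms$full_wm)
  curves_full <- t_curves(diff, seq(2L, np), mask = ms$full_wm)

  # 4. significance curves: thresholds on the full WM mask
  thr_tab <- rbind(
    significant_fraction(curves, config$alpha, "none"),
    significant_fraction(curves, 0.01, "none"),
    significant_fraction(curves, config$alpha, "bonferroni"),
    significant_fraction(curves, 0.01, "bonferroni"))
  files["fractions_thresholds"] <- write_table(
    thr_tab, file.path(outdir, "fractions_thresholds.csv"))

  # 5. per-sub-mask curves (same partition as the written masks)
  wm_idx <- which(ms$full_wm)
  sub_tab <- do.call(rbind, lapply(
    c("full_wm", "periventricular", "peripheral", "deep"),
    function(nm) {
      rows <- match(which(ms[[nm]]), wm_idx)
      rows <- rows[!is.na(rows)]
      if (length(rows) == 0) return(NULL)
      sf <- significant_fraction(curves, config$alpha, "none",
                                 voxels = rows)
      sf$mask <- nm
      sf
    }))
  files["fractions_submasks"] <- write_table(
    sub_tab, file.path(outdir, "fractions_submasks.csv"))

  # 6. time-to-significance and non-responders on the full grid
  tts <- time_to_significance(curves_full, config$alpha, "none")
  tts_map <- map_to_volume(tts$nsa, curves_full$voxels, config$shape)
  files["tts_map"] <- write_volume(
    tts_map, file.path(outdir, "time_to_significance_nsa.nii.gz"),
    tmap$voxel_size)
  nonresp <- find_nonresponders(curves_full)
  nr_map <- map_to_volume(rep(1, length(nonresp)), nonresp,
                          config$shape, fill = 0)
  files["nonresponder_mask"] <- write_volume(
    nr_map, file.path(outdir, "nonresponder_mask.nii.gz"),
    tmap$voxel_size)

  # 7. histogram evolution and skewness
  hists <- t_histograms(curves, bins = config$bins)
  hist_tab <- data.frame(
    t_bin_center = rep(hists$mids, times = length(hists$nsa_grid)),
    nsa = rep(hists$nsa_grid, each = length(hists$mids)),
    density = as.vector(hists$group_mean))
  files["t_histograms"] <- write_table(
    hist_tab, file.path(outdir, "t_histograms.csv"))
  skew_tab <- data.frame(
    nsa = curves$nsa_grid,
    skewness = apply(curves$t, 2L, function(tv)
      skewness(tv[is.finite(tv)])))
  files["t_skewness"] <- write_table(
    skew_tab, file.path(outdir, "t_skewness.csv"))

  # 8. response-curve and sqrt-law fits on the full-WM curve
  frac <- significant_fraction(curves, config$alpha, "none")
  rfit <- fit_response_curve(frac$nsa, 100 * frac$fraction)
  mean_t <- apply(curves$t, 2L, function(tv) mean(tv[is.finite(tv)]))
  sfit <- fit_sqrt_law(curves$nsa_grid, mean_t)
  fit_json <- file.path(outdir, "fits.json")
  jsonlite::write_json(list(
    response = list(best = rfit$best, fits = lapply(rfit$fits, function(f)
      list(params = as.list(f$params), residual_error = f$residual_error,
           ci = if (is.null(f$ci)) NULL else apply(f$ci, 1, as.list),
           converged = f$converged))),
    sqrt_law = list(K = sfit$K, residual_error = sfit$residual_error,
                    ci = as.list(sfit$ci[1, ]))),
    fit_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["fits"] <- fit_json

  if (config$make_plots)
    files["figures"] <- plot_report(thr_tab, sub_tab, hists, frac, rfit,
                                    outdir)

  # 9. provenance
  prov <- file.path(outdir, "provenance.json")
  jsonlite::write_json(list(
    package = "aslpower",
    version = as.character(utils::packageVersion("aslpower")),
    seed = config$seed,
    protocol = unclass(config$protocol),
    settings = list(shape = config$shape,
                    tissue = unclass(config$tissue),
                    kinetics = unclass(config$kinetics),
                    noise = unclass(config$noise),
                    masks = unclass(config$masks),
                    alpha = config$alpha,
                    curve_step = config$curve_step,
                    bins = config$bins),
    mask_counts = list(full_wm = sum(ms$full_wm),
                       periventricular = sum(ms$periventricular),
                       peripheral = sum(ms$peripheral),
                       deep = sum(ms$deep)),
    outputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))) ,
    timestamp = NULL),
    prov, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["provenance"] <- prov

  structure(list(tissue_map = tmap, masks = ms, curves = curves,
                 thresholds = thr_tab, submasks = sub_tab, tts = tts,
                 nonresponders = nonresp, histograms = hists,
                 response_fit = rfit, sqrt_fit = sfit, files = files,
                 config = config),
            class = "run_report")
}

# Convenience figures; every number shown also lives in CSV/JSON.
plot_report <- function(thr_tab, sub_tab, hists, frac, rfit, outdir) {
  pdf_path <- file.path(outdir, "figures.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  # threshold comparison
  plot(NA, xlim = range(thr_tab$nsa), ylim = c(0, 1), xlab = "NSA",
       ylab = "fraction significant",
       main = "Significant WM fraction by threshold")
  keys <- unique(thr_tab[, c("alpha", "correction")])
  for (i in seq_len(nrow(keys))) {
    sub <- thr_tab[thr_tab$alpha == keys$alpha[i] &
                     thr_tab$correction == keys$correction[i], ]
    graphics::lines(sub$nsa, sub$fraction, col = i, lwd = 2)
  }
  graphics::legend("bottomright", legend = paste(keys$alpha,
                                                 keys$correction),
                   col = seq_len(nrow(keys)), lwd = 2, bty = "n")
  # sub-mask filling
  plot(NA, xlim = range(sub_tab$nsa), ylim = c(0, 1), xlab = "NSA",
       ylab = "fraction significant", main = "Sub-mask filling")
  masks <- unique(sub_tab$mask)
  for (i in seq_along(masks)) {
    sub <- sub_tab[sub_tab$mask == masks[i], ]
    graphics::lines(sub$nsa, sub$fraction, col = i, lwd = 2)
  }
  graphics::legend("bottomright", legend = masks, col =
                     seq_along(masks), lwd = 2, bty = "n")
  # histogram evolution (first/middle/last NSA)
  j <- unique(round(c(1, length(hists$nsa_grid) / 2,
                      length(hists$nsa_grid))))
  plot(NA, xlim = range(hists$mids), ylim = c(0, max(hists$group_mean)),
       xlab = "t-value", ylab = "density", main = "t-histogram evolution")
  for (k in seq_along(j))
    graphics::lines(hists$mids, hists$group_mean[, j[k]], col = k,
                    lwd = 2)
  graphics::legend("topright", legend = paste("NSA",
                                              hists$nsa_grid[j]),
                   col = seq_along(j), lwd = 2, bty = "n")
  # response fit
  plot(frac$nsa, 100 * frac$fraction, pch = 16, xlab = "NSA",
       ylab = "% significant", main = paste("Response fit:", rfit$best))
  bf <- rfit$fits[[rfit$best]]
  xs <- seq(min(frac$nsa), max(frac$nsa), length.out = 200)
  ys <- switch(rfit$best,
               exp_recovery = bf$params["a"] * (1 - exp(-bf$params["b"] *
                                                          xs)),
               logarithmic = bf$params["a"] * log(xs),
               fractional = bf$params["a"] * xs / (bf$params["b"] + xs))
  graphics::lines(xs, ys, col = 2, lwd = 2)
  pdf_path
}

#' @export
print.run_report <- function(x, ...) {
  cat("aslpower run:", sum(x$masks$full_wm), "WM voxels,",
      length(x$nonresponders), "non-responders\n")
  cat("best response model:", x$response_fit$best, "\n")
  cat("outputs in:", x$config$outdir, "\n")
  invisible(x)
}
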