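#' Run configuration for the two-corpus analysis
#'
#' @param corpus_a_dir,corpus_b_dir directories of PNG/TIFF images (corpus A
#'   is the "painting-like" corpus in the reports, B the "photo-like").
#' @param labels length-2 character labels for the two corpora.
#' @param planes character vector of plane names to analyze.
#' @param warm_quadrants named list: for each plane, the quadrant subset
#'   treated as the quadrant of interest. Defaults: Q1 (warm) in the
#'   isoluminant plane, Q1+Q4 (+L/M) in the L/M-vs-achromatic plane, and Q3
#'   (blue: S < 0, dark) in the S-vs-achromatic plane.
#' @param n_boot bootstrap resamples (>= 1).
#' @param level bootstrap band coverage.
#' @param sigma Gaussian smoothing sd (curve samples) for displayed curves.
#' @param seed integer seed for the bootstrap.
#' @param colorspace a [dkl_config()] or path to a config file.
#' @param output_dir directory for tables/plots/report; `NULL` keeps results
#'   in memory only.
#' @param local_diff_side resize target of the local-difference analysis.
#' @param write_plots write PNG figures (default TRUE when `output_dir` set).
#' @return list of class `run_config`.
#' @export
run_config <- function(corpus_a_dir, corpus_b_dir,
                       labels = c("corpus_a", "corpus_b"),
                       planes = c("lm_s", "lm_ach", "s_ach"),
                       warm_quadrants = list(lm_s = "Q1",
                                             lm_ach = c("Q1", "Q4"),
                                             s_ach = "Q3"),
                       n_boot = 1000L, level = 0.95, sigma = 10,
                       seed = 1L, colorspace = dkl_config(),
                       output_dir = NULL, local_diff_side = 256L,
                       write_plots = !is.null(output_dir)) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (is.character(colorspace)) colorspace <- read_dkl_config(colorspace)
  structure(list(corpus_a_dir = corpus_a_dir, corpus_b_dir = corpus_b_dir,
                 labels = labels, planes = planes,
                 warm_quadrants = warm_quadrants, n_boot = as.integer(n_boot),
                 level = level, sigma = sigma, seed = as.integer(seed),
                 colorspace = colorspace, output_dir = output_dir,
                 local_diff_side = as.integer(local_diff_side),
                 write_plots = write_plots),
            class = "run_config")
}

read_corpus <- function(dir, label) {
  files <- list_corpus_images(dir)
  if (length(files) == 0) stop("no readable images in ", dir)
  imgs <- list(); skipped <- character()
  for (f in files) {
    img <- tryCatch(read_image(f), error = function(e) {
      warning("skipping unreadable image ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) skipped <- c(skipped, basename(f)) else imgs[[basename(f)]] <- img
  }
  if (length(imgs) == 0) stop("no readable images in ", dir)
  list(images = imgs, skipped = skipped, label = label)
}

analyze_corpus_images <- function(images, cfg, planes, warm_quadrants,
                                  n_boot, level, sigma, seed, side) {
  dkls <- lapply(images, srgb_to_dkl, cfg = cfg)
  out <- list(n_images = length(images))
  for (pl in planes) {
    plane <- plane_pair(pl)
    hists <- lapply(dkls, compute_joint_histogram, plane = plane)
    quads <- quadrant_set(warm_quadrants[[pl]])
    rest <- quadrant_complement(quads)
    q_curves <- lapply(hists, contrast_curve, quads = quads)
    r_curves <- lapply(hists, contrast_curve, quads = rest)
    mh <- mean_histogram(hists)
    band_q <- bootstrap_band(q_curves, n_boot, level, seed)
    band_r <- bootstrap_band(r_curves, n_boot, level, seed + 1L)
    mean_q <- contrast_curve(mh, quads)
    mean_r <- contrast_curve(mh, rest)
    out[[pl]] <- list(
      plane = plane, quadrants = quads,
      mean_histogram = mh,
      hists = hists,
      curve_q = mean_q, curve_rest = mean_r,
      curve_q_smooth = smooth_curve(mean_q, sigma),
      curve_rest_smooth = smooth_curve(mean_r, sigma),
      band_q = smooth_curve(band_q, sigma),
      band_rest = smooth_curve(band_r, sigma),
      excess = warm_excess_statistic(hists, quads))
  }
  # local chromatic/achromatic differences (corpus-independent of plane loop)
  recs <- do.call(rbind, lapply(names(images), function(nm)
    image_local_diffs(images[[nm]], source_id = nm, side = side, cfg = cfg)))
  out$local_diffs <- recs
  out
}

#' Run the full two-corpus chromatic-contrast analysis
#'
#' Ingests both image directories, converts to DKL, builds per-image and mean
#' joint histograms per plane, derives quadrant contrast curves with
#' percentile-bootstrap bands, computes the warm-excess statistic per corpus
#' (and its blue-quadrant control in the S-vs-achromatic plane), runs the
#' CIELUV local-difference analysis with per-corpus correlations, and — if an
#' output directory is configured — writes CSV tables, PNG figures and a
#' machine-readable `report.json`. Deterministic under a fixed seed.
#'
#' @param cfg a [run_config()].
#' @return An `analysis_report` list; see `$summary` for the headline numbers.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  a <- read_corpus(cfg$corpus_a_dir, cfg$labels[1])
  b <- read_corpus(cfg$corpus_b_dir, cfg$labels[2])
  res <- list()
  seeds <- c(cfg$seed, cfg$seed + 1000L)
  for (i in 1:2) {
    co <- list(a, b)[[i]]
    res[[cfg$labels[i]]] <- analyze_corpus_images(
      co$images, cfg$colorspace, cfg$planes, cfg$warm_quadrants,
      cfg$n_boot, cfg$level, cfg$sigma, seeds[i], cfg$local_diff_side)
    res[[cfg$labels[i]]]$skipped <- co$skipped
    res[[cfg$labels[i]]]$local_diffs$group <- cfg$labels[i]
  }
  summary <- list()
  for (pl in cfg$planes) {
    ea <- res[[cfg$labels[1]]][[pl]]$excess
    eb <- res[[cfg$labels[2]]][[pl]]$excess
    key <- if (pl == "s_ach") "blue_control" else paste0("excess_", pl)
    summary[[key]] <- list(corpus_a = ea, corpus_b = eb, difference = ea - eb)
  }
  recs <- rbind(res[[cfg$labels[1]]]$local_diffs, res[[cfg$labels[2]]]$local_diffs)
  correlations <- do.call(rbind, lapply(cfg$labels, function(g)
    correlate_diffs(recs, group = g)))
  report <- structure(list(
    config = cfg, corpora = res, local_diff_records = recs,
    correlations = correlations, summary = summary,
    n_skipped = c(length(res[[cfg$labels[1]]]$skipped),
                  length(res[[cfg$labels[2]]]$skipped))),
    class = "analysis_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Two-corpus DKL chromatic-contrast analysis\n")
  cat(sprintf("  %s: %d images   %s: %d images\n",
              x$config$labels[1], x$corpora[[1]]$n_images,
              x$config$labels[2], x$corpora[[2]]$n_images))
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-16s A=%+.4f  B=%+.4f  diff=%+.4f\n",
                nm, s$corpus_a, s$corpus_b, s$difference))
  }
  cat("  local-difference correlations:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  for (lab in cfg$labels) {
    co <- report$corpora[[lab]]
    for (pl in cfg$planes) {
      r <- co[[pl]]
      write_histogram_csv(r$mean_histogram,
                          file.path(out_dir, sprintf("hist_%s_%s.csv", lab, pl)))
      write_curves_csv(list(quadrant = r$curve_q_smooth, rest = r$curve_rest_smooth,
                            difference = curve_difference(r$curve_q_smooth,
                                                          r$curve_rest_smooth)),
                       file.path(out_dir, sprintf("curves_%s_%s.csv", lab, pl)),
                       band = r$band_q)
      if (isTRUE(cfg$write_plots)) {
        plot_histogram_png(r$mean_histogram,
                           file.path(out_dir, sprintf("hist_%s_%s.png", lab, pl)))
        plot_curves_png(r, file.path(out_dir, sprintf("curves_%s_%s.png", lab, pl)),
                        title = paste(lab, pl))
      }
    }
  }
  utils::write.csv(report$local_diff_records,
                   file.path(out_dir, "local_diffs.csv"), row.names = FALSE)
  utils::write.csv(report$correlations,
                   file.path(out_dir, "local_diff_correlations.csv"),
                   row.names = FALSE)
  if (isTRUE(cfg$write_plots))
    plot_local_diffs_png(report$local_diff_records,
                         file.path(out_dir, "local_diffs.png"))
  js <- list(labels = cfg$labels, seed = cfg$seed, n_boot = cfg$n_boot,
             level = cfg$level, sigma = cfg$sigma,
             n_images = c(report$corpora[[1]]$n_images, report$corpora[[2]]$n_images),
             n_skipped = report$n_skipped,
             summary = report$summary,
             correlations = report$correlations)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render a joint histogram as a gray-level PNG figure
#'
#' Darker gray means more pixels in the bin (log-compressed for visibility).
#'
#' @param hist a `joint_histogram`.
#' @param path output PNG path.
#' @export
plot_histogram_png <- function(hist, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  z <- log1p(hist$counts / max(hist$counts, 1e-12))
  cx <- hist_bin_centers(hist$nbins, hist$lim)
  graphics::image(cx, cx, -z, col = grDevices::gray.colors(256, 0, 1),
                  xlab = hist$plane$x_axis, ylab = hist$plane$y_axis,
                  main = paste("joint histogram:", hist$plane$name), asp = 1)
  graphics::abline(h = 0, v = 0, col = "gray40", lty = 3)
  invisible(path)
}

plot_curves_png <- function(plane_res, path, title = "") {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  bq <- plane_res$band_q; br <- plane_res$band_rest
  ylim <- range(0, bq$upper, br$upper)
  graphics::plot(bq$contrast, plane_res$curve_q_smooth$density, type = "n",
                 xlab = "chromatic contrast", ylab = "relative pixel frequency / bin",
                 ylim = ylim, main = title)
  graphics::polygon(c(bq$contrast, rev(bq$contrast)), c(bq$lower, rev(bq$upper)),
                    col = grDevices::rgb(1, 0, 0, 0.2), border = NA)
  graphics::polygon(c(br$contrast, rev(br$contrast)), c(br$lower, rev(br$upper)),
                    col = grDevices::rgb(0, 0, 0, 0.15), border = NA)
  graphics::lines(bq$contrast, plane_res$curve_q_smooth$density, col = "red", lwd = 2)
  graphics::lines(br$contrast, plane_res$curve_rest_smooth$density, col = "black", lwd = 2)
  graphics::legend("topright", legend = c(paste(plane_res$quadrants$included,
                                                collapse = "+"), "rest"),
                   col = c("red", "black"), lwd = 2, bty = "n")
  invisible(path)
}

plot_local_diffs_png <- function(records, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  groups <- unique(records$group)
  cols <- grDevices::hcl.colors(max(2, length(groups)), "Dark 2")
  ci <- match(records$group, groups)
  graphics::plot(records$achromatic_diff, records$chromatic_diff,
                 col = cols[ci], pch = 19,
                 xlab = "mean local achromatic difference (L)",
                 ylab = "mean local chromatic difference (u'v')")
  for (i in seq_along(groups)) {
    m <- records$group == groups[i]
    graphics::points(mean(records$achromatic_diff[m]),
                     mean(records$chromatic_diff[m]),
                     col = cols[i], pch = 3, cex = 3, lwd = 3)
  }
  graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                   pch = 19, bty = "n")
  invisible(path)
}
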