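#' Percentile-bootstrap confidence band for a mean contrast curve
#'
#' Resamples the N per-image curves with replacement N at a time, computes the
#' mean curve of each resample, repeats `n_boot` times, and at every contrast
#' level takes order statistics of the `n_boot` resampled means: for
#' `n_boot = 1000` and `level = 0.95`, the 25th and 975th sorted values.
#' "Sorting the curves" is pointwise per contrast level (the only
#' interpretation that yields a well-defined envelope).
#'
#' @param curves list of >= 2 `contrast_curve`s on identical grids (typically
#'   unsmoothed per-image curves; smooth the band afterwards for display).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level nominal coverage (default 0.95).
#' @param seed optional integer; when given, resampling is reproducible and
#'   the global RNG state is left untouched.
#' @return A `curve_band`: list with `contrast`, `mean` (of the original
#'   sample), `lower`, `upper`, `n_boot`, `level`, `seed`,
#'   `order_statistics` (the two indices used), `n_curves`.
#' @export
bootstrap_band <- function(curves, n_boot = 1000L, level = 0.95, seed = NULL) {
  if (length(curves) < 2) stop("need at least 2 curves")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  g0 <- curves[[1]]$contrast
  for (cv in curves) {
    stopifnot(inherits(cv, "contrast_curve"))
    if (!isTRUE(all.equal(cv$contrast, g0, tolerance = 0)))
      stop("curves are on different contrast grids")
  }
  M <- do.call(rbind, lapply(curves, `[[`, "density"))  # N x L
  N <- nrow(M)
  draw <- function() {
    # resample counts per replicate; one multinomial draw == N index draws
    W <- stats::rmultinom(n_boot, N, rep(1 / N, N))     # N x n_boot
    crossprod(W, M) / N                                 # n_boot x L resampled means
  }
  boot_means <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  k <- as.integer(floor(n_boot * (1 - level) / 2 + 1e-9))  # guard fp residue
  k_lo <- max(1L, k)
  k_hi <- max(k_lo, as.integer(n_boot) - k)
  S <- apply(boot_means, 2, sort)
  structure(list(contrast = g0, mean = colMeans(M),
                 lower = S[k_lo, ], upper = S[k_hi, ],
                 n_boot = as.integer(n_boot), level = level, seed = seed,
                 order_statistics = c(lower = k_lo, upper = k_hi),
                 n_curves = N, smoothed = isTRUE(curves[[1]]$smoothed),
                 sigma = curves[[1]]$sigma),
            class = "curve_band")
}

#' @export
print.curve_band <- function(x, ...) {
  cat(sprintf("percentile bootstrap band: N=%d curves, %d resamples, %.0f%% level\n",
              x$n_curves, x$n_boot, 100 * x$level))
  cat(sprintf("  order statistics %d / %d over %d contrast levels\n",
              x$order_statistics[1], x$order_statistics[2], length(x$contrast)))
  invisible(x)
}
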