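#' Stratify mitosis records by group and basal proximity
#'
#' @param records A `MitosisRecords` data.frame (see [read_mitoses()]).
#' @param basal_max_layer Maximum cell-layer distance from the basal
#'   membrane for the "basal" stratum (default 0: touching).
#' @return List with `basal` (named list: per group, the basal-stratum
#'   angles) and `by_layer` (data.frame `group`, `layer`, `angle_deg` for
#'   layer-resolved plotting).
#' @export
stratify_mitoses <- function(records, basal_max_layer = 0L) {
  stopifnot(inherits(records, "MitosisRecords"))
  if (!nrow(records)) stop("no mitosis records")
  bad <- which(records$angle_deg < 0 | records$angle_deg > 90)
  if (length(bad)) {
    stop("division angle outside [0, 90] for record(s): ",
         paste(utils::head(records$tumor_id[bad], 5), collapse = ", "))
  }
  basal <- lapply(split(records, records$group), function(df) {
    df$angle_deg[df$layer <= basal_max_layer]
  })
  list(basal = basal,
       by_layer = records[, c("group", "layer", "angle_deg")])
}

# column medians of an n x R matrix without per-column apply()
.col_medians <- function(x) {
  n <- nrow(x)
  xs <- matrix(x[order(col(x), x)], nrow = n)
  if (n %% 2L == 1L) xs[(n + 1L) / 2L, ] else
    (xs[n / 2L, ] + xs[n / 2L + 1L, ]) / 2
}

#' Resampling test for a high median division angle
#'
#' Compares the observed median division angle against the distribution of
#' medians of randomly generated angle sets of equal size. The default null
#' is uniform orientation on \[0, 90\] degrees; `null = "pooled"` instead
#' resamples (with replacement) from a pooled set of observed angles;
#' `null = "sine"` draws 3D-isotropic orientations projected to a section
#' (density proportional to sin of the angle from the membrane normal,
#' i.e. cos of the angle from the membrane, on \[0, 90\]).
#'
#' The p-value is one-sided toward 90 degrees with the add-one convention:
#' `p_high = (1 + #{null medians >= observed}) / (n_resamples + 1)`.
#'
#' @param angles Numeric vector of observed angles (degrees, at least 3).
#' @param n_resamples Number of null sets (default 10000).
#' @param null `"uniform"` (default), `"pooled"` or `"sine"`.
#' @param pooled_angles Angles to resample from when `null = "pooled"`.
#' @param seed Integer seed.
#' @param group Optional label carried into the result.
#' @return An `AngleTestResult`: list with `group`, `n`, `observed_median`,
#'   `null_median_mean`, `null_median_ci` (2.5/97.5 percentiles), `p_high`,
#'   `n_resamples`, `seed`, and the raw `null_medians`.
#' @export
median_angle_test <- function(angles, n_resamples = 10000L,
                              null = c("uniform", "pooled", "sine"),
                              pooled_angles = NULL, seed = 1L, group = "") {
  null <- match.arg(null)
  if (!length(angles)) stop("empty angle list")
  if (length(angles) < 3L) stop("need at least 3 angles")
  if (any(angles < 0 | angles > 90)) stop("angles must lie in [0, 90]")
  n <- length(angles)
  obs <- stats::median(angles)
  set.seed(seed)
  draws <- switch(null,
    uniform = stats::runif(n * n_resamples, 0, 90),
    sine = asin(stats::runif(n * n_resamples)) * 180 / pi,
    pooled = {
      if (is.null(pooled_angles)) pooled_angles <- angles
      sample(pooled_angles, n * n_resamples, replace = TRUE)
    })
  null_medians <- .col_medians(matrix(draws, nrow = n))
  p_high <- (1 + sum(null_medians >= obs)) / (n_resamples + 1)
  structure(list(group = group, n = n, observed_median = obs,
                 null_median_mean = mean(null_medians),
                 null_median_ci = unname(stats::quantile(null_medians,
                                                         c(0.025, 0.975))),
                 p_high = p_high, n_resamples = n_resamples, seed = seed,
                 null = null, null_medians = null_medians),
            class = "AngleTestResult")
}

#' @export
print.AngleTestResult <- function(x, ...) {
  cat("Median division-angle test",
      if (nzchar(x$group)) paste0(" [", x$group, "]"), "\n",
      "  n = ", x$n, ", observed median = ", signif(x$observed_median, 4),
      " deg\n  null (", x$null, "): median mean = ",
      signif(x$null_median_mean, 4), ", 95% band [",
      signif(x$null_median_ci[1], 4), ", ", signif(x$null_median_ci[2], 4),
      "]\n  p (toward 90 deg) = ", format(x$p_high, digits = 4),
      "  [", x$n_resamples, " resamples]\n", sep = "")
  invisible(x)
}

#' Run the basal median-angle test per group and write TSV output
#'
#' @param records A `MitosisRecords` data.frame.
#' @param basal_max_layer Basal stratum definition (default layer 0).
#' @param n_resamples,null,seed Passed to [median_angle_test()].
#' @param path Optional output TSV path (one row per group); a null-median
#'   histogram TSV is written next to it as `<path>.null.tsv`.
#' @return Named list of `AngleTestResult`s (groups with fewer than 3 basal
#'   angles are skipped with a warning).
#' @export
angle_tests_by_group <- function(records, basal_max_layer = 0L,
                                 n_resamples = 10000L, null = "uniform",
                                 seed = 1L, path = NULL) {
  strat <- stratify_mitoses(records, basal_max_layer)
  groups <- names(strat$basal)
  out <- list()
  for (i in seq_along(groups)) {
    ang <- strat$basal[[groups[i]]]
    if (length(ang) < 3L) {
      warning("group ", groups[i], ": fewer than 3 basal mitoses, skipped")
      next
    }
    out[[groups[i]]] <- median_angle_test(ang, n_resamples = n_resamples,
                                          null = null, seed = seed + i - 1L,
                                          group = groups[i])
  }
  if (!is.null(path) && length(out)) {
    df <- do.call(rbind, lapply(out, function(r) {
      data.frame(group = r$group, n = r$n, observed_median = r$observed_median,
                 null_median_mean = r$null_median_mean,
                 null_lo = r$null_median_ci[1], null_hi = r$null_median_ci[2],
                 p_high = r$p_high, n_resamples = r$n_resamples)
    }))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    hist_df <- do.call(rbind, lapply(out, function(r) {
      data.frame(group = r$group, null_median = r$null_medians)
    }))
    utils::write.table(hist_df, paste0(path, ".null.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
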