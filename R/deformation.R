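#' Top/bottom deformation statistic of one height map
#'
#' The frame's `top` value is the mean of the k largest valid cell heights
#' and `bottom` the mean of the k smallest; `deformation = top - bottom`
#' quantifies the surface corrugation while staying invariant to a uniform
#' height shift. Skewness of the full valid-height set (adjusted
#' Fisher-Pearson) is reported alongside as a distribution diagnostic.
#'
#' @param hm A `height_map` tibble.
#' @param k Number of extreme cells averaged on each side (default 5).
#' @return A one-row tibble: `top`, `bottom`, `deformation`, `skewness`,
#'   `k`, `n_valid`.
#' @export
top_bottom_deformation <- function(hm, k = 5) {
  h <- hm$h[hm$valid]
  n <- length(h)
  if (k < 1) abort("k must be at least 1")
  if (n < k) {
    abort(paste0("height map has ", n, " valid cells but k = ", k))
  }
  s <- sort(h)
  tibble::tibble(
    top = mean(s[(n - k + 1):n]),
    bottom = mean(s[1:k]),
    deformation = mean(s[(n - k + 1):n]) - mean(s[1:k]),
    skewness = if (n >= 3) sample_skewness(h) else NA_real_,
    k = as.integer(k),
    n_valid = n
  )
}

#' Per-frame deformation records for a height-map series
#'
#' @param hms A `height_map_series` from [height_map_series()].
#' @param k Number of extreme cells averaged on each side.
#' @return A `deformation_series` tibble: `frame`, `time`, `top`, `bottom`,
#'   `deformation`, `skewness`, `k`, `n_valid`. Use [glance()] for the
#'   mean +/- SE summary.
#' @export
deformation_series <- function(hms, k = 5) {
  out <- dplyr::reframe(
    dplyr::group_by(hms, .data$frame, .data$time),
    top_bottom_deformation(dplyr::pick(dplyr::everything()), k = k)
  )
  class(out) <- unique(c("deformation_series", class(out)))
  out
}

#' @describeIn deformation_series Mean and standard error of the
#'   deformation over frames (sample SD / sqrt(n); frames treated as
#'   independent, as in the source analysis).
#' @param x A `deformation_series`.
#' @param ... Unused.
#' @method glance deformation_series
#' @export
glance.deformation_series <- function(x, ...) {
  if (nrow(x) < 2) abort("SE needs at least 2 frames")
  tibble::tibble(
    n_frames = nrow(x),
    mean_deformation = mean(x$deformation),
    se_deformation = se_mean(x$deformation),
    mean_top = mean(x$top),
    mean_bottom = mean(x$bottom),
    mean_skewness = mean(x$skewness)
  )
}

#' Block-averaged standard error of a frame series
#'
#' Alternative to the naive SD/sqrt(n) that accounts for temporal
#' autocorrelation by averaging within contiguous blocks of frames first.
#'
#' @param x Numeric per-frame series.
#' @param block Frames per block.
#' @return Standard error of the block means.
#' @export
block_se <- function(x, block = 5) {
  nb <- floor(length(x) / block)
  if (nb < 2) abort("need at least 2 complete blocks")
  means <- vapply(seq_len(nb), function(b) {
    mean(x[((b - 1) * block + 1):(b * block)])
  }, numeric(1))
  se_mean(means)
}

#' Classify grid cells into hills/valleys and deformation categories
#'
#' Each valid cell is compared with the frame's global mean height
#' (mean over valid cells): cells above it are hills, cells below (or at)
#' it are valleys. The absolute deviation is binned into Category I
#' (large, `>= t2`), Category II (medium, `[t1, t2)`) and Category III
#' (weak, `(0, t1)`); a deviation of exactly 0 is tallied as Category III
#' and also flagged in `zero_dev` so no observation is silently lost.
#' Works per frame on a series input.
#'
#' @param hm A `height_map` or `height_map_series`.
#' @param thresholds `c(t1, t2)` category bounds, Angstrom
#'   (default `c(4, 8)`).
#' @return A `cell_classification` tibble of valid cells: (`frame`,
#'   `time`,) `i`, `j`, `h`, `dev`, `side` (`"hill"`/`"valley"`),
#'   `category` (`"I"`/`"II"`/`"III"`), `zero_dev`.
#' @export
classify_cells <- function(hm, thresholds = c(4, 8)) {
  if (length(thresholds) != 2 || any(thresholds <= 0) ||
      diff(thresholds) <= 0) {
    abort("thresholds must be two strictly increasing positive values")
  }
  t1 <- thresholds[1]; t2 <- thresholds[2]
  df <- dplyr::filter(hm, .data$valid)
  if (nrow(df) == 0) abort("height map has no valid cells")
  if ("frame" %in% names(df)) {
    df <- dplyr::group_by(df, .data$frame)
  }
  df <- dplyr::mutate(df, dev = .data$h - mean(.data$h))
  df <- dplyr::ungroup(df)
  out <- dplyr::mutate(
    df,
    side = dplyr::if_else(.data$dev > 0, "hill", "valley"),
    category = dplyr::case_when(
      abs(.data$dev) >= t2 ~ "I",
      abs(.data$dev) >= t1 ~ "II",
      TRUE ~ "III"
    ),
    zero_dev = .data$dev == 0
  )
  keep <- intersect(c("frame", "time", "i", "j", "h", "dev", "side",
                      "category", "zero_dev"), names(out))
  out <- dplyr::select(out, dplyr::all_of(keep))
  attr(out, "thresholds") <- thresholds
  class(out) <- unique(c("cell_classification", class(out)))
  out
}

#' Tally hill/valley counts per category
#'
#' @param cls A `cell_classification` from [classify_cells()].
#' @return A tibble with (`frame`,) `side`, `category`, `n`, plus
#'   attributes `n_valid` and `n_zero_dev`.
#' @export
category_tally <- function(cls) {
  grp <- intersect(c("frame", "side", "category"), names(cls))
  out <- dplyr::count(cls, dplyr::across(dplyr::all_of(grp)))
  out <- tidyr::complete(
    out,
    !!!rlang::syms(intersect("frame", grp)),
    side = c("hill", "valley"), category = c("I", "II", "III"),
    fill = list(n = 0L)
  )
  attr(out, "n_valid") <- nrow(cls)
  attr(out, "n_zero_dev") <- sum(cls$zero_dev)
  out
}

#' Cumulative hill/valley category distribution across frames
#'
#' For hills and valleys separately, the fraction of cell-frame
#' observations falling in each category. `"pooled"` (default) pools all
#' cell-frame observations; `"per_frame"` averages the per-frame
#' distributions. Zero-deviation cells are excluded from the fractions so
#' each side's three categories sum to 1.
#'
#' @param cls A `cell_classification` covering one or more frames.
#' @param method `"pooled"` or `"per_frame"`.
#' @return A tibble `side`, `category`, `fraction`.
#' @export
cumulative_category_distribution <- function(cls,
                                             method = c("pooled",
                                                        "per_frame")) {
  method <- match.arg(method)
  df <- dplyr::filter(cls, !.data$zero_dev)
  if (nrow(df) == 0) abort("no non-zero-deviation cells to tally")
  full <- tidyr::expand_grid(side = c("hill", "valley"),
                             category = c("I", "II", "III"))
  if (method == "pooled") {
    counts <- dplyr::count(df, .data$side, .data$category)
    counts <- dplyr::mutate(dplyr::group_by(counts, .data$side),
                            fraction = .data$n / sum(.data$n))
    out <- dplyr::left_join(full, dplyr::ungroup(counts),
                            by = c("side", "category"))
    out <- dplyr::mutate(out, fraction = dplyr::coalesce(.data$fraction, 0))
    dplyr::select(out, "side", "category", "fraction")
  } else {
    if (!"frame" %in% names(df)) abort("per_frame needs a frame column")
    per <- dplyr::count(df, .data$frame, .data$side, .data$category)
    per <- dplyr::mutate(dplyr::group_by(per, .data$frame, .data$side),
                         fraction = .data$n / sum(.data$n))
    per <- dplyr::ungroup(per)
    per <- tidyr::complete(per, !!rlang::sym("frame"),
                           side = c("hill", "valley"),
                           category = c("I", "II", "III"),
                           fill = list(fraction = 0))
    out <- dplyr::summarise(
      dplyr::group_by(per, .data$side, .data$category),
      fraction = mean(.data$fraction), .groups = "drop"
    )
    dplyr::left_join(full, out, by = c("side", "category"))
  }
}

#' Linear trend of skewness over time
#'
#' Ordinary least-squares fit of per-frame height-distribution skewness
#' against time; a slope indistinguishable from 0 indicates the surface
#' height distribution is stationary over the sampled window.
#'
#' @param records A `deformation_series` (needs `skewness` and `time`).
#' @return A `skew_trend` object; see [tidy()] for coefficients and
#'   [glance()] for the slope with its standard error.
#' @export
skewness_trend <- function(records) {
  if (nrow(records) < 3) abort("need at least 3 records to fit a trend")
  fit <- lm(skewness ~ time, data = records)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = nrow(records)),
            class = "skew_trend")
}

#' @export
print.skew_trend <- function(x, ...) {
  cat(sprintf("<skew_trend> slope %.4g per ns, intercept %.4g (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' @describeIn skewness_trend Coefficient table (term, estimate, SE,
#'   statistic, p-value).
#' @param x A `skew_trend`.
#' @param ... Unused.
#' @method tidy skew_trend
#' @export
tidy.skew_trend <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @describeIn skewness_trend One-row summary: slope, its SE, intercept,
#'   r.squared, n.
#' @method glance skew_trend
#' @export
glance.skew_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(slope = x$slope, slope_se = s$coefficients[2, 2],
                 intercept = x$intercept, r.squared = s$r.squared,
                 n = x$n)
}
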