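#' Numeric encoding of Modified Ashworth grades
#'
#' MAS grades are ordinal: 0, 1, 1+, 2, 3, 4. The intermediate grade `"1+"`
#' is represented numerically as 1.4; all other grades map to their face
#' value.
#'
#' @param grade Character vector of grades in `{"0","1","1+","2","3","4"}`
#'   (numeric input is accepted for the non-`1+` grades).
#' @return Numeric vector with values in `{0, 1, 1.4, 2, 3, 4}`.
#' @examples
#' encode_mas(c("0", "1+", "3"))  # 0.0 1.4 3.0
#' @export
encode_mas <- function(grade) {
  lut <- c("0" = 0, "1" = 1, "1+" = 1.4, "2" = 2, "3" = 3, "4" = 4)
  key <- as.character(grade)
  if (any(!key %in% names(lut)))
    abort_semg(paste0("unknown MAS grade(s): ",
                      paste(unique(key[!key %in% names(lut)]), collapse = ", ")),
               "value")
  unname(lut[key])
}

#' Pearson correlation with the exact t-transform p-value
#'
#' Product-moment correlation between mapped and manual scores, with a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, and significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points, both
#'   non-constant.
#' @return A one-row tibble: `r`, `t`, `df`, `p`, `stars`, `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort_semg("x and y lengths differ.", "alignment")
  n <- length(x)
  if (n < 3) abort_semg("need at least 3 paired points.", "sample_size")
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    abort_semg("correlation is undefined for a constant vector.",
               "undefined_correlation")
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1 - 1e-15) {
    tt <- sign(r) * Inf
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(r = r, t = tt, df = n - 2, p = p,
                 stars = significance_stars(p), n = n)
}

#' Paired pre/post comparison of the clinical scales
#'
#' FMA subscores (interval-like, typically normal) are compared with the
#' paired t-test; MAS grades (ordinal) with the paired Wilcoxon signed-rank
#' test on their numeric encoding. Shapiro-Wilk normality p-values per
#' session are reported for every scale. All-tied MAS differences make the
#' signed-rank test degenerate; such scales are flagged with a warning and an
#' `NA` p-value.
#'
#' @param scores A tibble with `participant_id`, `session` and the clinical
#'   columns `FMA_SE`, `FMA_WH`, `MAS_elbow`, `MAS_wrist`, `MAS_finger`
#'   (MAS as grade strings), containing both sessions.
#' @return A tibble with one row per scale: test used, per-session mean and
#'   SD, normality p-values, statistic, p-value and stars.
#' @export
compare_clinical_sessions <- function(scores) {
  pre <- dplyr::filter(scores, .data$session == "pre")
  post <- dplyr::filter(scores, .data$session == "post")
  ids <- intersect(pre$participant_id, post$participant_id)
  if (length(ids) < 3)
    abort_semg("need at least 3 paired participants.", "sample_size")
  pre <- pre[match(ids, pre$participant_id), ]
  post <- post[match(ids, post$participant_id), ]
  cols <- intersect(c("FMA_SE", "FMA_WH", "MAS_elbow", "MAS_wrist", "MAS_finger"),
                    names(scores))
  purrr::map_dfr(cols, function(col) {
    is_mas <- grepl("^MAS", col)
    a <- if (is_mas) encode_mas(pre[[col]]) else as.numeric(pre[[col]])
    b <- if (is_mas) encode_mas(post[[col]]) else as.numeric(post[[col]])
    sh_pre <- if (stats::sd(a) > 1e-12) stats::shapiro.test(a)$p.value else NA_real_
    sh_post <- if (stats::sd(b) > 1e-12) stats::shapiro.test(b)$p.value else NA_real_
    if (is_mas) {
      res <- tryCatch(
        suppressWarnings(stats::wilcox.test(b, a, paired = TRUE, exact = FALSE)),
        error = function(e) NULL)
      if (is.null(res) || is.na(res$p.value)) {
        rlang::warn(paste0(col, ": paired differences are all tied; ",
                           "signed-rank test is degenerate."))
        stat <- NA_real_; pv <- NA_real_
      } else { stat <- unname(res$statistic); pv <- res$p.value }
      test <- "wilcoxon signed-rank"
    } else {
      if (stats::sd(b - a) < 1e-12) {
        stat <- if (all(abs(b - a) < 1e-12)) 0 else NA_real_
        pv <- if (all(abs(b - a) < 1e-12)) 1 else NA_real_
      } else {
        tt <- stats::t.test(b, a, paired = TRUE)
        stat <- unname(tt$statistic); pv <- tt$p.value
      }
      test <- "paired t"
    }
    tibble::tibble(scale = col, test = test, n = length(ids),
                   mean_pre = mean(a), sd_pre = stats::sd(a),
                   mean_post = mean(b), sd_post = stats::sd(b),
                   shapiro_p_pre = sh_pre, shapiro_p_post = sh_post,
                   statistic = stat, p_value = pv,
                   stars = significance_stars(pv))
  })
}
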