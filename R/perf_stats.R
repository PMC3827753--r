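#' Pearson correlation with the least-squares prediction line
#'
#' Product-moment correlation between two series with the t-based two-sided
#' p-value, plus the slope and intercept of the ordinary least-squares line
#' `y = slope * x + intercept` (the form in which work-performance
#' prediction equations are reported, with `y` the 10 000-m time in
#' seconds).
#'
#' @param x,y Numeric series of equal length (`n >= 3`), both with non-zero
#'   variance.
#' @return An object of class `correlation_result`: `r`, `p`, `n`, `slope`,
#'   `intercept`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- stats::complete.cases(x, y)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " incomplete pair(s)")
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 3) stop("correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a series has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1])),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (p = %.4g, n = %d); y = %.4g x + %.4g\n",
              x$r, x$p, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Work-performance correlation table
#'
#' For each work component (`W_int`, `W_ext`, `W_tot`) and each allometric
#' exponent, correlates the per-subject work (rescaled from its `b = 1`,
#' per-kg-per-metre value to `J kg^-b m^-1` with the subject's own mass)
#' with 10 000-m performance time.
#'
#' @param cohort Data frame with columns `body_mass_kg`, `w_int`, `w_ext`,
#'   `w_tot` (in J kg^-1 m^-1) and `performance_s`.
#' @param b_values Allometric exponents (default `c(1, 0.75, 0.49)`).
#' @return Data frame with one row per component and exponent: `component`,
#'   `b`, `r`, `p`, `slope`, `intercept`, `n`.
#' @export
work_performance_table <- function(cohort, b_values = c(1, 0.75, 0.49)) {
  need <- c("body_mass_kg", "w_int", "w_ext", "w_tot", "performance_s")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0)
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(cohort) < 3) stop("need at least 3 subjects")
  comps <- c(W_int = "w_int", W_ext = "w_ext", W_tot = "w_tot")
  rows <- list()
  for (b in b_values) {
    for (k in seq_along(comps)) {
      w <- rescale_specific(cohort[[comps[k]]], cohort$body_mass_kg, b)
      ct <- pearson_correlation(w, cohort$performance_s)
      rows[[length(rows) + 1]] <- data.frame(
        component = names(comps)[k], b = b, r = ct$r, p = ct$p,
        slope = ct$slope, intercept = ct$intercept, n = ct$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Internal-to-external work ratio
#'
#' `100 * W_int / W_ext`, in percent: the contrast between the two work
#' components, independent of the allometric exponent used to normalise
#' them (the exponent cancels in the ratio when both are scaled with the
#' same mass).
#'
#' @param W_int,W_ext Works in the same units; `W_ext` must be positive.
#' @return The ratio in percent.
#' @examples
#' wint_wext_ratio(0.63, 1.22)  # ~51.6
#' @export
wint_wext_ratio <- function(W_int, W_ext) {
  if (any(W_ext <= 0)) stop("W_ext must be positive")
  100 * W_int / W_ext
}
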