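# ---------------------------------------------------------------------------
# Small summary statistics a target-calling study reports from printed
# numbers: Fisher's exact test on a 2x2 incidence table, Pearson
# correlation, an upregulation proportion, and the caliper tumor-volume
# formula.
# ---------------------------------------------------------------------------

#' Fisher's exact test for a 2x2 table
#'
#' Exact enumeration over all tables with the observed margins.  The
#' two-sided p-value follows the point-probability ("minimum-likelihood")
#' convention — the sum of hypergeometric probabilities of all tables no
#' more probable than the observed one (the convention of
#' `stats::fisher.test`); the "doubling" convention (twice the smaller
#' one-sided tail, capped at 1) is available via `method`.  Point
#' probabilities are compared with relative tolerance `1e-7` to keep the
#' enumeration safe against floating-point ties.
#'
#' @param a,b,c,d Counts: row 1 = group 1 with/without event, row 2 =
#'   group 2 with/without event.  Alternatively pass a 2x2 matrix as `a`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (one-sided tails in `a`).
#' @param method Two-sided convention, `"minlike"` (default) or
#'   `"doubling"`.
#' @return The p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(9, 2, 4, 9)  # 0.019 at 3 decimals
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("two.sided", "less", "greater"),
                             method = c("minlike", "doubling")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("empty table")
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  # P(X = x) for X ~ Hypergeometric(row1 = m, row2 = n, draws = k)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- probs[match(a, x)]
  p <- switch(alternative,
    less = sum(probs[x <= a]),
    greater = sum(probs[x >= a]),
    two.sided = if (method == "minlike") {
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    } else {
      min(1, 2 * min(sum(probs[x <= a]), sum(probs[x >= a])))
    })
  min(1, p)
}

#' Pearson correlation coefficient
#'
#' Thin validated wrapper around [stats::cor()] for expression-correlation
#' reporting: requires equal lengths of at least 3 and non-degenerate
#' variance in both vectors.
#'
#' @param x,y Numeric vectors.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  cor(x, y, method = "pearson")
}

#' Proportion of upregulated cases, as a printed percentage
#'
#' `100 * n_up / n_total`, rounded half-up to one decimal (the rounding
#' used when such proportions are printed, e.g. 98/151 -> 64.9).
#'
#' @param n_up,n_total Non-negative counts, `n_up <= n_total`,
#'   `n_total > 0`.
#' @return Percentage with one decimal.
#' @examples
#' proportion_upregulated(98, 151)  # 64.9
#' @export
proportion_upregulated <- function(n_up, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_up < 0 || n_up > n_total) stop("need 0 <= n_up <= n_total")
  pct <- 100 * n_up / n_total
  floor(pct * 10 + 0.5) / 10  # round half-up, 1 decimal
}

#' Caliper tumor volume
#'
#' The standard xenograft formula: volume (mm^3) = length x width^2 / 2.
#' By convention width <= length; a wider-than-long measurement is likely a
#' transposition and triggers a warning, but the value is still returned.
#'
#' @param length_mm,width_mm Caliper measurements in mm, positive;
#'   vectorised.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 6)  # 180
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("length and width must be positive")
  }
  if (any(width_mm > length_mm)) {
    warning("width exceeds length for ", sum(width_mm > length_mm),
            " measurement(s); by convention width <= length")
  }
  length_mm * width_mm^2 / 2
}
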