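#' Mann-Whitney U test (midranks, exact or tie-corrected normal)
#'
#' The U statistic is computed from midranks of the pooled sample.  For
#' small groups (`min(n0, n1) <= 8` under `mode = "auto"`) the two-sided
#' p-value comes from the exact permutation distribution of U given the
#' observed pooled values — computed by dynamic programming over midrank
#' sums, which enumerates the \eqn{\binom{n}{n_A}} group assignments
#' without listing them.  Otherwise the normal approximation with tie
#' correction and a 0.5 continuity correction is used.  Two-sided
#' probability is `P(|U - n0 n1 / 2| >= |u_obs - n0 n1 / 2|)`.
#'
#' @param a,b Numeric samples for the two groups (both nonempty).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return Object of class `mw_result`: `U` (for group `a`), `p`
#'   (two-sided), `n0`, `n1` (sizes of `a`, `b`), `method`, `stars`
#'   (`""`/`"*"`/`"**"`/`"***"`; `* p<=0.05, ** p<=0.01, *** p<=0.001`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("NA values in groups")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))                       # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "auto") mode <- if (min(na, nb) <= 8) "exact" else "normal"
  mu <- na * nb / 2
  if (length(unique(c(a, b))) == 1) {
    p <- 1
  } else if (mode == "exact") {
    p <- mw_exact_p(r, na, u)
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  structure(list(U = u, p = p, n0 = na, n1 = nb, method = mode,
                 stars = p_stars(p)), class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %s%s [%s]\n",
              x$U, x$n0, x$n1, format_p(x$p), x$stars, x$method))
  invisible(x)
}

# Exact permutation distribution of the group-A midrank sum by dynamic
# programming over doubled ranks (integers even with ties).  Counts stay
# below 2^53 for the group sizes routed here.
mw_exact_p <- function(r, na, u_obs) {
  d <- as.integer(round(2 * r))
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(na)])
  # f[j, s+1] = number of subsets of size j-1 with doubled-rank sum s
  f <- matrix(0, na + 1, smax + 1)
  f[1, 1] <- 1
  seen <- 0L
  for (dk in d) {
    seen <- seen + 1L
    for (j in seq(min(na, seen), 1)) {
      src <- f[j, seq_len(smax + 1 - dk)]
      if (!any(src > 0)) next
      tgt <- seq(dk + 1, smax + 1)
      f[j + 1, tgt] <- f[j + 1, tgt] + src
    }
  }
  cnt <- f[na + 1, ]
  sums <- (seq_along(cnt) - 1) / 2          # back to midrank scale
  us <- sums - na * (na + 1) / 2
  mu <- na * (length(d) - na) / 2
  keep <- cnt > 0
  dev <- abs(us[keep] - mu)
  sum(cnt[keep][dev >= abs(u_obs - mu) - 1e-9]) / sum(cnt[keep])
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else ""
}

format_p <- function(p) sprintf("%.3f", pmax(p, 0.001))

#' Feature-by-index significance screening
#'
#' Runs one two-sided Mann-Whitney test per (feature, index) pair of a
#' cohort table, comparing the feature's distribution between the index's
#' 0 and 1 groups.  Rows with a missing feature value are dropped per
#' pair; an index column with a single class is flagged untestable (`NA`
#' p).  Raw p-values are starred (`* <= 0.05`, `** <= 0.01`,
#' `*** <= 0.001`) and reported to three decimals floored at 0.001; a
#' Benjamini-Hochberg adjusted column is emitted alongside but does not
#' drive the stars.
#'
#' @param cohort Data frame containing the feature and index columns.
#' @param features,indexes Column names to test (defaults: the 19
#'   biometric features against the 8 binary indexes).
#' @param mode Passed to [mann_whitney()].
#' @return Data frame of class `significance_matrix`, one row per pair:
#'   `feature`, `index`, `n0`, `n1`, `U`, `p`, `p_display`, `stars`,
#'   `p_bh`, `testable`.
#' @export
significance_matrix <- function(cohort, features = feature_names(),
                                indexes = index_names(), mode = "auto") {
  cohort <- as.data.frame(cohort)
  miss <- setdiff(c(features, indexes), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  rows <- list()
  for (ix in indexes) {
    y <- cohort[[ix]]
    for (ft in features) {
      v <- cohort[[ft]]
      ok <- !is.na(v) & !is.na(y)
      g0 <- v[ok & y == 0]; g1 <- v[ok & y == 1]
      if (!length(g0) || !length(g1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = ft, index = ix, n0 = length(g0), n1 = length(g1),
          U = NA_real_, p = NA_real_, testable = FALSE)
      } else {
        mw <- mann_whitney(g0, g1, mode)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = ft, index = ix, n0 = mw$n0, n1 = mw$n1, U = mw$U,
          p = mw$p, testable = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out$p_display <- ifelse(is.na(out$p), NA_character_, format_p(out$p))
  out$stars <- vapply(out$p, p_stars, character(1))
  class(out) <- c("significance_matrix", "data.frame")
  out
}

#' @export
print.significance_matrix <- function(x, ...) {
  need <- c("feature", "index", "p_display", "stars", "testable")
  if (!all(need %in% names(x)))            # subsetted: plain frame printing
    return(print.data.frame(x, ...))
  wide <- stats::reshape(
    data.frame(feature = x$feature, index = x$index,
               cell = ifelse(x$testable, paste0(x$p_display, x$stars), "-")),
    idvar = "feature", timevar = "index", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
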