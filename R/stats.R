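# Mass-univariate nonparametric comparison of single-trial spectra with
# false-discovery-rate control.  The rank-sum test and the
# Benjamini-Hochberg step-up are implemented from first principles: exact
# permutation enumeration anchors the small-sample regime and the
# tie-corrected normal approximation (with continuity correction) covers
# the rest.

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test with midranks for ties.  The statistic
#' is the rank sum `W` of the first sample within the pooled ranking.  For
#' `length(x) + length(y) <= 12` (unless overridden) the p-value is
#' computed by exact enumeration of all assignments of the observed
#' midranks to the two groups; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` chooses by the size rule.
#' @return List with elements `statistic` (rank sum of `x`), `p.value`,
#'   and `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) > 0, length(y) > 0)
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  if (is.null(exact)) exact <- (n + m) <= 12
  if (length(unique(c(x, y))) == 1) {
    # all pooled values identical: no evidence either way
    return(list(statistic = mu, p.value = 1,
                method = "degenerate (all values tied)"))
  }
  if (exact) {
    combs <- utils::combn(n + m, n)
    ws <- colSums(matrix(r[combs], nrow = n))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, p.value = p, method = "exact enumeration"))
  }
  tie_term <- 0
  if (anyDuplicated(r)) {
    cnt <- rle(sort(r))$lengths
    tie_term <- sum(cnt^3 - cnt)
  }
  N <- n + m
  sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = w, p.value = 1,
                method = "degenerate (all values tied)"))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  if (abs(w - mu) < 0.5) z <- 0
  list(statistic = w, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Sorts the p-values ascending, finds the largest `i` with
#' `p(i) <= i * q / m`, and rejects every hypothesis with `p <= p(i)`.
#'
#' @param pvals Numeric vector of p-values.
#' @param q Target false-discovery rate, in (0, 1).
#' @return List with `reject` (logical mask in input order) and
#'   `threshold` (the realized p-value cutoff; 0 when nothing is
#'   rejected).
#' @examples
#' fdr_bh(c(0.001, 0.008, 0.039, 0.041), q = 0.05)$reject  # all TRUE
#' @export
fdr_bh <- function(pvals, q) {
  stopifnot(q > 0, q < 1)
  m <- length(pvals)
  if (m == 0) return(list(reject = logical(0), threshold = 0))
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(list(reject = rep(FALSE, m), threshold = 0))
  thr <- ps[max(ok)]
  list(reject = pvals <= thr, threshold = thr)
}

# vectorized tie-corrected normal-approximation rank-sum p-values for the
# columns of rbind(x_trials, y_trials); must agree with rank_sum_test()'s
# normal path (a test asserts this)
rank_sum_columns <- function(xy, n1) {
  N <- nrow(xy)
  n2 <- N - n1
  mu <- n1 * (N + 1) / 2
  stat_tie <- apply(xy, 2, function(v) {
    r <- rank(v)
    tie <- 0
    if (anyDuplicated(r)) {
      cnt <- rle(sort(r))$lengths
      tie <- sum(cnt^3 - cnt)
    }
    c(sum(r[seq_len(n1)]), tie)
  })
  w <- stat_tie[1, ]
  sigma2 <- n1 * n2 / 12 * ((N + 1) - stat_tie[2, ] / (N * (N - 1)))
  z <- ifelse(abs(w - mu) < 0.5 | sigma2 <= 0, 0,
              (w - mu - sign(w - mu) * 0.5) / sqrt(pmax(sigma2, 1e-300)))
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[sigma2 <= 0] <- 1
  list(statistic = w, p = p)
}

#' Electrode-by-frequency significance map of VR vs. No-VR spectra
#'
#' Runs a Wilcoxon rank-sum test per (electrode, frequency-bin) cell on the
#' single-trial spectral powers of the two conditions and controls the
#' false-discovery rate with one Benjamini-Hochberg family pooling all
#' electrode x bin p-values of the comparison.  Only bins in
#' `[fmin, fmax]` (default 1 Hz to Nyquist) enter the family.
#'
#' @param vr,novr `eeg_spectra` objects (see [power_spectrum()]) for the
#'   two conditions; same electrodes and frequency axis, one eye state per
#'   call.
#' @param q Target false-discovery rate.
#' @param fmin,fmax Analyzed frequency range in Hz (`fmax = NULL` means
#'   Nyquist).
#' @return An object of class `significance_map`: `channels`, `freqs`,
#'   `p` and `statistic` (electrodes x bins), logical `reject`,
#'   `q`, realized `threshold`, and the two trial counts.
#' @export
spectral_significance_map <- function(vr, novr, q = 0.01, fmin = 1,
                                      fmax = NULL) {
  stopifnot(inherits(vr, "eeg_spectra"), inherits(novr, "eeg_spectra"),
            identical(vr$channels, novr$channels))
  if (!isTRUE(all.equal(vr$freqs, novr$freqs))) {
    stop("conditions must share one frequency axis", call. = FALSE)
  }
  n1 <- dim(vr$power)[1]
  n2 <- dim(novr$power)[1]
  if (n1 < 2 || n2 < 2) stop("need at least 2 trials per condition",
                             call. = FALSE)
  if (is.null(fmax)) fmax <- max(vr$freqs)
  bins <- which(vr$freqs >= fmin & vr$freqs <= fmax)
  n_ch <- length(vr$channels)
  K <- n_ch * length(bins)

  # pooled trials x (channel, bin) matrix
  xy <- rbind(
    matrix(vr$power[, , bins, drop = FALSE], nrow = n1),
    matrix(novr$power[, , bins, drop = FALSE], nrow = n2)
  )
  if (n1 + n2 <= 12) {
    res <- apply(xy, 2, function(v) {
      t <- rank_sum_test(v[seq_len(n1)], v[-seq_len(n1)])
      c(t$statistic, t$p.value)
    })
    w <- res[1, ]
    p <- res[2, ]
  } else {
    rs <- rank_sum_columns(xy, n1)
    w <- rs$statistic
    p <- rs$p
  }
  bh <- fdr_bh(p, q)
  shape <- function(v) matrix(v, nrow = n_ch,
                              dimnames = list(vr$channels, NULL))
  structure(
    list(channels = vr$channels, freqs = vr$freqs[bins],
         p = shape(p), statistic = shape(w),
         reject = shape(bh$reject), q = q, threshold = bh$threshold,
         n_vr = n1, n_novr = n2),
    class = "significance_map"
  )
}

#' Export a significance map as a long table
#'
#' @param sig_map A `significance_map`.
#' @return Data frame with columns `electrode`, `freq`, `p`, `rejected`.
#' @export
significance_table <- function(sig_map) {
  stopifnot(inherits(sig_map, "significance_map"))
  data.frame(
    electrode = rep(sig_map$channels, times = length(sig_map$freqs)),
    freq = rep(sig_map$freqs, each = length(sig_map$channels)),
    p = as.vector(sig_map$p),
    rejected = as.vector(sig_map$reject),
    stringsAsFactors = FALSE
  )
}
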