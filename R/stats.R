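#' Wilcoxon signed-rank test with exact small-sample branch
#'
#' Paired two-sided test. Zero differences are dropped, tied absolute
#' differences receive mid-ranks. With at most 12 effective pairs the null
#' distribution of W+ is computed exactly by enumerating all sign
#' assignments of the observed (possibly tied) ranks via a shift-algorithm
#' convolution; larger samples use the normal approximation with tie and
#' continuity correction. The branch used is recorded in `$method`.
#'
#' @param x,y Paired numeric vectors of equal length (or `y = NULL` to
#'   test differences in `x` against zero).
#' @param exact_max Largest effective n for the exact branch (default 12).
#' @return An object of class `htest` with `statistic` (W+ = rank sum of
#'   positive differences), `p.value` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 12) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 1)
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(build_htest(0, 1, "Wilcoxon signed rank (degenerate)", "W"))
  }
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  r2 <- round(2 * r)                      # doubled ranks are integers
  if (n <= exact_max) {
    # counts[s + 1] = number of sign assignments with doubled W+ = s
    total <- sum(r2)
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (v in r2) {
      shifted <- c(numeric(v), counts[seq_len(total + 1 - v)])
      counts <- counts + shifted
    }
    mu2 <- total / 2
    dev <- abs(round(2 * w_obs) - mu2)
    p <- sum(counts[abs(seq(0, total) - mu2) >= dev - 1e-9]) / 2^n
    method <- "Wilcoxon signed rank, exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed rank, normal approximation"
  }
  build_htest(w_obs, p, method, "W")
}

#' Mann-Whitney U test with exact small-sample branch
#'
#' Unpaired two-sided test on mid-ranks. When `min(n, m) <= 8` the exact
#' null distribution of the rank sum is obtained by dynamic programming
#' over all \eqn{\binom{n+m}{n}} labelings (ties enter through the
#' mid-ranks); otherwise the normal approximation with tie correction is
#' used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest `min(n, m)` for the exact branch (default 8).
#' @return An `htest` with `statistic` (U for `x`), `p.value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(n)])
  u_obs <- rx - n * (n + 1) / 2
  r2 <- round(2 * r)
  big_n <- n + m
  if (min(n, m) <= exact_max) {
    # dp[k + 1, s + 1] = #subsets of size k with doubled rank sum s
    total <- sum(r2)
    dp <- matrix(0, n + 1, total + 1)
    dp[1, 1] <- 1
    for (v in r2) {
      for (k in n:1) {                     # k downwards: each value used once
        src <- dp[k, seq_len(total + 1 - v)]
        dp[k + 1, (v + 1):(total + 1)] <- dp[k + 1, (v + 1):(total + 1)] + src
      }
    }
    counts <- dp[n + 1, ]
    mu2 <- n * (big_n + 1)                 # mean of doubled rank sum
    dev <- abs(round(2 * rx) - mu2)
    p <- sum(counts[abs(seq(0, total) - mu2) >= dev - 1e-9]) /
      choose(big_n, n)
    method <- "Mann-Whitney U, exact"
  } else {
    ties <- table(r)
    mu <- n * m / 2
    sigma2 <- n * m / 12 *
      (big_n + 1 - sum(ties^3 - ties) / (big_n * (big_n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney U, normal approximation"
  }
  build_htest(u_obs, p, method, "U")
}

build_htest <- function(stat, p, method, name) {
  structure(
    list(statistic = stats::setNames(stat, name), p.value = p,
         method = method, alternative = "two.sided",
         data.name = "x and y"),
    class = "htest"
  )
}

KAPPA_BANDS <- tibble::tibble(
  lower = c(-Inf, 0, 0.21, 0.41, 0.61, 0.81),
  upper = c(0, 0.21, 0.41, 0.61, 0.81, 1 + 1e-9),
  band = c("poor", "slight", "fair", "moderate", "substantial",
           "almost perfect")
)

#' Interpretation band of a kappa value
#'
#' Conventional cut-points: 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect (lower bound
#' inclusive); negative values are labelled `"poor"`.
#'
#' @param kappa Kappa value between -1 and 1.
#' @return Band label.
#' @export
kappa_band <- function(kappa) {
  i <- findInterval(kappa, KAPPA_BANDS$lower)
  KAPPA_BANDS$band[i]
}

#' Cohen's kappa for two readers of ordinal ratings
#'
#' Unweighted kappa from the contingency table of reader1 x reader2 over
#' the 0..4 Likert categories. When both readers use a single identical
#' category kappa is formally 0/0; it is returned as 1 with a warning
#' (perfect observed agreement).
#'
#' @param ratings A ratings table (tibble with columns `reader1`,
#'   `reader2`), or a numeric vector of reader-1 scores.
#' @param reader2 Reader-2 scores when `ratings` is a vector.
#' @param levels Category levels (default 0:4).
#' @return List of class `cohen_kappa`: `kappa`, `band`, `p_o`, `p_e`,
#'   `table`.
#' @export
cohen_kappa <- function(ratings, reader2 = NULL, levels = 0:4) {
  if (is.data.frame(ratings)) {
    r1 <- ratings$reader1
    r2 <- ratings$reader2
  } else {
    r1 <- ratings
    r2 <- reader2
  }
  stopifnot(length(r1) == length(r2), length(r1) >= 2)
  lev <- sort(unique(c(levels, r1, r2)))
  tab <- table(factor(r1, lev), factor(r2, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (isTRUE(all.equal(p_e, 1))) {
    warning("degenerate table (single constant category); kappa set to 1",
            call. = FALSE)
    k <- 1
  } else {
    k <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = k, band = kappa_band(k), p_o = p_o, p_e = p_e,
                 table = tab),
            class = "cohen_kappa")
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s agreement); p_o = %.3f, p_e = %.3f\n",
              x$kappa, x$band, x$p_o, x$p_e))
  invisible(x)
}

#' Simulate two ordinal readers from streak scores
#'
#' Stands in for human Likert reading so the qualitative pipeline is
#' testable end to end. Reader 1 bins each case's streak score into 0..4
#' by quantiles of the NOMAR score distribution (monotone calibration);
#' reader 2 equals reader 1 perturbed by +/-1 with probability
#' `flip_prob`, clipped to the scale.
#'
#' @param scores Tibble with columns `case_id`, `arm`, `mean_score` (and
#'   optionally `stratum`), as produced by [score_case()].
#' @param calibration List with `probs` (quantile cut probabilities,
#'   default `c(0.1, 0.35, 0.65, 0.9)` of the NOMAR distribution) and
#'   `flip_prob` (default 0.2).
#' @param seed Integer seed for the perturbation.
#' @return A ratings tibble: `case_id`, `stratum`, `arm`, `reader1`,
#'   `reader2`, scores integral in 0..4.
#' @export
simulate_readers <- function(scores,
                             calibration = list(probs = c(0.1, 0.35, 0.65, 0.9),
                                                flip_prob = 0.2),
                             seed = 1) {
  stopifnot("NOMAR" %in% scores$arm)
  cuts <- quantile(scores$mean_score[scores$arm == "NOMAR"],
                   probs = calibration$probs, names = FALSE)
  bin <- function(v) findInterval(v, unique(cuts))
  r1 <- pmin(bin(scores$mean_score), 4L)
  flips <- with_seed(seed, {
    sgn <- sample(c(-1L, 1L), length(r1), replace = TRUE)
    on <- rbinom(length(r1), 1, calibration$flip_prob %||% 0.2)
    sgn * on
  })
  r2 <- pmin(pmax(r1 + flips, 0L), 4L)
  tibble::tibble(
    case_id = scores$case_id,
    stratum = if ("stratum" %in% names(scores)) scores$stratum else NA_character_,
    arm = scores$arm,
    reader1 = as.integer(r1),
    reader2 = as.integer(r2)
  )
}
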