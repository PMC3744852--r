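validate_fnr_params <- function(n, read_length, min_clip, dx) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("n must be a single non-negative integer")
  }
  if (min_clip < 1L) stop("min_clip must be >= 1")
  if (read_length %% 2L != 0L || read_length < 2L * min_clip) {
    stop("read_length must be even and at least 2 * min_clip")
  }
  if (dx < 0L) stop("dx must be >= 0")
  if (min_clip + dx - 1L > read_length / 2) {
    stop("min_clip + dx - 1 must not exceed read_length / 2")
  }
  invisible(TRUE)
}

#' Closed-form false negative rate of the split-read pairing
#'
#' The caller needs at least one usable 3'-clipped (MS) read and one usable
#' 5'-clipped (SM) read across the junction. With `n` junction-covering reads
#' of length `L`, each read is MS or SM with probability 1/2 depending on
#' which side of the midpoint its breakpoint offset falls; an MS read is
#' unusable when its clip is shorter than the threshold, which happens with
#' probability `q1 = (nS - 1) / (L / 2)`, and an SM read with probability
#' `q2 = (nS + dx - 1) / (L / 2)` — the breakpoint microhomology `dx` eats
#' into the SM clip. Summing over the number `i` of MS reads,
#' \deqn{FNR = \sum_{i=0}^{n} \binom{n}{i} 2^{-n}
#'   \left[ q_1^i + q_2^{n-i} - q_1^i q_2^{n-i} \right].}
#' The sum is accumulated with log-binomial coefficients for numerical
#' stability at large `n`.
#'
#' @param n Number of junction-covering reads (>= 0).
#' @param read_length Read length `L` in bases (even, >= 2 * `min_clip`).
#' @param min_clip Clip-length threshold `nS` (default 11).
#' @param dx Breakpoint homology length in bases (default 0).
#' @return Failure probability in `[0, 1]`; exactly 1 when `n = 0`.
#' @seealso [fnr_monte_carlo()] for a simulation cross-check.
#' @export
#' @examples
#' fnr_analytic(20, 100, min_clip = 11, dx = 10)
fnr_analytic <- function(n, read_length = 100L, min_clip = 11L, dx = 0L) {
  validate_fnr_params(n, read_length, min_clip, dx)
  half <- read_length / 2
  q1 <- (min_clip - 1) / half
  q2 <- (min_clip + dx - 1) / half
  i <- 0:n
  w <- exp(lchoose(n, i) - n * log(2))
  pow <- function(q, k) ifelse(k == 0L, 1, q^k) # 0^0 = 1
  t1 <- pow(q1, i)
  t2 <- pow(q2, n - i)
  min(1, max(0, sum(w * (t1 + t2 - t1 * t2))))
}

#' Monte-Carlo estimate of the false negative rate
#'
#' Simulates the read-usability model behind [fnr_analytic()] directly: per
#' replicate, `n` junction reads are each MS or SM with probability 1/2; an
#' MS read is usable with probability `1 - q1` and an SM read with
#' probability `1 - q2` (the probability that a uniformly placed breakpoint
#' offset leaves a clip at or above the threshold). A replicate fails when no
#' usable MS read or no usable SM read exists.
#'
#' @inheritParams fnr_analytic
#' @param reps Number of replicates (>= 1).
#' @param seed Optional integer seed.
#' @return List with `estimate`, `se` (binomial standard error), `failures`
#'   and `reps`.
#' @export
fnr_monte_carlo <- function(n, read_length = 100L, min_clip = 11L, dx = 0L,
                            reps = 1e5, seed = NULL) {
  validate_fnr_params(n, read_length, min_clip, dx)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  half <- read_length / 2
  q1 <- (min_clip - 1) / half
  q2 <- (min_clip + dx - 1) / half
  if (n == 0L) {
    return(list(estimate = 1, se = 0, failures = reps, reps = reps))
  }
  n_ms <- stats::rbinom(reps, n, 0.5)
  usable_ms <- stats::rbinom(reps, n_ms, 1 - q1)
  usable_sm <- stats::rbinom(reps, n - n_ms, 1 - q2)
  failures <- sum(usable_ms == 0L | usable_sm == 0L)
  p <- failures / reps
  list(
    estimate = p,
    se = sqrt(p * (1 - p) / reps),
    failures = failures,
    reps = reps
  )
}
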