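#' Random entropy of a location set
#'
#' Uncertainty assuming every one of the `L` distinct locations is visited
#' with equal frequency: `log2(L)` bits.
#'
#' @param L number of distinct locations, `>= 1`.
#' @return entropy in bits.
#' @export
random_entropy <- function(L) {
  if (length(L) != 1 || is.na(L) || L < 1) stopf("L must be a count >= 1")
  log2(L)
}

#' Uncorrelated (Shannon) entropy of visit frequencies
#'
#' `-sum(p_k log2 p_k)` over the empirical visitation frequencies; captures
#' heterogeneity of visits but no temporal order. Zero-count symbols are
#' ignored (`0 * log 0 := 0`).
#'
#' @param symbol_counts named numeric vector or `table` of non-negative
#'   counts with positive total.
#' @return entropy in bits.
#' @export
uncorrelated_entropy <- function(symbol_counts) {
  cnt <- as.numeric(symbol_counts)
  if (length(cnt) == 0) stopf("empty count map")
  if (any(cnt < 0)) stopf("counts must be non-negative")
  tot <- sum(cnt)
  if (tot <= 0) stopf("total count must be positive")
  p <- cnt[cnt > 0] / tot
  -sum(p * log2(p))
}

#' Lempel-Ziv match lengths of a symbol sequence
#'
#' For each position `j`, the length of the shortest substring starting at
#' `j` that does not occur as a contiguous substring of the prefix
#' `s[1..j-1]`. When even the full remaining suffix occurs in the prefix the
#' value is `n - j + 2`; the first position, with an empty prefix, gets 1.
#'
#' @param symbols atomic vector of symbols (no `NA`).
#' @return integer vector of match lengths, one per position.
#' @export
lz_match_lengths <- function(symbols) {
  if (anyNA(symbols)) stopf("symbols must not contain NA")
  n <- length(symbols)
  if (n == 0) return(integer(0))
  codes <- as.integer(factor(symbols, levels = unique(symbols))) - 1L
  lz_lambda_cpp(codes)
}

#' Lempel-Ziv estimate of the actual entropy rate
#'
#' Estimates the entropy rate of a symbolic sequence from its Lempel-Ziv
#' match lengths: `S_est = (n / sum(Lambda_j)) * log2(n)` bits, which
#' converges to the true entropy rate as the sequence length grows. The
#' estimate captures the full temporal order of the sequence, unlike the
#' random and uncorrelated entropies.
#'
#' @param symbols atomic vector; `NA` entries are treated as missing records.
#' @param drop_nulls if `TRUE` (default), `NA` entries are removed and the
#'   remaining symbols concatenated before estimation. Bias induced by
#'   missing records is the concern of the dedicated estimators
#'   ([estimate_H_shuff()], [estimate_H_unc()], [estimate_H_delta_e()]), not
#'   of this function.
#' @return estimated entropy rate in bits.
#' @export
lz_entropy_estimate <- function(symbols, drop_nulls = TRUE) {
  s <- seq_symbols(symbols)
  if (drop_nulls) s <- s[!is.na(s)]
  if (anyNA(s)) stopf("symbols contain NA; use drop_nulls = TRUE")
  n <- length(s)
  if (n < 2) stopf("need at least 2 symbols for the Lempel-Ziv estimator")
  lambda <- lz_match_lengths(s)
  (n / sum(lambda)) * log2(n)
}

#' Fano entropy of a prediction accuracy
#'
#' The right-hand side of Fano's inequality for accuracy `p` over `L`
#' locations, in bits:
#' `F(p) = -p log2 p - (1-p) log2(1-p) + (1-p) log2(L-1)`.
#' Strictly decreasing in `p` on `[1/L, 1]`, with `F(1/L) = log2 L` and
#' `F(1) = 0`.
#'
#' @param p accuracy in `[1/L, 1]`.
#' @param L number of distinct locations.
#' @return entropy in bits.
#' @export
fano_entropy <- function(p, L) {
  h <- function(z) ifelse(z <= 0 | z >= 1, 0, -z * log2(z) - (1 - z) * log2(1 - z))
  h(p) + (1 - p) * log2(pmax(L - 1, 1))
}

#' Solve Fano's inequality for the predictability bound
#'
#' Finds the unique accuracy `Pi` in `[1/L, 1]` with `fano_entropy(Pi, L)`
#' equal to the given entropy, by bisection on the strictly decreasing Fano
#' curve (converged when the entropy mismatch is below 1e-10 bits). All
#' entropies must be in bits: the logarithm base of the entropy and of the
#' Fano curve have to agree.
#'
#' Entropies above `log2(L)` can arise from estimator noise on short
#' sequences; they are clamped to the floor `1/L` and flagged via the
#' `"clamped"` attribute. `L = 1` returns 1 (a single location is always
#' predicted correctly).
#'
#' @param E entropy in bits, `>= 0`.
#' @param L number of distinct locations, `>= 1`.
#' @return predictability in `[1/L, 1]`, with attribute `clamped` (logical).
#' @export
solve_fano <- function(E, L) {
  if (length(E) != 1 || is.na(E)) stopf("E must be a single number")
  if (E < 0) stopf("E must be non-negative")
  if (L < 1) stopf("L must be >= 1")
  if (L == 1) return(structure(1, clamped = FALSE))
  if (E > log2(L)) return(structure(1 / L, clamped = TRUE))
  # F attains its maximum log2(L) flatly at Pi = 1/L; resolve the analytic
  # limit directly rather than bisecting through rounding noise.
  if (E >= log2(L) - 1e-12) return(structure(1 / L, clamped = FALSE))
  # Bisect on interval width, not on the entropy mismatch: the Fano curve is
  # flat at Pi = 1/L, so an f-value break would leave Pi imprecise there.
  lo <- 1 / L
  hi <- 1
  while (hi - lo > 1e-14) {
    mid <- (lo + hi) / 2
    if (fano_entropy(mid, L) > E) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, clamped = FALSE)
}

#' Entropies and predictability bounds of one sequence
#'
#' Computes the random, uncorrelated and Lempel-Ziv actual entropies of a
#' symbolic sequence (nulls dropped) and maps each through Fano's inequality
#' with the sequence's own number of distinct locations `L`. Degenerate
#' sequences — fewer than two non-null symbols — are completely predictable
#' by definition and are returned with all bounds equal to 1 and the
#' `degenerate` flag set.
#'
#' Note that `pi_unc <= pi_max` is only guaranteed asymptotically: on short
#' sequences the Lempel-Ziv estimate can exceed the uncorrelated entropy.
#'
#' @param seq a `time_bin_sequence`, `place_sequence`, or symbol vector
#'   (`NA` = null).
#' @return one-row data.frame: `n, L, s_rand, s_unc, s_est, pi_rand, pi_unc,
#'   pi_max, degenerate`.
#' @export
predictability_profile <- function(seq) {
  s <- seq_symbols(seq)
  s <- s[!is.na(s)]
  n <- length(s)
  if (n < 2) {
    return(data.frame(n = n, L = min(n, 1L), s_rand = 0, s_unc = 0,
                      s_est = NA_real_, pi_rand = 1, pi_unc = 1, pi_max = 1,
                      degenerate = TRUE))
  }
  cnt <- table(s)
  L <- length(cnt)
  s_rand <- random_entropy(L)
  s_unc <- uncorrelated_entropy(cnt)
  s_est <- lz_entropy_estimate(s, drop_nulls = FALSE)
  data.frame(
    n = n, L = L, s_rand = s_rand, s_unc = s_unc, s_est = s_est,
    pi_rand = as.numeric(solve_fano(s_rand, L)),
    pi_unc = as.numeric(solve_fano(s_unc, L)),
    pi_max = as.numeric(solve_fano(s_est, L)),
    degenerate = FALSE
  )
}

#' Exact entropy rate of a Markov chain
#'
#' Closed form `H = -sum_i pi_i sum_j P_ij log2 P_ij` with `pi` the
#' stationary distribution; used as an oracle when validating the Lempel-Ziv
#' estimator. Chains whose rows are all deterministic (for example the
#' identity) have rate 0 regardless of irreducibility; otherwise a unique
#' stationary distribution is required.
#'
#' @param transition_matrix row-stochastic matrix.
#' @return entropy rate in bits per symbol.
#' @export
markov_entropy_rate <- function(transition_matrix) {
  P <- as.matrix(transition_matrix)
  check_stochastic(P)
  row_h <- apply(P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  if (all(row_h < 1e-14)) return(0)
  pi <- stationary_distribution(P)
  sum(pi * row_h)
}
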