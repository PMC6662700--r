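# Choice entropy: cumulative Shannon entropy of a vessel's visitation series.

#' Choice-entropy trajectory of a visitation sequence
#'
#' For each prefix of length m of the chronologically ordered cell sequence,
#' computes the Shannon entropy (base 2) of the empirical location
#' frequencies: `S_m = -sum_j f(j) log2 f(j)`, where f(j) is the frequency
#' of location j among the first m elements. The trajectory typically rises
#' while new locations are discovered and plateaus as the vessel's choice
#' distribution stabilizes.
#'
#' @param cells nonempty vector of cell identifiers, in visit order.
#' @return tibble with `m` (prefix length), `S` (bits) and `N` (unique
#'   locations in the prefix).
#' @export
entropy_trajectory <- function(cells) {
  if (length(cells) == 0) stop("empty visitation sequence", call. = FALSE)
  ids <- as.integer(factor(cells))
  n <- length(ids)
  counts <- integer(max(ids))
  S <- numeric(n); N <- integer(n)
  for (m in seq_len(n)) {
    counts[ids[m]] <- counts[ids[m]] + 1L
    p <- counts[counts > 0L] / m
    S[m] <- -sum(p * log2(p))
    N[m] <- length(p)
  }
  tibble::tibble(m = seq_len(n), S = S, N = N)
}

#' Choice-entropy score (post-burn-in mean)
#'
#' The strategy score is the mean of the entropy trajectory after discarding
#' a burn-in prefix: values at positions `m > floor(length * burn_in)` are
#' averaged, so an even-length trajectory contributes exactly its second
#' half.
#'
#' @param trajectory an [entropy_trajectory()] result (or numeric vector of
#'   S values).
#' @param burn_in fraction of the trajectory discarded as burn-in.
#' @return score in bits; `NA` (with a warning) for trajectories shorter
#'   than 2, which are flagged for exclusion.
#' @export
entropy_score <- function(trajectory, burn_in = 0.5) {
  s <- if (is.data.frame(trajectory)) trajectory$S else as.numeric(trajectory)
  n <- length(s)
  if (n < 2) {
    warning("trajectory shorter than 2; vessel flagged for exclusion")
    return(NA_real_)
  }
  mean(s[seq.int(floor(n * burn_in) + 1L, n)])
}
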