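# Anti-clustering restraint. Without it, optimization tends to overpopulate
# helices with runs of alanine and strands with blocks of isoleucine/valine.
# The statistic is a one-sided z-score of adjacent same-class pair counts
# against the fixed-composition permutation null: only excess clustering is
# penalized, never dispersion.

# Closed-form mean and variance of the number of adjacent same-class pairs
# for a class with n members in a uniformly random permutation of length L.
adjacent_pair_null <- function(n, L) {
  m <- L - 1
  if (n < 2 || L < 4) {
    # exact small cases: n<2 gives O=0 surely; L<4 handled by the caller's
    # Monte Carlo fallback if ever needed
    return(list(mean = if (n >= 2) m * n * (n - 1) / (L * (L - 1)) else 0,
                var = 0))
  }
  p2 <- n * (n - 1) / (L * (L - 1))
  p3 <- p2 * (n - 2) / (L - 2)
  p4 <- p3 * (n - 3) / (L - 3)
  e <- m * p2
  e2 <- m * p2 + 2 * ((m - 1) * p3 + (choose(m, 2) - (m - 1)) * p4)
  list(mean = e, var = e2 - e^2)
}

# Observed adjacent same-class pair counts per class (window k: pairs up to k
# apart all count as "adjacent").
observed_adjacent <- function(cls, window = 1L) {
  L <- length(cls)
  O <- numeric(7)
  for (k in seq_len(window)) {
    if (L <= k) break
    same <- cls[seq_len(L - k)] == cls[(k + 1):L]
    t <- tabulate(cls[seq_len(L - k)][same], nbins = 7)
    O <- O + t
  }
  O
}

#' Per-class clustering statistics under the permutation null
#'
#' For each residue class: the observed count of adjacent same-class pairs
#' `O_c`, its expectation `E_c = n_c (n_c - 1) / L` and variance `V_c` under
#' uniformly random permutation of the fixed composition, and the z-score
#' `z_c = (O_c - E_c) / sqrt(V_c)`. With `method = "mc"` (or automatically
#' when the closed form degenerates at window > 1) the null moments come from
#' Monte Carlo permutations.
#'
#' @param seq sequence string (length >= 3)
#' @param class_map residue-class map
#' @param window pairs up to this many positions apart count as adjacent
#'   (default 1: immediate neighbours)
#' @param method `"closed_form"` (exact, window 1) or `"mc"`
#' @param n_perm Monte Carlo permutations for `method = "mc"`
#' @param rng stream for the Monte Carlo fallback
#' @return data frame with one row per class: `class`, `n`, `observed`,
#'   `expected`, `variance`, `z`
#' @export
clustering_stats <- function(seq, class_map = default_class_map(), window = 1L,
                             method = c("closed_form", "mc"), n_perm = 10000L,
                             rng = NULL) {
  method <- match.arg(method)
  cls <- class_index(seq, class_map)
  L <- length(cls)
  if (L < 3L) {
    stop_seqevolve("clustering statistic needs L >= 3", "seqevolve_degenerate_error")
  }
  if (window > 1L && method == "closed_form") method <- "mc"
  n_c <- tabulate(cls, nbins = 7)
  O <- observed_adjacent(cls, window)
  if (method == "closed_form") {
    mom <- lapply(n_c, adjacent_pair_null, L = L)
    E <- vapply(mom, `[[`, numeric(1), "mean")
    V <- vapply(mom, `[[`, numeric(1), "var")
  } else {
    if (is.null(rng)) rng <- mt_rng(5489L)
    Om <- matrix(0, n_perm, 7)
    x <- cls
    for (p in seq_len(n_perm)) {
      for (i in L:2) { # Fisher-Yates on the class vector
        j <- rng_int(rng, 1L, i)
        tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
      }
      Om[p, ] <- observed_adjacent(x, window)
    }
    E <- colMeans(Om)
    V <- apply(Om, 2, stats::var)
  }
  z <- ifelse(V > 1e-12, (O - E) / sqrt(V), 0)
  data.frame(class = CLASS_NAMES, n = n_c, observed = O, expected = E,
             variance = V, z = z, stringsAsFactors = FALSE)
}

#' Anti-clustering penalty
#'
#' Sum over classes of the positive part of the clustering z-score:
#' `penalty = sum_c max(0, z_c)`. Zero for sequences with no excess of
#' adjacent same-class pairs over the fixed-composition permutation null
#' (a homopolymer scores 0, since a one-class composition cannot show
#' excess).
#'
#' @inheritParams clustering_stats
#' @return non-negative penalty
#' @export
clustering_penalty <- function(seq, class_map = default_class_map(), window = 1L,
                               method = c("closed_form", "mc"), n_perm = 10000L,
                               rng = NULL) {
  st <- clustering_stats(seq, class_map, window, method, n_perm, rng)
  sum(pmax(0, st$z))
}
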