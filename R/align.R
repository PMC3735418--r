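# Structural alignment: least-squares (Kabsch) superposition, TM-score with
# iterative superposition refinement, and a TM-align-style heuristic aligner
# (gapless-threading and secondary-structure seeds, then alternating
# superposition / dynamic programming on the distance-derived score matrix).

#' Optimal rigid superposition of paired coordinates
#'
#' Least-squares (Kabsch) fit of `coordsB` onto `coordsA` over paired rows.
#' Always returns a proper rotation (determinant +1).
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates, n >= 3 and not
#'   collinear
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`, and
#'   `transform(x)` applying the fit to any m x 3 matrix
#' @export
superpose <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  n <- nrow(A)
  if (n < 3L || nrow(B) != n) {
    stop_seqevolve("superposition needs >= 3 paired coordinates",
                   "seqevolve_degenerate_error")
  }
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  M <- crossprod(Bc, Ac) # maximize tr(R' M) over rotations R
  s <- svd(M)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    stop_seqevolve("degenerate (collinear) geometry in superposition",
                   "seqevolve_degenerate_error")
  }
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- cA - as.numeric(cB %*% R)
  fitted <- Bc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Ac)^2)))
  transform <- function(x) sweep(as.matrix(x) %*% R, 2, t_vec, `+`)
  list(rotation = R, translation = t_vec, rmsd = rmsd, transform = transform)
}

#' TM-score normalisation distance d0
#' @param L_target target length used for normalisation
#' @return d0 in Angstrom, floored at 0.5
#' @export
tm_d0 <- function(L_target) {
  if (L_target > 15) max(0.5, 1.24 * (L_target - 15)^(1 / 3) - 1.8) else 0.5
}

#' TM-score of an alignment
#'
#' `TM = (1/L_target) * sum_i 1 / (1 + (d_i/d0)^2)` over aligned pairs. With
#' `optimize = TRUE` (default) the superposition maximizing the score is
#' searched iteratively: superpose on the current close-pair subset, rescore
#' all pairs, re-select pairs within a distance cut, repeat to convergence
#' from several seed subsets. With `optimize = FALSE` the coordinates are
#' scored as given (no superposition).
#'
#' @param pairs 2-column matrix of aligned indices (i in A, j in B)
#' @param coordsA,coordsB full coordinate matrices of the two structures
#' @param L_target normalisation length (the target's)
#' @param optimize search for the score-maximizing superposition
#' @return list with `score` in [0,1], `rmsd` over all aligned pairs, and the
#'   final `transform`
#' @export
tm_score <- function(pairs, coordsA, coordsB, L_target, optimize = TRUE) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) {
    stop_seqevolve("alignment is empty", "seqevolve_usage_error")
  }
  d0 <- tm_d0(L_target)
  A <- as.matrix(coordsA)[pairs[, 1], , drop = FALSE]
  B <- as.matrix(coordsB)[pairs[, 2], , drop = FALSE]
  n <- nrow(A)

  score_of <- function(d) sum(1 / (1 + (d / d0)^2)) / L_target

  if (!optimize) {
    d <- sqrt(rowSums((B - A)^2))
    return(list(score = score_of(d), rmsd = sqrt(mean(d^2)), transform = identity))
  }

  # seed subsets: all pairs plus sliding windows at two scales
  seeds <- list(seq_len(n))
  for (len in unique(pmax(4L, c(n %/% 2L, n %/% 4L)))) {
    if (len >= n || len < 4L) next
    starts <- unique(c(seq(1L, n - len + 1L, by = max(1L, len %/% 2L)), n - len + 1L))
    for (st in starts) seeds <- c(seeds, list(st:(st + len - 1L)))
  }

  best <- list(score = -Inf, rmsd = NA_real_, transform = NULL)
  for (sub in seeds) {
    if (length(sub) < 3L) next
    for (iter in seq_len(20L)) {
      sup <- tryCatch(superpose(A[sub, , drop = FALSE], B[sub, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sup)) break
      Bt <- sup$transform(B)
      d <- sqrt(rowSums((Bt - A)^2))
      sc <- score_of(d)
      if (sc > best$score) {
        best <- list(score = sc, rmsd = sqrt(mean(d^2)), transform = sup$transform)
      }
      dcut <- d0
      repeat {
        newsub <- which(d < dcut)
        if (length(newsub) >= 3L) break
        dcut <- dcut + 0.5
      }
      if (identical(newsub, sub)) break
      sub <- newsub
    }
  }
  best$score <- min(best$score, 1.0)
  best
}

# Gapless-threading seed pair sets for two chains of lengths la, lb.
threading_seeds <- function(la, lb, step = 1L) {
  min_overlap <- max(8L, min(la, lb) %/% 2L)
  offsets <- seq(-(la - min_overlap), lb - min_overlap, by = step)
  out <- list()
  for (off in offsets) {
    i <- seq_len(la)
    j <- i + off
    ok <- j >= 1L & j <= lb
    if (sum(ok) >= min_overlap) out <- c(out, list(cbind(i[ok], j[ok])))
  }
  out
}

#' Align two structures, maximizing TM-score
#'
#' A TM-align-style heuristic: seed alignments come from gapless threading at
#' all offsets and from dynamic programming on secondary-structure identity;
#' each seed is refined by alternating (i) superposition on the current pairs
#' and (ii) global dynamic programming on the score matrix
#' `1 / (1 + (d_ij/d0)^2)` with a linear gap penalty, until the aligned set is
#' stable (at most `max_iter` rounds). The best result by TM-score
#' (normalized by the target length) is returned. Fully deterministic.
#'
#' @param target,analog `structure3d` objects (both length >= 10)
#' @param gap gap penalty for the DP step (default -0.6)
#' @param max_iter maximum refinement rounds per seed
#' @param seed_step offset stride for the threading seeds (1 = all offsets)
#' @return object of class `struct_alignment`: `pairs` (2-column index
#'   matrix), `tm_score` (normalized by target length), `rmsd` (Calpha RMSD
#'   over aligned pairs)
#' @export
align_structures <- function(target, analog, gap = -0.6, max_iter = 30L,
                             seed_step = 1L) {
  A <- target$ca; B <- analog$ca
  la <- nrow(A); lb <- nrow(B)
  if (la < 10L || lb < 10L) {
    stop_seqevolve("alignment needs chains of >= 10 residues",
                   "seqevolve_degenerate_error")
  }
  d0 <- tm_d0(la)

  seeds <- threading_seeds(la, lb, step = seed_step)
  ss_seed <- {
    S <- outer(target$ss, analog$ss, `==`) * 1.0
    p <- nw_pairs_(S, gap)
    if (length(p$i) >= 3L) list(cbind(p$i, p$j)) else list()
  }
  seeds <- c(seeds, ss_seed)

  quick_tm <- function(pairs) {
    # score pairs under superposition on the pairs themselves (one pass)
    sup <- tryCatch(superpose(A[pairs[, 1], , drop = FALSE],
                              B[pairs[, 2], , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sup)) return(NULL)
    Bt <- sup$transform(B)
    d <- sqrt(rowSums((Bt[pairs[, 2], , drop = FALSE] -
                       A[pairs[, 1], , drop = FALSE])^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / la, sup = sup)
  }

  best_pairs <- NULL; best_quick <- -Inf
  for (seed in seeds) {
    pairs <- seed
    prev_key <- ""
    for (iter in seq_len(max_iter)) {
      qt <- quick_tm(pairs)
      if (is.null(qt)) break
      if (qt$score > best_quick) { best_quick <- qt$score; best_pairs <- pairs }
      Bt <- qt$sup$transform(B)
      D2 <- outer(rowSums(A^2), rep(1, lb)) + outer(rep(1, la), rowSums(Bt^2)) -
        2 * A %*% t(Bt)
      S <- 1 / (1 + pmax(D2, 0) / d0^2)
      p <- nw_pairs_(S, gap)
      pairs <- cbind(p$i, p$j)
      if (nrow(pairs) < 3L) break
      key <- paste(pairs[, 1], pairs[, 2], collapse = ";")
      if (identical(key, prev_key)) break
      prev_key <- key
    }
  }
  if (is.null(best_pairs)) {
    stop_seqevolve("no viable alignment found (degenerate geometry?)",
                   "seqevolve_degenerate_error")
  }
  final <- tm_score(best_pairs, A, B, la, optimize = TRUE)
  res <- list(pairs = best_pairs, tm_score = final$score, rmsd = final$rmsd,
              target_id = target$id, analog_id = analog$id)
  class(res) <- "struct_alignment"
  res
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf("<struct_alignment> %s vs %s: %d pairs, TM-score %.3f, RMSD %.2f A\n",
              x$target_id, x$analog_id, nrow(x$pairs), x$tm_score, x$rmsd))
  invisible(x)
}
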