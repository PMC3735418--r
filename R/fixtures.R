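# Synthetic structure and sequence generators. These provide idealized
# helices, antiparallel sheet pairs and jittered libraries with native-like
# sequences, so potential derivation, profile building and annealing are all
# testable without downloading a single structure. Geometry uses ideal
# secondary-structure parameters; it is meant to exercise distance binning,
# burial counting and alignment, not to be physically realistic.

# Approximate distance (A) from Cbeta to the side-chain centroid, by residue.
SC_EXTENSION <- c(A = 0.0, C = 0.9, D = 1.3, E = 1.6, F = 1.9, G = 0.0,
                  H = 1.6, I = 1.4, K = 1.9, L = 1.4, M = 1.7, N = 1.3,
                  P = 0.9, Q = 1.6, R = 2.3, S = 0.8, T = 0.9, V = 1.1,
                  W = 2.4, Y = 2.1)

# Draw a native-like sequence: a fixed positional base pattern (shared by all
# fixtures of the same kind, giving structure-based profiles a positional
# signal) with seeded substitutions from a biased composition.
biased_native <- function(L, rng, pattern, bias, p_sub = 0.3) {
  base <- rep(pattern, length.out = L)
  u <- rng_unif(rng, L)
  sub <- u < p_sub
  repl <- AA_CODES[rng_categorical(rng, L, bias)]
  out <- ifelse(sub, repl, base)
  paste(out, collapse = "")
}

helix_bias <- function() {
  f <- aa_frequencies()
  f[c("A", "L", "E", "K")] <- f[c("A", "L", "E", "K")] * 4
  f / sum(f)
}

strand_bias <- function() {
  f <- aa_frequencies()
  f[c("V", "I", "T", "Y")] <- f[c("V", "I", "T", "Y")] * 4
  f / sum(f)
}

# Place Cbeta and side-chain centroid along given unit directions.
place_side_chains <- function(aa, ca, dir) {
  L <- length(aa)
  cb <- ca + 1.53 * dir
  ext <- SC_EXTENSION[aa] + 0.8 # centroid 0.8-2.5 A beyond Cbeta
  sc <- cb + ext * dir
  gly <- aa == "G"
  cb[gly, ] <- ca[gly, ]
  sc[gly, ] <- ca[gly, ]
  list(cb = cb, sc = sc)
}

#' Generate an ideal alpha-helix fixture
#'
#' Calpha trace on a helix of radius 2.3 A, rise 1.5 A and 100 degrees per
#' residue (consecutive Calpha distance about 3.8 A); Cbeta 1.53 A radially
#' outward from Calpha, side-chain centroid 0.8-2.5 A beyond Cbeta depending
#' on residue type; all residues labelled H. The native sequence is
#' helix-biased (enriched in A/L/E/K over a positional base pattern) and
#' depends only on the seed; the geometry depends on the sequence only through
#' glycine and centroid extensions.
#'
#' @param n_res number of residues (>= 10)
#' @param seed integer seed for the native sequence
#' @return list with elements `structure` (a `structure3d`) and `sequence`
#' @export
make_helix <- function(n_res, seed = 1L) {
  if (n_res < 10L) {
    stop_seqevolve("helix fixture needs n_res >= 10", "seqevolve_degenerate_error")
  }
  rng <- mt_rng(seed)
  seq <- biased_native(n_res, rng, pattern = c("A", "L", "E", "K"),
                       bias = helix_bias())
  aa <- seq_chars(seq)
  i <- seq_len(n_res) - 1L
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  dir <- cbind(cos(theta), sin(theta), 0) # radially outward
  sidec <- place_side_chains(aa, ca, dir)
  st <- new_structure(sprintf("helix%d_s%d", n_res, seed), aa, ca,
                      sidec$cb, sidec$sc, ss = rep("H", n_res))
  list(structure = st, sequence = seq)
}

#' Generate an antiparallel two-strand sheet fixture
#'
#' Two antiparallel strands 4.8 A apart (rise 3.3 A per residue, pleat
#' alternating +-0.4 A in z) joined by a 4-residue turn; strand residues
#' labelled E, turn residues C. The native sequence is strand-biased
#' (enriched in V/I/T/Y). Geometry is seed-free; only the sequence is seeded.
#'
#' @param n_res_per_strand residues per strand (>= 5)
#' @param seed integer seed for the native sequence
#' @return list with elements `structure` and `sequence`
#' @export
make_sheet_pair <- function(n_res_per_strand, seed = 1L) {
  n <- n_res_per_strand
  if (n < 5L) {
    stop_seqevolve("sheet fixture needs n_res_per_strand >= 5",
                   "seqevolve_degenerate_error")
  }
  rng <- mt_rng(seed)
  L <- 2L * n + 4L
  seq <- biased_native(L, rng, pattern = c("V", "I", "T", "Y"),
                       bias = strand_bias())
  aa <- seq_chars(seq)

  i <- seq_len(n) - 1L
  pleat <- 0.4 * (-1)^i
  s1 <- cbind(rep(0, n), 3.3 * i, pleat)              # strand 1, +y
  s2 <- cbind(rep(4.8, n), 3.3 * rev(i), pleat)       # strand 2, -y (antiparallel)
  ymax <- 3.3 * (n - 1)
  turn <- rbind(c(0.0, ymax + 3.0, 1.0),
                c(0.8, ymax + 5.8, 2.0),
                c(4.0, ymax + 5.8, 2.0),
                c(4.8, ymax + 3.0, 1.0))
  ca <- rbind(s1, turn, s2)
  # side chains point along +-z, opposite to the local pleat
  dirz <- c(-sign(pleat), c(1, 1, 1, 1), -sign(pleat))
  dir <- cbind(0, 0, dirz)
  sidec <- place_side_chains(aa, ca, dir)
  ss <- c(rep("E", n), rep("C", 4), rep("E", n))
  st <- new_structure(sprintf("sheet%d_s%d", n, seed), aa, ca,
                      sidec$cb, sidec$sc, ss = ss)
  list(structure = st, sequence = seq)
}

#' Generate a synthetic reference library
#'
#' A mixture of coordinate-jittered helices and sheet pairs with native-like
#' sequences. The library doubles as the reference set for deriving the
#' statistical potentials and as the analog library for structure-based
#' profile construction.
#'
#' @param n_structures number of members (>= 2)
#' @param seed integer seed (drives jitter and member sequences)
#' @param n_res approximate member length (helices get exactly `n_res`; sheet
#'   pairs get the nearest realizable length)
#' @param kinds which fixture kinds to cycle through: subset of
#'   `c("helix", "sheet")`
#' @param jitter_sd coordinate jitter standard deviation (A), default 0.3
#' @return list of members, each a list with `structure` and `sequence`
#' @export
make_library <- function(n_structures, seed = 1L, n_res = 60L,
                         kinds = c("helix", "sheet"), jitter_sd = 0.3) {
  if (n_structures < 2L) {
    stop_seqevolve("library needs at least 2 structures", "seqevolve_degenerate_error")
  }
  kinds <- match.arg(kinds, several.ok = TRUE)
  rng <- mt_rng(seed)
  members <- vector("list", n_structures)
  for (m in seq_len(n_structures)) {
    kind <- kinds[((m - 1L) %% length(kinds)) + 1L]
    member_seed <- seed * 1000L + m
    fx <- if (kind == "helix") {
      make_helix(n_res, seed = member_seed)
    } else {
      make_sheet_pair(max(5L, (n_res - 4L) %/% 2L), seed = member_seed)
    }
    st <- fx$structure
    L <- st$L
    jit <- function(x) x + jitter_sd * matrix(rng_norm(rng, 3L * L), ncol = 3)
    st$ca <- jit(st$ca); st$cb <- jit(st$cb); st$sc <- jit(st$sc)
    st$id <- sprintf("lib%02d_%s", m, kind)
    members[[m]] <- list(structure = st, sequence = fx$sequence)
  }
  members
}

#' Draw a random protein-like sequence
#'
#' Independent draws from a background amino-acid composition (the bundled
#' Swiss-Prot table by default) using the shared MT19937 stream. This is the
#' recommended start for sequence evolution on real targets.
#'
#' @param L sequence length (>= 1)
#' @param table named frequency vector over [AA_CODES]
#' @param rng an [mt_rng()] stream
#' @return sequence string of length `L`
#' @export
random_sequence <- function(L, table = aa_frequencies(), rng) {
  if (L < 1L) stop_seqevolve("L must be >= 1", "seqevolve_usage_error")
  idx <- rng_categorical(rng, L, table[AA_CODES])
  int_to_seq(idx)
}

#' Shuffle a sequence, preserving its composition exactly
#'
#' Fisher-Yates permutation driven by the shared MT19937 stream. The residue
#' multiset of the output is identical to the input; useful as a
#' composition-preserving decoy or benchmark start.
#'
#' @param seq sequence string (length >= 2)
#' @param rng an [mt_rng()] stream
#' @return shuffled sequence string
#' @export
shuffle_sequence <- function(seq, rng) {
  x <- seq_chars(seq)
  L <- length(x)
  if (L < 2L) stop_seqevolve("need at least 2 residues to shuffle",
                             "seqevolve_usage_error")
  for (i in L:2) {
    j <- rng_int(rng, 1L, i)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  paste(x, collapse = "")
}
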