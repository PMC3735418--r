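# Structure-conditioned statistical potentials: Cbeta-neighbour burial,
# secondary-structure preferences, and the distance-dependent contact
# potential with a distance-scaled finite ideal-gas (DFIRE) reference state.
# All tables are log-odds with +1 pseudocounts so that small reference sets
# never produce infinities.

# ---- burial ---------------------------------------------------------------

#' Cbeta neighbour counts
#'
#' For each residue, the number of other residues whose Cbeta lies within
#' `radius` of this residue's Cbeta (glycine uses Calpha).
#'
#' @param structure a `structure3d`
#' @param radius neighbour cutoff in Angstrom (default 14)
#' @return integer vector of counts
#' @export
burial_counts <- function(structure, radius = 14) {
  d <- as.matrix(stats::dist(structure$cb))
  as.integer(colSums(d < radius) - 1L)
}

#' Discretize burial into states
#'
#' Neighbour counts are mapped to burial states by the model's bin edges
#' (equal-frequency boundaries derived from the reference set); the default
#' alphabet has 7 states over a 14 A Cbeta neighbourhood.
#'
#' @param structure a `structure3d`
#' @param model a `burial_model` from [derive_burial()]
#' @return integer vector of states in 1..n_states
#' @export
burial_states <- function(structure, model) {
  counts <- burial_counts(structure, model$radius)
  findInterval(counts, model$bin_edges) + 1L
}

# Log-odds table from a state x amino-acid count matrix:
# E(s,a) = -ln[(N(s,a)+1) / (N(s) * f(a) + 1)]
log_odds_table <- function(N) {
  state_tot <- rowSums(N)
  f <- colSums(N) / max(sum(N), 1)
  expected <- outer(state_tot, f)
  -log((N + 1) / (expected + 1))
}

#' Derive a burial potential from a reference set
#'
#' Bin edges are the equal-frequency (quantile) boundaries of Cbeta
#' neighbour counts over the reference set; the pseudo-energy table is the
#' negative log-odds of observing amino acid `a` in burial state `s` against
#' its overall frequency, with +1 pseudocounts.
#'
#' @param refset list of members, each `list(structure=, sequence=)`
#' @param radius neighbour cutoff (A)
#' @param n_states number of burial states (default 7)
#' @return object of class `burial_model` with `radius`, `n_states`,
#'   `bin_edges` and the states x 20 `table`
#' @export
derive_burial <- function(refset, radius = 14, n_states = 7L) {
  if (length(refset) < 2L) {
    stop_seqevolve("burial derivation needs at least 2 structures",
                   "seqevolve_derivation_error")
  }
  counts_all <- integer(0); aa_all <- integer(0)
  for (m in refset) {
    counts_all <- c(counts_all, burial_counts(m$structure, radius))
    aa_all <- c(aa_all, seq_to_int(m$sequence))
  }
  probs <- seq_len(n_states - 1L) / n_states
  edges <- unique(as.numeric(stats::quantile(counts_all, probs, type = 1)))
  states <- findInterval(counts_all, edges) + 1L
  n_eff <- length(edges) + 1L
  N <- matrix(0, n_eff, 20, dimnames = list(NULL, AA_CODES))
  for (k in seq_along(states)) N[states[k], aa_all[k]] <- N[states[k], aa_all[k]] + 1
  structure(list(radius = radius, n_states = n_eff, bin_edges = edges,
                 table = log_odds_table(N)),
            class = "burial_model")
}

#' Evaluate the burial term
#' @param seq sequence string
#' @param structure a `structure3d`
#' @param model a `burial_model`
#' @return raw pseudo-energy (lower is more native-like)
#' @export
evaluate_burial <- function(seq, structure, model) {
  aa <- seq_to_int(seq)
  if (length(aa) != structure$L) {
    stop_seqevolve("sequence length does not match structure",
                   "seqevolve_consistency_error")
  }
  st <- burial_states(structure, model)
  sum(model$table[cbind(st, aa)])
}

# ---- secondary-structure preferences --------------------------------------

#' Derive secondary-structure preferences from a reference set
#'
#' Same log-odds construction as the burial term, with the 7 STRIDE states
#' in place of burial states.
#'
#' @inheritParams derive_burial
#' @return object of class `ss_model` with the 7 x 20 `table`
#' @export
derive_ss <- function(refset) {
  if (length(refset) < 2L) {
    stop_seqevolve("SS derivation needs at least 2 structures",
                   "seqevolve_derivation_error")
  }
  N <- matrix(0, 7, 20, dimnames = list(SS_STATES, AA_CODES))
  for (m in refset) {
    s <- match(m$structure$ss, SS_STATES)
    a <- seq_to_int(m$sequence)
    for (k in seq_along(s)) N[s[k], a[k]] <- N[s[k], a[k]] + 1
  }
  structure(list(table = log_odds_table(N)), class = "ss_model")
}

#' Evaluate the secondary-structure term
#' @param seq sequence string
#' @param ss secondary-structure labels (length must match)
#' @param model an `ss_model`
#' @return raw pseudo-energy (lower is more native-like)
#' @export
evaluate_ss <- function(seq, ss, model) {
  aa <- seq_to_int(seq)
  if (length(aa) != length(ss)) {
    stop_seqevolve("sequence and secondary structure differ in length",
                   "seqevolve_consistency_error")
  }
  s <- match(ss, SS_STATES)
  sum(model$table[cbind(s, aa)])
}

# ---- distance-dependent contact potential (DFIRE reference state) ---------

contact_coords <- function(structure, atom_mode) {
  switch(atom_mode, CA = structure$ca, SC = structure$sc,
         stop_seqevolve("atom_mode must be 'CA' or 'SC'", "seqevolve_usage_error"))
}

# Pair list (i, j, bin) for |i-j| >= min_seq_sep and d < r_cut.
contact_pairs <- function(structure, atom_mode, bin_width = 0.5,
                          r_cut = 14.5, min_seq_sep = 2L) {
  xyz <- contact_coords(structure, atom_mode)
  d <- as.matrix(stats::dist(xyz))
  L <- nrow(xyz)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1] >= min_seq_sep) & (d[idx] < r_cut)
  i <- idx[keep, 1]; j <- idx[keep, 2]
  bin <- pmin(floor(d[cbind(i, j)] / bin_width) + 1L,
              as.integer(ceiling(r_cut / bin_width)))
  list(i = i, j = j, bin = as.integer(bin))
}

#' Derive a distance-dependent contact potential
#'
#' Counts residue-pair distances (Calpha or side-chain centroid mode) in
#' `bin_width` shells up to the reference distance `r_cut`, then converts them
#' to pseudo-energies against the distance-scaled finite ideal-gas reference
#' state: `E(a,b,r) = -ln[ N(a,b,r) / ((r/r_ref)^alpha * N(a,b,r_ref)) ]`
#' with `alpha = 1.61`, +1 pseudocounts on all counts, and the outermost bin
#' as the reference shell (energy 0 there by construction, and 0 beyond
#' `r_cut`). The table is symmetric in the two amino acids. Only pairs with
#' sequence separation `|i-j| >= min_seq_sep` are counted.
#'
#' @param refset list of members, each `list(structure=, sequence=)`
#' @param atom_mode `"CA"` or `"SC"`
#' @param bin_width shell width in Angstrom
#' @param min_seq_sep minimum sequence separation for a pair to count
#' @param r_cut reference distance (A)
#' @param alpha distance-scaling exponent
#' @return object of class `contact_model`
#' @export
derive_contact <- function(refset, atom_mode = c("CA", "SC"), bin_width = 0.5,
                           min_seq_sep = 2L, r_cut = 14.5, alpha = 1.61) {
  atom_mode <- match.arg(atom_mode)
  if (length(refset) < 2L) {
    stop_seqevolve("contact derivation needs at least 2 structures",
                   "seqevolve_derivation_error")
  }
  n_bins <- as.integer(ceiling(r_cut / bin_width))
  N <- array(0, dim = c(20, 20, n_bins),
             dimnames = list(AA_CODES, AA_CODES, NULL))
  for (m in refset) {
    aa <- seq_to_int(m$sequence)
    cp <- contact_pairs(m$structure, atom_mode, bin_width, r_cut, min_seq_sep)
    for (k in seq_along(cp$i)) {
      a <- aa[cp$i[k]]; b <- aa[cp$j[k]]; bn <- cp$bin[k]
      N[a, b, bn] <- N[a, b, bn] + 1
      N[b, a, bn] <- N[b, a, bn] + 1
    }
  }
  N <- N + 1 # pseudocount
  mids <- (seq_len(n_bins) - 0.5) * bin_width
  r_ref <- mids[n_bins]
  E <- array(0, dim = dim(N), dimnames = dimnames(N))
  for (bn in seq_len(n_bins)) {
    expected <- (mids[bn] / r_ref)^alpha * N[, , n_bins]
    E[, , bn] <- -log(N[, , bn] / expected)
  }
  structure(list(atom_mode = atom_mode, r_cut = r_cut, alpha = alpha,
                 bin_width = bin_width, min_seq_sep = as.integer(min_seq_sep),
                 n_bins = n_bins, counts = N, energies = E),
            class = "contact_model")
}

#' Evaluate the contact term
#'
#' Sum of pair energies over all residue pairs with sequence separation at
#' least `min_seq_sep` and distance under the reference cutoff, using the
#' coordinates selected by the model's atom mode.
#'
#' @param seq sequence string
#' @param structure a `structure3d`
#' @param model a `contact_model`
#' @param pairs optional precomputed pair list from the internal pair finder
#'   (used by the annealer's cached path)
#' @return raw pseudo-energy (lower is more native-like)
#' @export
evaluate_contact <- function(seq, structure, model, pairs = NULL) {
  aa <- seq_to_int(seq)
  if (is.null(pairs)) {
    pairs <- contact_pairs(structure, model$atom_mode, model$bin_width,
                           model$r_cut, model$min_seq_sep)
  }
  if (!length(pairs$i)) return(0)
  sum(model$energies[cbind(aa[pairs$i], aa[pairs$j], pairs$bin)])
}

# ---- length-independence transform ----------------------------------------

#' Fit a linear length transform for a raw term
#'
#' Regresses the mean raw energy of random background sequences against chain
#' length over fixtures of at least three distinct lengths; subtracting the
#' fitted line makes the term's random-sequence mean independent of protein
#' length.
#'
#' @param term_fn function `(seq, structure) -> raw energy`
#' @param fixtures named list of `structure3d` keyed by anything; at least 3
#'   distinct lengths
#' @param rng an [mt_rng()] stream
#' @param n_random random sequences per length (default 100)
#' @param freq background composition for the random sequences
#' @return object of class `length_transform` with `slope` and `intercept`
#' @export
fit_length_transform <- function(term_fn, fixtures, rng, n_random = 100L,
                                 freq = aa_frequencies()) {
  lengths <- vapply(fixtures, function(s) s$L, numeric(1))
  if (length(unique(lengths)) < 3L) {
    stop_seqevolve("length transform needs fixtures of >= 3 distinct lengths",
                   "seqevolve_derivation_error")
  }
  means <- vapply(fixtures, function(s) {
    mean(vapply(seq_len(n_random), function(k) {
      term_fn(random_sequence(s$L, freq, rng), s)
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(means ~ lengths)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
            class = "length_transform")
}

#' Apply a length transform to a raw term value
#' @param raw raw term value
#' @param L chain length
#' @param lt a `length_transform`
#' @return transformed value (random-sequence mean approximately 0 at any L)
#' @export
apply_length_transform <- function(raw, L, lt) {
  raw - (lt$slope * L + lt$intercept)
}
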