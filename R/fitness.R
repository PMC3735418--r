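# Combined fitness: the five structure-conditioned terms (burial, secondary
# structure, two contact flavours, profile) plus the anti-clustering
# restraint are z-normalized per target against random background sequences,
# oriented so that native-favouring is positive, and combined as
# fitness = 1 + sum_t w_t z_t. Random sequences therefore score about 1.0 by
# construction, and the weights form a convex combination.

TERM_NAMES <- c("burial", "ss", "contact_ca", "contact_sc", "profile", "antigroup")
TERM_ORIENT <- c(burial = -1, ss = -1, contact_ca = -1, contact_sc = -1,
                 profile = 1, antigroup = -1)

#' Derive the full potential set from a reference library
#'
#' Bundles the burial model, secondary-structure preferences and both contact
#' models (Calpha and side-chain centroid), derived from the same reference
#' set, together with the residue-class map and background composition. The
#' potential set is target-independent; combine it with a target structure and
#' profile via [build_energy_model()].
#'
#' @param refset list of members, each `list(structure=, sequence=)`
#' @param class_map residue-class map
#' @param freq background composition
#' @param min_seq_sep,bin_width contact model parameters
#' @return object of class `potential_set`
#' @export
derive_potentials <- function(refset, class_map = default_class_map(),
                              freq = aa_frequencies(), min_seq_sep = 2L,
                              bin_width = 0.5) {
  structure(list(
    burial = derive_burial(refset),
    ssm = derive_ss(refset),
    contact_ca = derive_contact(refset, "CA", bin_width = bin_width,
                                min_seq_sep = min_seq_sep),
    contact_sc = derive_contact(refset, "SC", bin_width = bin_width,
                                min_seq_sep = min_seq_sep),
    class_map = check_class_map(class_map),
    freq = freq
  ), class = "potential_set")
}

# Precompute everything sequence-independent about (structure, potentials,
# profile): burial states, SS indices, contact pair lists, profile log-ratio
# matrix, and the permutation-null moments for every possible class count.
model_cache <- function(structure, potentials, profile, window = 1L) {
  L <- structure$L
  lp <- log(profile$freq / matrix(rep(profile$background, each = L), L, 7))
  nb_of <- function(cm) {
    cp <- contact_pairs(structure, cm$atom_mode, cm$bin_width, cm$r_cut,
                        cm$min_seq_sep)
    nb <- vector("list", L)
    for (k in seq_along(cp$i)) {
      i <- cp$i[k]; j <- cp$j[k]; b <- cp$bin[k]
      nb[[i]] <- rbind(nb[[i]], c(j, b))
      nb[[j]] <- rbind(nb[[j]], c(i, b))
    }
    list(pairs = cp, nb = nb)
  }
  nulltab <- lapply(0:L, adjacent_pair_null, L = L)
  list(
    L = L,
    bstate = burial_states(structure, potentials$burial),
    ssidx = match(structure$ss, SS_STATES),
    lp = lp,
    ca = nb_of(potentials$contact_ca),
    sc = nb_of(potentials$contact_sc),
    null_mean = vapply(nulltab, `[[`, numeric(1), "mean"),
    null_var = vapply(nulltab, `[[`, numeric(1), "var"),
    window = window
  )
}

# Anti-clustering penalty from an integer class vector using cached null
# moments (window 1 closed form).
penalty_from_classes <- function(cls, cache) {
  n_c <- tabulate(cls, nbins = 7)
  O <- observed_adjacent(cls, cache$window)
  E <- cache$null_mean[n_c + 1L]
  V <- cache$null_var[n_c + 1L]
  z <- ifelse(V > 1e-12, (O - E) / sqrt(V), 0)
  sum(pmax(0, z))
}

# Raw values of the six terms for an integer-coded sequence.
raw_terms_int <- function(aa, model) {
  cache <- model$cache
  cls <- match(model$class_map[AA_CODES[aa]], CLASS_NAMES)
  cp_ca <- cache$ca$pairs; cp_sc <- cache$sc$pairs
  c(burial = sum(model$potentials$burial$table[cbind(cache$bstate, aa)]),
    ss = sum(model$potentials$ssm$table[cbind(cache$ssidx, aa)]),
    contact_ca = if (length(cp_ca$i)) {
      sum(model$potentials$contact_ca$energies[cbind(aa[cp_ca$i], aa[cp_ca$j], cp_ca$bin)])
    } else 0,
    contact_sc = if (length(cp_sc$i)) {
      sum(model$potentials$contact_sc$energies[cbind(aa[cp_sc$i], aa[cp_sc$j], cp_sc$bin)])
    } else 0,
    profile = sum(cache$lp[cbind(seq_along(cls), cls)]),
    antigroup = penalty_from_classes(cls, cache))
}

#' Raw term values for a sequence on a model's target
#' @param seq sequence string
#' @param model an `energy_model` from [build_energy_model()]
#' @return named numeric vector over the six terms
#' @export
raw_terms <- function(seq, model) {
  aa <- seq_to_int(seq)
  if (length(aa) != model$cache$L) {
    stop_seqevolve("sequence length does not match model target",
                   "seqevolve_consistency_error")
  }
  raw_terms_int(aa, model)
}

#' Calibrate per-term normalizers against random sequences
#'
#' Draws `n_random` background-composition sequences, evaluates each raw term,
#' and stores the sample mean and standard deviation together with the term's
#' native-favouring orientation. After calibration the oriented normalized
#' terms have mean approximately 0 on random sequences, anchoring the combined
#' fitness of random sequences at 1.0.
#'
#' @param model an `energy_model` (normalizers may be absent)
#' @param n_random number of random sequences (>= 30)
#' @param rng an [mt_rng()] stream
#' @return the model with `normalizers` filled in (`mu`, `sigma`, `orient`)
#' @export
calibrate_normalizers <- function(model, n_random = 200L, rng = mt_rng(5489L)) {
  if (n_random < 30L) {
    stop_seqevolve("calibration needs n_random >= 30", "seqevolve_usage_error")
  }
  L <- model$cache$L
  raws <- matrix(0, n_random, length(TERM_NAMES),
                 dimnames = list(NULL, TERM_NAMES))
  for (k in seq_len(n_random)) {
    s <- random_sequence(L, model$freq, rng)
    raws[k, ] <- raw_terms_int(seq_to_int(s), model)
  }
  mu <- colMeans(raws)
  sigma <- apply(raws, 2, stats::sd)
  if (any(sigma < 1e-12)) {
    stop_seqevolve(sprintf("term(s) %s are degenerate (zero variance) on this target",
                           paste(TERM_NAMES[sigma < 1e-12], collapse = ", ")),
                   "seqevolve_calibration_error")
  }
  model$normalizers <- list(mu = mu, sigma = sigma, orient = TERM_ORIENT,
                            n_random = n_random)
  model
}

#' Assemble (and calibrate) an energy model for a target structure
#'
#' Binds a potential set and a profile to one target: precomputes burial
#' states, contact pair lists and profile log-ratios for the target backbone,
#' then calibrates the per-term normalizers against random sequences. Weights
#' default to uniform over the six terms; see [calibrate_weights()].
#'
#' @param structure the target `structure3d` (secondary structure attached)
#' @param potentials a `potential_set`; derived from `library` when `NULL`
#' @param profile a `seq_profile`; built from `library` when `NULL`
#' @param library analog/reference library used when `potentials` or `profile`
#'   is missing
#' @param weights named non-negative weights over the six terms, summing to 1
#' @param n_random random sequences for normalizer calibration
#' @param rng an [mt_rng()] stream for calibration
#' @param calibrate run normalizer calibration (default TRUE)
#' @param window anti-clustering adjacency window
#' @return object of class `energy_model`
#' @export
build_energy_model <- function(structure, potentials = NULL, profile = NULL,
                               library = NULL, weights = NULL,
                               n_random = 200L, rng = mt_rng(5489L),
                               calibrate = TRUE, window = 1L) {
  if (is.null(potentials)) {
    if (is.null(library)) {
      stop_seqevolve("need either a potential_set or a library to derive one",
                     "seqevolve_usage_error")
    }
    potentials <- derive_potentials(library)
  }
  if (is.null(profile)) {
    if (is.null(library)) {
      stop_seqevolve("need either a profile or a library to build one",
                     "seqevolve_usage_error")
    }
    profile <- build_profile(structure, library,
                             class_map = potentials$class_map,
                             freq = potentials$freq)
  }
  if (nrow(profile$freq) != structure$L) {
    stop_seqevolve("profile length does not match structure",
                   "seqevolve_consistency_error")
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(TERM_NAMES), length(TERM_NAMES))
    names(weights) <- TERM_NAMES
  }
  weights <- check_weights(weights)
  model <- base::structure(list(
    structure_id = structure$id,
    potentials = potentials,
    profile = profile,
    class_map = potentials$class_map,
    freq = potentials$freq,
    weights = weights,
    normalizers = NULL,
    cache = model_cache(structure, potentials, profile, window)
  ), class = "energy_model")
  if (calibrate) model <- calibrate_normalizers(model, n_random, rng)
  model
}

check_weights <- function(w) {
  if (!setequal(names(w), TERM_NAMES)) {
    stop_seqevolve("weights must be named over the six terms", "seqevolve_usage_error")
  }
  w <- w[TERM_NAMES]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_seqevolve("weights must be non-negative and sum to 1", "seqevolve_usage_error")
  }
  w
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> target %s (L=%d), %scalibrated\n",
              x$structure_id, x$cache$L,
              if (is.null(x$normalizers)) "un" else ""))
  cat(" weights:", paste(sprintf("%s=%.3f", TERM_NAMES, x$weights),
                         collapse = " "), "\n")
  invisible(x)
}

# Oriented normalized terms for a raw vector.
z_terms <- function(raw, model) {
  nz <- model$normalizers
  if (is.null(nz)) {
    stop_seqevolve("model is not calibrated; run calibrate_normalizers()",
                   "seqevolve_state_error")
  }
  nz$orient[TERM_NAMES] * (raw[TERM_NAMES] - nz$mu[TERM_NAMES]) / nz$sigma[TERM_NAMES]
}

#' Combined fitness of a sequence on a calibrated model
#'
#' `fitness = 1 + sum_t w_t z_t(seq)` with z the oriented normalized terms.
#' Random background sequences score about 1.0; higher is more native-like.
#'
#' @param seq sequence string
#' @param model a calibrated `energy_model`
#' @return fitness score
#' @export
fitness <- function(seq, model) {
  raw <- raw_terms(seq, model)
  1 + sum(model$weights * z_terms(raw, model))
}

# ---- incremental evaluation for the annealing inner loop -------------------

# Mutable state: integer sequence, class vector, cached raw terms, plus the
# per-class counts behind the anti-clustering penalty so its single-mutation
# delta is O(1). The delta path must agree with full re-evaluation to 1e-9;
# that identity is the key correctness property of the optimizer.
make_sa_state <- function(seq, model) {
  aa <- seq_to_int(seq)
  cache <- model$cache
  if (length(aa) != cache$L) {
    stop_seqevolve("sequence length does not match model target",
                   "seqevolve_consistency_error")
  }
  e <- new.env(parent = emptyenv())
  e$aa <- aa
  e$cls <- match(model$class_map[AA_CODES[aa]], CLASS_NAMES)
  e$raw <- raw_terms_int(aa, model)
  e$n_c <- tabulate(e$cls, nbins = 7)
  e$O <- observed_adjacent(e$cls, cache$window)
  z <- ifelse(cache$null_var[e$n_c + 1L] > 1e-12,
              (e$O - cache$null_mean[e$n_c + 1L]) /
                sqrt(cache$null_var[e$n_c + 1L]), 0)
  e$zpos <- pmax(0, z)
  # flattened contact energy tables and per-position neighbour offsets
  e$Eca <- as.numeric(model$potentials$contact_ca$energies)
  e$Esc <- as.numeric(model$potentials$contact_sc$energies)
  e
}

state_fitness <- function(state, model) {
  1 + sum(model$weights * z_terms(state$raw, model))
}

zpos_of <- function(n, O, cache) {
  v <- cache$null_var[n + 1L]
  if (v > 1e-12) max(0, (O - cache$null_mean[n + 1L]) / sqrt(v)) else 0
}

# Count of immediate neighbours of pos whose class is cl.
adjacent_class_count <- function(cls, pos, cl, L) {
  cnt <- 0L
  if (pos > 1L && cls[pos - 1L] == cl) cnt <- cnt + 1L
  if (pos < L && cls[pos + 1L] == cl) cnt <- cnt + 1L
  cnt
}

# Raw-term deltas (in TERM_NAMES order, unnamed) for mutating position pos to
# new_aa; does not modify the state. Returns the per-class clustering updates
# alongside so apply_move can commit them without recomputation.
move_deltas_fast <- function(state, model, pos, new_aa, cls_int) {
  cache <- model$cache
  old_aa <- state$aa[pos]
  d <- numeric(6)
  bt <- model$potentials$burial$table
  stt <- model$potentials$ssm$table
  nb_s <- nrow(bt)
  d[1] <- bt[cache$bstate[pos] + (new_aa - 1L) * nb_s] -
    bt[cache$bstate[pos] + (old_aa - 1L) * nb_s]
  d[2] <- stt[cache$ssidx[pos] + (new_aa - 1L) * 7L] -
    stt[cache$ssidx[pos] + (old_aa - 1L) * 7L]
  nb <- cache$ca$nb[[pos]]
  if (!is.null(nb)) {
    off <- (state$aa[nb[, 1L]] - 1L) * 20L + (nb[, 2L] - 1L) * 400L
    d[3] <- sum(state$Eca[off + new_aa]) - sum(state$Eca[off + old_aa])
  }
  nb <- cache$sc$nb[[pos]]
  if (!is.null(nb)) {
    off <- (state$aa[nb[, 1L]] - 1L) * 20L + (nb[, 2L] - 1L) * 400L
    d[4] <- sum(state$Esc[off + new_aa]) - sum(state$Esc[off + old_aa])
  }
  new_cls <- cls_int[new_aa]
  old_cls <- state$cls[pos]
  d[5] <- cache$lp[pos + (new_cls - 1L) * cache$L] -
    cache$lp[pos + (old_cls - 1L) * cache$L]
  upd <- NULL
  if (new_cls != old_cls) {
    if (cache$window == 1L) {
      L <- cache$L
      O1 <- state$O[old_cls] - adjacent_class_count(state$cls, pos, old_cls, L)
      O2 <- state$O[new_cls] + adjacent_class_count(state$cls, pos, new_cls, L)
      n1 <- state$n_c[old_cls] - 1L
      n2 <- state$n_c[new_cls] + 1L
      z1 <- zpos_of(n1, O1, cache)
      z2 <- zpos_of(n2, O2, cache)
      d[6] <- z1 + z2 - state$zpos[old_cls] - state$zpos[new_cls]
      upd <- list(old_cls = old_cls, new_cls = new_cls, O1 = O1, O2 = O2,
                  n1 = n1, n2 = n2, z1 = z1, z2 = z2)
    } else {
      cls2 <- state$cls; cls2[pos] <- new_cls
      d[6] <- penalty_from_classes(cls2, cache) - state$raw[["antigroup"]]
      upd <- list(old_cls = old_cls, new_cls = new_cls)
    }
  }
  list(d = d, upd = upd, new_cls = new_cls)
}

# Named-vector wrapper kept for the property tests and external callers.
move_deltas <- function(state, model, pos, new_aa) {
  cls_int <- match(model$class_map[AA_CODES], CLASS_NAMES)
  d <- move_deltas_fast(state, model, pos, new_aa, cls_int)$d
  names(d) <- TERM_NAMES
  d
}

apply_move <- function(state, model, pos, new_aa, mv) {
  state$aa[pos] <- new_aa
  state$cls[pos] <- mv$new_cls
  state$raw <- state$raw + mv$d
  upd <- mv$upd
  if (!is.null(upd)) {
    if (!is.null(upd$O1)) {
      state$O[upd$old_cls] <- upd$O1
      state$O[upd$new_cls] <- upd$O2
      state$n_c[upd$old_cls] <- upd$n1
      state$n_c[upd$new_cls] <- upd$n2
      state$zpos[upd$old_cls] <- upd$z1
      state$zpos[upd$new_cls] <- upd$z2
    } else {
      # general window: rebuild the clustering caches
      state$n_c <- tabulate(state$cls, nbins = 7)
      state$O <- observed_adjacent(state$cls, model$cache$window)
      cache <- model$cache
      z <- ifelse(cache$null_var[state$n_c + 1L] > 1e-12,
                  (state$O - cache$null_mean[state$n_c + 1L]) /
                    sqrt(cache$null_var[state$n_c + 1L]), 0)
      state$zpos <- pmax(0, z)
    }
  }
  invisible(state)
}

# ---- weight calibration ----------------------------------------------------

#' Build decoy sequences for a native
#'
#' Half composition-preserving shuffles of the native, half random
#' background-composition sequences.
#'
#' @param native native sequence string
#' @param n number of decoys
#' @param rng an [mt_rng()] stream
#' @param freq background composition for the random half
#' @return character vector of decoys
#' @export
make_decoys <- function(native, n, rng, freq = aa_frequencies()) {
  n_shuf <- n %/% 2
  L <- length(seq_chars(native))
  c(vapply(seq_len(n_shuf), function(k) shuffle_sequence(native, rng), character(1)),
    vapply(seq_len(n - n_shuf), function(k) random_sequence(L, freq, rng), character(1)))
}

#' Calibrate term weights on native-vs-decoy cases
#'
#' Maximizes the mean, over cases, of the z-gap between the native fitness and
#' the decoy fitness distribution, `(f_native - mean(f_decoy)) / sd(f_decoy)`,
#' over the probability simplex of term weights, by projected coordinate
#' ascent from the uniform start. Deterministic given the cases; case order
#' does not matter.
#'
#' @param cases list of cases, each `list(model = <calibrated energy_model>,
#'   native = <sequence>, decoys = <character vector>)`; at least 5 cases with
#'   at least 10 decoys each. Alternatively a case may carry precomputed
#'   oriented-normalized term values directly: `list(zn = <numeric 6>,
#'   Zd = <n x 6 matrix>)`.
#' @param max_sweeps maximum coordinate-ascent sweeps
#' @return named weight vector over the six terms (non-negative, sums to 1)
#' @export
calibrate_weights <- function(cases, max_sweeps = 100L) {
  n_dec <- vapply(cases, function(cs) {
    if (!is.null(cs$Zd)) nrow(cs$Zd) else length(cs$decoys)
  }, 0L)
  if (length(cases) < 5L || any(n_dec < 10L)) {
    stop_seqevolve("weight calibration needs >= 5 cases with >= 10 decoys each",
                   "seqevolve_usage_error")
  }
  mats <- lapply(cases, function(cs) {
    if (!is.null(cs$Zd)) return(list(zn = cs$zn, Zd = cs$Zd))
    zn <- z_terms(raw_terms(cs$native, cs$model), cs$model)
    Zd <- t(vapply(cs$decoys, function(s) z_terms(raw_terms(s, cs$model), cs$model),
                   numeric(length(TERM_NAMES))))
    list(zn = zn, Zd = Zd)
  })
  objective <- function(w) {
    mean(vapply(mats, function(m) {
      fd <- as.numeric(m$Zd %*% w)
      s <- stats::sd(fd)
      if (s < 1e-12) return(0)
      (sum(m$zn * w) - mean(fd)) / s
    }, numeric(1)))
  }
  k <- length(TERM_NAMES)
  w <- rep(1 / k, k); names(w) <- TERM_NAMES
  best <- objective(w)
  start <- best
  gammas <- c(-0.5, -0.2, -0.1, -0.05, -0.02, 0.02, 0.05, 0.1, 0.2, 0.5)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (t in seq_len(k)) {
      for (g in gammas) {
        w2 <- (1 - g) * w
        w2[t] <- w2[t] + g
        if (any(w2 < 0)) next
        w2 <- w2 / sum(w2)
        o2 <- objective(w2)
        if (o2 > best + 1e-10) {
          w <- w2; best <- o2; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  if (best <= start + 1e-10 && isTRUE(all.equal(unname(w), rep(1 / k, k)))) {
    warning("no improving direction found; returning uniform weights", call. = FALSE)
  }
  w
}
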