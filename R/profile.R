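# Structure-based sequence profiles: align the target against a library of
# analogs, keep statistically significant alignments (TM-score >= 0.4), and
# accumulate per-position frequencies over the 7 reduced residue classes.
# The reduced alphabet trades residue-level detail for signal-to-noise in
# low-homology profiles.

#' Build a structure-based sequence profile
#'
#' Each library member whose alignment to the target reaches `threshold`
#' (inclusive) contributes, for every aligned pair (i, j), one count of the
#' class of the analog residue j at target position i. Rows are normalized
#' with +0.5 pseudocounts per class; positions with no contributor fall back
#' to the background class frequencies. The target's own sequence is not
#' added, so the profile carries only analog-derived signal.
#'
#' @param target a `structure3d`
#' @param library list of members, each `list(structure=, sequence=)`
#' @param threshold minimum TM-score for an analog to contribute (default 0.4,
#'   inclusive)
#' @param class_map residue-class map (see [default_class_map()])
#' @param freq background amino-acid composition (defines the background class
#'   frequencies)
#' @param alignments optional list of precomputed `struct_alignment` objects
#'   (same order as `library`); when `NULL` each member is aligned with
#'   [align_structures()]
#' @param pseudocount per-class pseudocount (default 0.5)
#' @return object of class `seq_profile`: `freq` (L x 7 row-stochastic
#'   matrix), `counts`, `n_contributors`, `background`, `tm_scores`
#' @export
build_profile <- function(target, library, threshold = 0.4,
                          class_map = default_class_map(),
                          freq = aa_frequencies(), alignments = NULL,
                          pseudocount = 0.5) {
  if (!length(library)) {
    stop_seqevolve("analog library is empty", "seqevolve_usage_error")
  }
  class_map <- check_class_map(class_map)
  L <- target$L
  counts <- matrix(0, L, 7, dimnames = list(NULL, CLASS_NAMES))
  n_contrib <- integer(L)
  tms <- numeric(length(library))
  for (m in seq_along(library)) {
    member <- library[[m]]
    aln <- if (!is.null(alignments)) alignments[[m]] else {
      align_structures(target, member$structure)
    }
    tms[m] <- aln$tm_score
    if (aln$tm_score < threshold) next
    cls <- class_index(member$sequence, class_map)
    ti <- aln$pairs[, 1]; aj <- aln$pairs[, 2]
    for (k in seq_along(ti)) {
      counts[ti[k], cls[aj[k]]] <- counts[ti[k], cls[aj[k]]] + 1
      n_contrib[ti[k]] <- n_contrib[ti[k]] + 1L
    }
  }
  if (all(n_contrib == 0L)) {
    warning("no analog passed the TM-score threshold; profile is pure background",
            call. = FALSE)
  }
  bg <- class_background(freq, class_map)
  fr <- matrix(rep(bg, each = L), L, 7, dimnames = list(NULL, CLASS_NAMES))
  has <- n_contrib > 0L
  if (any(has)) {
    num <- counts[has, , drop = FALSE] + pseudocount
    fr[has, ] <- num / rowSums(num)
  }
  structure(list(freq = fr, counts = counts, n_contributors = n_contrib,
                 background = bg, threshold = threshold, tm_scores = tms),
            class = "seq_profile")
}

#' Evaluate the profile term
#'
#' Log-likelihood ratio of the sequence's residue classes against the
#' background: `sum_i ln[ p(i, class(aa_i)) / bg(class(aa_i)) ]`. Higher is a
#' better fit; the fitness layer orients it.
#'
#' @param seq sequence string (length must equal the profile's)
#' @param profile a `seq_profile`
#' @param class_map residue-class map
#' @return raw profile score (higher is more native-like)
#' @export
evaluate_profile <- function(seq, profile, class_map = default_class_map()) {
  cls <- class_index(seq, class_map)
  if (length(cls) != nrow(profile$freq)) {
    stop_seqevolve("sequence length does not match profile", "seqevolve_consistency_error")
  }
  sum(log(profile$freq[cbind(seq_along(cls), cls)] / profile$background[cls]))
}

#' Write a profile as TSV
#'
#' Header row of the 7 class names, then one row of frequencies per target
#' position. The format is also the import path for profiles computed by
#' external structure-alignment programs.
#'
#' @param profile a `seq_profile`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_profile <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  rows <- apply(profile$freq, 1, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
  writeLines(c(paste(CLASS_NAMES, collapse = "\t"), rows), con, sep = "\n")
  invisible(path)
}

#' Read a profile from TSV
#'
#' Accepts the format written by [write_profile()] (and by external tools):
#' a header of the 7 class names and L frequency rows. Rows are renormalized
#' to sum to 1.
#'
#' @param path input file
#' @param freq background composition used to fill the `background` slot
#' @param class_map residue-class map
#' @return a `seq_profile`
#' @export
read_profile <- function(path, freq = aa_frequencies(),
                         class_map = default_class_map()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!setequal(names(tab), CLASS_NAMES)) {
    stop_seqevolve("profile TSV must have the 7 class names as header",
                   "seqevolve_format_error")
  }
  fr <- as.matrix(tab[, CLASS_NAMES])
  if (any(fr < 0) || any(!is.finite(fr))) {
    stop_seqevolve("profile frequencies must be finite and non-negative",
                   "seqevolve_format_error")
  }
  fr <- fr / rowSums(fr)
  dimnames(fr) <- list(NULL, CLASS_NAMES)
  structure(list(freq = fr, counts = NULL, n_contributors = rep(NA_integer_, nrow(fr)),
                 background = class_background(freq, class_map),
                 threshold = NA_real_, tm_scores = NULL),
            class = "seq_profile")
}
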