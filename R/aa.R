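# Amino-acid alphabets, background frequencies and the reduced class map.

#' The 20 standard amino acids (one-letter codes, alphabetical)
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The seven STRIDE secondary-structure states
#' @export
SS_STATES <- c("H", "G", "I", "E", "B", "T", "C")

#' Names of the seven reduced residue classes
#' @export
CLASS_NAMES <- c("small_polar", "large_polar", "negative", "positive",
                 "hydrophobic", "aromatic", "histidine")

#' Background amino-acid frequencies
#'
#' Loads a 20-row table of amino-acid frequencies. The bundled default holds
#' UniProtKB/Swiss-Prot release composition statistics; pass `path` to use a
#' different background (TSV with columns `aa` and `frequency`). Frequencies
#' are renormalized to sum to exactly 1.
#'
#' @param path optional path to a user table; `NULL` uses the bundled default.
#' @return named numeric vector over [AA_CODES], summing to 1.
#' @export
aa_frequencies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "swissprot_aa_freq.tsv", package = "seqevolve")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("aa", "frequency") %in% names(tab))) {
    stop_seqevolve("frequency table needs columns 'aa' and 'frequency'",
                   "seqevolve_format_error")
  }
  f <- tab$frequency
  names(f) <- tab$aa
  if (!setequal(names(f), AA_CODES)) {
    stop_seqevolve("frequency table must cover the 20 standard amino acids",
                   "seqevolve_format_error")
  }
  f <- f[AA_CODES]
  if (any(f <= 0)) {
    stop_seqevolve("all frequencies must be strictly positive",
                   "seqevolve_format_error")
  }
  f / sum(f)
}

#' Default reduced residue-class map
#'
#' Maps each of the 20 amino acids to one of seven physicochemical classes:
#' small polar \{G,S,T,C\}, large polar \{N,Q\}, negatively charged \{D,E\},
#' positively charged \{K,R\}, hydrophobic \{A,V,L,I,M,P\}, aromatic
#' \{F,W,Y\}, and histidine on its own. Used by the profile term and the
#' anti-clustering restraint.
#'
#' @return named character vector: amino acid -> class name.
#' @export
default_class_map <- function() {
  m <- c(G = "small_polar", S = "small_polar", T = "small_polar", C = "small_polar",
         N = "large_polar", Q = "large_polar",
         D = "negative", E = "negative",
         K = "positive", R = "positive",
         A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
         I = "hydrophobic", M = "hydrophobic", P = "hydrophobic",
         F = "aromatic", W = "aromatic", Y = "aromatic",
         H = "histidine")
  m[AA_CODES]
}

# Validate a class map: total, exhaustive, single-valued over the 20 aa.
check_class_map <- function(class_map) {
  if (!setequal(names(class_map), AA_CODES) ||
      !all(class_map %in% CLASS_NAMES)) {
    stop_seqevolve("class map must assign each of the 20 amino acids to one of the 7 classes",
                   "seqevolve_usage_error")
  }
  class_map[AA_CODES]
}

# Integer class index (1..7 in CLASS_NAMES order) for each position of seq.
class_index <- function(seq, class_map = default_class_map()) {
  match(class_map[seq_chars(seq)], CLASS_NAMES)
}

#' Class background frequencies implied by an amino-acid background
#' @param freq named frequency vector as from [aa_frequencies()]
#' @param class_map residue-class map as from [default_class_map()]
#' @return named numeric vector over [CLASS_NAMES], summing to 1
#' @export
class_background <- function(freq = aa_frequencies(),
                             class_map = default_class_map()) {
  class_map <- check_class_map(class_map)
  bg <- vapply(CLASS_NAMES, function(cl) sum(freq[names(class_map)[class_map == cl]]),
               numeric(1))
  bg / sum(bg)
}

# --- sequence representation helpers -------------------------------------
# User-facing sequences are plain uppercase strings; internally positions are
# integer indices into AA_CODES.

seq_chars <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) strsplit(seq, "")[[1]] else as.character(seq)
}

seq_to_int <- function(seq) {
  idx <- match(seq_chars(seq), AA_CODES)
  if (anyNA(idx)) {
    stop_seqevolve("sequence contains non-standard amino acid codes",
                   "seqevolve_format_error")
  }
  idx
}

int_to_seq <- function(idx) paste(AA_CODES[idx], collapse = "")

#' Fraction of identical positions between two equal-length sequences
#' @param a,b sequences (strings or character vectors) of equal length
#' @return fraction in [0, 1]
#' @export
sequence_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    stop_seqevolve("sequences must have equal length", "seqevolve_consistency_error")
  }
  mean(ca == cb)
}
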