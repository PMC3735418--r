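# Structure container and I/O for the formats the tool touches:
# single-chain PDB, STRIDE ASG records, FASTA, profile and trajectory tables.

#' Construct a structure object
#'
#' A `structure3d` holds one ordered single-chain backbone: per residue the
#' amino acid, the Calpha coordinate, the Cbeta coordinate (Calpha for
#' glycine), the side-chain centroid (Calpha for glycine), and a 7-state
#' secondary-structure label.
#'
#' @param id free-text identifier
#' @param aa character vector of one-letter amino-acid codes
#' @param ca,cb,sc L x 3 coordinate matrices (Angstrom)
#' @param ss character vector of labels in \{H,G,I,E,B,T,C\}
#' @param check_gaps warn when consecutive Calpha distances fall outside
#'   (2.5, 4.5) Angstrom
#' @return object of class `structure3d`
#' @export
new_structure <- function(id, aa, ca, cb = NULL, sc = NULL,
                          ss = rep("C", length(aa)), check_gaps = TRUE) {
  aa <- seq_chars(aa)
  L <- length(aa)
  if (L < 10L) {
    stop_seqevolve(sprintf("chain of %d residues is degenerate (need >= 10)", L),
                   "seqevolve_degenerate_error")
  }
  ca <- as.matrix(ca)
  if (is.null(cb)) cb <- ca
  if (is.null(sc)) sc <- cb
  cb <- as.matrix(cb); sc <- as.matrix(sc)
  dimnames(ca) <- dimnames(cb) <- dimnames(sc) <- NULL
  if (!all(dim(ca) == c(L, 3)) || !all(dim(cb) == c(L, 3)) ||
      !all(dim(sc) == c(L, 3))) {
    stop_seqevolve("coordinate matrices must be L x 3", "seqevolve_consistency_error")
  }
  if (!all(is.finite(ca)) || !all(is.finite(cb)) || !all(is.finite(sc))) {
    stop_seqevolve("coordinates must be finite", "seqevolve_format_error")
  }
  if (anyNA(match(aa, AA_CODES))) {
    stop_seqevolve("unknown amino-acid codes in structure", "seqevolve_format_error")
  }
  ss <- ifelse(ss %in% SS_STATES, ss, "C")
  if (length(ss) != L) {
    stop_seqevolve("secondary-structure labels must match chain length",
                   "seqevolve_consistency_error")
  }
  if (check_gaps && L > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE])^2))
    bad <- which(d <= 2.5 | d >= 4.5)
    if (length(bad)) {
      warning(sprintf("chain %s: %d consecutive Calpha distance(s) outside (2.5, 4.5) A (possible gap)",
                      id, length(bad)), call. = FALSE)
    }
  }
  structure(list(id = id, aa = aa, ca = ca, cb = cb, sc = sc, ss = ss, L = L),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %s: %d residues\n", x$id, x$L))
  cat(" sequence:", native_sequence(x), "\n")
  cat(" ss:      ", paste(x$ss, collapse = ""), "\n")
  invisible(x)
}

#' Native sequence carried by a structure
#' @param structure a `structure3d`
#' @return sequence string
#' @export
native_sequence <- function(structure) paste(structure$aa, collapse = "")

#' Attach secondary-structure labels to a structure
#' @param structure a `structure3d`
#' @param ss labels, e.g. from [parse_stride()]; length must equal the chain
#'   length
#' @return the updated structure
#' @export
set_secondary <- function(structure, ss) {
  if (length(ss) != structure$L) {
    stop_seqevolve(sprintf("secondary-structure labels (%d) do not match chain length (%d)",
                           length(ss), structure$L), "seqevolve_consistency_error")
  }
  structure$ss <- ifelse(ss %in% SS_STATES, ss, "C")
  structure
}

# Ideal Cbeta from backbone N, CA, C (tetrahedral geometry, 1.53 A bond).
ideal_cb <- function(n, ca, c) {
  b1 <- n - ca; b2 <- c - ca
  b1 <- b1 / sqrt(sum(b1^2)); b2 <- b2 / sqrt(sum(b2^2))
  bis <- -(b1 + b2); bis <- bis / sqrt(sum(bis^2))
  perp <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
  perp <- perp / sqrt(sum(perp^2))
  # rotate the bisector out of the N-CA-C plane to the tetrahedral direction
  dirv <- bis * cos(0.9599) + perp * sin(0.9599) # ~55 degrees out of plane
  ca + 1.53 * dirv / sqrt(sum(dirv^2))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a single-chain structure from PDB text
#'
#' Parses ATOM records (first MODEL only; HETATM and waters ignored;
#' highest-occupancy alternate locations kept, ties broken by file order) and
#' builds one residue per position with a Calpha, a Cbeta (Calpha for glycine,
#' ideal reconstruction from N/CA/C when the CB atom is missing), and a
#' side-chain centroid (mean of side-chain heavy atoms including Cbeta;
#' Calpha for glycine and for residues with no side-chain atoms resolved).
#' Residues lacking a Calpha are dropped with a warning. Residues are
#' re-indexed 1..L in file order regardless of author numbering or insertion
#' codes.
#'
#' @param pdb path to a PDB file, or PDB-format text (single string with
#'   newlines or a character vector of lines)
#' @param chain_id chain to extract; may be omitted if the file holds exactly
#'   one chain
#' @param id identifier for the resulting structure (default: chain id or file
#'   name)
#' @param mass_weighted use mass-weighted side-chain centroids instead of the
#'   default unweighted mean
#' @return a `structure3d` (secondary structure initialised to coil; attach
#'   STRIDE labels with [set_secondary()])
#' @export
read_structure <- function(pdb, chain_id = NULL, id = NULL,
                           mass_weighted = FALSE) {
  path <- pdb_as_file(pdb)
  pdbobj <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop_seqevolve(paste("cannot parse PDB input:",
                                             conditionMessage(e)),
                                       "seqevolve_format_error"))
  at <- pdbobj$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0) {
    stop_seqevolve("no ATOM records found", "seqevolve_format_error")
  }
  chains <- unique(at$chain)
  if (is.null(chain_id)) {
    if (length(chains) > 1) {
      stop_seqevolve(sprintf("multiple chains present (%s); supply chain_id",
                             paste(chains, collapse = ",")),
                     "seqevolve_ambiguity_error")
    }
    chain_id <- chains[1]
  }
  at <- at[at$chain %in% chain_id, , drop = FALSE]
  if (nrow(at) == 0) {
    stop_seqevolve(sprintf("chain '%s' not found", chain_id),
                   "seqevolve_format_error")
  }
  # drop hydrogens
  elt <- at$elesy
  if (is.null(elt) || all(is.na(elt))) elt <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  at <- at[!(toupper(trimws(elt)) %in% c("H", "D")), , drop = FALSE]

  # alternate locations: per residue+atom keep highest occupancy, ties first
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(match(key, unique(key)), -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), ,
           drop = FALSE]

  reskey <- paste(at$resno, at$insert, sep = "|")
  groups <- split(seq_len(nrow(at)), factor(reskey, levels = unique(reskey)))

  aa <- character(0); ca <- cb <- sc <- NULL; dropped <- 0L
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  for (g in groups) {
    ga <- at[g, , drop = FALSE]
    one <- suppressWarnings(bio3d::aa321(ga$resid[1]))
    if (is.na(one) || !(one %in% AA_CODES)) { dropped <- dropped + 1L; next }
    ica <- which(ga$elety == "CA")
    if (!length(ica)) { dropped <- dropped + 1L; next }
    xyz <- function(i) c(ga$x[i], ga$y[i], ga$z[i])
    p_ca <- xyz(ica[1])
    side <- which(!(ga$elety %in% BACKBONE_ATOMS))
    icb <- which(ga$elety == "CB")
    if (one == "G") {
      p_cb <- p_ca; p_sc <- p_ca
    } else {
      if (length(icb)) {
        p_cb <- xyz(icb[1])
      } else {
        i_n <- which(ga$elety == "N"); i_c <- which(ga$elety == "C")
        p_cb <- if (length(i_n) && length(i_c)) {
          ideal_cb(xyz(i_n[1]), p_ca, xyz(i_c[1]))
        } else p_ca
      }
      if (length(side)) {
        pts <- cbind(ga$x[side], ga$y[side], ga$z[side])
        if (mass_weighted) {
          el <- toupper(substr(gsub("[0-9]", "", ga$elety[side]), 1, 1))
          w <- masses[el]; w[is.na(w)] <- 12.011
          p_sc <- colSums(pts * w) / sum(w)
        } else {
          p_sc <- colMeans(pts)
        }
      } else {
        p_sc <- p_ca
      }
    }
    aa <- c(aa, one)
    ca <- rbind(ca, p_ca); cb <- rbind(cb, p_cb); sc <- rbind(sc, p_sc)
  }
  if (dropped > 0) {
    warning(sprintf("dropped %d residue(s) without Calpha or with non-standard identity",
                    dropped), call. = FALSE)
  }
  if (length(aa) < 10L) {
    stop_seqevolve(sprintf("only %d usable residues (need >= 10)", length(aa)),
                   "seqevolve_degenerate_error")
  }
  if (is.null(id)) id <- if (is.na(chain_id) || chain_id == "") "chain" else chain_id
  new_structure(id, aa, ca, cb, sc)
}

# Accept a path, a single string of PDB text, or a vector of lines; return a
# file path bio3d can read.
pdb_as_file <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

#' Render a structure as PDB-format text
#'
#' Writes CA and CB atoms, plus (when the side-chain centroid differs from
#' Cbeta) a CG pseudo-atom placed so that the mean of CB and CG reproduces the
#' stored centroid, making the text round-trippable through
#' [read_structure()] at the format's 3-decimal precision.
#'
#' @param structure a `structure3d`
#' @param chain_id one-character chain identifier
#' @return character vector of PDB lines
#' @export
pdb_text <- function(structure, chain_id = "A") {
  fmt <- function(serial, name, res3, resno, p) {
    sprintf("ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, res3, chain_id, resno, p[1], p[2], p[3],
            substr(name, 1, 1))
  }
  lines <- character(0); serial <- 0L
  for (i in seq_len(structure$L)) {
    res3 <- bio3d::aa123(structure$aa[i])
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", res3, i, structure$ca[i, ]))
    if (structure$aa[i] != "G") {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, "CB", res3, i, structure$cb[i, ]))
      if (sqrt(sum((structure$sc[i, ] - structure$cb[i, ])^2)) > 5e-4) {
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, "CG", res3, i,
                              2 * structure$sc[i, ] - structure$cb[i, ]))
      }
    }
  }
  c(lines, "TER", "END")
}

#' Parse STRIDE output into 7-state secondary-structure labels
#'
#' Reads the ASG records of a STRIDE report, one label per record in file
#' order. The one-letter codes \{H,G,I,E,B,T,C\} are kept as-is, `b` maps to
#' `B`, and any other (lower-case or unknown) code maps to coil `C`.
#'
#' @param stride_text STRIDE output: a path, a single string, or lines
#' @return character vector of labels in [SS_STATES]
#' @export
parse_stride <- function(stride_text) {
  lines <- if (length(stride_text) == 1L && !grepl("\n", stride_text) &&
               file.exists(stride_text)) {
    readLines(stride_text)
  } else if (length(stride_text) == 1L) {
    strsplit(stride_text, "\n", fixed = TRUE)[[1]]
  } else as.character(stride_text)
  asg <- grep("^ASG", lines, value = TRUE)
  if (!length(asg)) {
    stop_seqevolve("no ASG records in STRIDE input", "seqevolve_format_error")
  }
  code <- vapply(asg, function(l) {
    # one-letter code is column 25 of the fixed layout; fall back to token 6
    c25 <- if (nchar(l) >= 25) substr(l, 25, 25) else " "
    if (c25 != " ") return(c25)
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) >= 6) tok[6] else "C"
  }, character(1), USE.NAMES = FALSE)
  code[code == "b"] <- "B"
  ifelse(code %in% SS_STATES, code, "C")
}

#' Write STRIDE-style ASG records for a structure
#'
#' Emits a minimal STRIDE report (ASG records only) from the labels stored in
#' the structure, so synthetic fixtures can drive the same input path as real
#' STRIDE output.
#'
#' @param structure a `structure3d`
#' @param path output file; `NULL` returns the lines
#' @param chain_id chain identifier to print
#' @return invisibly, the lines written
#' @export
write_stride_asg <- function(structure, path = NULL, chain_id = "A") {
  full <- c(H = "AlphaHelix", G = "310Helix", I = "PiHelix", E = "Strand",
            B = "Bridge", T = "Turn", C = "Coil")
  lines <- vapply(seq_len(structure$L), function(i) {
    sprintf("ASG  %3s %s %4d %4d    %s    %-11s   360.00    360.00       0.0",
            bio3d::aa123(structure$aa[i]), chain_id, i, i,
            structure$ss[i], full[structure$ss[i]])
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a sequence as FASTA
#' @param seq sequence string
#' @param path output file
#' @param header FASTA header (without `>`)
#' @param width line width (default 60)
#' @return invisibly, `path`
#' @export
write_fasta <- function(seq, path, header = "sequence", width = 60L) {
  s <- paste(seq_chars(seq), collapse = "")
  starts <- seq(1L, nchar(s), by = width)
  body <- vapply(starts, function(i) substr(s, i, min(i + width - 1L, nchar(s))),
                 character(1))
  con <- file(path, open = "wb") # fixed EOL for byte-identical output
  on.exit(close(con))
  writeLines(c(paste0(">", header), body), con, sep = "\n")
  invisible(path)
}

#' Write an annealing trajectory as TSV
#'
#' Columns are the cumulative Metropolis step, the temperature, the current
#' fitness and the fraction of positions identical to the native sequence.
#' Output is byte-identical for identical in-memory trajectories.
#'
#' @param trajectory data frame with columns `step`, `temperature`, `fitness`,
#'   `identity` (extra columns are ignored)
#' @param path output file
#' @return invisibly, `path`
#' @export
write_trajectory <- function(trajectory, path) {
  if (is.null(trajectory) || nrow(trajectory) == 0) {
    stop_seqevolve("trajectory is empty", "seqevolve_usage_error")
  }
  rows <- sprintf("%d\t%.6f\t%.6f\t%.6f", as.integer(trajectory$step),
                  trajectory$temperature, trajectory$fitness,
                  trajectory$identity)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# step temperature fitness identity", rows), con, sep = "\n")
  invisible(path)
}

#' Write the evolved sequence and its annealing trajectory
#'
#' @param sequence evolved sequence string
#' @param trajectory trajectory data frame (see [write_trajectory()])
#' @param fasta_path,trajectory_path output files
#' @param structure_id identifier carried in the FASTA header
#' @param seed RNG seed carried in the FASTA header
#' @param fitness final fitness carried in the FASTA header
#' @return invisibly, a named list of the paths written
#' @export
write_outputs <- function(sequence, trajectory, fasta_path, trajectory_path,
                          structure_id = "target", seed = NA, fitness = NA) {
  header <- sprintf("%s evolved seed=%s fitness=%.6f", structure_id,
                    as.character(seed), fitness)
  write_fasta(sequence, fasta_path, header = header)
  write_trajectory(trajectory, trajectory_path)
  invisible(list(fasta = fasta_path, trajectory = trajectory_path))
}
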