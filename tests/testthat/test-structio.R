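# PDB text fixture: 12-residue helix of given residues, CA + CB (+ optional
# extras) with full control over columns.
atom_line <- function(serial, name, res3, chain, resno, xyz, alt = " ", occ = 1.0) {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
          serial, name, alt, res3, chain, resno, xyz[1], xyz[2], xyz[3], occ,
          substr(name, 1, 1))
}

helix_ca <- function(n) {
  i <- seq_len(n) - 1
  cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180), 1.5 * i)
}

test_that("fixture structures round-trip through PDB text at format precision", {
  fx <- make_helix(12, seed = 4)
  txt <- pdb_text(fx$structure)
  back <- read_structure(paste(txt, collapse = "\n"))
  expect_equal(back$L, 12)
  expect_equal(back$aa, fx$structure$aa)
  expect_equal(back$ca, fx$structure$ca, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$cb, fx$structure$cb, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$sc, fx$structure$sc, tolerance = 2e-3, ignore_attr = TRUE)
  non_gly <- fx$structure$aa != "G"
  expect_true(all(rowSums((back$cb - back$ca)^2)[non_gly] > 0))
})

test_that("degenerate and malformed PDB inputs are rejected", {
  one_res <- c(atom_line(1, "CA", "ALA", "A", 1, c(0, 0, 0)),
               atom_line(2, "CB", "ALA", "A", 1, c(1.5, 0, 0)))
  expect_error(read_structure(one_res), class = "seqevolve_degenerate_error")
  expect_error(read_structure("HEADER only\nEND"), class = "seqevolve_format_error")
})

test_that("glycine and missing side chains fall back to Calpha", {
  ca <- helix_ca(12)
  lines <- character(0); s <- 0
  for (i in 1:12) {
    res3 <- if (i == 5) "GLY" else "ALA"
    s <- s + 1; lines <- c(lines, atom_line(s, "N", res3, "A", i, ca[i, ] + c(-1.2, 0.8, -0.5)))
    s <- s + 1; lines <- c(lines, atom_line(s, "CA", res3, "A", i, ca[i, ]))
    s <- s + 1; lines <- c(lines, atom_line(s, "C", res3, "A", i, ca[i, ] + c(1.2, 0.8, 0.5)))
    if (i != 5 && i != 7) { # residue 7: ALA with no CB resolved
      s <- s + 1; lines <- c(lines, atom_line(s, "CB", res3, "A", i, ca[i, ] + c(1.5, 0, 0)))
    }
  }
  st <- read_structure(lines)
  expect_equal(st$aa[5], "G")
  expect_equal(st$cb[5, ], st$ca[5, ], ignore_attr = TRUE)
  expect_equal(st$sc[5, ], st$ca[5, ], ignore_attr = TRUE)
  # missing CB on a non-glycine: ideal reconstruction, 1.53 A from CA
  expect_equal(sqrt(sum((st$cb[7, ] - st$ca[7, ])^2)), 1.53, tolerance = 1e-6)
  # no side-chain atoms resolved -> centroid falls back to Calpha
  expect_equal(st$sc[7, ], st$ca[7, ], ignore_attr = TRUE)
})

test_that("alternate locations keep the highest occupancy", {
  ca <- helix_ca(12)
  lines <- character(0); s <- 0
  for (i in 1:12) {
    s <- s + 1; lines <- c(lines, atom_line(s, "CA", "ALA", "A", i, ca[i, ]))
    if (i == 3) {
      s <- s + 1; lines <- c(lines, atom_line(s, "CB", "ALA", "A", i,
                                              ca[i, ] + c(1.5, 0, 0), alt = "A", occ = 0.4))
      s <- s + 1; lines <- c(lines, atom_line(s, "CB", "ALA", "A", i,
                                              ca[i, ] + c(0, 1.5, 0), alt = "B", occ = 0.6))
    } else {
      s <- s + 1; lines <- c(lines, atom_line(s, "CB", "ALA", "A", i, ca[i, ] + c(1.5, 0, 0)))
    }
  }
  st <- read_structure(lines)
  expect_equal(st$cb[3, ] - st$ca[3, ], c(0, 1.5, 0), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("multi-chain files require an explicit chain", {
  ca <- helix_ca(12)
  mk <- function(chain, shift) {
    unlist(lapply(1:12, function(i) {
      atom_line(i, "CA", "ALA", chain, i, ca[i, ] + shift)
    }))
  }
  txt <- c(mk("A", 0), mk("B", 50))
  expect_error(read_structure(txt), class = "seqevolve_ambiguity_error")
  st <- read_structure(txt, chain_id = "B")
  expect_equal(st$L, 12)
  expect_equal(st$ca[1, 1], 2.3 + 50, tolerance = 1e-3)
})

test_that("STRIDE parsing maps codes to the 7-state alphabet", {
  fx <- make_helix(12, seed = 1)
  asg <- write_stride_asg(fx$structure)
  expect_equal(parse_stride(asg), rep("H", 12))
  # b -> B, lower-case/unknown -> C, file order preserved
  lines <- c("ASG  ALA A    1    1    b          Bridge     360.00    360.00       0.0",
             "ASG  ALA A    2    2    g          Coil       360.00    360.00       0.0",
             "ASG  ALA A    3    3    E          Strand     360.00    360.00       0.0",
             "REM  not an ASG record")
  expect_equal(parse_stride(lines), c("B", "C", "E"))
  expect_error(parse_stride("REM nothing here"), class = "seqevolve_format_error")
  expect_error(set_secondary(fx$structure, rep("H", 11)),
               class = "seqevolve_consistency_error")
})

test_that("sequence and trajectory writers are deterministic byte-for-byte", {
  traj <- data.frame(step = c(0L, 1000L), temperature = c(5000, 4990.02),
                     fitness = c(1.01, 1.25), identity = c(0.08, 0.10))
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a"); p2 <- file.path(d, "b")
  seqs <- strrep("ACDEFGHIKLMNPQRSTVWY", 4) # 80 residues -> 60/20 split
  for (p in c(p1, p2)) {
    write_outputs(seqs, traj, paste0(p, ".fasta"), paste0(p, ".tsv"),
                  structure_id = "tgt", seed = 42, fitness = 1.25)
  }
  expect_identical(readBin(paste0(p1, ".fasta"), "raw", 1e4),
                   readBin(paste0(p2, ".fasta"), "raw", 1e4))
  expect_identical(readBin(paste0(p1, ".tsv"), "raw", 1e4),
                   readBin(paste0(p2, ".tsv"), "raw", 1e4))
  fasta <- readLines(paste0(p1, ".fasta"))
  expect_equal(nchar(fasta[2]), 60)
  expect_equal(nchar(fasta[3]), 20)
  tsv <- readLines(paste0(p1, ".tsv"))
  expect_equal(tsv[1], "# step temperature fitness identity")
  expect_equal(length(tsv), 3)
  expect_error(write_trajectory(traj[0, ], file.path(d, "x")),
               class = "seqevolve_usage_error")
})
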