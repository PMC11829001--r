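# Shared fixtures, built in code. `toy()` caches the default synthetic
# complex for the session; `mini_input()` is a hand-placed 4-atom input
# whose moiety mass centres are exactly 5 A apart, convenient for
# boundary-exact distance tests.

.fixture_env <- new.env()

toy <- function() {
  if (is.null(.fixture_env$toy)) .fixture_env$toy <- make_toy_complex()
  .fixture_env$toy
}

# one protein atom + one single-atom moiety per side; anchor at origin,
# warhead at (5, 0, 0)
mini_structure <- function(chain, protein_xyz, het_xyz, het_res = "LIG") {
  df <- data.frame(
    serial = 1:2, name = c("CA", "C1"), altloc = "",
    resname = c("ALA", het_res), chain = chain, resseq = 1:2, icode = "",
    x = c(protein_xyz[1], het_xyz[1]), y = c(protein_xyz[2], het_xyz[2]),
    z = c(protein_xyz[3], het_xyz[3]),
    element = "C", is_het = c(FALSE, TRUE), stringsAsFactors = FALSE)
  df$mass <- element_mass(df$element)
  structure(df, class = c("protern_structure", "data.frame"))
}

mini_input <- function(receptor_protein = c(0, 0, 30),
                       mobile_protein = c(5, 0, 30)) {
  ternary_input(
    mini_structure("A", receptor_protein, c(0, 0, 0)),
    mini_structure("B", mobile_protein, c(5, 0, 0)))
}

# a synthetic PDB text block with `n_res` residues of `atoms_per_res`
# carbon atoms each, on chain A
pdb_text_fixture <- function(n_res = 3, atoms_per_res = 10) {
  lines <- character(0)
  serial <- 0
  for (r in seq_len(n_res)) {
    for (a in seq_len(atoms_per_res)) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  C%-2d ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, a, r, r * 3.8, a * 1.0, 0))
    }
  }
  c(lines, "END")
}

pose_ids <- function(poses) vapply(poses, `[[`, character(1), "id")

expect_coords_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
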