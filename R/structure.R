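#' @useDynLib protern, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median sd setNames cor
#' @importFrom utils read.delim write.table head
NULL

# Atomic masses (Da) keyed by upper-case element symbol.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.99, K = 39.098,
  CA = 40.078, MN = 54.938, SE = 78.971, CU = 63.546, CO = 58.933
)

.water_resnames <- c("HOH", "WAT", "DOD")

#' Look up atomic masses by element symbol
#'
#' Unknown symbols fall back to the mass of carbon with a warning, so that
#' mass centres are always computable.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in Dalton.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element symbol(s) ",
            paste(unique(key[unknown]), collapse = ", "),
            "; using carbon mass")
    m[unknown] <- .element_masses[["C"]]
  }
  unname(m)
}

# Infer the element symbol from a PDB atom name when the element column is
# absent. Leading digits (e.g. "1HB") indicate hydrogens; two-letter symbols
# are recognised from a fixed list.
.infer_element <- function(name) {
  nm <- toupper(trimws(name))
  vapply(nm, function(x) {
    if (grepl("^[0-9]", x)) return("H")
    two <- substr(x, 1, 2)
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "CU", "CO"))
      return(two)
    substr(x, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

.new_structure <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("protern_structure", "data.frame")
  df
}

#' @export
print.protern_structure <- function(x, ...) {
  cat(sprintf("<protern_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(residue_ids(x))),
              paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

#' Residue identifiers of a structure
#'
#' Residues are identified by `(chain, residue number, insertion code)` so
#' that insertion codes survive round-tripping.
#'
#' @param structure a `protern_structure`.
#' @return character vector, one id per atom.
#' @export
residue_ids <- function(structure) {
  paste(structure$chain, structure$resseq, structure$icode, sep = "|")
}

#' Atom coordinates as a matrix
#'
#' @param structure a `protern_structure`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

.set_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}

#' Read a structure from PDB-format input
#'
#' Parses ATOM and HETATM records (both retained) into an atom table with
#' residue identity `(chain, resseq, insertion code)` preserved. Alternate
#' locations other than `' '`/`'A'` are dropped, so a single conformer
#' remains. The element symbol is taken from the element column when present
#' and otherwise inferred from the atom name; atomic masses are attached from
#' a built-in table.
#'
#' @param input path to a PDB file, or a character vector of PDB text
#'   (a single string with embedded newlines is also accepted).
#' @return a `protern_structure` data frame with columns `serial`, `name`,
#'   `altloc`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `element`, `mass`, `is_het`.
#' @export
read_structure <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    stop("empty structure: input contains no ATOM/HETATM records")
  }
  # validate coordinate fields before handing over to the parser, so a bad
  # line is reported by number
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v)) {
        stop(sprintf("format error on line %d: unparseable coordinate field '%s'",
                     i, trimws(substr(ln, fld[1], fld[2]))))
      }
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = TRUE)
  a <- pdb$atom
  element <- toupper(trimws(as.character(a$elesy)))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) element[missing_el] <- .infer_element(a$elety[missing_el])
  df <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resseq = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    element = element,
    is_het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure")
  }
  df$mass <- element_mass(df$element)
  .new_structure(df)
}

#' Prepare a structure for rigid-body modelling
#'
#' Removes all water residues and all hydrogen/deuterium atoms, preserving
#' the order of the remaining atoms. Idempotent; heavy non-water atoms are
#' never touched.
#'
#' @param structure a `protern_structure`.
#' @return the prepared `protern_structure`.
#' @export
prepare_structure <- function(structure) {
  keep <- !(structure$resname %in% .water_resnames) &
    !(structure$element %in% c("H", "D"))
  .new_structure(structure[keep, , drop = FALSE])
}

#' Tag a bound ligand moiety
#'
#' A moiety tag names the anchor (on the E3 structure) or the warhead (on
#' the POI structure) by the atom serials of its hetero atoms.
#'
#' @param role `"anchor"` or `"warhead"`.
#' @param atom_serials integer vector of atom serial numbers.
#' @return a `protern_moiety` object.
#' @export
moiety_tag <- function(role, atom_serials) {
  role <- match.arg(role, c("anchor", "warhead"))
  atom_serials <- unique(as.integer(atom_serials))
  if (length(atom_serials) == 0) stop("moiety tag must reference at least one atom")
  structure(list(role = role, atom_serials = atom_serials),
            class = "protern_moiety")
}

.default_moiety <- function(structure, role) {
  serials <- structure$serial[structure$is_het]
  if (length(serials) == 0) {
    stop("no HETATM atoms to tag as the ", role,
         "; pass an explicit moiety tag")
  }
  moiety_tag(role, serials)
}

.check_moiety <- function(structure, tag, label) {
  hit <- match(tag$atom_serials, structure$serial)
  if (anyNA(hit)) {
    stop("consistency error: ", label, " tag references serial(s) ",
         paste(tag$atom_serials[is.na(hit)], collapse = ", "),
         " absent from the structure")
  }
  if (!all(structure$is_het[hit])) {
    stop("consistency error: ", label, " tag references non-hetero atoms")
  }
  invisible(hit)
}

#' Assemble the two-protein docking input
#'
#' Couples the fixed receptor structure (E3 + anchor) with the mobile
#' structure (POI + warhead) that poses move. Both structures must already
#' be prepared (no waters/hydrogens) and must not share chain identifiers.
#' When no explicit moiety tag is given, all HETATM atoms of a structure
#' form its moiety — the benchmark inputs carry exactly one bound ligand
#' residue each.
#'
#' @param receptor prepared `protern_structure` held fixed (E3 + anchor).
#' @param mobile prepared `protern_structure` moved by poses (POI + warhead).
#' @param receptor_moiety,mobile_moiety optional `protern_moiety` tags;
#'   default tags all HETATM atoms of the respective structure.
#' @param protac_file optional path to a PROTAC structure handed to the
#'   external docking stage; never parsed by this package.
#' @return a `protern_input` object.
#' @export
ternary_input <- function(receptor, mobile,
                          receptor_moiety = NULL, mobile_moiety = NULL,
                          protac_file = NULL) {
  if (length(intersect(unique(receptor$chain), unique(mobile$chain))) > 0) {
    stop("receptor and mobile structures share chain identifier(s)")
  }
  if (is.null(receptor_moiety)) receptor_moiety <- .default_moiety(receptor, "anchor")
  if (is.null(mobile_moiety)) mobile_moiety <- .default_moiety(mobile, "warhead")
  .check_moiety(receptor, receptor_moiety, "receptor moiety")
  .check_moiety(mobile, mobile_moiety, "mobile moiety")
  structure(list(receptor = receptor, mobile = mobile,
                 receptor_moiety = receptor_moiety,
                 mobile_moiety = mobile_moiety,
                 protac_file = protac_file),
            class = "protern_input")
}

#' Split a docking input into protein-only and moiety structures
#'
#' @param input a `protern_input`.
#' @return list with `receptor_protein`, `mobile_protein` (tagged atoms
#'   removed) and `receptor_moiety`, `mobile_moiety` (exactly the tagged
#'   atoms).
#' @export
strip_moieties <- function(input) {
  ri <- .check_moiety(input$receptor, input$receptor_moiety, "receptor moiety")
  mi <- .check_moiety(input$mobile, input$mobile_moiety, "mobile moiety")
  list(
    receptor_protein = .new_structure(input$receptor[-ri, , drop = FALSE]),
    mobile_protein = .new_structure(input$mobile[-mi, , drop = FALSE]),
    receptor_moiety = .new_structure(input$receptor[ri, , drop = FALSE]),
    mobile_moiety = .new_structure(input$mobile[mi, , drop = FALSE])
  )
}

#' Construct a rigid transform
#'
#' A rotation about `center` followed by a translation:
#' `x -> R (x - c) + c + t`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @param center length-3 rotation centre (Angstrom).
#' @return a `protern_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("invariant error: rotation matrix is not orthonormal with det +1")
  }
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "protern_transform")
}

.apply_transform <- function(xyz, tf) {
  centered <- sweep(xyz, 2, tf$center)
  rotated <- centered %*% t(tf$rotation)
  sweep(rotated, 2, tf$center + tf$translation, FUN = "+")
}

#' Construct a rigid pose of the mobile protein
#'
#' @param id unique pose identifier.
#' @param transform a `protern_transform` applied to the mobile structure.
#' @param seed_id identifier of the originating docking seed (defaults to
#'   `id`).
#' @param provenance pipeline stage that produced the pose: `"seed"`,
#'   `"translated"` or `"rotated"`.
#' @return a `protern_pose`.
#' @export
pose <- function(id, transform = rigid_transform(), seed_id = id,
                 provenance = c("seed", "translated", "rotated")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(transform, "protern_transform"))
  structure(list(id = as.character(id), seed_id = as.character(seed_id),
                 transform = transform, provenance = provenance),
            class = "protern_pose")
}

#' Place the mobile structure according to a pose
#'
#' Applies `x -> R (x - c) + c + t` to every mobile atom; the receptor is
#' untouched. The map is an isometry, so all intra-mobile distances are
#' preserved.
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @return the placed mobile `protern_structure`.
#' @export
apply_pose <- function(input, pose) {
  stopifnot(inherits(pose, "protern_pose"))
  .set_coords(input$mobile, .apply_transform(coords(input$mobile), pose$transform))
}

#' Write a posed complex as PDB text
#'
#' Emits the receptor chains followed by the placed mobile chains in
#' standard PDB convention (`%8.3f` coordinates), with TER records between
#' chains. Reading the output back reproduces coordinates to the format's
#' 0.001 Angstrom precision.
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @param file optional path; when `NULL` the text is only returned.
#' @return invisibly, the PDB text as a character vector of lines.
#' @export
write_pose <- function(input, pose, file = NULL) {
  if (nrow(input$mobile) == 0) stop("empty mobile structure")
  placed <- apply_pose(input, pose)
  if (length(intersect(unique(input$receptor$chain), unique(placed$chain))) > 0) {
    stop("chain-id collision between receptor and mobile")
  }
  combined <- rbind(as.data.frame(input$receptor), as.data.frame(placed))
  combined$serial <- seq_len(nrow(combined))
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz = as.numeric(t(as.matrix(combined[, c("x", "y", "z")]))),
    type = ifelse(combined$is_het, "HETATM", "ATOM"),
    resno = combined$resseq, resid = combined$resname,
    eleno = combined$serial, elety = combined$name,
    chain = combined$chain,
    insert = ifelse(combined$icode == "", NA, combined$icode),
    elesy = combined$element,
    o = rep(1, nrow(combined)), b = rep(0, nrow(combined)),
    chainter = TRUE
  )
  out <- readLines(tmp, warn = FALSE)
  if (is.null(file)) unlink(tmp)
  invisible(out)
}
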