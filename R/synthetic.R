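#' Specification for the synthetic toy-complex generator
#'
#' Controls the deterministic pseudo-protein pair (ideal-helix poly-alanine
#' lattices docked face-to-face with one hetero moiety each) and the decoy
#' ensemble drawn around the native placement. A fixed seed yields
#' byte-identical structures.
#'
#' @param n_residues residues per pseudo-protein.
#' @param moiety_atoms atoms per hetero moiety.
#' @param separation distance between the two helix axes, Angstrom.
#' @param seed RNG seed for decoy generation.
#' @param n_decoys number of decoys (the first is always the native
#'   placement).
#' @param max_translation maximum decoy translation perturbation, Angstrom.
#' @param max_rotation maximum decoy rotation perturbation, degrees.
#' @param far_fraction fraction of decoys displaced far outside the 3-20 A
#'   anchor-warhead window ("unpromising" decoys).
#' @return a `protern_synth` object.
#' @export
synthetic_spec <- function(n_residues = 12, moiety_atoms = 3, separation = 10.4,
                           seed = 1, n_decoys = 50, max_translation = 3,
                           max_rotation = 10, far_fraction = 0.1) {
  stopifnot(n_residues >= 3, moiety_atoms >= 1, n_decoys >= 1,
            max_translation >= 0, max_rotation >= 0,
            far_fraction >= 0, far_fraction <= 1)
  structure(as.list(environment()), class = "protern_synth")
}

# ideal-helix poly-alanine-like backbone (N, CA, C, O, CB per residue)
.helix <- function(n_res, chain, x_offset = 0, phase = 0) {
  radius <- 2.3; rise <- 1.5; turn <- 50 * pi / 180
  rows <- list()
  serial <- 0
  for (i in seq_len(n_res) - 1) {
    th <- phase + i * turn
    z <- i * rise
    at <- function(name, r, dth, dz) {
      serial <<- serial + 1
      data.frame(serial = serial, name = name, altloc = "",
                 resname = "ALA", chain = chain, resseq = i + 1, icode = "",
                 x = x_offset + r * cos(th + dth), y = r * sin(th + dth),
                 z = z + dz,
                 element = substr(name, 1, 1), is_het = FALSE,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- rbind(
      at("N", radius, -26 * pi / 180, -1.0),
      at("CA", radius, 0, 0),
      at("C", radius, 26 * pi / 180, 1.05),
      at("O", radius + 1.23, 26 * pi / 180, 1.05),
      at("CB", radius + 1.5, 0, 0))
  }
  df <- do.call(rbind, rows)
  df$mass <- element_mass(df$element)
  .new_structure(df)
}

.moiety_res <- function(resname, chain, resseq, serial_start, center) {
  elements <- c("C", "N", "O")
  k <- length(center$n)
  df <- data.frame(
    serial = serial_start + seq_len(k) - 1,
    name = paste0(elements[(seq_len(k) - 1) %% 3 + 1], seq_len(k)),
    altloc = "", resname = resname, chain = chain, resseq = resseq,
    icode = "",
    x = center$x + 1.4 * (seq_len(k) - (k + 1) / 2),
    y = center$y, z = center$z,
    element = elements[(seq_len(k) - 1) %% 3 + 1], is_het = TRUE,
    stringsAsFactors = FALSE)
  df$mass <- element_mass(df$element)
  .new_structure(df)
}

#' Build a deterministic synthetic ternary-docking input
#'
#' Two non-overlapping pseudo-proteins (poly-alanine-like ideal helices)
#' are docked face-to-face with a multi-residue interface, and each carries
#' one small hetero moiety (the anchor on the fixed protein, the warhead on
#' the mobile one) placed so the native anchor-warhead mass-centre distance
#' lies inside the 3-20 A window. The native pose is the identity.
#'
#' @param spec a `protern_synth`.
#' @return list with `input` (a `protern_input`) and `native` (the identity
#'   `protern_pose`).
#' @export
make_toy_complex <- function(spec = synthetic_spec()) {
  n <- spec$n_residues
  receptor <- .helix(n, chain = "A", x_offset = 0, phase = 0)
  mobile <- .helix(n, chain = "B", x_offset = spec$separation, phase = pi)
  z_mid <- (n - 1) * 1.5 / 2
  k <- spec$moiety_atoms
  anchor <- .moiety_res("ANC", "A", n + 1, max(receptor$serial) + 1,
                        list(n = seq_len(k), x = spec$separation / 2 - 2,
                             y = 1.2, z = z_mid))
  warhead <- .moiety_res("WHD", "B", n + 1, max(mobile$serial) + 1,
                         list(n = seq_len(k), x = spec$separation / 2 + 2,
                              y = -1.2, z = z_mid))
  receptor <- .new_structure(rbind(as.data.frame(receptor), as.data.frame(anchor)))
  mobile <- .new_structure(rbind(as.data.frame(mobile), as.data.frame(warhead)))
  input <- ternary_input(receptor, mobile)
  list(input = input, native = pose("d0000"))
}

.axis_angle <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)),
    3, 3, byrow = TRUE)
}

.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Draw synthetic docking decoys around the native placement
#'
#' Decoy 1 is always the native placement (identity transform). Near
#' decoys are perturbed by a uniform random rotation up to
#' `max_rotation` about the mobile mass centre and a random translation up
#' to `max_translation`; the last `round(far_fraction * n_decoys)` decoys
#' are additionally displaced ~35 A so their anchor-warhead distance falls
#' outside the rough-filter window. All randomness is confined to this
#' generator; the caller's RNG state is restored on exit.
#'
#' @param input a `protern_input` (from [make_toy_complex()]).
#' @param spec a `protern_synth`.
#' @return list with `poses` (list of `protern_pose`, provenance `"seed"`)
#'   and `truth` (data frame of true perturbation magnitudes per decoy).
#' @export
make_decoys <- function(input, spec = synthetic_spec()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  centre <- mass_center(input$mobile)
  n <- spec$n_decoys
  n_far <- round(spec$far_fraction * n)
  poses <- vector("list", n)
  truth <- data.frame(id = sprintf("d%04d", seq_len(n) - 1),
                      kind = "near", angle = 0, shift = 0,
                      stringsAsFactors = FALSE)
  truth$kind[n - seq_len(n_far) + 1] <- "far"
  truth$kind[1] <- "native"
  for (i in seq_len(n)) {
    id <- truth$id[i]
    if (i == 1) {
      poses[[i]] <- pose(id)
      next
    }
    ang <- stats::runif(1, 0, spec$max_rotation)
    rot <- .axis_angle(.runit(), ang)
    shift <- if (truth$kind[i] == "far") {
      stats::runif(1, 30, 40)
    } else {
      spec$max_translation * stats::runif(1)^(1 / 3)
    }
    tr <- .runit() * shift
    truth$angle[i] <- ang
    truth$shift[i] <- shift
    poses[[i]] <- pose(id, rigid_transform(rot, tr, centre))
  }
  list(poses = poses, truth = truth)
}

#' Write poses as a transform table
#'
#' Tab-separated, one row per pose: id, seed id, provenance, the row-major
#' rotation matrix, translation and rotation centre. Round-trips through
#' [read_transform_table()].
#'
#' @param poses list of `protern_pose`.
#' @param file output path.
#' @export
write_transform_table <- function(poses, file) {
  rows <- lapply(poses, function(p) {
    tf <- p$transform
    data.frame(id = p$id, seed_id = p$seed_id, provenance = p$provenance,
               t(as.numeric(t(tf$rotation))), t(tf$translation), t(tf$center),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("id", "seed_id", "provenance",
                 paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)),
                 paste0("t", 1:3), paste0("c", 1:3))
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read poses from a transform table
#'
#' @param file path written by [write_transform_table()].
#' @return list of `protern_pose`.
#' @export
read_transform_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    rot <- matrix(as.numeric(df[i, paste0("r", c(11, 12, 13, 21, 22, 23,
                                                 31, 32, 33))]),
                  3, 3, byrow = TRUE)
    pose(df$id[i],
         rigid_transform(rot, as.numeric(df[i, paste0("t", 1:3)]),
                         as.numeric(df[i, paste0("c", 1:3)])),
         seed_id = df$seed_id[i],
         provenance = df$provenance[i])
  })
}
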