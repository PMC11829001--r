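#' Mass centre of a set of atoms
#'
#' Mass-weighted mean coordinate, `sum(m_i x_i) / sum(m_i)`.
#'
#' @param atoms a `protern_structure` (or any data frame with `x`, `y`, `z`
#'   and `mass` columns).
#' @return length-3 numeric vector (Angstrom).
#' @export
mass_center <- function(atoms) {
  if (nrow(atoms) == 0) stop("mass_center: empty atom set")
  w <- atoms$mass / sum(atoms$mass)
  as.numeric(crossprod(w, coords(atoms)))
}

#' Anchor-warhead mass-centre distance for a pose
#'
#' Euclidean distance between the mass centre of the receptor moiety
#' (anchor) and the mass centre of the posed mobile moiety (warhead) — the
#' quantity the rough ligand-based filter thresholds.
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @return distance in Angstrom.
#' @export
moiety_distance <- function(input, pose) {
  parts <- strip_moieties(input)
  warhead <- .set_coords(parts$mobile_moiety,
                         .apply_transform(coords(parts$mobile_moiety),
                                          pose$transform))
  sqrt(sum((mass_center(parts$receptor_moiety) - mass_center(warhead))^2))
}

#' Grid specification for translational/rotational refinement
#'
#' Defaults are the pipeline's study settings: translations of +/-4.5 A at
#' 1.5 A resolution and rotations of +/-15 degrees at 5 degree resolution
#' on all three axes.
#'
#' @param translation_extent,translation_step Angstrom.
#' @param rotation_extent,rotation_step degrees.
#' @return a `protern_grid` object.
#' @export
grid_spec <- function(translation_extent = 4.5, translation_step = 1.5,
                      rotation_extent = 15, rotation_step = 5) {
  for (p in list(c(translation_extent, translation_step),
                 c(rotation_extent, rotation_step))) {
    if (p[1] <= 0 || p[2] <= 0 || abs(p[1] / p[2] - round(p[1] / p[2])) > 1e-9) {
      stop("grid extent must be a positive integer multiple of its step")
    }
  }
  structure(list(translation_extent = translation_extent,
                 translation_step = translation_step,
                 rotation_extent = rotation_extent,
                 rotation_step = rotation_step),
            class = "protern_grid")
}

.axis_values <- function(extent, step) {
  k <- round(extent / step)
  step * seq.int(-k, k)
}

#' Enumerate translational grid offsets
#'
#' Full Cartesian product of the per-axis offsets, in deterministic
#' lexicographic `(x, y, z)` order (x varies slowest). The origin is always
#' included; the default spec yields `7^3 = 343` offsets.
#'
#' @param spec a `protern_grid`.
#' @return numeric matrix with columns `x`, `y`, `z` (Angstrom).
#' @export
translation_offsets <- function(spec = grid_spec()) {
  v <- .axis_values(spec$translation_extent, spec$translation_step)
  g <- expand.grid(z = v, y = v, x = v, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, c("x", "y", "z")])
}

#' Enumerate rotational grid Euler triples
#'
#' Full Cartesian product of per-axis Euler angles in degrees, deterministic
#' lexicographic `(phi, theta, psi)` order; the identity triple is included.
#' The default spec yields `7^3 = 343` triples.
#'
#' @param spec a `protern_grid`.
#' @return numeric matrix with columns `phi`, `theta`, `psi` (degrees,
#'   rotations about x, y, z).
#' @export
rotation_triples <- function(spec = grid_spec()) {
  v <- .axis_values(spec$rotation_extent, spec$rotation_step)
  g <- expand.grid(psi = v, theta = v, phi = v, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, c("phi", "theta", "psi")])
}

#' Rotation matrix from an Euler triple
#'
#' Convention: intrinsic x -> y -> z rotations,
#' `R = Rz(psi) %*% Ry(theta) %*% Rx(phi)`, angles in degrees. The
#' convention is fixed and documented so grid rotations are reproducible.
#'
#' @param phi,theta,psi rotation angles in degrees about x, y, z.
#' @return 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(phi, theta, psi) {
  r <- pi / 180
  cp <- cos(phi * r); sp <- sin(phi * r)
  ct <- cos(theta * r); st <- sin(theta * r)
  cs <- cos(psi * r); ss <- sin(psi * r)
  rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  ry <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3)
  rz <- matrix(c(cs, ss, 0, -ss, cs, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Derive a translated child pose
#'
#' The child applies the parent transform followed by a translation by
#' `offset`; provenance becomes `"translated"` and the seed id is inherited.
#'
#' @param parent a `protern_pose`.
#' @param offset length-3 numeric offset (Angstrom).
#' @param id identifier for the child pose.
#' @return a `protern_pose`.
#' @export
make_translated_pose <- function(parent, offset,
                                 id = paste0(parent$id, "_t")) {
  tf <- parent$transform
  child <- rigid_transform(tf$rotation, tf$translation + as.numeric(offset),
                           tf$center)
  pose(id, child, seed_id = parent$seed_id, provenance = "translated")
}

#' Derive a rotated child pose
#'
#' Applies an Euler-grid rotation about the mass centre of the mobile
#' protein in its current (parent) pose, so that centre is a fixed point of
#' the added motion. The rotation centre is the posed centre, keeping
#' children near the parent placement.
#'
#' @param input a `protern_input` (needed for the posed mobile mass centre).
#' @param parent a `protern_pose`.
#' @param euler length-3 numeric `(phi, theta, psi)` in degrees.
#' @param id identifier for the child pose.
#' @return a `protern_pose`.
#' @export
make_rotated_pose <- function(input, parent, euler,
                              id = paste0(parent$id, "_r")) {
  if (any(euler < -180 | euler > 180)) stop("Euler angles must lie in [-180, 180]")
  r2 <- euler_rotation(euler[1], euler[2], euler[3])
  tf <- parent$transform
  c2 <- mass_center(apply_pose(input, parent))
  # compose: x -> R1(x - c1) + c1 + t1, then y -> R2(y - c2) + c2,
  # re-expressed about the original centre c1
  rot <- r2 %*% tf$rotation
  trans <- as.numeric(r2 %*% (tf$center + tf$translation - c2)) + c2 - tf$center
  pose(id, rigid_transform(rot, trans, tf$center),
       seed_id = parent$seed_id, provenance = "rotated")
}
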