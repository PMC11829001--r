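.backbone_atoms <- c("N", "CA", "C", "O")

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `target` via the SVD of the
#' cross-covariance matrix, with the determinant correction that excludes
#' reflections. Returns the map `x -> R x + t` and the minimised RMSD.
#'
#' @param mobile,target n x 3 coordinate matrices in row correspondence,
#'   n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `transformed` (the fitted mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) {
    stop("coordinate sets differ in size: ", nrow(mobile), " vs ", nrow(target))
  }
  if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  p <- sweep(mobile, 2, cm); q <- sweep(target, 2, ct)
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p %*% t(rot)
  fitted <- sweep(fitted, 2, ct, FUN = "+")
  list(rotation = rot,
       translation = as.numeric(ct - rot %*% cm),
       rmsd = sqrt(mean(rowSums((fitted - target)^2))),
       transformed = fitted)
}

#' Assemble a receptor+mobile complex for evaluation
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @param proteins_only drop the tagged moiety atoms (default TRUE; the
#'   DockQ layer compares the proteins).
#' @return list (class `protern_complex`) with `receptor` and `mobile`
#'   structures.
#' @export
posed_complex <- function(input, pose, proteins_only = TRUE) {
  if (proteins_only) {
    pp <- .protein_pair(input, pose)
  } else {
    pp <- list(receptor = input$receptor, mobile = apply_pose(input, pose))
  }
  structure(pp, class = "protern_complex")
}

#' Residue contacts of an evaluation complex
#'
#' @param complex a `protern_complex`.
#' @param cutoff heavy-atom contact cutoff, Angstrom (5 A for fnat).
#' @return character set of `"receptor_residue--mobile_residue"` pairs.
#' @export
complex_contacts <- function(complex, cutoff = 5) {
  pairs <- cpp_close_pairs(coords(complex$receptor), coords(complex$mobile),
                           cutoff)
  sort(unique(paste(residue_ids(complex$receptor)[pairs[, 1]],
                    residue_ids(complex$mobile)[pairs[, 2]], sep = "--")))
}

#' Fraction of native contacts
#'
#' `|model intersect native| / |native|` over residue contacts at the 5 A
#' native-contact definition.
#'
#' @param model_contacts,native_contacts character contact sets (from
#'   [complex_contacts()]) or `protern_complex` objects.
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(model_contacts, native_contacts) {
  as_set <- function(x) if (inherits(x, "protern_complex")) complex_contacts(x) else x
  m <- as_set(model_contacts); n <- as_set(native_contacts)
  if (length(n) == 0) stop("native contact set is empty: no interface to score")
  length(intersect(m, n)) / length(n)
}

# matched backbone coordinate pair between two structures sharing residue
# numbering; keys are (residue id, atom name)
.matched_backbone <- function(model_s, native_s, residues = NULL) {
  key <- function(s) paste(residue_ids(s), s$name, sep = "@")
  nat_keep <- native_s$name %in% .backbone_atoms
  if (!is.null(residues)) nat_keep <- nat_keep & residue_ids(native_s) %in% residues
  nk <- key(native_s)[nat_keep]
  mk <- key(model_s)
  hit <- match(nk, mk)
  if (anyNA(hit)) {
    bad <- unique(sub("@.*", "", nk[is.na(hit)]))
    stop("unmappable residue(s) between model and native: ",
         paste(bad, collapse = ", "))
  }
  list(model = coords(model_s)[hit, , drop = FALSE],
       native = coords(native_s)[nat_keep, , drop = FALSE])
}

#' Ligand RMSD
#'
#' Superposes the model's receptor backbone (N, CA, C, O) onto the
#' native's, applies that fit to the model's mobile protein, and reports
#' the backbone RMSD of the mobile (ligand) protein.
#'
#' @param model,native `protern_complex` objects sharing residue numbering.
#' @return RMSD in Angstrom.
#' @export
lrmsd <- function(model, native) {
  rec <- .matched_backbone(model$receptor, native$receptor)
  fit <- kabsch_superpose(rec$model, rec$native)
  mob <- .matched_backbone(model$mobile, native$mobile)
  placed <- sweep(mob$model %*% t(fit$rotation), 2, fit$translation, FUN = "+")
  sqrt(mean(rowSums((placed - mob$native)^2)))
}

#' Native interface residues
#'
#' Residues of both proteins with any heavy atom within `cutoff` (10 A for
#' iRMSD) of the partner protein.
#'
#' @param complex a `protern_complex`.
#' @param cutoff Angstrom.
#' @return character vector of residue ids.
#' @export
interface_residues <- function(complex, cutoff = 10) {
  pairs <- cpp_close_pairs(coords(complex$receptor), coords(complex$mobile),
                           cutoff)
  sort(unique(c(residue_ids(complex$receptor)[pairs[, 1]],
                residue_ids(complex$mobile)[pairs[, 2]])))
}

#' Interface RMSD
#'
#' Backbone RMSD over the native interface residues (both proteins, 10 A
#' definition) after superposing the model interface backbone onto the
#' native interface backbone.
#'
#' @param model,native `protern_complex` objects sharing residue numbering.
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(model, native) {
  res <- interface_residues(native)
  if (length(res) == 0) stop("native complex has an empty interface")
  rec <- .matched_backbone(model$receptor, native$receptor, res)
  mob <- .matched_backbone(model$mobile, native$mobile, res)
  m <- rbind(rec$model, mob$model)
  n <- rbind(rec$native, mob$native)
  kabsch_superpose(m, n)$rmsd
}

#' DockQ quality class from a DockQ score
#'
#' Boundaries: `< 0.23` Incorrect, `[0.23, 0.49)` Acceptable,
#' `[0.49, 0.80)` Medium, `>= 0.80` High.
#'
#' @param dockq numeric vector of DockQ scores.
#' @return character vector of classes.
#' @export
dockq_class <- function(dockq) {
  cut_pts <- c(-Inf, 0.23, 0.49, 0.80, Inf)
  labs <- c("Incorrect", "Acceptable", "Medium", "High")
  as.character(cut(dockq, cut_pts, labs, right = FALSE))
}

#' Combine fnat, iRMSD and LRMSD into a DockQ result
#'
#' `DockQ = (fnat + 1/(1 + (irmsd/1.5)^2) + 1/(1 + (lrmsd/8.5)^2)) / 3`,
#' with the 1.5 A and 8.5 A scaling constants of the DockQ method.
#'
#' @param fnat fraction of native contacts in `[0, 1]`.
#' @param irmsd interface RMSD, Angstrom.
#' @param lrmsd ligand RMSD, Angstrom.
#' @return list (class `protern_dockq`) with `fnat`, `irmsd`, `lrmsd`,
#'   `dockq` and `quality_class`.
#' @export
dockq <- function(fnat, irmsd, lrmsd) {
  stopifnot(fnat >= 0, fnat <= 1, irmsd >= 0, lrmsd >= 0)
  score <- (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
  structure(list(fnat = fnat, irmsd = irmsd, lrmsd = lrmsd, dockq = score,
                 quality_class = dockq_class(score)),
            class = "protern_dockq")
}

#' @export
print.protern_dockq <- function(x, ...) {
  cat(sprintf("DockQ %.3f (%s): fnat %.3f, iRMSD %.3f A, LRMSD %.3f A\n",
              x$dockq, x$quality_class, x$fnat, x$irmsd, x$lrmsd))
  invisible(x)
}

#' Full DockQ evaluation of a model against a native complex
#'
#' @param model,native `protern_complex` objects sharing residue numbering.
#' @return a `protern_dockq` result.
#' @export
dockq_eval <- function(model, native) {
  dockq(fnat(model, native), irmsd(model, native), lrmsd(model, native))
}

#' Percentage of near-native poses
#'
#' Share of DockQ values at or above the acceptable boundary (0.23),
#' as a percentage.
#'
#' @param dockq_values numeric vector of DockQ scores in a cluster.
#' @return percentage in `[0, 100]`.
#' @export
near_native_percentage <- function(dockq_values) {
  if (length(dockq_values) == 0) stop("empty cluster: no DockQ values")
  100 * sum(dockq_values >= 0.23) / length(dockq_values)
}

#' Ranking accuracy versus rank threshold
#'
#' `accuracy(tau) = |{rank <= tau}| / n` — the share of cases whose
#' best-cluster rank does not exceed the threshold; non-decreasing in tau.
#'
#' @param ranks positive integer cluster ranks, one per benchmark case.
#' @param thresholds integer thresholds to evaluate.
#' @return data frame with `threshold` and `accuracy`.
#' @export
ranking_accuracy_curve <- function(ranks, thresholds) {
  stopifnot(all(ranks >= 1))
  data.frame(threshold = thresholds,
             accuracy = vapply(thresholds,
                               function(t) mean(ranks <= t), numeric(1)))
}
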