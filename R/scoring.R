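# Bondi van der Waals radii (A) used by the SASA sphere-point method.
.vdw_radii <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                ZN = 1.39, FE = 1.52, MG = 1.73)

# UFF nonbonded parameters: well depth D (kcal/mol) and minimum-energy
# distance x (A) per element; geometric-mean combination rules.
.uff_eps <- c(H = 0.044, C = 0.105, N = 0.069, O = 0.060, S = 0.274,
              P = 0.305, F = 0.050, CL = 0.227, BR = 0.251, I = 0.339,
              ZN = 0.124, FE = 0.013)
.uff_xm <- c(H = 2.886, C = 3.851, N = 3.660, O = 3.500, S = 4.035,
             P = 4.147, F = 3.364, CL = 3.947, BR = 4.189, I = 4.009,
             ZN = 2.763, FE = 2.912)

.lookup <- function(table, element, default) {
  v <- table[toupper(element)]
  v[is.na(v)] <- default
  unname(v)
}

#' Anchor-warhead distance window
#'
#' Defaults 3-20 Angstrom; both boundaries are inclusive (poses at exactly
#' 3 or 20 A are kept).
#'
#' @param d_min,d_max Angstrom, `0 < d_min < d_max`.
#' @return a `protern_window`.
#' @export
distance_window <- function(d_min = 3, d_max = 20) {
  if (!(d_min > 0 && d_min < d_max)) stop("require 0 < d_min < d_max")
  structure(list(d_min = d_min, d_max = d_max), class = "protern_window")
}

#' Rough ligand-based pose filter
#'
#' Keeps poses whose anchor-warhead mass-centre distance lies inside the
#' window (boundaries inclusive), preserving input order. The fastest
#' filter in the pipeline: it discards orientations whose ligands point
#' away from each other before any protein-based scoring runs.
#'
#' @param input a `protern_input`.
#' @param poses list of `protern_pose`.
#' @param window a `protern_window`.
#' @param quiet suppress the removed-count message.
#' @return the kept poses (a sub-list of `poses`).
#' @export
rough_ligand_filter <- function(input, poses, window = distance_window(),
                                quiet = FALSE) {
  d <- vapply(poses, function(p) moiety_distance(input, p), numeric(1))
  keep <- d >= window$d_min & d <= window$d_max
  if (!quiet) {
    message(sprintf("rough ligand filter: removed %d of %d poses",
                    sum(!keep), length(poses)))
  }
  poses[keep]
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Total SASA by the sphere-point method: each atom's solvent sphere
#' (van der Waals radius + probe) carries `n_points` deterministic
#' golden-spiral test points; points inside any other solvent sphere are
#' buried. Deterministic for a fixed point count.
#'
#' @param structure a `protern_structure` (heavy atoms).
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points test points per atom.
#' @return total area in Angstrom^2.
#' @export
sasa_score <- function(structure, probe_radius = 1.4, n_points = 960) {
  if (nrow(structure) == 0) stop("sasa_score: empty structure")
  radii <- .lookup(.vdw_radii, structure$element, 1.70)
  sum(cpp_sasa(coords(structure), radii, probe_radius, as.integer(n_points)))
}

# Receptor/mobile protein-only coordinate pair for a placed pose (moieties
# stripped, as all protein-based scores operate on the proteins alone).
.protein_pair <- function(input, pose) {
  parts <- strip_moieties(input)
  mob <- .set_coords(parts$mobile_protein,
                     .apply_transform(coords(parts$mobile_protein),
                                      pose$transform))
  list(receptor = parts$receptor_protein, mobile = mob)
}

#' Inter-protein interaction energy (UFF Lennard-Jones surrogate)
#'
#' Builtin provider: 12-6 Lennard-Jones sum over receptor-mobile heavy-atom
#' pairs within the cutoff, with per-element UFF well depths and minimum
#' distances under geometric-mean combination. This is a documented
#' surrogate for an Open Babel `obenergy` UFF total; an external provider
#' command can be substituted via [filter_config()].
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @param cutoff pair cutoff in Angstrom; `<= 0` disables it.
#' @return energy in kcal/mol (lower is better).
#' @export
interaction_energy <- function(input, pose, cutoff = 8) {
  pp <- .protein_pair(input, pose)
  cpp_lj_energy(coords(pp$receptor), coords(pp$mobile),
                .lookup(.uff_eps, pp$receptor$element, 0.105),
                .lookup(.uff_eps, pp$mobile$element, 0.105),
                .lookup(.uff_xm, pp$receptor$element, 3.851),
                .lookup(.uff_xm, pp$mobile$element, 3.851),
                cutoff)
}

#' Steric stability score (clash penalty)
#'
#' Builtin surrogate: minus the number of inter-protein heavy-atom pairs
#' closer than `clash_cutoff`; a clash-free pose scores 0 and more clashes
#' score lower (higher is better).
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @param clash_cutoff Angstrom.
#' @return non-positive numeric.
#' @export
stability_score <- function(input, pose, clash_cutoff = 2.5) {
  pp <- .protein_pair(input, pose)
  -cpp_count_close_pairs(coords(pp$receptor), coords(pp$mobile), clash_cutoff)
}

#' Interface quality score
#'
#' Builtin surrogate: the number of inter-protein residue-residue contacts
#' at the given heavy-atom cutoff — a monotone proxy for an external
#' structure-quality assessor such as VoroMQA (this is NOT VoroMQA's
#' statistical potential). Higher is better either way, so the ScoreRecord
#' contract is provider-independent.
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @param cutoff contact cutoff, Angstrom.
#' @return non-negative numeric.
#' @export
interface_quality <- function(input, pose, cutoff = 5) {
  length(interface_contacts(input, pose, cutoff)$contacts)
}

#' Interaction z-scores over a pose set
#'
#' Builtin surrogate for an external interaction z-score assessor:
#' population z-score of each pose's interface contact count relative to
#' the current pose set. A degenerate set (zero spread) yields all zeros
#' with a warning.
#'
#' @param input a `protern_input`.
#' @param poses list of `protern_pose`.
#' @param cutoff contact cutoff, Angstrom.
#' @return named numeric vector of z-scores (higher is better).
#' @export
interaction_zscore <- function(input, poses, cutoff = 5) {
  counts <- vapply(poses, function(p) interface_quality(input, p, cutoff),
                   numeric(1))
  names(counts) <- vapply(poses, `[[`, character(1), "id")
  n <- length(counts)
  s <- sqrt(sum((counts - mean(counts))^2) / n)  # population sd
  if (s == 0) {
    warning("degenerate pose set: zero contact-count variance; all z-scores 0")
    return(counts * 0)
  }
  (counts - mean(counts)) / s
}

#' Sequential-filtration configuration
#'
#' Components run in a prioritised order, fastest first; each stage keeps
#' the top `retention` fraction of survivors by that component's value.
#' The published pipeline fixes absolute per-stage thresholds in material
#' not reproduced here, so retention fractions (default 0.75 per stage)
#' stand in and are fully configurable. A custom provider function
#' `function(input, poses) named numeric` may replace any builtin
#' component.
#'
#' @param components character vector, ordered subset of
#'   `c("stability", "sasa", "energy", "pizsa")`.
#' @param retention single fraction or one per component, each in (0, 1].
#' @param providers optional named list of provider functions.
#' @param sasa_points SASA test points per atom for the sasa component.
#' @param energy_cutoff Lennard-Jones pair cutoff, Angstrom.
#' @param contact_cutoff residue-contact cutoff, Angstrom.
#' @return a `protern_filters` object.
#' @export
filter_config <- function(components = c("stability", "sasa", "energy", "pizsa"),
                          retention = 0.75, providers = list(),
                          sasa_points = 960, energy_cutoff = 8,
                          contact_cutoff = 5) {
  known <- c("stability", "sasa", "energy", "pizsa")
  if (!all(components %in% known)) {
    stop("unknown filter component(s): ",
         paste(setdiff(components, known), collapse = ", "))
  }
  retention <- rep_len(retention, length(components))
  if (any(retention <= 0 | retention > 1)) stop("retention fractions must be in (0, 1]")
  structure(list(components = components,
                 retention = setNames(retention, components),
                 providers = providers,
                 sasa_points = sasa_points,
                 energy_cutoff = energy_cutoff,
                 contact_cutoff = contact_cutoff),
            class = "protern_filters")
}

# direction of each score component: TRUE when larger values are better
.higher_is_better <- c(stability = TRUE, sasa = TRUE, energy = FALSE,
                       pizsa = TRUE, quality = TRUE)

# Compute one component for a pose set; returns a named numeric vector.
.component_values <- function(input, poses, component, config) {
  ids <- vapply(poses, `[[`, character(1), "id")
  prov <- config$providers[[component]]
  if (!is.null(prov)) return(setNames(prov(input, poses), ids))
  v <- switch(component,
    stability = vapply(poses, function(p) stability_score(input, p), numeric(1)),
    sasa = vapply(poses, function(p) {
      pp <- .protein_pair(input, p)
      sasa_score(.new_structure(rbind(as.data.frame(pp$receptor),
                                      as.data.frame(pp$mobile))),
                 n_points = config$sasa_points)
    }, numeric(1)),
    energy = vapply(poses, function(p)
      interaction_energy(input, p, config$energy_cutoff), numeric(1)),
    pizsa = as.numeric(interaction_zscore(input, poses, config$contact_cutoff)),
    quality = vapply(poses, function(p)
      interface_quality(input, p, config$contact_cutoff), numeric(1)),
    stop("unknown component: ", component))
  setNames(v, ids)
}

.score_records <- function(values, component) {
  better <- if (.higher_is_better[[component]]) -values else values
  data.frame(pose_id = names(values), component = component,
             value = as.numeric(values),
             rank = rank(better, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Sequential protein-based filtration
#'
#' Applies the configured score components in order; at each stage the top
#' `ceiling(retention * n)` poses by that component survive (ties broken by
#' pose id for determinism). Every computed score is retained in the
#' returned table, including scores of poses dropped later, and each final
#' survivor carries a value for every component in the chain.
#'
#' @param input a `protern_input`.
#' @param poses list of `protern_pose` (already past the rough filter).
#' @param config a `protern_filters`.
#' @param quiet suppress per-stage survivor messages.
#' @return list with `kept` (surviving poses, input order) and `table`
#'   (data frame `pose_id`, `component`, `value`, `rank`).
#' @export
sequential_filter <- function(input, poses, config = filter_config(),
                              quiet = FALSE) {
  if (length(poses) == 0) stop("pipeline error at stage 'sequential_filter': empty pose set")
  records <- list()
  current <- poses
  for (component in config$components) {
    if (length(current) == 0) {
      stop("pipeline error: empty survivor set entering stage '", component, "'")
    }
    values <- .component_values(input, current, component, config)
    records[[component]] <- .score_records(values, component)
    n_keep <- ceiling(config$retention[[component]] * length(current))
    better <- if (.higher_is_better[[component]]) -values else values
    keep_ids <- names(values)[order(better, names(values))][seq_len(n_keep)]
    current <- current[vapply(current, `[[`, character(1), "id") %in% keep_ids]
    if (!quiet) {
      message(sprintf("filter '%s': kept %d of %d poses", component,
                      length(current), length(values)))
    }
  }
  list(kept = current, table = do.call(rbind, c(records, make.row.names = FALSE)))
}

#' External score provider via a command-line tool
#'
#' Builds a provider function that writes each posed complex to a PDB file,
#' invokes `command` on it and parses the last numeric field of the line
#' matched by `pattern` as the score. Use in
#' `filter_config(providers = list(energy = external_provider("obenergy")))`.
#'
#' @param command executable name or path.
#' @param args extra arguments placed before the PDB path.
#' @param pattern regular expression selecting the output line holding the
#'   score (default: a line containing "TOTAL ENERGY").
#' @return a provider `function(input, poses)`.
#' @export
external_provider <- function(command, args = character(),
                              pattern = "TOTAL ENERGY") {
  force(command); force(args); force(pattern)
  function(input, poses) {
    if (Sys.which(command) == "") {
      stop("configuration error: external tool '", command,
           "' not found; fall back to the builtin provider")
    }
    vapply(poses, function(p) {
      f <- tempfile(fileext = ".pdb")
      on.exit(unlink(f), add = TRUE)
      write_pose(input, p, file = f)
      out <- suppressWarnings(system2(command, c(args, f), stdout = TRUE,
                                      stderr = TRUE))
      hit <- grep(pattern, out, value = TRUE)
      if (length(hit) == 0) {
        stop("provider error: no line matching '", pattern,
             "' in output of ", command, ":\n", paste(out, collapse = "\n"))
      }
      tok <- regmatches(hit[1], gregexpr("-?[0-9]+\\.?[0-9]*", hit[1]))[[1]]
      as.numeric(tok[length(tok)])
    }, numeric(1))
  }
}
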