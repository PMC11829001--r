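#' Aggregate per-component ranks into a consensus order
#'
#' Two-component Borda / mean-rank aggregation: each component is ranked
#' descending (larger SASA and larger quality are better) with average-rank
#' tie handling; the aggregate score is the (optionally weighted) mean of
#' the component ranks, and the output is ordered by ascending aggregate,
#' ties broken by pose id. Being rank-based, the result is invariant under
#' any strictly monotone transform of either component's values.
#'
#' @param scores data frame with columns `pose_id`, `component`, `value`
#'   covering every pose for every requested component.
#' @param components components to aggregate (default SASA + quality).
#' @param weights optional numeric weights, one per component.
#' @return data frame (class `protern_ranked`) ordered by `aggregate`, with
#'   one `rank_<component>` column per component.
#' @export
aggregate_ranks <- function(scores, components = c("sasa", "quality"),
                            weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(components))
  weights <- weights / sum(weights)
  ids <- sort(unique(scores$pose_id))
  ranks <- matrix(NA_real_, length(ids), length(components),
                  dimnames = list(ids, components))
  for (k in seq_along(components)) {
    comp <- components[k]
    sub <- scores[scores$component == comp, , drop = FALSE]
    missing <- setdiff(ids, sub$pose_id)
    if (length(missing) > 0) {
      stop("missing '", comp, "' value for pose(s): ",
           paste(missing, collapse = ", "))
    }
    v <- setNames(sub$value, sub$pose_id)[ids]
    better <- if (.higher_is_better[[comp]]) -v else v
    ranks[, k] <- rank(better, ties.method = "average")
  }
  aggregate <- as.numeric(ranks %*% weights)
  ord <- order(aggregate, ids)
  out <- data.frame(pose_id = ids[ord], aggregate = aggregate[ord],
                    stringsAsFactors = FALSE)
  for (k in seq_along(components)) {
    out[[paste0("rank_", components[k])]] <- ranks[ord, k]
  }
  class(out) <- c("protern_ranked", "data.frame")
  out
}

#' Select the top-ranked pose ids
#'
#' @param ranked a `protern_ranked` data frame.
#' @param n number to keep (default 200, the pipeline's per-stage budget).
#' @return character vector of at most `n` pose ids, best first.
#' @export
select_top <- function(ranked, n = 200) {
  if (n < 1) stop("n must be >= 1")
  head(ranked$pose_id, n)
}

#' Inter-protein residue contacts of a pose
#'
#' A receptor-mobile residue pair is in contact when any heavy-atom pair
#' between the two residues is within `cutoff` (default 5 A, the fraction-
#' of-common-contacts literature convention). Moiety atoms are excluded.
#'
#' @param input a `protern_input`.
#' @param pose a `protern_pose`.
#' @param cutoff Angstrom.
#' @return list (class `protern_contacts`) with `pose_id` and `contacts`,
#'   a character set of `"receptor_residue--mobile_residue"` pairs.
#' @export
interface_contacts <- function(input, pose, cutoff = 5) {
  pp <- .protein_pair(input, pose)
  pairs <- cpp_close_pairs(coords(pp$receptor), coords(pp$mobile), cutoff)
  contacts <- unique(paste(residue_ids(pp$receptor)[pairs[, 1]],
                           residue_ids(pp$mobile)[pairs[, 2]], sep = "--"))
  structure(list(pose_id = pose$id, contacts = sort(contacts)),
            class = "protern_contacts")
}

#' Fraction of common contacts
#'
#' `fcc(a, b) = |a intersect b| / |a|` — asymmetric by definition. An empty
#' reference set yields 0 with a warning.
#'
#' @param a,b `protern_contacts` objects (or plain character vectors).
#' @return fraction in `[0, 1]`.
#' @export
fcc_similarity <- function(a, b) {
  ca <- if (inherits(a, "protern_contacts")) a$contacts else a
  cb <- if (inherits(b, "protern_contacts")) b$contacts else b
  if (length(ca) == 0) {
    warning("empty contact set: fcc defined as 0")
    return(0)
  }
  length(intersect(ca, cb)) / length(ca)
}

# Pairwise symmetrised FCC similarity matrix via the pose x contact
# incidence matrix (crossprod gives all intersections at once).
.fcc_matrix <- function(contact_sets, sym = c("min", "mean", "max")) {
  sym <- match.arg(sym)
  ids <- vapply(contact_sets, `[[`, character(1), "pose_id")
  universe <- sort(unique(unlist(lapply(contact_sets, `[[`, "contacts"))))
  n <- length(contact_sets)
  inc <- matrix(0, n, length(universe), dimnames = list(ids, universe))
  for (i in seq_len(n)) inc[i, contact_sets[[i]]$contacts] <- 1
  inter <- inc %*% t(inc)
  sizes <- rowSums(inc)
  denom <- pmax(sizes, 1)  # empty sets get similarity 0 below
  f_ab <- inter / denom              # row-normalised: fcc(a, b)
  f_ba <- t(f_ab)
  sim <- switch(sym, min = pmin(f_ab, f_ba), mean = (f_ab + f_ba) / 2,
                max = pmax(f_ab, f_ba))
  sim[sizes == 0, ] <- 0
  sim[, sizes == 0] <- 0
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Greedy leader (Taylor-Butina) clustering on FCC similarity
#'
#' Poses are clustered on the thresholded similarity graph: repeatedly the
#' unassigned pose with the most unassigned neighbours at
#' `similarity >= threshold` becomes a cluster centre (ties: lowest pose
#' id) and absorbs those neighbours; clusters below `min_size` dissolve and
#' their poses are reported unclustered ("eliminated"). The pairwise
#' similarity is the FCC in both directions combined by `sym`
#' (default `min`, the conservative choice for the 0.5 criterion).
#'
#' @param contact_sets list of `protern_contacts`, one per pose.
#' @param threshold similarity criterion in (0, 1] (default 0.5).
#' @param min_size minimum cluster size (default 2).
#' @param sym symmetrisation of the asymmetric FCC: `"min"`, `"mean"` or
#'   `"max"`.
#' @return list with `clusters` (named list of member pose-id vectors,
#'   centre first) and `unclustered` (character vector).
#' @export
fcc_cluster <- function(contact_sets, threshold = 0.5, min_size = 2,
                        sym = "min") {
  stopifnot(threshold > 0, threshold <= 1, min_size >= 1)
  ids <- vapply(contact_sets, `[[`, character(1), "pose_id")
  if (anyDuplicated(ids)) stop("duplicate pose ids in contact sets")
  sim <- .fcc_matrix(contact_sets, sym)
  adj <- sim >= threshold
  diag(adj) <- FALSE
  unassigned <- ids
  clusters <- list()
  while (length(unassigned) > 0) {
    counts <- rowSums(adj[unassigned, unassigned, drop = FALSE])
    best <- max(counts)
    if (best + 1 < min_size) break
    centre <- sort(unassigned[counts == best])[1]
    members <- c(centre,
                 sort(unassigned[adj[centre, unassigned] & unassigned != centre]))
    clusters[[sprintf("c%03d", length(clusters) + 1)]] <- members
    unassigned <- setdiff(unassigned, members)
  }
  list(clusters = clusters, unclustered = unassigned)
}

#' Energy-based cluster filtration
#'
#' The lowest-energy `ceiling(fraction * N)` poses over all clustered poses
#' are selected; every cluster containing at least one selected pose is
#' kept and the rest are eliminated. The cluster holding the global
#' minimum-energy pose is therefore always kept.
#'
#' @param clusters named list of member pose-id vectors.
#' @param energies named numeric vector covering every clustered pose
#'   (kcal/mol, lower is better).
#' @param fraction proportion of poses to select (default 0.25).
#' @return the kept subset of `clusters`.
#' @export
energy_cluster_filter <- function(clusters, energies, fraction = 0.25) {
  members <- unlist(clusters, use.names = FALSE)
  if (anyNA(energies[members])) {
    stop("missing energy for pose(s): ",
         paste(members[is.na(energies[members])], collapse = ", "))
  }
  n_sel <- ceiling(fraction * length(members))
  sel <- members[order(energies[members], members)][seq_len(n_sel)]
  keep <- vapply(clusters, function(m) any(m %in% sel), logical(1))
  clusters[keep]
}

#' Rank clusters by their best members
#'
#' Each cluster is represented by its maximum member SASA and maximum
#' member quality; rank aggregation over these representatives yields the
#' final cluster ranks 1..K.
#'
#' @param clusters named list of member pose-id vectors (after
#'   re-clustering).
#' @param scores score table with `sasa` and `quality` values for every
#'   member pose.
#' @return data frame `cluster_id`, `final_rank`, `size`, `rep_sasa`,
#'   `rep_quality`, `members` (comma-separated), ordered by `final_rank`.
#' @export
rank_clusters <- function(clusters, scores) {
  if (length(clusters) == 0) stop("no clusters to rank")
  val <- function(comp, m) {
    sub <- scores[scores$component == comp & scores$pose_id %in% m, "value"]
    if (length(sub) == 0) stop("missing '", comp, "' values for cluster members")
    max(sub)
  }
  rep_tab <- do.call(rbind, lapply(names(clusters), function(cid) {
    m <- clusters[[cid]]
    data.frame(pose_id = cid,
               component = c("sasa", "quality"),
               value = c(val("sasa", m), val("quality", m)),
               stringsAsFactors = FALSE)
  }))
  ranked <- aggregate_ranks(rep_tab)
  out <- data.frame(
    cluster_id = ranked$pose_id,
    final_rank = seq_len(nrow(ranked)),
    size = vapply(clusters[ranked$pose_id], length, integer(1)),
    rep_sasa = vapply(ranked$pose_id, function(cid)
      val("sasa", clusters[[cid]]), numeric(1)),
    rep_quality = vapply(ranked$pose_id, function(cid)
      val("quality", clusters[[cid]]), numeric(1)),
    members = vapply(clusters[ranked$pose_id], paste, character(1),
                     collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
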