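#' Pipeline configuration
#'
#' Bundles every stage parameter with the study defaults: 200 poses kept
#' after seed ranking and again after translational refinement, the 3-20 A
#' anchor-warhead window, the four-stage sequential filter, the +/-4.5 A /
#' 1.5 A and +/-15 deg / 5 deg grids, FCC clustering at 0.5 with minimum
#' cluster size 2, and the 25% lowest-energy cluster filtration.
#'
#' @param pose_source list describing stage-(ii) pose input: one of
#'   `list(type = "synthetic", spec = synthetic_spec())`,
#'   `list(type = "transform_table", file = path)`, or
#'   `list(type = "pdb_dir", dir = path)`.
#' @param receptor_file,mobile_file PDB paths (ignored for the synthetic
#'   source, which builds its own input).
#' @param protac_file optional PROTAC PDB path passed through to the
#'   external docking stage.
#' @param n_seed_keep,n_translated_keep top-N budgets after rank
#'   aggregation.
#' @param window a `protern_window`.
#' @param filters a `protern_filters`.
#' @param grid a `protern_grid`.
#' @param fcc_threshold,min_cluster_size,energy_fraction clustering and
#'   cluster-filtration parameters.
#' @param contact_cutoff residue-contact cutoff, Angstrom.
#' @param output_dir optional directory for cluster tables and per-cluster
#'   PDBs.
#' @param dock_command optional external PROTAC-docking command; when
#'   unset, the docking stage is skipped with a notice.
#' @return a `protern_config` object.
#' @export
pipeline_config <- function(pose_source = list(type = "synthetic",
                                               spec = synthetic_spec()),
                            receptor_file = NULL, mobile_file = NULL,
                            protac_file = NULL,
                            n_seed_keep = 200, n_translated_keep = 200,
                            window = distance_window(),
                            filters = filter_config(),
                            grid = grid_spec(),
                            fcc_threshold = 0.5, min_cluster_size = 2,
                            energy_fraction = 0.25, contact_cutoff = 5,
                            output_dir = NULL, dock_command = NULL) {
  stopifnot(n_seed_keep >= 1, n_translated_keep >= 1)
  structure(as.list(environment()), class = "protern_config")
}

#' Import stage-(ii) seed poses
#'
#' Loads rigid candidate poses from an external docking run (a transform
#' table or a directory of pose PDBs, from which the rigid map is recovered
#' by superposition onto the input mobile structure) or generates synthetic
#' decoys. All imported poses get provenance `"seed"`.
#'
#' @param input a `protern_input`.
#' @param source pose source description (see [pipeline_config()]).
#' @return list of `protern_pose`.
#' @export
import_seed_poses <- function(input, source) {
  poses <- switch(source$type,
    synthetic = make_decoys(input, source$spec)$poses,
    transform_table = {
      if (!file.exists(source$file)) stop("cannot read transform table: ", source$file)
      read_transform_table(source$file)
    },
    pdb_dir = {
      files <- sort(list.files(source$dir, pattern = "\\.pdb$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no pose PDBs found in ", source$dir)
      ref <- coords(input$mobile)
      mobile_chains <- unique(input$mobile$chain)
      lapply(files, function(f) {
        s <- read_structure(f)
        s <- s[s$chain %in% mobile_chains, , drop = FALSE]
        if (nrow(s) != nrow(ref)) {
          stop("pose file ", basename(f), " does not match the mobile structure")
        }
        fit <- kabsch_superpose(ref, coords(s))
        pose(sub("\\.pdb$", "", basename(f)),
             rigid_transform(fit$rotation, fit$translation, c(0, 0, 0)))
      })
    },
    stop("unknown pose source type: ", source$type))
  if (length(poses) == 0) stop("pose source yielded zero poses")
  for (p in poses) stopifnot(inherits(p, "protern_pose"))
  poses
}

.stage_report <- function(reports, stage, n_in, n_out, t0) {
  rbind(reports, data.frame(
    stage = stage, n_in = n_in, n_out = n_out,
    seconds = round(as.numeric(Sys.time()) - t0, 3),
    stringsAsFactors = FALSE))
}

# rough + sequential filtration + SASA/quality rank aggregation; returns
# survivors in aggregate order plus their score table
.filter_and_rank <- function(input, poses, config, quiet) {
  kept <- rough_ligand_filter(input, poses, config$window, quiet = quiet)
  if (length(kept) == 0) {
    stop("pipeline error: rough ligand filter removed every pose")
  }
  sf <- sequential_filter(input, kept, config$filters, quiet = quiet)
  qual <- .component_values(input, sf$kept, "quality", config$filters)
  tab <- rbind(sf$table, .score_records(qual, "quality"))
  ranked <- aggregate_ranks(tab[tab$pose_id %in% names(qual), ])
  list(poses = sf$kept[match(ranked$pose_id,
                             vapply(sf$kept, `[[`, character(1), "id"))],
       table = tab, ranked = ranked)
}

#' Run the candidate pipeline end-to-end
#'
#' Executes the stages in order: input preparation, seed import, rough
#' ligand-based filtration, sequential protein-based filtration,
#' SASA+quality rank aggregation and top-N selection, translational grid
#' enumeration with re-filtration and re-selection, rotational grid
#' enumeration with re-filtration, FCC clustering, energy-based cluster
#' filtration, re-clustering, and final cluster ranking. With a fixed
#' configuration (and fixed synthetic seed) two runs produce byte-identical
#' cluster tables; the stages themselves contain no randomness.
#'
#' @param config a `protern_config`.
#' @param input optional pre-built `protern_input`; required unless the
#'   pose source is synthetic or `receptor_file`/`mobile_file` are set.
#' @param quiet suppress per-stage messages.
#' @return list with `clusters` (ranked cluster table), `reports` (stage
#'   report data frame), `score_table`, `cluster_members`, `final_poses`
#'   and, when `output_dir` is set, `files`.
#' @export
run_pipeline <- function(config, input = NULL, quiet = FALSE) {
  reports <- NULL
  t0 <- as.numeric(Sys.time())

  # (i) preparation
  if (is.null(input)) {
    if (identical(config$pose_source$type, "synthetic")) {
      input <- make_toy_complex(config$pose_source$spec)$input
    } else {
      if (is.null(config$receptor_file) || is.null(config$mobile_file)) {
        stop("provide `input` or receptor_file/mobile_file paths")
      }
      input <- ternary_input(
        prepare_structure(read_structure(config$receptor_file)),
        prepare_structure(read_structure(config$mobile_file)),
        protac_file = config$protac_file)
    }
  }
  reports <- .stage_report(reports, "prepare", NA, nrow(input$receptor) +
                             nrow(input$mobile), t0)

  # (ii) seed import
  seeds <- import_seed_poses(input, config$pose_source)
  reports <- .stage_report(reports, "import_seeds", NA, length(seeds), t0)

  # (iii)-(iv) filtration + rank aggregation on seeds
  fr <- .filter_and_rank(input, seeds, config, quiet)
  selected <- fr$poses[seq_len(min(config$n_seed_keep, length(fr$poses)))]
  reports <- .stage_report(reports, "seed_filter_rank", length(seeds),
                           length(selected), t0)

  # (iv) translational grid
  offsets <- translation_offsets(config$grid)
  translated <- vector("list", length(selected) * nrow(offsets))
  k <- 0
  for (p in selected) {
    for (i in seq_len(nrow(offsets))) {
      k <- k + 1
      translated[[k]] <- make_translated_pose(
        p, offsets[i, ], id = sprintf("%s_t%03d", p$id, i))
    }
  }
  reports <- .stage_report(reports, "translate_enumerate", length(selected),
                           length(translated), t0)
  fr_t <- .filter_and_rank(input, translated, config, quiet)
  selected_t <- fr_t$poses[seq_len(min(config$n_translated_keep,
                                       length(fr_t$poses)))]
  reports <- .stage_report(reports, "translate_filter_rank",
                           length(translated), length(selected_t), t0)

  # (iv) rotational grid
  triples <- rotation_triples(config$grid)
  rotated <- vector("list", length(selected_t) * nrow(triples))
  k <- 0
  for (p in selected_t) {
    for (i in seq_len(nrow(triples))) {
      k <- k + 1
      rotated[[k]] <- make_rotated_pose(
        input, p, triples[i, ], id = sprintf("%s_r%03d", p$id, i))
    }
  }
  reports <- .stage_report(reports, "rotate_enumerate", length(selected_t),
                           length(rotated), t0)
  fr_r <- .filter_and_rank(input, rotated, config, quiet)
  final_poses <- fr_r$poses
  reports <- .stage_report(reports, "rotate_filter_rank", length(rotated),
                           length(final_poses), t0)

  # (v) clustering
  contact_sets <- lapply(final_poses, function(p)
    interface_contacts(input, p, config$contact_cutoff))
  cl <- fcc_cluster(contact_sets, config$fcc_threshold,
                    config$min_cluster_size)
  reports <- .stage_report(reports, "fcc_cluster", length(final_poses),
                           length(cl$clusters), t0)

  # (vi) energy-based cluster filtration
  etab <- fr_r$table[fr_r$table$component == "energy", ]
  energies <- setNames(etab$value, etab$pose_id)
  kept_cl <- energy_cluster_filter(cl$clusters, energies,
                                   config$energy_fraction)
  reports <- .stage_report(reports, "energy_cluster_filter",
                           length(cl$clusters), length(kept_cl), t0)

  # (vii) re-clustering of surviving members
  surviving_ids <- unlist(kept_cl, use.names = FALSE)
  recl <- fcc_cluster(
    contact_sets[vapply(contact_sets, `[[`, character(1), "pose_id") %in%
                   surviving_ids],
    config$fcc_threshold, config$min_cluster_size)
  reports <- .stage_report(reports, "recluster", length(surviving_ids),
                           length(recl$clusters), t0)

  # (viii) final cluster ranking
  clusters <- rank_clusters(recl$clusters, fr_r$table)
  reports <- .stage_report(reports, "rank_clusters", length(recl$clusters),
                           nrow(clusters), t0)

  files <- NULL
  if (!is.null(config$output_dir)) {
    files <- .write_outputs(input, config, clusters, recl$clusters,
                            final_poses, reports)
  }

  # (ix) external PROTAC docking, when configured
  if (!is.null(config$dock_command)) {
    if (is.null(files)) stop("dock_command requires output_dir")
    for (f in files$cluster_pdbs) {
      external_dock_adapter(f, config$protac_file, config$dock_command)
    }
  } else if (!quiet) {
    message("external docking stage skipped: no dock_command configured")
  }

  list(clusters = clusters, reports = reports, score_table = fr_r$table,
       cluster_members = recl$clusters, final_poses = final_poses,
       files = files)
}

.write_outputs <- function(input, config, clusters, members, final_poses,
                           reports) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- clusters
  for (col in c("rep_sasa", "rep_quality")) fmt[[col]] <- sprintf("%.6f", fmt[[col]])
  cluster_file <- file.path(config$output_dir, "clusters.tsv")
  write.table(fmt, cluster_file, sep = "\t", quote = FALSE, row.names = FALSE)
  report_file <- file.path(config$output_dir, "stage_report.tsv")
  write.table(reports[, c("stage", "n_in", "n_out")], report_file,
              sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- vapply(final_poses, `[[`, character(1), "id")
  pdbs <- character(0)
  for (cid in clusters$cluster_id) {
    rep_id <- members[[cid]][1]
    f <- file.path(config$output_dir, paste0(cid, "_", rep_id, ".pdb"))
    write_pose(input, final_poses[[match(rep_id, ids)]], file = f)
    pdbs <- c(pdbs, f)
  }
  list(cluster_table = cluster_file, stage_report = report_file,
       cluster_pdbs = pdbs)
}

#' Invoke an external PROTAC-docking command on a complex PDB
#'
#' Pass-through adapter for the final pipeline stage: invokes `command`
#' with the protein-protein complex PDB (and the PROTAC file when given)
#' and captures the output verbatim; no chemistry is parsed.
#'
#' @param complex_pdb path to a receptor+mobile PDB written by the
#'   pipeline.
#' @param protac_file optional PROTAC structure path appended to the
#'   command line.
#' @param command external executable.
#' @param args extra arguments (free-form; external docking parameters are
#'   tool-specific).
#' @return invocation record: list with `command`, `files`, `status`,
#'   `output`.
#' @export
external_dock_adapter <- function(complex_pdb, protac_file = NULL, command,
                                  args = character()) {
  if (Sys.which(command) == "") {
    stop("configuration error: docking command '", command, "' not found")
  }
  files <- c(complex_pdb, protac_file)
  out <- suppressWarnings(system2(command, c(args, files), stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("external docking failed (exit ", status, "):\n",
         paste(out, collapse = "\n"))
  }
  list(command = command, files = files, status = 0, output = out)
}
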