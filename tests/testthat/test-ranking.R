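score_df <- function(ids, sasa, quality) {
  rbind(data.frame(pose_id = ids, component = "sasa", value = sasa,
                   stringsAsFactors = FALSE),
        data.frame(pose_id = ids, component = "quality", value = quality,
                   stringsAsFactors = FALSE))
}

contact_set <- function(id, contacts) {
  structure(list(pose_id = id, contacts = sort(unique(contacts))),
            class = "protern_contacts")
}

test_that("rank aggregation is mean-rank Borda with deterministic ties", {
  # A: sasa rank 1, quality rank 3; B: 2, 1; C: 3, 2
  sc <- score_df(c("A", "B", "C"), sasa = c(30, 20, 10), quality = c(1, 9, 5))
  r <- aggregate_ranks(sc)
  expect_equal(r$pose_id, c("B", "A", "C"))
  expect_equal(r$aggregate, c(1.5, 2.0, 2.5))

  # both components induce the same order: aggregate order equals it
  sc2 <- score_df(c("x", "y", "z"), c(3, 2, 1), c(30, 20, 10))
  expect_equal(aggregate_ranks(sc2)$pose_id, c("x", "y", "z"))

  # full tie: pose-id order
  sc3 <- score_df(c("c", "a", "b"), c(1, 1, 1), c(2, 2, 2))
  expect_equal(aggregate_ranks(sc3)$pose_id, c("a", "b", "c"))

  # invariance under strictly monotone transforms of either component
  sc4 <- score_df(letters[1:5], runif(5), runif(5))
  sc5 <- sc4
  sc5$value[sc5$component == "sasa"] <- exp(sc5$value[sc5$component == "sasa"])
  sc5$value[sc5$component == "quality"] <-
    log(sc5$value[sc5$component == "quality"] + 1)
  expect_equal(aggregate_ranks(sc4)$pose_id, aggregate_ranks(sc5)$pose_id)

  expect_error(aggregate_ranks(sc[sc$pose_id != "A" |
                                    sc$component != "quality", ]), "A")
})

test_that("top-N selection preserves order and saturates", {
  r <- aggregate_ranks(score_df(c("A", "B", "C"), c(30, 20, 10), c(9, 5, 1)))
  expect_equal(select_top(r, 200), c("A", "B", "C"))
  expect_equal(select_top(r, 1), "A")
  expect_error(select_top(r, 0), ">= 1")
  # 200-of-5000 default budget is 4%
  expect_equal(200 / 5000, 0.04)
})

test_that("interface contacts match a brute-force residue scan", {
  input <- toy()$input
  far <- pose("f", rigid_transform(translation = c(40, 0, 0)))
  expect_equal(length(interface_contacts(input, far)$contacts), 0)

  # 2-residue toy with a single atom pair at 4.9 A: exactly one contact
  rec <- mini_structure("A", c(0, 0, 0), c(50, 0, 0))
  mob <- mini_structure("B", c(4.9, 0, 0), c(60, 0, 0))
  cs <- interface_contacts(ternary_input(rec, mob), pose("p"))
  expect_equal(length(cs$contacts), 1)

  # brute-force oracle on the toy complex under a perturbed pose
  set.seed(3)
  p <- pose("q", rigid_transform(euler_rotation(4, -7, 9), rnorm(3, sd = 0.5),
                                 mass_center(input$mobile)))
  got <- interface_contacts(input, p)$contacts
  parts <- strip_moieties(input)
  placed <- apply_pose(input, p)
  mobp <- placed[!placed$is_het, ]
  brute <- character(0)
  for (i in seq_len(nrow(parts$receptor_protein))) {
    for (j in seq_len(nrow(mobp))) {
      d <- sqrt(sum((coords(parts$receptor_protein)[i, ] -
                       coords(mobp)[j, ])^2))
      if (d <= 5) {
        brute <- c(brute, paste(residue_ids(parts$receptor_protein)[i],
                                residue_ids(mobp)[j], sep = "--"))
      }
    }
  }
  expect_setequal(got, unique(brute))

  # contact count invariant under joint rigid motion
  rot <- euler_rotation(10, 20, 30)
  move <- function(s) {
    s[, c("x", "y", "z")] <- sweep(coords(s) %*% t(rot), 2, c(3, 2, 1), "+")
    s
  }
  moved <- ternary_input(move(input$receptor), move(input$mobile))
  expect_equal(length(interface_contacts(moved, pose("p"))$contacts),
               length(interface_contacts(input, pose("p"))$contacts))
})

test_that("FCC similarity is the asymmetric overlap fraction", {
  a <- contact_set("a", c("p", "q", "r", "s"))
  b <- contact_set("b", c("p", "q"))
  expect_equal(fcc_similarity(a, a), 1)
  expect_equal(fcc_similarity(a, contact_set("d", c("u", "v"))), 0)
  expect_equal(fcc_similarity(a, b), 0.5)
  expect_equal(fcc_similarity(b, a), 1)
  expect_warning(v <- fcc_similarity(contact_set("e", character(0)), a),
                 "empty")
  expect_equal(v, 0)
})

test_that("FCC clustering forms leader clusters and eliminates singletons", {
  # all mutually similar: one cluster with everything
  clique <- lapply(c("a", "b", "c"), contact_set,
                   contacts = c("x", "y", "z"))
  out <- fcc_cluster(clique)
  expect_equal(length(out$clusters), 1)
  expect_setequal(out$clusters[[1]], c("a", "b", "c"))
  expect_equal(length(out$unclustered), 0)

  # all dissimilar at min_size 2: no clusters, everything eliminated
  loners <- lapply(1:4, function(i)
    contact_set(paste0("p", i), paste0("c", i, "_", 1:3)))
  out2 <- fcc_cluster(loners)
  expect_equal(length(out2$clusters), 0)
  expect_setequal(out2$unclustered, paste0("p", 1:4))

  # two 3-cliques plus a singleton
  sets <- c(lapply(c("a1", "a2", "a3"), contact_set, contacts = c("u", "v")),
            lapply(c("b1", "b2", "b3"), contact_set, contacts = c("w", "x")),
            list(contact_set("solo", c("y", "z"))))
  out3 <- fcc_cluster(sets)
  expect_equal(length(out3$clusters), 2)
  expect_setequal(unlist(out3$clusters), c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(out3$unclustered, "solo")
})

test_that("FCC clustering agrees with a brute-force implementation", {
  # independent oracle: direct set arithmetic, no incidence matrices
  brute_cluster <- function(sets, threshold = 0.5, min_size = 2) {
    ids <- vapply(sets, `[[`, character(1), "pose_id")
    cs <- lapply(sets, `[[`, "contacts")
    names(cs) <- ids
    simfun <- function(i, j) {
      f <- function(x, y) if (length(x) == 0) 0 else
        length(intersect(x, y)) / length(x)
      min(f(cs[[i]], cs[[j]]), f(cs[[j]], cs[[i]]))
    }
    un <- ids; clusters <- list()
    repeat {
      if (length(un) == 0) break
      nb <- lapply(un, function(i)
        un[un != i & vapply(un, function(j) j != i && simfun(i, j) >= threshold,
                            logical(1))])
      names(nb) <- un
      sizes <- vapply(nb, length, integer(1))
      if (max(sizes) + 1 < min_size) break
      centre <- sort(un[sizes == max(sizes)])[1]
      members <- c(centre, sort(nb[[centre]]))
      clusters[[length(clusters) + 1]] <- members
      un <- setdiff(un, members)
    }
    list(clusters = clusters, unclustered = un)
  }

  set.seed(11)
  universe <- sprintf("ct%02d", 1:12)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    sets <- lapply(seq_len(n), function(i)
      contact_set(sprintf("p%02d", i),
                  sample(universe, sample(2:8, 1))))
    got <- fcc_cluster(sets)
    want <- brute_cluster(sets)
    expect_equal(length(got$clusters), length(want$clusters))
    for (k in seq_along(want$clusters)) {
      expect_setequal(got$clusters[[k]], want$clusters[[k]])
    }
    expect_setequal(got$unclustered, want$unclustered)
    # partition invariant
    all_ids <- sprintf("p%02d", seq_len(n))
    expect_setequal(c(unlist(got$clusters), got$unclustered), all_ids)
    expect_equal(anyDuplicated(unlist(got$clusters)), 0)
  }
})

test_that("energy cluster filtration keeps clusters holding low-energy poses", {
  clusters <- list(c1 = c("a", "b", "c"), c2 = c("d", "e", "f"),
                   c3 = c("g", "h"))
  energies <- setNames(c(-5, 1, 2, -4, 3, 4, 9, 10), letters[1:8])
  # 8 poses at fraction 0.25: ceiling(2) = 2 selected (a, d)
  kept <- energy_cluster_filter(clusters, energies)
  expect_setequal(names(kept), c("c1", "c2"))
  # the cluster with the global minimum is always kept
  expect_true("c1" %in% names(kept))
  # fraction 1: everything kept
  expect_equal(names(energy_cluster_filter(clusters, energies, 1)),
               names(clusters))

  # property: global-minimum cluster survives any random partition
  set.seed(5)
  for (rep in 1:10) {
    ids <- sprintf("p%02d", 1:12)
    e <- setNames(rnorm(12), ids)
    split_at <- sort(sample(2:11, 3))
    cl <- split(ids, cut(seq_along(ids), c(0, split_at, 12)))
    names(cl) <- sprintf("k%d", seq_along(cl))
    cl <- cl[vapply(cl, length, integer(1)) > 0]
    kept <- energy_cluster_filter(cl, e, 0.25)
    holder <- names(cl)[vapply(cl, function(m)
      names(which.min(e[ids])) %in% m, logical(1))]
    expect_true(holder %in% names(kept))
  }
})

test_that("cluster ranking uses max-member representatives", {
  sc <- score_df(c("a", "b", "c", "d", "e", "f"),
                 sasa = c(10, 50, 30, 40, 20, 60),
                 quality = c(5, 1, 4, 2, 3, 6))
  # single cluster: rank 1
  r1 <- rank_clusters(list(c1 = c("a", "b")), sc)
  expect_equal(r1$final_rank, 1)

  # dominating cluster ranks first
  r2 <- rank_clusters(list(c1 = c("a", "e"), c2 = c("f")), sc)
  expect_equal(r2$cluster_id[r2$final_rank == 1], "c2")

  # 3-cluster hand example matches the mean-rank arithmetic
  cl <- list(c1 = c("a", "b"), c2 = c("c", "d"), c3 = c("e", "f"))
  # reps: c1 (sasa 50, qual 5), c2 (40, 4), c3 (60, 6)
  # sasa ranks: c3 1, c1 2, c2 3; quality ranks: c3 1, c1 2, c2 3
  r3 <- rank_clusters(cl, sc)
  expect_equal(r3$cluster_id, c("c3", "c1", "c2"))
  expect_equal(r3$rep_sasa, c(60, 50, 40))
})
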