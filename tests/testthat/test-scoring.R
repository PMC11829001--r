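test_that("rough ligand filter keeps the inclusive 3-20 A window", {
  input <- mini_input()  # anchor-warhead distance 5 + translation along x
  shift <- function(dx) pose(sprintf("p%+.1f", dx),
                             rigid_transform(translation = c(dx, 0, 0)))
  poses <- list(shift(-2.1), shift(-2), shift(0), shift(15), shift(15.1))
  # distances: 2.9, 3.0, 5.0, 20.0, 20.1
  kept <- rough_ligand_filter(input, poses, quiet = TRUE)
  expect_equal(pose_ids(kept), c("p-2.0", "p+0.0", "p+15.0"))

  # all inside the window: output = input, order preserved, idempotent
  inside <- list(shift(0), shift(1), shift(-1))
  kept2 <- rough_ligand_filter(input, inside, quiet = TRUE)
  expect_identical(pose_ids(kept2), pose_ids(inside))
  expect_identical(pose_ids(rough_ligand_filter(input, kept2, quiet = TRUE)),
                   pose_ids(kept2))
})

test_that("SASA matches analytic spheres and is rigid-motion invariant", {
  atom <- function(xyz, chain = "A") {
    s <- mini_structure(chain, xyz, c(99, 99, 99))[1, , drop = FALSE]
    class(s) <- c("protern_structure", "data.frame")
    s
  }
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sasa_score(atom(c(0, 0, 0))), iso, tolerance = 0.01)

  # two atoms beyond mutual solvent reach: areas add
  pair <- rbind(atom(c(0, 0, 0)), atom(c(10, 0, 0)))
  class(pair) <- c("protern_structure", "data.frame")
  expect_equal(sasa_score(pair), 2 * iso, tolerance = 0.01)

  # fully enclosed atom contributes ~ nothing
  cage_xyz <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                    c(0, 0, 2), c(0, 0, -2))
  cage <- do.call(rbind, lapply(seq_len(6), function(i) atom(cage_xyz[i, ])))
  with_centre <- rbind(atom(c(0, 0, 0)), cage)
  class(cage) <- class(with_centre) <- c("protern_structure", "data.frame")
  expect_equal(sasa_score(with_centre), sasa_score(cage), tolerance = 0.002)

  # rigid-motion invariance within discretisation drift
  input <- toy()$input
  s <- input$receptor
  rot <- euler_rotation(33, -71, 140)
  moved <- s
  moved[, c("x", "y", "z")] <- sweep(coords(s) %*% t(rot), 2, c(5, -3, 8), "+")
  expect_equal(sasa_score(moved), sasa_score(s),
               tolerance = 0.005)
})

test_that("Lennard-Jones energy honours the cutoff and the pair minimum", {
  # two single-atom proteins farther than the cutoff: exactly zero
  far <- ternary_input(mini_structure("A", c(0, 0, 0), c(50, 0, 0)),
                       mini_structure("B", c(20, 0, 0), c(60, 0, 0)))
  expect_equal(interaction_energy(far, pose("p")), 0)

  # single C..C pair at the UFF minimum distance: energy = -eps(C)
  at_min <- ternary_input(mini_structure("A", c(0, 0, 0), c(50, 0, 0)),
                          mini_structure("B", c(3.851, 0, 0), c(60, 0, 0)))
  expect_equal(interaction_energy(at_min, pose("p")), -0.105,
               tolerance = 1e-9)

  # toy dimer: equals the brute-force all-pairs sum when every pair < 8 A
  input <- toy()$input
  pp <- strip_moieties(input)
  a <- coords(pp$receptor_protein); b <- coords(pp$mobile_protein)
  brute <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (r <= 8) {
      eps <- sqrt(protern:::.uff_eps[[pp$receptor_protein$element[i]]] *
                    protern:::.uff_eps[[pp$mobile_protein$element[j]]])
      xm <- sqrt(protern:::.uff_xm[[pp$receptor_protein$element[i]]] *
                   protern:::.uff_xm[[pp$mobile_protein$element[j]]])
      brute <- brute + eps * ((xm / r)^12 - 2 * (xm / r)^6)
    }
  }
  expect_equal(interaction_energy(input, pose("p")), brute, tolerance = 1e-3)

  # invariance under joint rigid motion of receptor + mobile
  rot <- euler_rotation(12, 34, -56)
  move <- function(s) {
    s[, c("x", "y", "z")] <- sweep(coords(s) %*% t(rot), 2, c(1, 2, 3), "+")
    s
  }
  moved <- ternary_input(move(input$receptor), move(input$mobile))
  expect_equal(interaction_energy(moved, pose("p")),
               interaction_energy(input, pose("p")), tolerance = 1e-9)
})

test_that("stability score counts steric clashes", {
  input <- toy()$input
  expect_equal(stability_score(input, pose("p")), 0)
  crash <- pose("c", rigid_transform(translation = c(-5.2, 0, 0)))
  expect_lt(stability_score(input, crash), 0)

  # constructed 3-clash toy vs a direct pair-count oracle
  rec <- do.call(rbind, lapply(1:3, function(i)
    mini_structure("A", c(0, 0, 3 * i), c(50, 0, 0))[1, ]))
  mob <- do.call(rbind, lapply(1:3, function(i)
    mini_structure("B", c(1, 0, 3 * i), c(60, 0, 0))[1, ]))
  rec <- rbind(rec, mini_structure("A", c(0, 0, 0), c(50, 0, 0))[2, ])
  mob <- rbind(mob, mini_structure("B", c(1, 0, 0), c(60, 0, 0))[2, ])
  class(rec) <- class(mob) <- c("protern_structure", "data.frame")
  rec$serial <- seq_len(nrow(rec)); mob$serial <- seq_len(nrow(mob))
  inp3 <- ternary_input(rec, mob)
  # protein atoms pair up at 1 A on each rung: exactly 3 clashing pairs
  expect_equal(stability_score(inp3, pose("p")), -3)
})

test_that("interaction z-scores standardise contact counts per pose set", {
  input <- toy()$input
  # three poses with distinct contact counts via increasing separation
  poses <- list(pose("a"),
                pose("b", rigid_transform(translation = c(2, 0, 0))),
                pose("c", rigid_transform(translation = c(6, 0, 0))))
  z <- interaction_zscore(input, poses)
  counts <- vapply(poses, function(p) interface_quality(input, p), numeric(1))
  s <- sqrt(mean((counts - mean(counts))^2))
  expect_equal(unname(z), (counts - mean(counts)) / s)
  # monotone in contact count
  expect_equal(order(z), order(counts))

  # hand-computed population z for counts {10, 20, 30}
  counts2 <- c(10, 20, 30)
  z2 <- (counts2 - mean(counts2)) / sqrt(mean((counts2 - mean(counts2))^2))
  expect_equal(round(z2, 4), c(-1.2247, 0, 1.2247))

  expect_warning(z3 <- interaction_zscore(input, list(pose("a"), pose("a2"))),
                 "degenerate")
  expect_equal(unname(z3), c(0, 0))
})

test_that("sequential filtration follows the retention ceiling chain", {
  # fast fake providers so the chain arithmetic is isolated from scoring
  set.seed(1)
  n <- 100
  poses <- lapply(sprintf("p%03d", seq_len(n)), pose)
  vals <- lapply(1:4, function(k) setNames(rnorm(n), pose_ids(poses)))
  prov <- function(k) function(input, ps) vals[[k]][pose_ids(ps)]
  cfg <- filter_config(providers = list(stability = prov(1), sasa = prov(2),
                                        energy = prov(3), pizsa = prov(4)))
  res <- sequential_filter(mini_input(), poses, cfg, quiet = TRUE)
  expect_equal(length(res$kept), 33)  # 100 -> 75 -> 57 -> 43 -> 33
  counts <- table(res$table$component)[cfg$components]
  expect_equal(unname(as.integer(counts)), c(100, 75, 57, 43))
  # survivors carry a value for every component in the chain
  kept_ids <- pose_ids(res$kept)
  for (comp in cfg$components) {
    expect_true(all(kept_ids %in%
                      res$table$pose_id[res$table$component == comp]))
  }

  # retention 1.0 everywhere: no-op
  cfg1 <- filter_config(retention = 1, providers = cfg$providers)
  expect_equal(length(sequential_filter(mini_input(), poses, cfg1,
                                        quiet = TRUE)$kept), n)

  # component order matters: adversarial two-component set
  v1 <- setNames(c(3, 2, 1, 0), c("a", "b", "c", "d"))
  v2 <- setNames(c(0, 1, 2, 3), c("a", "b", "c", "d"))
  ps4 <- lapply(c("a", "b", "c", "d"), pose)
  mk <- function(order) filter_config(
    components = order, retention = 0.5,
    providers = list(stability = function(i, p) v1[pose_ids(p)],
                     sasa = function(i, p) v2[pose_ids(p)]))
  s12 <- sequential_filter(mini_input(), ps4, mk(c("stability", "sasa")),
                           quiet = TRUE)
  s21 <- sequential_filter(mini_input(), ps4, mk(c("sasa", "stability")),
                           quiet = TRUE)
  expect_false(setequal(pose_ids(s12$kept), pose_ids(s21$kept)))

  expect_error(sequential_filter(mini_input(), list(), cfg, quiet = TRUE),
               "empty pose set")
})

test_that("external providers fail loudly when the binary is missing", {
  prov <- external_provider("no-such-tool-xyz")
  expect_error(prov(mini_input(), list(pose("p"))), "configuration error")
})
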