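test_that("serial enumeration covers the grammar and canonicalizes", {
  ser <- enumerate_serial()
  expect_equal(ser$raw_count, 72)  # 2 * 3 * 2 * 3 * 2 slot assignments
  expect_true("[S>R>D]" %in% ser$canonical)
  expect_true("[-]" %in% ser$canonical)  # the all-empty identity network
  expect_equal(ser$raw$canonical[ser$raw$assignment == "00000"], "[-]")
  # deterministic, ordering-stable
  expect_identical(ser$canonical, enumerate_serial()$canonical)
})

test_that("parallel enumeration covers the grammar with branch symmetry", {
  par <- enumerate_parallel()
  expect_equal(par$raw_count, 576)  # 2 * 12 * 12 * 2 slot assignments
  # branch order is canonical: swapped assignments map to one structure
  m1 <- motif_canonicalize(network_motif(branch1 = "S", branch2 = "D"))
  m2 <- motif_canonicalize(network_motif(branch1 = "D", branch2 = "S"))
  expect_identical(format(m1), format(m2))
  # the all-empty parallel network sums two identity branches: a doubler,
  # not the identity
  m0 <- network_motif(branch1 = character(0), branch2 = character(0))
  x <- stimulus(sin(2 * pi * 300 * (0:999) / 10000))
  expect_equal(run_motif(m0, x)$output, 2 * x$samples)
})

test_that("functional deduplication merges equivalent and separates
           distinct computations", {
  battery <- motif_battery(seed = 1)
  motifs <- list(network_motif(serial = "R"),
                 network_motif(serial = c("R", "R")),
                 network_motif(serial = "S"),
                 network_motif(serial = "D"),
                 network_motif(serial = c("S", "R", "D")),
                 network_motif(serial = c("D", "R", "S")))
  dd <- dedup_functional(motifs, battery)
  expect_equal(dd$classes[1], dd$classes[2])       # rectification idempotent
  expect_false(dd$classes[3] == dd$classes[4])     # S vs D on a step
  expect_false(dd$classes[5] == dd$classes[6])     # order matters

  expect_error(dedup_functional(motifs, list()), "empty")
})

test_that("dedup is an equivalence relation on the serial set at fixed tol", {
  ser <- enumerate_serial()
  battery <- motif_battery(seed = 1)
  dd <- dedup_functional(ser, battery, tol = 1e-6)
  # symmetry/reflexivity hold by construction; check transitivity: members
  # of one class are pairwise within tol, members of different classes are
  # not within tol of the other class representative
  for (ci in unique(dd$classes)) {
    members <- which(dd$classes == ci)
    if (length(members) < 2) next
    for (i in members) {
      expect_lt(max(abs(dd$signatures[[i]] -
                          dd$signatures[[dd$representatives[ci]]])), 1e-6)
    }
  }
  reps <- dd$representatives
  for (i in seq_along(reps)) {
    for (j in seq_along(reps)) {
      if (i < j)
        expect_gt(max(abs(dd$signatures[[reps[i]]] -
                            dd$signatures[[reps[j]]])), 1e-6)
    }
  }
})

test_that("selection is invariant to the protocol noise seed for the
           canonical motif", {
  m <- network_motif(serial = c("S", "R", "D"))
  for (sd_ in c(11, 12)) {
    proto <- eval_protocol(seed = sd_, n_reps = 6)
    ev <- evaluate_motif(m, proto)
    expect_true(ev$pass)
  }
})
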