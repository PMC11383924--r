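test_that("candidate enumeration equals a brute-force pair scan", {
  s <- small_complex()
  prep <- small_prep()
  prof <- sda()
  got <- enumerate_candidates(s, prof, "both", prep = prep)

  # independent O(N^2) scan using the same chemistry inputs
  xl1 <- crosslinkable_residues(s, prof$side1, prep$digest, prep$sasa)
  xl2 <- crosslinkable_residues(s, prof$side2, prep$digest, prep$sasa)
  k1 <- paste(xl1$chain, xl1$resno)
  k2 <- paste(xl2$chain, xl2$resno)
  res <- do.call(rbind, lapply(chain_ids(s), function(ch)
    data.frame(chain = ch, resno = chain_residues(s, ch)$resno)))
  manual <- character()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (i >= j) next
      ki <- paste(res$chain[i], res$resno[i])
      kj <- paste(res$chain[j], res$resno[j])
      if (!((ki %in% k1 && kj %in% k2) || (ki %in% k2 && kj %in% k1))) next
      d <- ca_distance(s, residue_ref(res$chain[i], res$resno[i]),
                       residue_ref(res$chain[j], res$resno[j]))
      if (d <= prof$max_ca) manual <- c(manual, paste(ki, kj))
    }
  }
  expect_setequal(paste(got$chain1, got$res1, got$chain2, got$res2), manual)
  # canonical order: chain id then residue number
  expect_false(is.unsorted(order(got$chain1, got$res1, got$chain2,
                                 got$res2)))
  expect_true(all(got$dist <= prof$max_ca))
})

test_that("chains placed beyond the cutoff yield no inter candidates", {
  far <- make_two_chain_complex(fixture_sequence(20), fixture_sequence(20),
                                translation = c(200, 0, 0))
  got <- enumerate_candidates(far, sda(), "inter")
  expect_identical(nrow(got), 0L)
})

test_that("a lone reactive residue pairs only with its partners", {
  # 3 residues: one K and two A within the cutoff, all exposed; SDA side1
  # is K/S/T/Y, side2 is any surface residue -> exactly the 2 pairs with K
  s <- xl_structure(data.frame(
    chain = "A", resno = 1:3, resid = c("LYS", "ALA", "ALA"),
    elety = "CA", element = "C", x = c(0, 5, 10), y = 0, z = 0))
  prep_free <- xl_prep(s, sda(), min_len = 1)
  got <- prep_free$scopes[["intra:A"]]$candidates
  expect_identical(nrow(got), 2L)
  expect_true(all(got$res1 == 1L))
  expect_identical(sort(got$res2), c(2L, 3L))
})

test_that("true-link sampling honours the coverage rule and the seed", {
  cand <- data.frame(chain1 = "A", res1 = 1:60, chain2 = "B", res2 = 1:60,
                     dist = 10)
  p <- simulation_params(coverage = 0.1, seed = 5)
  s <- small_complex()
  # coverage 0.10 x longer chain 200 -> 20 links
  got <- sample_true_links(cand, s, p, longest = 200)
  expect_identical(nrow(got), 20L)
  expect_true(all(!got$is_decoy))
  # cap at the candidate pool size
  got_cap <- sample_true_links(cand[1:5, ], s,
                               simulation_params(coverage = 1, seed = 5),
                               longest = 100)
  expect_identical(nrow(got_cap), 5L)
  # determinism: same seed identical, different seeds differ
  again <- sample_true_links(cand, s, p, longest = 200)
  expect_identical(got, again)
  other <- sample_true_links(cand, s, simulation_params(seed = 6),
                             longest = 200)
  expect_false(identical(got$res1, other$res1))
  # zero coverage outcome warns and returns an empty set
  expect_warning(
    none <- sample_true_links(cand, s, simulation_params(coverage = 0.001),
                              longest = 100),
    "zero true links")
  expect_identical(nrow(none), 0L)
})

test_that("decoy injection enforces the FDR count formula and the floor", {
  s <- big_complex()
  prep <- big_prep()
  pool <- prep$scopes$inter$decoys
  p <- simulation_params(fdr = 0.2, seed = 3)
  true8 <- data.frame(chain1 = "A", res1 = 1:8, chain2 = "B", res2 = 1:8,
                      is_decoy = FALSE, link_fdr = NA_real_)
  set <- inject_noise(true8, s, sda(), p, decoy_pool = pool)
  expect_identical(nrow(set$links), 10L)
  expect_identical(sum(set$links$is_decoy), 2L)       # realised FDR 0.2
  # n_true = 0 -> the at-least-one-incorrect floor
  set0 <- inject_noise(true8[0, ], s, sda(), p, decoy_pool = pool)
  expect_identical(nrow(set0$links), 1L)
  expect_true(all(set0$links$is_decoy))
  # empty decoy universe cannot honour the FDR
  expect_error(inject_noise(true8, s, sda(), p, decoy_pool = pool[0, ]),
               "decoy universe")
})

test_that("decoys violate and true links satisfy the distance bound", {
  s <- small_complex()
  prep <- small_prep()
  for (seed in 1:25) {
    xs <- simulate_crosslinks(s, sda(), simulation_params(seed = seed),
                              prep = prep)
    d <- link_distances(s, xs$links)
    expect_true(all(d[!xs$links$is_decoy] <= 25))
    expect_true(all(d[xs$links$is_decoy] > 25))
    # no duplicate unordered pairs
    key <- paste(xs$links$chain1, xs$links$res1, xs$links$chain2,
                 xs$links$res2)
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("link-level FDR is the running incorrect fraction", {
  mk <- function(decoy) crosslink_set(
    data.frame(chain1 = rep("A", length(decoy)), res1 = seq_along(decoy),
               chain2 = rep("B", length(decoy)), res2 = seq_along(decoy),
               is_decoy = decoy, link_fdr = rep(NA_real_, length(decoy))),
    simulation_params())
  # all-true set: every link_fdr is 0
  all_true <- annotate_link_fdr(mk(rep(FALSE, 8)), seed = 1)
  expect_identical(all_true$links$link_fdr, rep(0, 8))
  # running-count rule holds for any shuffle, e.g. T,D,T,T -> 0, 1/2, 1/3, 1/4
  xs <- annotate_link_fdr(mk(c(TRUE, FALSE, FALSE, FALSE)), seed = 2)
  expect_equal(xs$links$link_fdr,
               cumsum(xs$links$is_decoy) / seq_len(4))
  ordered_example <- cumsum(c(FALSE, TRUE, FALSE, FALSE)) / (1:4)
  expect_equal(ordered_example, c(0, 1/2, 1/3, 1/4))
  # final position always carries the total decoy fraction
  for (seed in 1:20) {
    xs <- annotate_link_fdr(mk(rep(c(TRUE, FALSE), c(10, 40))), seed = seed)
    expect_equal(xs$links$link_fdr[50], 0.2)
  }
  # empty set passes through
  empty <- annotate_link_fdr(mk(logical()), seed = 1)
  expect_identical(nrow(empty$links), 0L)
})

test_that("simulation is deterministic down to the restraint file bytes", {
  s <- small_complex()
  prep <- small_prep()
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.tsv"); f2 <- file.path(td, "b.tsv")
  p <- simulation_params(seed = 9)
  write_restraints(simulate_crosslinks(s, sda(), p, prep = prep), f1)
  write_restraints(simulate_crosslinks(s, sda(), p, prep = prep), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  other <- simulate_crosslinks(s, sda(), simulation_params(seed = 10),
                               prep = prep)
  expect_false(identical(readLines(f1),
                         {write_restraints(other, f2); readLines(f2)}))
})

test_that("far-apart chains give a decoy-only inter set of size one", {
  far <- make_two_chain_complex(fixture_sequence(40), fixture_sequence(40),
                                translation = c(120, 0, 0))
  xs <- simulate_crosslinks(far, sda(),
                            simulation_params(seed = 4, scope = "inter"))
  expect_identical(nrow(xs$links), 1L)
  expect_true(xs$links$is_decoy)
})

test_that("per-candidate selection frequency is uniform across seeds", {
  cand <- data.frame(chain1 = "A", res1 = 1:30, chain2 = "B", res2 = 1:30,
                     dist = 10)
  s <- small_complex()
  counts <- integer(30)
  for (seed in 1:400) {
    got <- sample_true_links(cand, s, simulation_params(seed = seed),
                             longest = 50)  # 5 of 30 per draw
    counts[got$res1] <- counts[got$res1] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})
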