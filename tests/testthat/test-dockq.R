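# Perturbed model used across DockQ checks: ligand chain rotated and
# translated, deterministic.
perturbed_model <- function(native, rotation = 8, translation = 2) {
  make_decoy_ladder(native, data.frame(rotation = rotation,
                                       translation = translation))[[1]]
}

test_that("interface contacts honour the heavy-atom threshold", {
  far <- make_two_chain_complex(fixture_sequence(10), fixture_sequence(10),
                                translation = c(100, 0, 0))
  expect_identical(nrow(interface_contacts(far, "A", "B", 5)), 0L)

  # two single-residue chains with CB atoms 4.9 A apart: one contact
  s <- xl_structure(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1L, 1L, 1L, 1L),
    resid = "ALA", elety = c("CA", "CB", "CA", "CB"), element = "C",
    x = c(0, 1, 5.9 + 2, 5.9), y = 0, z = 0))
  expect_identical(nrow(interface_contacts(s, "A", "B", 5)), 1L)
  s$atoms$x[4] <- 6.2   # now 5.2 A: no contact
  expect_identical(nrow(interface_contacts(s, "A", "B", 5)), 0L)
  expect_error(interface_contacts(s, "A", "Z", 5), "unknown")
})

test_that("contact scan equals the O(N^2) brute-force oracle", {
  s <- small_complex()
  for (cutoff in c(5, 10)) {
    got <- interface_contacts(s, "A", "B", cutoff)
    expect_identical(got, oracle_contacts(s, "A", "B", cutoff))
  }
})

test_that("fnat is the recall of native contacts", {
  s <- small_complex()
  expect_equal(fnat(s, s, "A", "B"), 1.0)
  # hand-built case: native contacts (1,1) (2,2) (3,3); the model keeps
  # two, breaks (3,3) and gains a non-native contact (2,3) -> recall 2/3
  mk <- function(b_xyz) xl_structure(data.frame(
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2),
    resid = "GLY", elety = "CA", element = "C",
    x = c(0, 0, 0, b_xyz[, 1]), y = c(0, 10, 20, b_xyz[, 2]),
    z = c(0, 0, 0, b_xyz[, 3])))
  native <- mk(cbind(4, c(0, 10, 20), 0))
  model  <- mk(cbind(4, c(0, 10, 12), 0))
  expect_equal(fnat(native, model, "A", "B"), 2 / 3)
  # no native contacts: 0 with a message
  far <- mk(cbind(100, c(0, 10, 20), 0))
  expect_message(z <- fnat(far, far, "A", "B"), "no contacts")
  expect_equal(z, 0)
})

test_that("irms is zero under identity and rigid motion, else matches oracle", {
  s <- small_complex()
  expect_equal(irms(s, s, "A", "B"), 0, tolerance = 1e-9)
  withr::with_seed(3, {
    moved <- apply_rigid_to_structure(s, random_rigid_transform())
    expect_lt(irms(s, moved, "A", "B"), 1e-9)
  })
  model <- perturbed_model(s)
  expect_equal(irms(s, model, "A", "B"),
               oracle_dockq_interface(s, model, "A", "B")$irms,
               tolerance = 1e-3)
})

test_that("lrms superposes on the larger chain and measures the smaller", {
  s <- small_complex()          # A: 60 residues (larger), B: 50 (smaller)
  expect_equal(lrms(s, s, "A", "B"), 0, tolerance = 1e-9)
  # pure translation of the smaller chain shows up verbatim
  model <- s
  sel <- model$atoms$chain == "B"
  model$atoms$z[sel] <- model$atoms$z[sel] + 3
  expect_equal(lrms(s, model, "A", "B"), 3, tolerance = 1e-9)
  # rotation + translation decoy matches the grid/optim oracle
  decoy <- perturbed_model(s, rotation = 20, translation = 4)
  expect_equal(lrms(s, decoy, "A", "B"),
               oracle_dockq_interface(s, decoy, "A", "B")$lrms,
               tolerance = 1e-3)
})

test_that("dockq combines the three terms and classifies quality", {
  s <- small_complex()
  dq <- dockq(s, s)
  expect_equal(dq$dockq, 1.0, tolerance = 1e-9)
  expect_identical(dq$quality, "high")

  # far-displaced model: all terms collapse and the score tends to zero
  wrecked <- perturbed_model(s, rotation = 180, translation = 300)
  expect_lt(dockq(s, wrecked)$dockq, 0.05)

  # term-by-term equality with the independent recomputation
  model <- perturbed_model(s)
  got <- dockq(s, model)
  want <- oracle_dockq_interface(s, model, "A", "B")
  expect_equal(got$fnat, want$fnat, tolerance = 1e-9)
  expect_equal(got$irms, want$irms, tolerance = 1e-3)
  expect_equal(got$lrms, want$lrms, tolerance = 1e-3)
  expect_equal(got$dockq, want$dockq, tolerance = 1e-3)
  expect_true(got$dockq >= 0 && got$dockq <= 1)
})

test_that("dockq is invariant to global rigid motion of the model", {
  s <- small_complex()
  model <- perturbed_model(s)
  base <- dockq(s, model)$dockq
  withr::with_seed(17, {
    for (i in 1:10) {
      moved <- apply_rigid_to_structure(model, random_rigid_transform())
      expect_equal(dockq(s, moved)$dockq, base, tolerance = 1e-9)
    }
  })
})

test_that("quality classes split at 0.23, 0.49 and 0.8", {
  expect_identical(classify_dockq(c(0.22, 0.23, 0.49, 0.50, 0.79, 0.8, 1.0)),
                   c("incorrect", "acceptable", "acceptable", "medium",
                     "medium", "high", "high"))
})

test_that("multi-chain dockq averages native interfaces, skipping empty ones", {
  s <- small_complex()
  c3 <- make_ideal_helix(fixture_sequence(30), chain_id = "C")
  c3$atoms$x <- c3$atoms$x + 500   # far away: contacts with nobody
  three <- xl_structure(rbind(s$atoms, c3$atoms))
  model <- perturbed_model(s)      # only B moved
  model3 <- xl_structure(rbind(model$atoms, c3$atoms))
  got <- dockq(three, model3)
  expect_identical(nrow(got$per_interface), 1L)   # A-B only
  expect_equal(got$dockq, dockq(s, model)$dockq, tolerance = 1e-12)
  expect_error(dockq(three, xl_structure(c3$atoms)), "fewer than 2")
})

test_that("fnat decreases monotonically along a perturbation ladder", {
  s <- small_complex()
  ladder <- make_decoy_ladder(
    s, data.frame(rotation = c(0, 5, 15, 45, 120),
                  translation = c(0, 1, 3, 8, 30)))
  fn <- vapply(ladder, function(m) fnat(s, m, "A", "B"), numeric(1))
  expect_true(all(diff(fn) <= 1e-12))
  expect_equal(fn[1], 1)
})
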