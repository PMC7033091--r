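test_that("residue currents pass all flux through the only intermediate", {
  field <- flux_field(worked_chain(), A = "A1", B = "B3")
  expect_equal(unname(residue_current(field, "M2")), 1 / 6, tolerance = 1e-12)
  expect_error(residue_current(field, "Z9"), "unknown residue")
})

test_that("residue currents split over parallel paths and sum to the total", {
  # A1 -- M2 -- B5 (short path) and A1 -- M3 -- M4 -- B5 (long path)
  tm <- matrix(NA_real_, 5, 5)
  tm[1, 2] <- tm[2, 1] <- 1
  tm[2, 5] <- tm[5, 2] <- 1
  tm[1, 3] <- tm[3, 1] <- 1
  tm[3, 4] <- tm[4, 3] <- 1
  tm[4, 5] <- tm[5, 4] <- 1
  tau <- tau_matrix(tm, labels = c("A1", "M2", "M3", "M4", "B5"))
  field <- flux_field(build_generator(tau), A = "A1", B = "B5")
  rc <- residue_current(field)
  # the cut {M2, M3} of intermediates carries the whole net current
  expect_equal(unname(rc["M2"] + rc["M3"]), field$F_net, tolerance = 1e-8)
  # shorter path (higher conductance: 2 unit edges vs 3) carries more
  expect_gt(rc[["M2"]], rc[["M3"]])
  # path currents proportional to path conductances 1/2 and 1/3
  expect_equal(rc[["M2"]] / rc[["M3"]], 3 / 2, tolerance = 1e-10)
})

test_that("delta_F implements the percent change exactly", {
  expect_equal(delta_F(1, 1), 0)
  expect_equal(delta_F(1.2, 1), 20.0)
  expect_equal(delta_F(0.5, 1), -50.0)
  expect_error(delta_F(1, 0), "undefined")
})

test_that("identical states give a null modulation report", {
  sys <- generate_block_tau(n = 30, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 23)
  rep <- compare_states(sys$tau, sys$tau)
  expect_equal(rep$delta_F, 0)
  expect_equal(rep$delta_F_net, 0)
  expect_lt(max(abs(rep$per_residue$delta_F_X), na.rm = TRUE), 1e-10)
  expect_length(rep$hotspots, 0)
})

test_that("planted hotspots are the top-ranked residues", {
  sys <- generate_block_tau(n = 40, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 31)
  hs <- sys$tau$labels[sys$clusters == 1][1:4]
  mod <- apply_modulator(sys, hs, gamma = 5)
  rep <- compare_states(sys$tau, mod$tau)
  expect_gt(rep$delta_F, 0)
  pr <- rep$per_residue
  top4 <- pr$label[order(-pr$delta_F_X)][1:4]
  expect_setequal(top4, hs)
  expect_true(all(hs %in% rep$hotspots))
})

test_that("an intra-block perturbation barely moves the inter-cluster current", {
  sys <- generate_block_tau(n = 40, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 37)
  in1 <- sys$tau$labels[sys$clusters == 1]
  hs <- in1[1:4]
  # modulator on inter-block edges
  rep_hot <- compare_states(sys$tau, apply_modulator(sys, hs, gamma = 5)$tau)
  # same factor applied to intra-block edges of the same residues
  tm <- sys$tau$times
  others <- setdiff(in1, hs)
  for (h in hs) {
    tm[h, others] <- tm[h, others] / 5
    tm[others, h] <- tm[others, h] / 5
  }
  rep_intra <- compare_states(sys$tau,
                              tau_matrix(tm, labels = sys$tau$labels))
  expect_gt(rep_hot$delta_F, 10)
  expect_lt(abs(rep_intra$delta_F), rep_hot$delta_F / 10)
})

test_that("a global rate rescaling of one state shifts delta_F by (lambda-1)*100", {
  sys <- generate_block_tau(n = 30, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 41)
  lambda <- 1.2
  tau_fast <- tau_matrix(sys$tau$times / lambda, labels = sys$tau$labels)
  rep <- compare_states(sys$tau, tau_fast)
  expect_equal(rep$delta_F, (lambda - 1) * 100, tolerance = 1e-8)
  expect_equal(max(abs(rep$per_residue$delta_F_X - 20), na.rm = TRUE), 0,
               tolerance = 1e-6)
})

test_that("delta_F is invariant under a common rescaling of both states", {
  sys <- generate_block_tau(n = 30, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 43)
  hs <- sys$tau$labels[sys$clusters == 2][1:3]
  mod <- apply_modulator(sys, hs, gamma = 4)
  rep1 <- compare_states(sys$tau, mod$tau)
  lambda <- 7.3
  scale_tau <- function(tau) tau_matrix(tau$times / lambda, labels = tau$labels)
  rep2 <- compare_states(scale_tau(sys$tau), scale_tau(mod$tau))
  expect_equal(rep2$delta_F, rep1$delta_F, tolerance = 1e-10)
  expect_equal(rep2$per_residue$delta_F_X, rep1$per_residue$delta_F_X,
               tolerance = 1e-10)
})

test_that("compare_states validates its inputs", {
  sys <- generate_block_tau(n = 12, blocks = 2, ratio = 100, noise = 0.1,
                            seed = 3)
  other <- generate_block_tau(n = 12, blocks = 2, ratio = 100, noise = 0.1,
                              seed = 4)
  expect_error(compare_states(sys$tau, other$tau), "identical residue label")
})

test_that("rank_residues filters and orders by delta_F_X", {
  rep <- structure(list(per_residue = data.frame(
    label = c("Y80", "W422", "D103"),
    F_X_ag = c(1, 1, 1), F_X_all = c(1.85, 1.8, 1.3),
    delta_F_X = c(85, 80, 30), low_flux = FALSE,
    stringsAsFactors = FALSE)), class = "modulation_report")
  expect_identical(rank_residues(rep, 70), c("Y80", "W422"))
  expect_identical(rank_residues(rep, 100), character(0))
  expect_identical(rank_residues(rep, 0), c("Y80", "W422", "D103"))
})
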