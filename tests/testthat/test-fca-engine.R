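single_rx_model <- function(k = 0.01, c_a = 10, c_e = 2, c_p = 0,
                            inhibitors = NULL, eKd = NA_real_) {
  molecular_model(
    list(species("a", "protein", concentration = c_a),
         species("e", "protein", concentration = c_e),
         species("p", "protein", concentration = c_p)),
    list(reaction("r1", "phosphorylation", reactants = "a", products = "p",
                  enzymes = "e", k = k, eKd = eKd,
                  inhibitors = inhibitors)))
}

test_that("reaction speed follows the mass-action inhibitor law", {
  m <- single_rx_model()
  st <- c(a = 10, e = 2, p = 0)
  s0 <- reaction_speed(m$reactions[[1]], st)
  expect_identical(s0, 0.2)                 # k * C_a * C_e = 0.01*10*2
  ## inhibitor at [I] = iKd leaves the speed exactly unchanged
  m1 <- single_rx_model(inhibitors = data.frame(ref = "drug", iKd = 3,
                                                conc = 3))
  expect_identical(reaction_speed(m1$reactions[[1]], st), s0)
  ## inhibitor at [I] = 2*iKd exactly halves it
  m2 <- single_rx_model(inhibitors = data.frame(ref = "drug", iKd = 3,
                                                conc = 6))
  expect_identical(reaction_speed(m2$reactions[[1]], st), s0 / 2)
  ## inhibitor at zero concentration contributes factor 1
  m3 <- single_rx_model(inhibitors = data.frame(ref = "drug", iKd = 3,
                                                conc = 0))
  expect_identical(reaction_speed(m3$reactions[[1]], st), s0)
  ## eKd divides
  m4 <- single_rx_model(eKd = 4)
  expect_identical(reaction_speed(m4$reactions[[1]], st), s0 / 4)
  expect_error(reaction_speed(m$reactions[[1]], c(a = -1, e = 2, p = 0)),
               "negative")
})

test_that("one step fires by the guarded rule", {
  ## hand trace: guard (0 < 10 and 0.2 < 7.5) passes -> p 0.2, a 9.8
  out <- fca_step(single_rx_model())
  expect_identical(unname(out$state[c("a", "e", "p")]), c(9.8, 2, 0.2))
  expect_identical(unname(out$speeds), 0.2)
  ## product already above reactant: no firing
  out2 <- fca_step(single_rx_model(c_p = 12))
  expect_identical(unname(out2$state[c("a", "e", "p")]), c(10, 2, 12))
  expect_identical(unname(out2$speeds), 0)
  ## speed above the 0.75 cap (S = 9 > 7.5): no firing
  out3 <- fca_step(single_rx_model(k = 0.45))
  expect_identical(unname(out3$state[c("a", "e", "p")]), c(10, 2, 0))
})

test_that("a net with no fireable reactions is steady at the window", {
  m <- single_rx_model(c_p = 12)
  r <- simulate_to_steady(m)
  expect_true(r$reached_steady)
  expect_identical(r$steps_taken, 5L)
  expect_identical(unname(r$final), c(10, 2, 12))
})

test_that("trajectories match the naive oracle step by step", {
  ## two-species transfer
  m <- molecular_model(
    list(species("A", "compound", concentration = 8),
         species("B", "compound")),
    list(reaction("t1", "translocation", reactants = "A", products = "B",
                  k = 0.05)))
  eng <- simulate_to_steady(m, sim_config(max_steps = 200,
                                          steady_tol = 1e-300,
                                          record_trajectory = TRUE))
  nv <- naive_trajectory(m, 200)
  expect_identical(unname(eng$trajectory),
                   unname(nv[seq_len(nrow(eng$trajectory)), , drop = FALSE]))
  ## random small nets, bit-identical over 1000 steps
  for (sd in 1:20) {
    mm <- rand_net(sd)
    eng <- simulate_to_steady(mm, sim_config(max_steps = 1000,
                                             steady_tol = 1e-300,
                                             record_trajectory = TRUE))
    nv <- naive_trajectory(mm, 1000)
    expect_identical(unname(eng$trajectory),
                     unname(nv[seq_len(nrow(eng$trajectory)), , drop = FALSE]))
  }
})

test_that("a decaying chain converges near its fixed point", {
  m <- one_gene_cascade()
  r <- simulate_to_steady(m, sim_config(record_trajectory = TRUE))
  expect_true(r$reached_steady)
  expect_lt(r$steps_taken, 10000L)
  ## fixed point of the update map: production = decay at equilibrium
  ## mRNA* = (k_tc/k_dec) * gene ; prot* = (k_tl/k_dec) * mRNA*
  expect_equal(r$final[["mRNA:g"]], 0.01 / 0.1 * 20, tolerance = 0.02)
  expect_equal(r$final[["prot:g"]], 0.01 / 0.05 * (0.01 / 0.1 * 20),
               tolerance = 0.02)
  ## the declared stop obeys the steady window criterion
  tr <- r$trajectory
  t <- r$steps_taken
  expect_true(all(abs(tr[t + 1L, ] - tr[t - 4L, ]) <= 0.001))
})

test_that("max_steps exhaustion is reported, not thrown", {
  ## undamped source: the readout grows every step
  m <- molecular_model(
    list(species("g", "gene", concentration = 10),
         species("m", "mRNA")),
    list(reaction("tc", "transcription", enzymes = "g", products = "m",
                  k = 0.01)))
  r <- simulate_to_steady(m, sim_config(max_steps = 50))
  expect_false(r$reached_steady)
  expect_identical(r$steps_taken, 50L)
})

test_that("closed 1:1 transfer nets conserve total tokens", {
  m <- molecular_model(
    list(species("A", "compound", concentration = 5),
         species("B", "compound", concentration = 2),
         species("C", "compound", concentration = 1)),
    list(reaction("t1", "translocation", reactants = "A", products = "B",
                  k = 0.11),
         reaction("t2", "translocation", reactants = "B", products = "C",
                  k = 0.07),
         reaction("t3", "translocation", reactants = "C", products = "A",
                  k = 0.19)))
  r <- simulate_to_steady(m, sim_config(max_steps = 500,
                                        steady_tol = 1e-300,
                                        record_trajectory = TRUE))
  totals <- rowSums(r$trajectory)
  expect_true(all(abs(totals - 8) < 1e-12))
})

test_that("no species ever goes negative on random nets", {
  for (sd in 1:30) {
    m <- rand_net(sd)
    r <- simulate_to_steady(m, sim_config(max_steps = 300,
                                          steady_tol = 1e-300,
                                          record_trajectory = TRUE))
    expect_true(all(r$trajectory >= 0))
  }
})

test_that("the engine is deterministic", {
  m <- rand_net(3)
  cfg <- sim_config(max_steps = 500, record_trajectory = TRUE)
  r1 <- simulate_to_steady(m, cfg)
  r2 <- simulate_to_steady(m, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final, r2$final)
})

test_that("flux comparison is 1 for an off-target drug and <1 on target", {
  spec <- fixture_spec(1, n_genes = 2, n_mirnas = 0, effect_size = 8,
                       noise_sd = 0)
  toy <- gen_toy_model(spec)
  s <- gen_cohort(spec, 1, 0)[[1]]
  m <- suppressMessages(
    initialize_model(toy$model, s$gene_profile, s$mirna_profile))
  off <- suppressWarnings(run_fca(m, "sorafenib", inhibitor_conc = 100))
  expect_identical(unname(off$P), 1)
  on1 <- run_fca(m, "everolimus", inhibitor_conc = 4.4)
  expect_lt(on1$P[["proliferation"]], 1)
  ## doubling the inhibitor concentration strictly deepens the response
  on2 <- run_fca(m, "everolimus", inhibitor_conc = 8.8)
  expect_lt(on2$P[["proliferation"]], on1$P[["proliferation"]])
})

test_that("undefined fold changes are flagged when the control is silent", {
  m <- molecular_model(
    list(species("g", "gene"), species("m", "mRNA"),
         species("h", "pseudo-object")),
    list(reaction("tc", "transcription", enzymes = "g", products = "m",
                  k = 0.01)),
    readouts = "h")
  r <- suppressWarnings(run_fca(m, "everolimus", readouts = "h"))
  expect_true(is.na(r$P[["h"]]))
  expect_equal(r$undefined, "h")
})
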