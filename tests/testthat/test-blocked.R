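test_that("linear chain producibility matches hand derivation", {
  fx <- lin3_network()
  prepped <- apply_media(prepare_for_blocking(fx$net), fx$media)
  wt <- producible_set_milp(prepped)
  expect_equal(wt$blocked, character(0))
  mut <- producible_set_milp(apply_knockout(prepped, "g1"))
  expect_equal(candidate_blocked(wt, mut), c("B", "C"))
  mut2 <- producible_set_milp(apply_knockout(prepped, "g2"))
  expect_equal(candidate_blocked(wt, mut2), "C")
})

test_that("source-free cycle members are blocked despite feasible cycle flux", {
  fx <- cycle_network()
  prepped <- apply_media(prepare_for_blocking(fx$net), fx$media)
  wt <- producible_set_milp(prepped)
  expect_true(all(c("X", "Y", "Z") %in% wt$blocked))
  expect_true(all(c("N_c", "B", "C") %in% wt$producible))
  # the cycle can carry internal flux: RC1=RC2=RC3=t is steady-state feasible,
  # which the LP confirms when we force flux through one cycle reaction
  tri <- qbiomass:::net_triplets(prepped)
  bnd <- qbiomass:::net_bounds(prepped)
  p <- qbiomass:::lp_new(length(tri$rxn_ids), "max")
  qbiomass:::lp_set_bounds(p, lb = bnd$lb, ub = bnd$ub)
  nm <- length(tri$met_ids)
  qbiomass:::lp_add_rows(p, tri$i, tri$j, tri$x, rep("=", nm), rep(0, nm))
  qbiomass:::lp_set_bounds(p, lb = 1, idx = match("RC1", tri$rxn_ids))
  expect_true(qbiomass:::lp_feasible(p))
})

test_that("MILP and per-metabolite oracle agree on hand fixtures", {
  for (mk in list(lin3_network, cycle_network, byproduct_network,
                  diamond_network)) {
    fx <- mk()
    prepped <- apply_media(prepare_for_blocking(fx$net), fx$media)
    a <- producible_set_milp(prepped)
    b <- producible_oracle(prepped)
    expect_equal(a$blocked, b$blocked, info = fx$net$id)
  }
})

test_that("blocked sets grow monotonically under added knockouts", {
  fx <- demo_fixture()
  prepped <- apply_media(prepare_for_blocking(fx$net), fx$media)
  b0 <- producible_set_milp(prepped)$blocked
  b1 <- producible_set_milp(apply_knockout(prepped, "g2"))$blocked
  b2 <- producible_set_milp(apply_knockout(prepped, c("g2", "g5")))$blocked
  expect_true(all(b0 %in% b1))
  expect_true(all(b1 %in% b2))
})

test_that("candidate_blocked rejects incomparable results", {
  fx1 <- lin3_network()
  fx2 <- diamond_network()
  p1 <- apply_media(prepare_for_blocking(fx1$net), fx1$media)
  p2 <- apply_media(prepare_for_blocking(fx2$net), fx2$media)
  r1 <- producible_set_milp(p1)
  r2 <- producible_set_milp(p2)
  expect_error(candidate_blocked(r1, r2), "universe")
})

test_that("media restriction alone can block metabolites (demo wild type)", {
  fx <- demo_fixture()
  prepped <- apply_media(prepare_for_blocking(fx$net), fx$media)
  wt <- producible_set_milp(prepped)
  expect_equal(wt$blocked, c("I", "I_ex"))  # EX_I closed by the media
  all_open <- apply_media(prepare_for_blocking(fx$net),
                          media_condition("rich",
                                          c(EX_A = 10, EX_G = 10, EX_I = 10)))
  expect_equal(producible_set_milp(all_open)$blocked, character(0))
})

test_that("blocking configuration guards its numeric preconditions", {
  expect_error(blocking_config(v_min = 1e-6, tol = 1e-7), "tolerance")
  expect_error(blocking_config(v_min = -1), "v_min")
  cfg <- blocking_config(v_min = 0.01, tol = 1e-5)
  expect_equal(cfg$v_min, 0.01)
})
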