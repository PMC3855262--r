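test_that("the generator is deterministic under its seed", {
  a <- make_random_network(fixture_spec(seed = 11))
  b <- make_random_network(fixture_spec(seed = 11))
  expect_identical(names(a$net$reactions), names(b$net$reactions))
  expect_identical(a$planted, b$planted)
  c0 <- make_random_network(fixture_spec(seed = 12))
  expect_false(identical(a$planted, c0$planted) &&
                 identical(names(a$net$reactions),
                           names(c0$net$reactions)))
})

test_that("generated networks are structurally valid with producible plants", {
  for (seed in c(1, 5, 9)) {
    fx <- make_random_network(fixture_spec(seed = seed))
    expect_silent(validate_network(fx$net))
    prepped <- apply_media(prepare_for_blocking(fx$net), fx$media)
    wt <- producible_set_milp(prepped)
    expect_true(all(fx$planted %in% wt$producible), info = seed)
    expect_true(all(fx$cycle_members %in% wt$blocked), info = seed)
  }
})

test_that("generated producibility matches an independent reachability oracle", {
  for (seed in c(3, 8)) {
    fx <- make_random_network(fixture_spec(seed = seed))
    prepped <- prepare_for_blocking(fx$net)
    wt_milp <- producible_set_milp(apply_media(prepped, fx$media))
    reach <- closure_producible(prepped, fx$media)
    expect_equal(wt_milp$producible,
                 intersect(sort(fx$net$metabolites$id), reach), info = seed)
    # and for a knockout
    g <- fx$net$genes[1]
    mut <- producible_set_milp(apply_knockout(apply_media(prepped, fx$media),
                                              g))
    reach_mut <- closure_producible(prepped, fx$media, genes = g)
    expect_equal(mut$producible,
                 intersect(sort(fx$net$metabolites$id), reach_mut),
                 info = seed)
  }
})

test_that("planted phenotypes are consistent with the planted biomass", {
  fx <- make_random_network(fixture_spec(seed = 4))
  ph <- plant_phenotypes(fx$net, fx$planted, media = fx$media, seed = 4)
  expect_equal(nrow(ph), length(fx$net$genes))
  expect_setequal(unique(ph$observed), c("G", "NG"))
  expect_identical(ph$observed, attr(ph, "truth"))  # noiseless by default
  # noise flips roughly the requested fraction, deterministically per seed
  ph1 <- plant_phenotypes(fx$net, fx$planted, media = fx$media,
                          noise_rate = 0.5, seed = 21)
  ph2 <- plant_phenotypes(fx$net, fx$planted, media = fx$media,
                          noise_rate = 0.5, seed = 21)
  expect_identical(ph1$observed, ph2$observed)
  flips <- mean(ph1$observed != attr(ph1, "truth"))
  expect_gt(flips, 0.2)
  expect_lt(flips, 0.8)
})

test_that("planting an unproducible biomass is rejected", {
  fx <- make_random_network(fixture_spec(seed = 2))
  expect_error(plant_phenotypes(fx$net, fx$cycle_members[1],
                                media = fx$media),
               "not producible")
})

test_that("the generator draws do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_random_network(fixture_spec(seed = 77)))
  after <- runif(1)
  expect_identical(before, after)
})
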