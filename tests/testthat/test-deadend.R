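test_that("an obligatory co-product with no consumer is detected", {
  fx <- byproduct_network()
  rep1 <- deadend_byproducts(fx$net, "M", genes = "gx", media = fx$media,
                             experiment_id = "b2")
  expect_true(rep1$feasible)
  expect_equal(rep1$active_sinks, "W")
})

test_that("no dead ends are reported when none are forced", {
  fx <- demo_fixture()
  rep1 <- deadend_byproducts(fx$net, "C", genes = "g3", media = fx$media,
                             experiment_id = "e2")
  expect_true(rep1$feasible)
  expect_equal(rep1$active_sinks, character(0))
})

test_that("growth unattainable even with sinks is flagged, not errored", {
  fx <- byproduct_network()
  # deleting gb removes the only route to M: no sink set can help
  rep1 <- deadend_byproducts(fx$net, "M", genes = "gb", media = fx$media,
                             experiment_id = "b1")
  expect_false(rep1$feasible)
})

test_that("the minimal active-sink count matches brute force", {
  fx <- byproduct_network()
  rep1 <- deadend_byproducts(fx$net, "M", genes = "gx", media = fx$media)
  bf <- bf_min_sinks(fx$net, "M", genes = "gx", media = fx$media)
  expect_equal(length(rep1$active_sinks), bf)
  fx2 <- demo_fixture()
  rep2 <- deadend_byproducts(fx2$net, "C", genes = "g3", media = fx2$media)
  bf2 <- bf_min_sinks(fx2$net, "C", genes = "g3", media = fx2$media)
  expect_equal(length(rep2$active_sinks), bf2)
})

test_that("augmentation repairs every matched growth experiment", {
  fx <- byproduct_network()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  prop <- select_de_novo(lists)
  expect_equal(prop$components, "M")
  # before augmentation, plain FBA cannot grow: W accumulates
  bio0 <- build_biomass_reaction("M")
  expect_equal(as.character(predict_growth(fx$net, bio0, "gx", fx$media)),
               "NG")
  prop2 <- augment_biomass(prop, fx$experiments, fx$net,
                           media_list(fx$media))
  expect_equal(prop2$sink_additions, "W")
  bio1 <- build_biomass_reaction(c(prop2$components, prop2$sink_additions))
  preds <- predict_growth_all(fx$net, bio1, fx$experiments,
                              media_list(fx$media))
  expect_equal(preds$predicted[preds$experiment_id == "b2"], "G")
  expect_equal(preds$predicted[preds$experiment_id == "b1"], "NG")
})

test_that("dead-end reports serialize to a readable table", {
  fx <- byproduct_network()
  rep1 <- deadend_byproducts(fx$net, "M", genes = "gx", media = fx$media,
                             experiment_id = "b2")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_deadend_reports(rep1, tmp)
  tab <- utils::read.delim(tmp)
  expect_equal(tab$metabolite_id, "W")
  expect_equal(tab$role, "byproduct")
})
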