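test_that("FBA growth calls respect knockouts and media", {
  fx <- demo_fixture()
  bio <- build_biomass_reaction("C")
  expect_equal(as.character(predict_growth(fx$net, bio, media = fx$media)),
               "G")
  expect_equal(as.character(predict_growth(fx$net, bio, "g2", fx$media)),
               "NG")
  # upstream of C: g1 also kills growth; unrelated g4 does not
  expect_equal(as.character(predict_growth(fx$net, bio, "g1", fx$media)),
               "NG")
  expect_equal(as.character(predict_growth(fx$net, bio, "g4", fx$media)),
               "G")
  # no nutrients, no growth
  empty <- media_condition("none")
  expect_equal(as.character(predict_growth(fx$net, bio, media = empty)),
               "NG")
})

test_that("growth calls are invariant to the biomass coefficient scale", {
  fx <- demo_fixture()
  for (coefficient in c(2e-4, 1e-2, 1)) {
    bio <- build_biomass_reaction("C", coefficient)
    expect_equal(as.character(predict_growth(fx$net, bio, media = fx$media)),
                 "G", info = coefficient)
    expect_equal(as.character(predict_growth(fx$net, bio, "g2", fx$media)),
                 "NG", info = coefficient)
  }
})

test_that("the predefined biomass reaction is removed before evaluation", {
  fx <- demo_fixture()
  # biomass over I (wild-type blocked): the predefined {F, H} drain must not
  # leak flux into the call
  bio <- build_biomass_reaction("I")
  g <- predict_growth(fx$net, bio, media = fx$media)
  expect_equal(as.character(g), "NG")
  expect_lt(attr(g, "flux"), 1e-6)
})

test_that("agreement report tallies per class and flags comparison diffs", {
  ex <- experiment_table(c("x1", "x2", "x3", "x4"), "gX", "m",
                         c("G", "G", "NG", "NG"))
  preds <- data.frame(experiment_id = c("x1", "x2", "x3", "x4"),
                      predicted = c("G", "NG", "NG", "G"),
                      predicted_alt = c("G", "G", "NG", "NG"),
                      stringsAsFactors = FALSE)
  rep1 <- agreement_report(preds, ex)
  expect_equal(rep1$overall, 50)
  expect_equal(rep1$overall_alt, 100)
  expect_equal(sort(rep1$only_first_wrong), c("x2", "x4"))
  expect_equal(rep1$only_second_wrong, character(0))
  recs <- rep1$records
  expect_equal(recs$concordance[recs$experiment_id == "x1"], "TP")
  expect_equal(recs$concordance[recs$experiment_id == "x2"], "FN")
  expect_equal(recs$concordance[recs$experiment_id == "x3"], "TN")
  expect_equal(recs$concordance[recs$experiment_id == "x4"], "FP")
  expect_error(agreement_report(preds[1:2, ], ex), "missing prediction")
})

test_that("building a biomass from nothing is a usage error", {
  expect_error(build_biomass_reaction(character(0)), "zero components")
})
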