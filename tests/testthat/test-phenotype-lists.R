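test_that("demo include/exclude lists match the hand derivation", {
  fx <- demo_fixture()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  expect_equal(lists$include, list(e1 = c("C", "D")))
  expect_equal(lists$exclude, list(e2 = "D", e3 = "F", e4 = character(0)))
  expect_equal(lists$universe, c("C", "D", "F"))
  expect_equal(lists$ng, "e1")
  expect_equal(sort(lists$g), c("e2", "e3", "e4"))
  # wild-type blocked metabolites (I, I_ex) never enter any list
  expect_false(any(c("I", "I_ex") %in% unlist(c(lists$include,
                                                lists$exclude))))
})

test_that("lists are invariant to experiment row order", {
  fx <- demo_fixture()
  l1 <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  shuffled <- fx$experiments[c(3, 1, 4, 2), ]
  l2 <- build_lists(shuffled, fx$net, media_list(fx$media))
  expect_equal(l1$include, l2$include)
  expect_equal(l1$exclude, l2$exclude)
  expect_equal(l1$universe, l2$universe)
})

test_that("oversized candidate sets are filtered out as uninformative", {
  fx <- demo_fixture()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media),
                       filter_max = 1)
  # e1 blocks {C, D}: two candidates exceed the cap of one
  expect_true("e1" %in% lists$filtered_out)
  expect_false("e1" %in% lists$ng)
  expect_false("e1" %in% names(lists$include))
  # growth experiments with <= 1 candidate are retained
  expect_true("e3" %in% names(lists$exclude))
})

test_that("milp and oracle list-building methods coincide", {
  fx <- demo_fixture()
  l1 <- build_lists(fx$experiments, fx$net, media_list(fx$media),
                    method = "milp")
  l2 <- build_lists(fx$experiments, fx$net, media_list(fx$media),
                    method = "oracle")
  expect_equal(l1$include, l2$include)
  expect_equal(l1$exclude, l2$exclude)
})

test_that("unknown genes are ignored with one aggregated warning", {
  fx <- demo_fixture()
  ex <- fx$experiments
  ex$deleted_genes[1] <- "g2;ghost1"
  ex$deleted_genes[2] <- "g3;ghost2"
  expect_warning(lists <- build_lists(ex, fx$net, media_list(fx$media)),
                 "ghost1, ghost2")
  expect_equal(lists$include, list(e1 = c("C", "D")))
})

test_that("replicate experiments merge by summing weights", {
  fx <- demo_fixture()
  ex <- rbind(fx$experiments, fx$experiments[1, ])
  ex$experiment_id[5] <- "e1b"
  lists <- build_lists(ex, fx$net, media_list(fx$media))
  expect_equal(unname(lists$weights["e1"]), 2)
  expect_false("e1b" %in% names(lists$weights))
})

test_that("missing media definitions fail loudly", {
  fx <- demo_fixture()
  expect_error(build_lists(fx$experiments, fx$net,
                           list(other_media = fx$media)),
               "demo_media")
})

test_that("frequency table classifies the evidence direction", {
  fx <- demo_fixture()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  ft <- frequency_table(lists)
  expect_equal(ft$metabolite_id, c("C", "D", "F"))
  expect_equal(ft$evidence, c("supporting", "inconclusive", "refuting"))
  ftH <- frequency_table(lists, focus = c("C", "H"))
  expect_equal(ftH$evidence[ftH$metabolite_id == "H"], "none")
})
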