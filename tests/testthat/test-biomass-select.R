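test_that("demo de novo selection picks the single supported metabolite", {
  fx <- demo_fixture()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  ma <- max_agreement(lists)
  expect_equal(ma$fix_obj, 4)  # all four experiments reconcilable
  prop <- select_de_novo(lists)
  expect_equal(prop$components, "C")
  expect_equal(prop$agreement, 4)
  expect_equal(prop$matched_ng, "e1")
  expect_equal(sort(prop$matched_g), c("e2", "e3", "e4"))
  # H has no evidence in any list and must not appear
  expect_false("H" %in% prop$components)
})

test_that("demo modification adds C, removes F and keeps H untouched", {
  fx <- demo_fixture()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  prop <- modify_biomass(lists, mu = fx$mu)
  expect_equal(prop$added, "C")
  expect_equal(prop$removed, "F")
  expect_equal(prop$unmodified, "H")
  expect_equal(prop$components, c("C", "H"))
  expect_equal(prop$agreement, 4)
})

test_that("IP agreement equals exhaustive enumeration on random instances", {
  for (seed in 1:12) {
    k <- 5 + (seed %% 6)
    lists <- random_lists(k, n_ng = 4 + seed %% 4, n_g = 3 + seed %% 3,
                          seed = seed)
    bf <- bf_agreement(lists)
    ma <- max_agreement(lists)
    expect_equal(ma$fix_obj, bf$fix_obj, info = paste("seed", seed))
    prop <- select_de_novo(lists, fix_obj = ma$fix_obj)
    expect_equal(length(prop$components), bf$min_size,
                 info = paste("seed", seed))
    expect_equal(prop$agreement, bf$fix_obj, info = paste("seed", seed))
  }
})

test_that("selection is deterministic and order-independent", {
  lists <- random_lists(8, n_ng = 5, n_g = 4, seed = 99)
  p1 <- select_de_novo(lists)
  p2 <- select_de_novo(lists)
  expect_identical(p1$components, p2$components)
  # permuting the stored list order must not change the outcome
  lists2 <- lists
  lists2$include <- rev(lists2$include)
  lists2$exclude <- rev(lists2$exclude)
  p3 <- select_de_novo(lists2)
  expect_identical(p1$components, p3$components)
})

test_that("ties break toward the lexicographically smallest component set", {
  # two interchangeable candidates: one NG experiment with include {a, b}
  lists <- structure(list(
    include = list(ng1 = c("met_a", "met_b")),
    exclude = list(),
    filtered_out = character(0),
    universe = c("met_a", "met_b"),
    ng = "ng1", g = character(0),
    weights = c(ng1 = 1)), class = "include_exclude_lists")
  prop <- select_de_novo(lists)
  expect_equal(prop$components, "met_a")
})

test_that("weighted scheme prefers designated metabolites among equals", {
  lists <- structure(list(
    include = list(ng1 = c("met_a", "met_b")),
    exclude = list(),
    filtered_out = character(0),
    universe = c("met_a", "met_b"),
    ng = "ng1", g = character(0),
    weights = c(ng1 = 1)), class = "include_exclude_lists")
  prop <- select_de_novo(lists,
                         scheme = weight_scheme("weighted",
                                                preferred = "met_b"))
  expect_equal(prop$components, "met_b")
  expect_error(weight_scheme("weighted", preferred = "x",
                             preferred_weight = 2),
               "preferred_weight")
})

test_that("experiment weights steer conflicting evidence", {
  # one metabolite, one NG (include {c}) vs one G (exclude {c}): the heavier
  # side wins the agreement
  base <- function(w_ng, w_g) structure(list(
    include = list(n1 = "cX"), exclude = list(g1 = "cX"),
    filtered_out = character(0), universe = "cX",
    ng = "n1", g = "g1",
    weights = c(n1 = w_ng, g1 = w_g)), class = "include_exclude_lists")
  p_heavy_ng <- select_de_novo(base(3, 1))
  expect_equal(p_heavy_ng$components, "cX")
  p_heavy_g <- select_de_novo(base(1, 3))
  expect_equal(p_heavy_g$components, character(0))
})

test_that("measured components act as soft, overridable evidence", {
  fx <- demo_fixture()
  lists <- build_lists(fx$experiments, fx$net, media_list(fx$media))
  # a measurement for H (no phenotype evidence) pulls it in
  prop <- select_de_novo(lists, em = "H")
  expect_true("H" %in% prop$components)
  expect_equal(prop$em_pseudo, "EM_H")
  # a measurement for F conflicts with growth experiment e3 (weight 1 each):
  # dropping F keeps e3 matched, so agreement ties and the minimal set omits F
  prop2 <- select_de_novo(lists, em = "F")
  expect_false("F" %in% prop2$components)
  # with a dominant measurement weight the measurement wins instead
  prop3 <- select_de_novo(lists, em = "F", em_weight = 5)
  expect_true("F" %in% prop3$components)
})

test_that("modification is a no-op when data fully support the predefined set", {
  fx <- demo_fixture()
  # experiments consistent with biomass {F}: deleting g4 (F synthesis) is NG,
  # deleting g3 (irrelevant) is G
  ex <- experiment_table(c("c1", "c2"), c("g4", "g3"), "demo_media",
                         c("NG", "G"))
  lists <- build_lists(ex, fx$net, media_list(fx$media))
  prop <- modify_biomass(lists, mu = "F")
  expect_equal(prop$added, character(0))
  expect_equal(prop$removed, character(0))
  expect_equal(prop$unmodified, "F")
})
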