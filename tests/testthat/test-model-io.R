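test_that("the JSON and SBML renderings of the toy model load identically", {
  j <- read_model(system.file("extdata", "toy_model.json",
                              package = "qbiomass"))
  x <- read_model(system.file("extdata", "toy_model.xml",
                              package = "qbiomass"))
  expect_equal(sort(j$metabolites$id), sort(x$metabolites$id))
  expect_equal(sort(names(j$reactions)), sort(names(x$reactions)))
  expect_equal(sort(j$genes), sort(x$genes))
  expect_equal(j$mu, x$mu)
  expect_equal(j$biomass_ids, "BIOMASS_toy")
  for (rid in names(j$reactions)) {
    rj <- j$reactions[[rid]]
    rx <- x$reactions[[rid]]
    expect_equal(rj$stoich[sort(names(rj$stoich))],
                 rx$stoich[sort(names(rx$stoich))], info = rid)
    expect_equal(rj$lower_bound, rx$lower_bound, info = rid)
    expect_equal(rj$upper_bound, rx$upper_bound, info = rid)
    expect_equal(qbiomass:::gpr_string(rj$gpr_tree),
                 qbiomass:::gpr_string(rx$gpr_tree), info = rid)
  }
})

test_that("a written model reads back equal", {
  x <- read_model(system.file("extdata", "toy_model.xml",
                              package = "qbiomass"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_json(x, tmp)
  x2 <- read_model(tmp)
  expect_equal(sort(names(x2$reactions)), sort(names(x$reactions)))
  expect_equal(x2$mu, x$mu)
  expect_equal(x2$reactions$R3$stoich[sort(names(x2$reactions$R3$stoich))],
               x$reactions$R3$stoich[sort(names(x$reactions$R3$stoich))])
})

test_that("malformed model files raise format errors", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", tmp)
  expect_error(read_model(tmp), "format error")
  writeLines('{"id": "x"}', tmp)
  expect_error(read_model(tmp), "format error")
  expect_error(read_model("no_such_file.json"), "format error")
  tmp2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml xmlns='http://www.sbml.org/sbml/level3/version1/core'/>",
             tmp2)
  expect_error(read_model(tmp2), "format error")
})

test_that("phenotype tables round-trip and support fitness classification", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("experiment_id\tdeleted_genes\tmedia_id\tfitness",
               "e1\tg1\tm1\t-3.2",
               "e2\tg2;g3\tm1\t0.4"), tmp)
  ph <- read_phenotypes(tmp)
  expect_equal(ph$observed, c("NG", "G"))
  expect_equal(ph$weight, c(1, 1))
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, tmp2)
  ph2 <- read_phenotypes(tmp2)
  expect_equal(ph2$observed, ph$observed)
  expect_equal(ph2$deleted_genes, ph$deleted_genes)
})

test_that("fitness exactly at the threshold is growth, with a message", {
  expect_message(cls <- classify_phenotype(NA, fitness = -1),
                 "threshold")
  expect_equal(cls, "G")
  expect_equal(classify_phenotype(NA, fitness = -1.0001), "NG")
  expect_equal(classify_phenotype(NA, fitness = -0.9999), "G")
  expect_equal(classify_phenotype("NG", fitness = 5), "NG")  # call wins
  expect_error(classify_phenotype(NA, NA), "data error")
  expect_error(classify_phenotype("maybe"), "data error")
})

test_that("media files parse from JSON and TSV", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"m1": {"EX_a": 10, "EX_b": 5}, "m2": {"EX_a": 1}}', tmp)
  md <- read_media(tmp)
  expect_equal(names(md), c("m1", "m2"))
  expect_equal(md$m1$allowed_uptakes, c(EX_a = 10, EX_b = 5))
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("media_id\texchange_id\tmax_uptake",
               "m1\tEX_a\t10", "m1\tEX_b\t5"), tmp2)
  md2 <- read_media(tmp2)
  expect_equal(md2$m1$allowed_uptakes, md$m1$allowed_uptakes)
})
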