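test_that("find_o2_reactions returns the planted enzymatic set, sorted", {
  toy <- toy_fixture()
  expect_identical(find_o2_reactions(toy$model),
                   sort(toy$truth$o2_enzymatic_reactions))
  # flags pull exchange and transport reactions back in
  with_ex <- find_o2_reactions(toy$model, include_exchange = TRUE)
  expect_true("EX_o2" %in% with_ex)
  with_tr <- find_o2_reactions(toy$model, include_transport = TRUE)
  expect_true("O2t" %in% with_tr)
  expect_false("EX_o2" %in% with_tr)
})

test_that("a model with only an O2 exchange yields nothing by default", {
  m <- metabolic_model(
    "m",
    list(metabolite("o2_e", compartment = "e", formula = "O2"),
         metabolite("x", compartment = "c")),
    list(reaction("EX_o2", c(o2_e = -1)), reaction("B", c(x = 1))),
    "B")
  expect_identical(find_o2_reactions(m), character(0))
  expect_identical(find_o2_reactions(m, include_exchange = TRUE), "EX_o2")
  m$o2_metabolite_ids <- character()
  expect_error(find_o2_reactions(m), "no O2 metabolite")
})

test_that("scan recovers exactly the planted essential set", {
  toy <- toy_fixture()
  scan <- o2_essentiality_scan(toy$model, toy$media$oxic)
  expect_setequal(scan$reaction_id[scan$essential],
                  toy$truth$essential_o2_reactions)
  expect_true(all(scan$o2_role == "consumes"))
  expect_true(all(scan$essential == (scan$mu_after_deletion <
                                       GROWTH_EPSILON)))
  expect_gt(attr(scan, "baseline_mu"), 0)
})

test_that("deleting the respiratory chain leaves substrate-level growth", {
  toy <- toy_fixture()
  scan <- o2_essentiality_scan(toy$model, toy$media$oxic)
  etc <- scan[scan$reaction_id == "ETC_O2", ]
  expect_false(etc$essential)
  # substrate-level-only value from the ATP budget: (s*g - m) / b
  p <- toy$truth$parameters
  expect_equal(etc$mu_after_deletion,
               (p$substrate_level_atp * p$glucose_limit -
                  p$maintenance_atp) / p$biomass_atp_demand,
               tolerance = 1e-8)
})

test_that("scan agrees with brute-force deletion restricted to O2 subset", {
  toy <- toy_fixture()
  model <- apply_medium(toy$model, toy$media$oxic)
  scan <- o2_essentiality_scan(model)
  for (i in seq_len(nrow(scan))) {
    mu <- fba(delete_reaction(model, scan$reaction_id[i]))$mu
    expect_equal(scan$mu_after_deletion[i], mu, tolerance = 1e-10)
  }
})

test_that("a redundant duplicate makes a planted essential non-essential", {
  toy <- toy_fixture()
  dup <- reaction_def("HEME_SYNTH_O2_copy",
                      toy$model$reactions$HEME_SYNTH_O2$stoichiometry,
                      lower_bound = 0, upper_bound = 1000,
                      provenance = "redundant duplicate")
  m2 <- add_reactions(toy$model, dup)
  scan <- o2_essentiality_scan(m2, toy$media$oxic)
  expect_false(scan$essential[scan$reaction_id == "HEME_SYNTH_O2"])
})

test_that("restoration: re-adding a deleted reaction recovers baseline mu", {
  toy <- toy_fixture()
  model <- apply_medium(toy$model, toy$media$oxic)
  baseline <- fba(model)$mu
  for (id in find_o2_reactions(model)) {
    del <- delete_reaction(model, id)
    restored <- del
    restored$reactions[[id]]$lower_bound <-
      model$reactions[[id]]$lower_bound
    restored$reactions[[id]]$upper_bound <-
      model$reactions[[id]]$upper_bound
    expect_equal(fba(restored)$mu, baseline, tolerance = 1e-8, info = id)
  }
})

test_that("scan refuses a non-growing baseline", {
  toy <- toy_fixture()
  expect_error(o2_essentiality_scan(toy$model, toy$media$anoxic),
               "baseline")
})
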