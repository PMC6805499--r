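test_that("constructors enforce the basic invariants", {
  expect_error(metabolite("m1", compartment = ""), "compartment")
  expect_error(reaction("r1", numeric()), "non-empty")
  expect_error(reaction("r1", c(a = 1), lower_bound = 2, upper_bound = 1),
               "lower_bound")
  mets <- list(metabolite("a", compartment = "c"))
  rxns <- list(reaction("r1", c(a = 1)))
  expect_error(metabolic_model("m", mets, rxns, "nope"), "objective")
  expect_error(metabolic_model("m", mets,
                               list(reaction("r1", c(ghost = 1))), "r1"),
               "unknown metabolite")
  expect_error(metabolic_model("m", c(mets, mets), rxns, "r1"),
               "duplicate")
})

test_that("exchange and transport reactions are auto-flagged", {
  mets <- list(metabolite("glc_e", compartment = "e"),
               metabolite("glc", compartment = "c"),
               metabolite("g6p", compartment = "c"))
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), lower_bound = -10),
    reaction("GLCt", c(glc_e = -1, glc = 1)),
    reaction("HEX", c(glc = -1, g6p = 1)),
    reaction("SINK", c(g6p = -1))
  )
  m <- metabolic_model("m", mets, rxns, "SINK")
  expect_true(m$reactions$EX_glc$is_exchange)
  expect_true(m$reactions$GLCt$is_transport)
  expect_false(m$reactions$GLCt$is_exchange)
  expect_false(m$reactions$HEX$is_transport)
  # SINK touches one metabolite but in the cytosol: not an exchange
  expect_false(m$reactions$SINK$is_exchange)
  expect_identical(exchange_reactions(m), "EX_glc")
})

test_that("O2 metabolites are detected by formula, with id fallback", {
  by_formula <- metabolic_model(
    "m",
    list(metabolite("ox_e", compartment = "e", formula = "O2"),
         metabolite("x", compartment = "c")),
    list(reaction("EX_ox", c(ox_e = -1)), reaction("B", c(x = 1))),
    "B")
  expect_identical(by_formula$o2_metabolite_ids, "ox_e")
  by_id <- metabolic_model(
    "m",
    list(metabolite("o2_e", compartment = "e"),
         metabolite("x", compartment = "c")),
    list(reaction("EX_o2", c(o2_e = -1)), reaction("B", c(x = 1))),
    "B")
  expect_identical(by_id$o2_metabolite_ids, "o2_e")
  expect_identical(o2_exchange_reactions(by_id), "EX_o2")
})

test_that("apply_medium sets uptake bounds only, never stoichiometry", {
  toy <- toy_fixture()
  m2 <- apply_medium(toy$model, toy$media$anoxic)
  expect_equal(m2$reactions$EX_o2$lower_bound, 0)
  expect_equal(m2$reactions$EX_o2$upper_bound,
               toy$model$reactions$EX_o2$upper_bound)
  for (id in names(m2$reactions)) {
    expect_identical(m2$reactions[[id]]$stoichiometry,
                     toy$model$reactions[[id]]$stoichiometry)
  }
  # overlay leaves unlisted exchanges untouched
  expect_equal(m2$reactions$EX_glc$lower_bound,
               toy$model$reactions$EX_glc$lower_bound)
  # full medium closes unlisted exchanges for uptake
  m3 <- apply_medium(toy$model, toy$media$minimal)
  expect_equal(m3$reactions$EX_ac$lower_bound, 0)
  expect_equal(m3$reactions$EX_glc$lower_bound,
               -toy$truth$parameters$glucose_limit)
})

test_that("media naming unknown exchanges warn by default, error in strict",
{
  toy <- toy_fixture()
  ghost <- medium_spec("ghost", c(EX_ghost = 5), default_uptake = NA_real_)
  expect_warning(apply_medium(toy$model, ghost), "EX_ghost")
  expect_error(apply_medium(toy$model, ghost, strict = TRUE), "EX_ghost")
})

test_that("medium presets carry the published uptake limits", {
  toy <- toy_fixture()
  oxic <- medium_preset("oxic", toy$model)
  expect_equal(unname(oxic$uptake_limits["EX_o2"]), 18.5)
  anoxic <- medium_preset("anoxic", toy$model)
  expect_equal(unname(anoxic$uptake_limits["EX_o2"]), 0)
  rich <- medium_preset("rich", toy$model)
  expect_false("EX_o2" %in% names(rich$uptake_limits))
  expect_true(all(rich$uptake_limits == 1000))
  minimal <- medium_preset("minimal_glucose", toy$model)
  expect_equal(unname(minimal$uptake_limits["EX_glc"]), 6.14)
  ov <- medium_preset("minimal_glucose", toy$model,
                      extra_limits = c(EX_glc = 10))
  expect_equal(unname(ov$uptake_limits["EX_glc"]), 10)
})

test_that("deletion zeroes bounds, keeps the reaction, and is idempotent", {
  toy <- toy_fixture()
  del <- delete_reaction(toy$model, "BIOMASS")
  expect_equal(fba(del)$mu, 0)
  expect_true("BIOMASS" %in% names(del$reactions))
  expect_error(delete_reaction(toy$model, "nope"), "unknown reaction")
  twice <- delete_reaction(del, "BIOMASS")
  expect_identical(twice$reactions$BIOMASS, del$reactions$BIOMASS)
})

test_that("add_reactions: identity on empty, errors on collision and ghosts",
{
  toy <- toy_fixture()
  expect_identical(add_reactions(toy$model, list()), toy$model)
  dup <- reaction_def("GLYC", c(acp = 1), provenance = "x")
  expect_error(add_reactions(toy$model, dup), "collision")
  ghost <- reaction_def("NEW", c(ghost_met = 1), provenance = "x")
  expect_error(add_reactions(toy$model, ghost), "undeclared")
  ok <- reaction_def("NEW", c(newmet = 1), provenance = "x",
                     new_metabolites = list(metabolite("newmet",
                                                       compartment = "c")))
  m2 <- add_reactions(toy$model, ok)
  expect_equal(length(m2$reactions), length(toy$model$reactions) + 1L)
  expect_true("newmet" %in% names(m2$metabolites))
})

test_that("adding reactions is monotone and deleting anti-monotone for FBA",
{
  toy <- toy_fixture()
  base <- fba(toy$model)$mu
  expanded <- apply_intervention(toy$model, toy$designs$ACK)
  expect_gte(fba(expanded)$mu, base - 1e-9)
  for (id in c("ETC_O2", "GLYC", "ACP_HYDR")) {
    expect_lte(fba(delete_reaction(toy$model, id))$mu, base + 1e-9)
  }
})
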