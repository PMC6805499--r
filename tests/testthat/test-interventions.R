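test_that("the design library is complete, attributed, and balanced", {
  lib <- builtin_designs()
  expect_gte(length(lib), 9L)
  expect_setequal(
    c("ACK", "NIKEL", "NAR", "NIR_NOR", "ELECTRODE", "DHODH_I", "RNR_III",
      "NADB_FUM", "HEMG_Q"),
    intersect(names(lib), c("ACK", "NIKEL", "NAR", "NIR_NOR", "ELECTRODE",
                            "DHODH_I", "RNR_III", "NADB_FUM", "HEMG_Q")))
  for (set in lib) {
    expect_true(nzchar(set$provenance), info = set$name)
    for (r in set$reactions) {
      expect_true(nzchar(r$provenance), info = r$id)
    }
    viol <- check_defs_balance(set$reactions)
    expect_identical(nrow(viol), 0L, info = set$name)
    expect_length(attr(viol, "skipped"), 0L)
  }
})

test_that("the consolidated fermentation design is in the library", {
  lib <- builtin_designs()
  consolidated <- c("DHODH_I", "RNR_III", "ACK")
  expect_true(all(consolidated %in% names(lib)))
  # class I DHODH: fumarate- and NAD-coupled variants
  expect_setequal(names(lib$DHODH_I$reactions),
                  c("DHODH_FUM", "DHODH_NAD"))
  # class III RNR: one reaction per NTP plus thioredoxin recycling
  expect_length(grep("^RNR3_", names(lib$RNR_III$reactions)), 4L)
  expect_true("ACKr" %in% names(lib$ACK$reactions))
})

test_that("toy balance holds under the generator's pseudo-formula scheme", {
  toy <- toy_fixture()
  viol <- check_balance(toy$model, elements = c("C", "P"))
  expect_identical(nrow(viol), 0L)
})

test_that("growth classification boundaries are half-open as documented", {
  eps <- GROWTH_EPSILON
  mu_ref <- 0.5
  expect_identical(classify_growth(0, mu_ref), "none")
  expect_identical(classify_growth(eps / 2, mu_ref), "none")
  expect_identical(classify_growth(eps, mu_ref), "poor")
  expect_identical(classify_growth(0.1 * mu_ref - 1e-12, mu_ref), "poor")
  expect_identical(classify_growth(0.1 * mu_ref, mu_ref), "growth")
})

test_that("the design grid reproduces cell-by-cell manual evaluation", {
  toy <- toy_fixture()
  model <- apply_medium(toy$model, toy$media$oxic)
  combos <- list(wild_type = character(),
                 alternatives = "alternatives",
                 `alternatives+ACK` = c("alternatives", "ACK"))
  grid <- evaluate_designs(model, combos,
                           conditions = list(toy$media$anoxic),
                           designs = toy$designs)
  expect_identical(nrow(grid), 3L)
  expect_identical(grid$growth_class[grid$combo == "wild_type"], "none")
  for (i in seq_len(nrow(grid))) {
    manual <- Reduce(function(m, nm) apply_intervention(m,
                                                        toy$designs[[nm]]),
                     combos[[grid$combo[i]]], init = model)
    manual_mu <- fba(apply_medium(manual, toy$media$anoxic))$mu
    expect_equal(grid$mu[i], manual_mu, tolerance = 1e-10)
  }
  expect_equal(attr(grid, "mu_ref"), fba(model)$mu)
})

test_that("unknown design names fail before any solve", {
  toy <- toy_fixture()
  expect_error(
    evaluate_designs(toy$model, list("nope"), list(toy$media$anoxic),
                     designs = toy$designs),
    "unknown design")
})

test_that("adding a design set never decreases mu (monotone grid)", {
  toy <- toy_fixture()
  model <- apply_medium(toy$model, toy$media$oxic)
  chain <- list(character(), "alternatives", c("alternatives", "ACK"))
  grid <- evaluate_designs(model, chain, list(toy$media$anoxic),
                           designs = toy$designs)
  expect_true(all(diff(grid$mu) >= -1e-9))
})

test_that("the shipped design-library file round-trips the built-ins", {
  shipped <- system.file("extdata", "design_library.json",
                         package = "anaerodesign")
  lib <- load_design_library(shipped)
  ref <- builtin_designs()
  expect_identical(names(lib), names(ref))
  for (nm in names(lib)) {
    expect_identical(names(lib[[nm]]$reactions), names(ref[[nm]]$reactions))
    for (id in names(lib[[nm]]$reactions)) {
      expect_equal(lib[[nm]]$reactions[[id]]$stoichiometry,
                   ref[[nm]]$reactions[[id]]$stoichiometry, info = id)
    }
  }
  # write -> read is the identity, so users can extend the file
  tmp <- tempfile(fileext = ".json")
  write_design_library(lib, tmp)
  expect_identical(load_design_library(tmp), lib)
})

test_that("library sets already present in the host are skipped quietly", {
  toy <- toy_fixture()
  m1 <- apply_intervention(toy$model, toy$designs$ACK)
  # re-applying must not error on the id collision
  m2 <- apply_intervention(m1, toy$designs$ACK)
  expect_identical(names(m2$reactions), names(m1$reactions))
})
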