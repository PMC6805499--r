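test_that("toy generator rejects infeasible parameter budgets", {
  expect_error(make_toy_model(maintenance_atp = -1), "> 0")
  # substrate-level ATP cannot cover maintenance: no design could grow
  expect_error(make_toy_model(substrate_level_atp = 0.1,
                              glucose_limit = 5, maintenance_atp = 2),
               "maintenance")
  # explicit biomass demand too low: carbon-limited, not ATP-limited
  expect_error(make_toy_model(biomass_atp_demand = 0.5), "carbon-limited")
})

test_that("planted truth predicts the anoxic growth ladder across params", {
  grid <- expand.grid(s = c(0.5, 1, 1.5), g = c(6.14, 10, 20),
                      m = c(0.5, 2))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    toy <- make_toy_model(substrate_level_atp = p$s, glucose_limit = p$g,
                          maintenance_atp = p$m)
    anox <- function(m) fba(apply_medium(m, toy$media$anoxic))$mu
    expect_equal(anox(toy$model), 0, info = i)
    m_alt <- apply_intervention(toy$model, toy$designs$alternatives)
    mu_alt <- anox(m_alt)
    expect_equal(mu_alt, toy$truth$anaerobic_mu_expected[["alternatives"]],
                 tolerance = 1e-8, info = i)
    mu_ack <- anox(apply_intervention(m_alt, toy$designs$ACK))
    expect_equal(mu_ack,
                 toy$truth$anaerobic_mu_expected[["alternatives_ack"]],
                 tolerance = 1e-8, info = i)
    expect_equal(mu_ack / mu_alt, 2, tolerance = 1e-8, info = i)
  }
})

test_that("toy model is deterministic: two calls give identical models", {
  a <- make_toy_model()
  b <- make_toy_model()
  expect_identical(a$model, b$model)
  expect_identical(a$truth, b$truth)
})

test_that("domain tables: noiseless construction is exactly shared+planted",
{
  sim <- make_domain_tables(seed = 7, n_exclusive = 5, n_shared_core = 10,
                            n_noise = 0, dropout = 0)
  sets <- lapply(seq_len(nrow(sim$groups)), function(i) {
    load_domain_annotations(sim$groups$path[i],
                            genome_id = sim$groups$genome_id[i],
                            group = sim$groups$group[i])
  })
  for (i in seq_along(sets)) {
    expected <- sort(c(sim$truth$shared_core_domains,
                       if (sim$groups$group[i] == "anaerobe")
                         sim$truth$exclusive_core_domains))
    expect_identical(sets[[i]]$domains, expected,
                     info = sim$groups$genome_id[i])
  }
})

test_that("planted exclusive domains never leak into background genomes", {
  sim <- make_domain_tables(seed = 3, n_noise = 500)
  bgd <- sim$groups[sim$groups$group == "aerobe", ]
  for (i in seq_len(nrow(bgd))) {
    g <- load_domain_annotations(bgd$path[i], genome_id = bgd$genome_id[i],
                                 group = "aerobe")
    expect_false(any(sim$truth$exclusive_core_domains %in% g$domains))
  }
})

test_that("same seed gives byte-identical tables, different seed differs", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  s1 <- make_domain_tables(seed = 11, dir = d1, n_shared_core = 50,
                           n_noise = 100)
  s2 <- make_domain_tables(seed = 11, dir = d2, n_shared_core = 50,
                           n_noise = 100)
  s3 <- make_domain_tables(seed = 12, dir = d3, n_shared_core = 50,
                           n_noise = 100)
  for (g in names(s1$files)) {
    expect_identical(readLines(s1$files[[g]]), readLines(s2$files[[g]]))
  }
  expect_false(identical(readLines(s1$files[[1]]),
                         readLines(s3$files[[1]])))
  # planted truth sidecar rides along with every dataset
  expect_true(file.exists(file.path(d1, "planted_truth.json")))
  side <- jsonlite::read_json(file.path(d1, "planted_truth.json"),
                              simplifyVector = TRUE)
  expect_identical(side$exclusive_core_domains,
                   s1$truth$exclusive_core_domains)
})

test_that("zero planted exclusive domains warns when requested", {
  expect_warning(make_domain_tables(seed = 1, n_exclusive = 0,
                                    n_shared_core = 5, n_noise = 0),
                 "vacuous")
})
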