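test_that("formula parsing reads Hill strings, implicit counts and pseudo-elements", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_equal(parse_formula("CHO2R"), c(C = 1, H = 1, O = 2, R = 1))
  expect_equal(parse_formula("Fe2S2"), c(Fe = 2, S = 2))
  expect_error(parse_formula("C6(H2O)6"), "unparseable")
  expect_error(parse_formula(""), "non-empty")
})

test_that("mass balance verdicts cover balanced, imbalanced, undetermined", {
  cat <- data.frame(id = c("glc", "lac", "b", "q"),
                    formula = c("C6H12O6", "C3H6O3", "C6H12O5", NA),
                    charge = c(0, 0, 0, NA), stringsAsFactors = FALSE)
  expect_equal(check_mass_balance(c(glc = -1, lac = 2), cat), "balanced")
  expect_equal(check_mass_balance(c(glc = -1, b = 1), cat), "imbalanced")
  expect_equal(check_mass_balance(c(glc = -1, q = 1), cat), "undetermined")
  # charge imbalance with equal elements
  cat2 <- data.frame(id = c("a", "b"), formula = c("C1H1", "C1H1"),
                     charge = c(0, 1), stringsAsFactors = FALSE)
  expect_equal(check_mass_balance(c(a = -1, b = 1), cat2), "imbalanced")
  # missing charge: element check decides
  cat2$charge[2] <- NA
  expect_equal(check_mass_balance(c(a = -1, b = 1), cat2), "balanced")
})

test_that("database curation removes biomass, exchange, excluded and imbalanced reactions", {
  mets <- data.frame(id = c("a_c", "b_c", "c_c"), name = c("a", "b", "c"),
                     formula = c("C2H2", "C2H2", "C2H1"),
                     charge = 0, compartment = "c", stringsAsFactors = FALSE)
  ids <- c("R_ok", "BIOMASS_Ecoli_core_w_GAM", "EX_a", "R_bad", "R_out")
  S <- Matrix::sparseMatrix(
    i = c(1, 2,  1,  1,  1, 3,  1, 2),
    j = c(1, 1,  2,  3,  4, 4,  5, 5),
    x = c(-1, 1, -1, -1, -1, 1, -1, 1),
    dims = c(3, 5), dimnames = list(mets$id, ids))
  raw <- list(rxns = data.frame(id = ids, name = ids, lb = -5, ub = 5,
                                stringsAsFactors = FALSE),
              S = S, mets = mets)
  db <- curate_database(raw, exclusions = "R_out", flux_cap = 800)
  expect_setequal(db$rxns$id, "R_ok")
  expect_equal(db$rxns$lb, -800)  # reversible reset to the cap
  expect_equal(db$rxns$ub, 800)
  rep <- attr(db, "curation_report")
  expect_equal(rep$removed[rep$rule == "biomass"], 1)
  expect_equal(rep$removed[rep$rule == "exchange"], 1)
  expect_equal(rep$removed[rep$rule == "excluded"], 1)
  expect_equal(rep$removed[rep$rule == "imbalanced"], 1)

  # idempotence: curating the curated database changes nothing
  db2 <- curate_database(db, flux_cap = 800)
  expect_equal(db2$rxns$id, db$rxns$id)
  expect_equal(db2$rxns$lb, db$rxns$lb)

  # every retained reaction re-checks as balanced
  for (rid in db$rxns$id) {
    st <- db$S[, rid, drop = TRUE]; st <- st[st != 0]
    expect_equal(check_mass_balance(st, db$mets), "balanced")
  }

  # undetermined retained only on request
  mets$formula[1] <- NA
  raw$mets <- mets
  dbu <- curate_database(raw, exclusions = "R_out")
  expect_false("R_ok" %in% dbu$rxns$id)
  dbk <- curate_database(raw, exclusions = "R_out", keep_undetermined = TRUE)
  expect_true("R_ok" %in% dbk$rxns$id)
})

test_that("JSON round trip preserves ids, stoichiometry and bounds", {
  m <- toy_chain_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$rxns$id, m$rxns$id)
  expect_equal(m2$rxns$lb, m$rxns$lb)
  expect_equal(m2$rxns$ub, m$rxns$ub)
  expect_equal(m2$mets$id, m$mets$id)
  expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
  expect_equal(m2$biomass_reaction_id, "BIO")
})

test_that("SBML-FBC round trip preserves the model and detects bad references", {
  m <- toy_chain_model()
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$rxns$id, m$rxns$id)
  expect_equal(m2$rxns$lb, m$rxns$lb)
  expect_equal(m2$rxns$ub, m$rxns$ub)
  expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
  expect_equal(m2$biomass_reaction_id, "BIO")
  expect_equal(m2$mets$formula, m$mets$formula)

  # a reaction referencing an undeclared species errors, naming it
  txt <- readLines(f)
  txt <- sub('species="M_s1_c"', 'species="M_ghost_c"', txt)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, f2)
  expect_error(read_model(f2), "ghost_c")
})

test_that("flux cap replaces out-of-range bounds and biomass detection falls back to patterns", {
  m <- toy_chain_model()
  m$rxns$is_biomass[] <- FALSE
  m$rxns$id[m$rxns$id == "BIO"] <- "Growth_biomass_v1"
  colnames(m$S)[colnames(m$S) == "BIO"] <- "Growth_biomass_v1"
  m$rxns$ub[1] <- 99999
  m$biomass_reaction_id <- NA_character_
  f <- withr::local_tempfile(fileext = ".json")
  # write without objective marker to force pattern fallback
  .tmp <- m; .tmp$rxns$name <- .tmp$rxns$id
  write_model(.tmp, f)
  m2 <- read_model(f, flux_cap = 500)
  expect_equal(m2$biomass_reaction_id, "Growth_biomass_v1")
  expect_equal(max(m2$rxns$ub), 500)
  expect_error(read_model(f, flux_cap = 500, biomass_patterns = "zzz"),
               "no biomass")
})

test_that("a minimal one-metabolite one-exchange JSON model is valid", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    id = "mini",
    metabolites = list(list(id = "a_e", compartment = "e")),
    reactions = list(list(id = "EX_a_e", metabolites = list(a_e = -1),
                          lower_bound = -10, upper_bound = 10))),
    f, auto_unbox = TRUE)
  m <- read_model(f, require_biomass = FALSE)
  expect_equal(nrow(m$mets), 1)
  expect_equal(nrow(m$rxns), 1)
  expect_true(m$rxns$is_exchange)
})

test_that("medium JSON round trip and validation", {
  med <- medium(list(glc__D = c(-10, 1000), o2 = c(0, 0)))
  f <- withr::local_tempfile(fileext = ".json")
  write_medium(med, f)
  med2 <- read_medium(f)
  expect_equal(med2$bounds, med$bounds)
  expect_equal(med2$default_policy, med$default_policy)
  expect_error(medium(list(glc__D = c(5, -5))), "lb > ub")
})

test_that("knockout removes reactions and validates ids", {
  m <- toy_chain_model()
  expect_equal(knockout(m, character())$rxns$id, m$rxns$id)
  m2 <- knockout(m, "C_2")
  expect_false("C_2" %in% m2$rxns$id)
  expect_error(knockout(m, "NOPE"), "NOPE")
  # removing the only route to biomass kills growth
  expect_solver()
  expect_equal(fba(m)$objective, 10)
  expect_equal(fba(m2)$objective, 0)
})
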