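test_that("compartment building namespaces, dedupes and keeps disconnected candidates", {
  m <- toy_chain_model()
  db <- toy_chain_db(c("C_2", "C_3"))           # C_2, C_3 still in model
  comp <- build_compartment(m, db, "mA", 0.1)
  # both db reactions exist in the model -> deduped, attributed to model
  expect_equal(sum(comp$rxns$source == "database"), 0)
  expect_true(all(grepl("@mA$", comp$rxns$id)))
  expect_true(all(grepl("@mA$", comp$mets$id)))
  # exchange reactions are replaced (dropped here, transfers come later)
  expect_false(any(grepl("^EX_", comp$rxns$orig_id)))

  m2 <- knockout(m, "C_2")
  comp2 <- build_compartment(m2, db, "mB", 0.1)
  expect_equal(comp2$rxns$orig_id[comp2$rxns$source == "database"], "C_2")
  # candidate enters fully reversible
  k <- which(comp2$rxns$source == "database")
  expect_equal(comp2$rxns$lb[k], -1000)
  expect_equal(comp2$rxns$ub[k], 1000)

  # dedupe by canonical stoichiometry, not only id
  db_alias <- toy_chain_db("C_3")
  db_alias$rxns$id <- "C3_ALIAS"
  colnames(db_alias$S) <- "C3_ALIAS"
  comp3 <- build_compartment(m, db_alias, "mC", 0.1)
  expect_equal(sum(comp3$rxns$source == "database"), 0)

  # empty database -> namespaced model only
  comp4 <- build_compartment(m, empty_database(), "mD", 0.1)
  expect_equal(nrow(comp4$rxns), sum(!m$rxns$is_exchange))

  expect_error(build_compartment(m, db, "mE", -1), "min_growth")
})

test_that("community assembly installs transfers, pool rows and medium bounds", {
  m <- toy_chain_model()
  fxm <- list(gl = m, ac = m)   # two copies of the same organism
  cm <- build_community(fxm, empty_database(), toy_medium(),
                        min_growth = 0.1)
  expect_equal(length(cm$members), 2)
  expect_equal(cm$pool$base_id, "nut")
  # transfer coefficients: -1 on the member e-metabolite, +1 on pool
  tr <- cm$rxns$id[cm$rxns$type == "transfer"]
  expect_length(tr, 2)
  for (t in tr) {
    st <- cm$S[, t, drop = TRUE]; st <- st[st != 0]
    expect_setequal(unname(st), c(-1, 1))
    expect_equal(unname(st[cm$pool$pool_id]), 1)
  }
  # environment exchange carries the medium bound
  ek <- which(cm$rxns$type == "env_exchange")
  expect_equal(cm$rxns$lb[ek], -10)
  # reaction count identity: members' reactions + per-pool (links + 1)
  n_member <- sum(vapply(cm$members, function(cp) nrow(cp$rxns), 0))
  expect_equal(nrow(cm$rxns), n_member + 2 + 1)

  # duplicated tags and bad abundances are rejected
  expect_error(build_community(list(a = m, a = m), empty_database(),
                               toy_medium()), "duplicate")
  expect_error(build_community(fxm, empty_database(), toy_medium(),
                               abundances = c(0.7, 0.7)), "sum to 1")
})

test_that("medium naming an unknown metabolite warns and stays inert", {
  m <- toy_chain_model()
  med <- medium(list(nut = c(-10, 1000), ghostmet = c(-5, 5)))
  expect_warning(cm <- build_community(list(a = m), empty_database(), med),
                 "ghostmet")
  expect_true("ghostmet" %in% cm$pool$base_id)
})

test_that("apply_medium is idempotent, supports policies and member scoping", {
  m <- toy_chain_model()
  cm <- build_community(list(a = m), empty_database(), toy_medium())
  cm1 <- apply_medium(cm, toy_medium())
  expect_equal(cm1$rxns$lb, cm$rxns$lb)
  expect_equal(cm1$rxns$ub, cm$rxns$ub)

  # open_secretion_only default: unlisted -> (0, cap)
  cm2 <- apply_medium(cm, medium())
  ek <- which(cm2$rxns$type == "env_exchange")
  expect_equal(cm2$rxns$lb[ek], 0)
  expect_equal(cm2$rxns$ub[ek], 1000)
  # closed policy shuts the environment completely
  cm3 <- apply_medium(cm, medium(default_policy = "closed"))
  expect_equal(cm3$rxns$ub[which(cm3$rxns$type == "env_exchange")], 0)
  # anaerobic-style switch: named entry (0,0) forbids uptake for all
  cm4 <- apply_medium(cm, medium(list(nut = c(0, 0))))
  ek4 <- which(cm4$rxns$type == "env_exchange" & cm4$rxns$base_id == "nut")
  expect_equal(cm4$rxns$lb[ek4], 0)
  expect_equal(cm4$rxns$ub[ek4], 0)

  # member-scoped override hits the transfer reaction only
  cm5 <- apply_medium(cm, medium(list(nut = c(-10, 1000),
                                      "nut@a" = c(0, 50))))
  tk <- which(cm5$rxns$id == "TR_nut@a")
  expect_equal(cm5$rxns$lb[tk], 0)
  expect_equal(cm5$rxns$ub[tk], 50)
})

test_that("a one-member community with open medium reproduces standalone FBA", {
  expect_solver()
  m <- toy_chain_model(L = 4, uptake = 7)
  solo <- fba(m)
  cm <- build_community(list(a = m), empty_database(),
                        toy_medium(uptake = 7), min_growth = 0.01)
  comm <- community_fba(cm, member = "a")
  expect_equal(comm$status, "optimal")
  expect_equal(comm$objective, solo$objective, tolerance = 1e-6)
})

test_that("pool balance row equals member transfers minus environment exchange", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 2, chain_length = 3,
                            gaps_per_member = 0, n_decoys = 0,
                            cross_feed = TRUE, seed = 5)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)
  r <- community_fba(cm, enforce_floors = TRUE)
  expect_equal(r$status, "optimal")
  for (z in seq_len(nrow(cm$pool))) {
    tr_ids <- cm$rxns$id[cm$rxns$type == "transfer" &
                           cm$rxns$base_id == cm$pool$base_id[z]]
    lhs <- sum(r$fluxes[tr_ids]) - r$fluxes[[cm$pool$environment_exchange_id[z]]]
    expect_lt(abs(lhs), 1e-6)
  }
})
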