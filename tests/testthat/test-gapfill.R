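test_that("formulation counts binaries and rejects non-positive floors", {
  fx <- make_linear_fixture(n_members = 2, chain_length = 3,
                            gaps_per_member = 1, n_decoys = 3,
                            seed = 1, compute_oracle = FALSE)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)
  p <- formulate_gapfill(cm, fx$floors)
  # every database reaction becomes one binary per compartment
  expect_equal(nrow(p$cand), 2 * nrow(fx$database$rxns))
  expect_error(formulate_gapfill(cm, c(org1 = 0, org2 = 0.1)), "positive")
})

test_that("a single planted gap is repaired by exactly that reaction", {
  expect_solver()
  m <- knockout(toy_chain_model(L = 3), "C_2")
  db <- toy_chain_db(c("C_2", "C_3"))   # C_3 still present -> deduped
  cm <- build_community(list(a = m), db, toy_medium(), min_growth = 0.1)
  sol <- solve_gapfill(formulate_gapfill(cm, c(a = 0.1)))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1L)
  expect_equal(sol$added$a, "C_2")
  expect_gte(sol$growth[["a"]], 0.1)
})

test_that("a deficiency covered by a partner's secretion needs no repair", {
  expect_solver()
  # cross-feed fixture where member 2's only gap is upstream of the
  # planted exchange entry point: the oracle proves one repair (member
  # 1's own gap) suffices
  found <- FALSE
  for (seed in 1:20) {
    fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                              gaps_per_member = 1, n_decoys = 1,
                              cross_feed = TRUE, seed = 1000 + seed)
    gap2 <- as.integer(sub("C2_", "", fx$spec$planted_gaps$org2))
    if (gap2 <= fx$spec$planted_exchange$entry_step &&
        fx$expected_min_repair == 1) {
      found <- TRUE
      cm <- reduce_community(build_community(fx$models, fx$database,
                                             fx$medium,
                                             min_growth = fx$floors))
      sol <- solve_gapfill(formulate_gapfill(cm, fx$floors))
      expect_equal(sol$objective_value, 1L)
      expect_length(sol$added$org2, 0)   # repaired by cross-feeding
      break
    }
  }
  expect_true(found)
})

test_that("solutions satisfy gating, conservation and growth floors", {
  expect_solver()
  for (seed in c(3, 9, 15)) {
    fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                              gaps_per_member = 1, n_decoys = 2,
                              cross_feed = seed %% 2 == 1, seed = seed,
                              compute_oracle = FALSE)
    cm <- reduce_community(build_community(fx$models, fx$database,
                                           fx$medium,
                                           min_growth = fx$floors))
    p <- formulate_gapfill(cm, fx$floors)
    sol <- solve_gapfill(p)
    expect_equal(sol$status, "optimal")
    # Sv = 0 on every member and pool row
    expect_lt(steady_state_residual(cm, sol$fluxes), 1e-6)
    # gating: unselected candidates carry no flux
    off <- setdiff(seq_len(nrow(p$cand)), sol$support)
    expect_true(all(abs(sol$fluxes[p$cand$reaction_id[off]]) <= 1e-6))
    # growth floors
    expect_true(all(sol$growth >= fx$floors - 1e-9))
    # objective equals the added-reaction count
    expect_equal(sum(lengths(sol$added)), sol$objective_value)
  }
})

test_that("optimal solutions are irreducible: dropping any added reaction breaks feasibility", {
  expect_solver()
  for (seed in c(21, 22, 23)) {
    fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                              gaps_per_member = 1, n_decoys = 1,
                              seed = seed, compute_oracle = FALSE)
    cm <- reduce_community(build_community(fx$models, fx$database,
                                           fx$medium,
                                           min_growth = fx$floors))
    p <- formulate_gapfill(cm, fx$floors)
    sol <- solve_gapfill(p)
    expect_gte(sol$objective_value, 1L)
    for (drop in sol$support) {
      expect_false(support_feasible(p, setdiff(sol$support, drop)))
    }
  }
})

test_that("infeasible communities report which member's floor fails", {
  expect_solver()
  m <- knockout(toy_chain_model(L = 3), "C_2")
  # database cannot repair the gap
  cm <- build_community(list(a = m), toy_chain_db("C_3"), toy_medium(),
                        min_growth = 0.1)
  sol <- solve_gapfill(formulate_gapfill(cm, c(a = 0.1)))
  expect_equal(sol$status, "infeasible")
  expect_equal(sol$infeasible_members, "a")
})

test_that("enumeration finds symmetric optima exhaustively and k=1 matches solve", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 1, chain_length = 3,
                            gaps_per_member = 1, n_decoys = 1,
                            alt_routes = 1, seed = 31)
  # one gap, one planted parallel route -> exactly two optimal supports
  expect_equal(fx$expected_min_repair, 1L)
  expect_length(fx$oracle_supports, 2L)
  cm <- reduce_community(build_community(fx$models, fx$database,
                                         fx$medium, min_growth = fx$floors))
  p <- formulate_gapfill(cm, fx$floors)
  en <- enumerate_alternatives(p, k = 10, allow_suboptimal = FALSE)
  expect_true(en$exhaustive_at_optimum)
  keys <- lapply(en$solutions, function(s) support_key(s$added))
  expect_setequal(vapply(keys, paste, "", collapse = "|"),
                  vapply(fx$oracle_supports, paste, "", collapse = "|"))
  # no two solutions share a support
  expect_equal(anyDuplicated(vapply(keys, paste, "", collapse = "|")), 0L)

  en1 <- enumerate_alternatives(p, k = 1)
  s0 <- solve_gapfill(p)
  expect_equal(support_key(en1$solutions[[1]]$added), support_key(s0$added))
})

test_that("suboptimal enumeration grows the objective monotonically", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 1, chain_length = 3,
                            gaps_per_member = 1, n_decoys = 0,
                            seed = 33)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)   # unpruned: decoyless
  p <- formulate_gapfill(cm, fx$floors)
  en <- enumerate_alternatives(p, k = 3, allow_suboptimal = TRUE)
  objs <- vapply(en$solutions, `[[`, 0L, "objective_value")
  expect_true(all(diff(objs) >= 0))
  if (length(objs) > 1) expect_gt(objs[2], objs[1])
})

test_that("zero-objective case: a growing community needs no additions", {
  expect_solver()
  m <- toy_chain_model(L = 3)
  cm <- build_community(list(a = m), toy_chain_db("C_2"), toy_medium(),
                        min_growth = 0.1)
  sol <- solve_gapfill(formulate_gapfill(cm, c(a = 0.1)))
  expect_equal(sol$objective_value, 0L)
  # enumerating past the empty support requires at least one binary on
  en <- enumerate_alternatives(formulate_gapfill(cm, c(a = 0.1)), k = 2)
  expect_equal(en$solutions[[1]]$objective_value, 0L)
  if (length(en$solutions) > 1) {
    expect_gte(en$solutions[[2]]$objective_value, 1L)
  }
})

test_that("single-member mode reduces to classical gap-filling (oracle match)", {
  expect_solver()
  for (seed in c(41, 42, 43, 44)) {
    fx <- make_linear_fixture(n_members = 1, chain_length = 4,
                              gaps_per_member = 1 + seed %% 2,
                              n_decoys = 2, seed = seed)
    cm <- reduce_community(build_community(fx$models, fx$database,
                                           fx$medium,
                                           min_growth = fx$floors))
    sol <- solve_gapfill(formulate_gapfill(cm, fx$floors))
    expect_equal(sol$objective_value, fx$expected_min_repair)
  }
})

test_that("equal abundance weights reproduce the unweighted optimum", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                            gaps_per_member = 1, cross_feed = TRUE,
                            n_decoys = 1, seed = 51)
  cmU <- build_community(fx$models, fx$database, fx$medium,
                         min_growth = fx$floors)
  sU <- solve_gapfill(formulate_gapfill(cmU, fx$floors))
  cmW <- build_community(fx$models, fx$database, fx$medium,
                         min_growth = fx$floors,
                         abundances = c(0.5, 0.5))
  sW <- solve_gapfill(formulate_gapfill(cmW, fx$floors, weighted = TRUE))
  expect_equal(sW$objective_value, sU$objective_value)
  # pool conservation holds under the weighted rows too
  expect_lt(steady_state_residual(cmW, sW$fluxes, weighted = TRUE), 1e-6)

  # unequal abundances still conserve mass in the weighted rows
  cmW2 <- build_community(fx$models, fx$database, fx$medium,
                          min_growth = fx$floors,
                          abundances = c(0.66, 0.34))
  sW2 <- solve_gapfill(formulate_gapfill(cmW2, fx$floors, weighted = TRUE))
  expect_equal(sW2$status, "optimal")
  expect_lt(steady_state_residual(cmW2, sW2$fluxes, weighted = TRUE), 1e-6)
  expect_error(formulate_gapfill(cmU, fx$floors, weighted = TRUE),
               "abundances")
})

test_that("apply_and_verify materializes repairs and confirms community growth", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                            gaps_per_member = 1, n_decoys = 1,
                            cross_feed = TRUE, seed = 61)
  cm <- reduce_community(build_community(fx$models, fx$database,
                                         fx$medium, min_growth = fx$floors))
  sol <- solve_gapfill(formulate_gapfill(cm, fx$floors))
  ver <- apply_and_verify(fx$models, sol, fx$database, fx$medium,
                          fx$floors)
  expect_true(all(ver$growth >= fx$floors - 1e-6))
  # added reactions are materialized with reversible bounds, not the
  # FVA-tightened community bounds
  for (tg in names(sol$added)) {
    for (rid in sol$added[[tg]]) {
      k <- match(rid, ver$models[[tg]]$rxns$id)
      expect_equal(ver$models[[tg]]$rxns$lb[k], -1000)
      expect_equal(ver$models[[tg]]$rxns$ub[k], 1000)
    }
  }
  # applying an empty solution leaves a growing model unchanged
  m <- toy_chain_model()
  cm0 <- build_community(list(a = m), empty_database(), toy_medium(),
                         min_growth = 0.1)
  s0 <- solve_gapfill(formulate_gapfill(cm0, c(a = 0.1)))
  m0 <- apply_solution(m, s0, empty_database(), member = "a")
  expect_equal(m0$rxns$id, m$rxns$id)
})
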