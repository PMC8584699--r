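make_crossfeed_setup <- function(seed = 61) {
  fx <- make_linear_fixture(n_members = 2, chain_length = 4,
                            gaps_per_member = 1, n_decoys = 1,
                            cross_feed = TRUE, seed = seed,
                            compute_oracle = FALSE)
  cm <- reduce_community(build_community(fx$models, fx$database,
                                         fx$medium, min_growth = fx$floors))
  en <- enumerate_alternatives(formulate_gapfill(cm, fx$floors), k = 4)
  list(fx = fx, cm = cm, en = en)
}

test_that("exchange extraction finds the planted cross-feeding edge", {
  expect_solver()
  found_edge <- FALSE
  for (seed in c(11, 61, 62)) {
    s <- make_crossfeed_setup(seed)
    xr <- extract_exchanges(s$en, s$cm)
    # pool balance cross-check on every solution's rows
    for (r in seq_along(s$en$solutions)) {
      f <- xr$fluxes[xr$fluxes$solution_rank == r, ]
      e <- xr$environment[xr$environment$solution_rank == r, ]
      for (met in unique(f$metabolite)) {
        expect_lt(abs(sum(f$flux[f$metabolite == met]) -
                        e$flux[e$metabolite == met]), 1e-6)
      }
    }
    hit <- xr$edges[xr$edges$metabolite == "xf" &
                      xr$edges$from == "org1" & xr$edges$to == "org2", ]
    if (nrow(hit)) {
      found_edge <- TRUE
      expect_true(all(hit$magnitude > 0))
    }
  }
  # at least one of the planted-exchange fixtures must actually use it
  expect_true(found_edge)
})

test_that("single-member solutions produce no cross-feeding edges", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 1, chain_length = 3,
                            gaps_per_member = 1, n_decoys = 0, seed = 2,
                            compute_oracle = FALSE)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)
  en <- enumerate_alternatives(formulate_gapfill(cm, fx$floors), k = 2)
  xr <- extract_exchanges(en, cm)
  expect_equal(nrow(xr$edges), 0)
})

test_that("an edge needs a consumer: secretion by both members is not cross-feeding", {
  # hand-built report path: two members both secrete, nobody consumes
  fx <- make_linear_fixture(n_members = 2, chain_length = 2,
                            gaps_per_member = 0, n_decoys = 0, seed = 3,
                            compute_oracle = FALSE)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)
  fake <- structure(list(status = "optimal", objective_value = 0L,
                         added = list(org1 = character(),
                                      org2 = character()),
                         fluxes = setNames(rep(0, nrow(cm$rxns)),
                                           cm$rxns$id),
                         growth = c(org1 = 0.1, org2 = 0.1),
                         support = integer()),
                    class = "gapfill_solution")
  fake$fluxes[c("TR_nut1@org1", "TR_nut2@org2")] <- 5
  fake$fluxes[c("EXC_nut1", "EXC_nut2")] <- 5
  xr <- extract_exchanges(fake, cm)
  expect_equal(nrow(xr$edges), 0)
})

test_that("addition frequencies are order-invariant fractions in [0,1]", {
  expect_solver()
  fx <- make_linear_fixture(n_members = 1, chain_length = 3,
                            gaps_per_member = 1, alt_routes = 1,
                            n_decoys = 0, seed = 12)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)
  en <- enumerate_alternatives(formulate_gapfill(cm, fx$floors), k = 10,
                               allow_suboptimal = FALSE)
  expect_length(en$solutions, 2)
  tab <- summarize_additions(en, cm)
  # two symmetric single-reaction repairs: each appears in half the list
  expect_equal(sort(tab$frequency), c(0.5, 0.5))
  rev_en <- en; rev_en$solutions <- rev(en$solutions)
  tab2 <- summarize_additions(rev_en, cm)
  expect_equal(tab[order(tab$reaction_id), ]$frequency,
               tab2[order(tab2$reaction_id), ]$frequency)
  expect_true(all(tab$frequency >= 0 & tab$frequency <= 1))
  expect_error(summarize_additions(list(), cm), "no solutions")
})

test_that("quality flags catch near-bound fluxes and opposed reaction pairs", {
  fx <- make_linear_fixture(n_members = 1, chain_length = 3,
                            gaps_per_member = 0, n_decoys = 0, seed = 4,
                            compute_oracle = FALSE)
  cm <- build_community(fx$models, fx$database, fx$medium,
                        min_growth = fx$floors)
  sol <- structure(list(fluxes = setNames(rep(0, nrow(cm$rxns)),
                                          cm$rxns$id)),
                   class = "gapfill_solution")
  # all small fluxes: clean report
  sol$fluxes[] <- 5
  qf <- flag_quality(sol, cm)
  expect_length(qf$near_bound, 0)
  expect_equal(nrow(qf$cycle_pairs), 0)
  expect_equal(qf$trust_penalty, 0)
  # a flux at 999 of a 1000 cap is flagged
  sol$fluxes["C1_1@org1"] <- 999
  qf2 <- flag_quality(sol, cm)
  expect_true("C1_1@org1" %in% qf2$near_bound)

  # build a community whose member carries both a reaction and its
  # mirror; both at +500 = a classic pairwise cycle
  m <- toy_chain_model(L = 2)
  mirror <- m
  mets <- m$mets
  rxns <- rbind(m$rxns,
                data.frame(id = "C_1_rev", name = "C_1_rev", lb = -1000,
                           ub = 1000, is_exchange = FALSE,
                           is_biomass = FALSE))
  S <- cbind(m$S, Matrix::sparseMatrix(
    i = match(c("s0_c", "s1_c"), mets$id), j = c(1, 1), x = c(1, -1),
    dims = c(nrow(mets), 1)))
  mm <- metabolic_model("loopy", mets, rxns, S, "BIO")
  cml <- build_community(list(a = mm), empty_database(), toy_medium(),
                         min_growth = 0.1)
  soll <- structure(list(fluxes = setNames(rep(0, nrow(cml$rxns)),
                                           cml$rxns$id)),
                    class = "gapfill_solution")
  soll$fluxes["C_1@a"] <- 500
  soll$fluxes["C_1_rev@a"] <- 500
  qfl <- flag_quality(soll, cml)
  expect_equal(nrow(qfl$cycle_pairs), 1)
  expect_setequal(unlist(qfl$cycle_pairs[1, ]), c("C_1@a", "C_1_rev@a"))
})

test_that("report writers emit the TSV and DOT artifacts", {
  expect_solver()
  s <- make_crossfeed_setup(61)
  xr <- extract_exchanges(s$en, s$cm)
  d <- withr::local_tempdir()
  write_exchange_report(xr, d)
  expect_true(file.exists(file.path(d, "transfer_fluxes.tsv")))
  tab <- read.delim(file.path(d, "transfer_fluxes.tsv"))
  expect_setequal(names(tab), c("solution_rank", "metabolite", "member",
                                "flux"))
  dot <- file.path(d, "cf.dot")
  write_crossfeeding_dot(xr, dot)
  expect_match(readLines(dot)[1], "digraph")
})
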