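# Small hand-built models used across tests. All fixtures are built in
# code; nothing is read from disk except what a test writes itself.

# linear chain model: EX -> transport -> C_1..C_L -> biomass
toy_chain_model <- function(id = "toy", L = 3, uptake = 10, cap = 1000) {
  smet <- sprintf("s%d_c", 0:L)
  mets <- data.frame(id = c(smet, "nut_e"), name = c(smet, "nut_e"),
                     formula = "X", charge = 0,
                     compartment = c(rep("c", L + 1), "e"),
                     stringsAsFactors = FALSE)
  ids <- c("EX_nut_e", "T1", sprintf("C_%d", seq_len(L)), "BIO")
  rxns <- data.frame(id = ids, name = ids,
                     lb = c(-uptake, rep(0, L + 2)),
                     ub = cap,
                     is_exchange = c(TRUE, rep(FALSE, L + 2)),
                     is_biomass = c(rep(FALSE, L + 2), TRUE),
                     stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(nrow(mets), nrow(rxns)),
                            dimnames = list(mets$id, ids))
  S["nut_e", "EX_nut_e"] <- -1
  S["nut_e", "T1"] <- -1; S["s0_c", "T1"] <- 1
  for (k in seq_len(L)) {
    S[sprintf("s%d_c", k - 1), sprintf("C_%d", k)] <- -1
    S[sprintf("s%d_c", k), sprintf("C_%d", k)] <- 1
  }
  S[sprintf("s%d_c", L), "BIO"] <- -1
  metabolic_model(id, mets, rxns, S, "BIO")
}

# database holding the named chain reactions of toy_chain_model
toy_chain_db <- function(ids = "C_2", L = 3, cap = 1000) {
  smet <- sprintf("s%d_c", 0:L)
  mets <- data.frame(id = smet, name = smet, formula = "X", charge = 0,
                     compartment = "c", stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(smet), length(ids)),
                            dimnames = list(smet, ids))
  for (z in seq_along(ids)) {
    k <- as.integer(sub("C_", "", ids[z]))
    S[sprintf("s%d_c", k - 1), z] <- -1
    S[sprintf("s%d_c", k), z] <- 1
  }
  reaction_database(data.frame(id = ids, name = ids, lb = -cap, ub = cap,
                               stringsAsFactors = FALSE),
                    S, mets, provenance = "toy")
}

toy_medium <- function(uptake = 10, cap = 1000) {
  medium(list(nut = c(-uptake, cap)))
}

# residuals of the steady-state rows for a solution on a community
steady_state_residual <- function(cm, fluxes, weighted = FALSE) {
  S <- comgapfill:::.community_S(cm, weighted)
  max(abs(as.numeric(S %*% fluxes[colnames(S)])))
}

expect_solver <- function() {
  # the whole package is built around an external MILP backend; tests
  # cannot run without it, so fail loudly rather than skip
  expect_true(solver_available())
}
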