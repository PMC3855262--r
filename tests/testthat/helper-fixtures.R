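# Hand-built networks with hand-derived expected outcomes.

# Linear chain: nutrient N -> B -> C. Wild type blocks nothing; deleting g1
# blocks {B, C}; deleting g2 blocks {C}.
lin3_network <- function() {
  mets <- data.frame(id = c("N_e", "N_c", "B", "C"),
                     name = c("N_e", "N_c", "B", "C"),
                     compartment = c("e", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction_record("EX_N", c(N_e = -1), -1000, 1000),
    reaction_record("T_N", c(N_e = -1, N_c = 1), 0, 1000, gpr = "gt"),
    reaction_record("R1", c(N_c = -1, B = 1), 0, 1000, gpr = "g1"),
    reaction_record("R2", c(B = -1, C = 1), 0, 1000, gpr = "g2"))
  list(net = metabolic_network(mets, rxns, id = "lin3"),
       media = media_condition("m_lin", c(EX_N = 10)))
}

# lin3 plus a source-free 3-cycle X -> Y -> Z -> X: internal flux around the
# cycle is feasible, but no net production of any member is.
cycle_network <- function() {
  fx <- lin3_network()
  net <- fx$net
  net$metabolites <- rbind(net$metabolites,
                           data.frame(id = c("X", "Y", "Z"),
                                      name = c("X", "Y", "Z"),
                                      compartment = "c",
                                      stringsAsFactors = FALSE))
  net$reactions$RC1 <- reaction_record("RC1", c(X = -1, Y = 1), 0, 1000,
                                       gpr = "gc1")
  net$reactions$RC2 <- reaction_record("RC2", c(Y = -1, Z = 1), 0, 1000,
                                       gpr = "gc2")
  net$reactions$RC3 <- reaction_record("RC3", c(Z = -1, X = 1), 0, 1000,
                                       gpr = "gc3")
  net$genes <- sort(union(net$genes, c("gc1", "gc2", "gc3")))
  list(net = net, media = fx$media)
}

# Diamond: nutrient-fed S with two parallel branches to T. Deleting g0 blocks
# everything downstream of S, so the include list of that no-growth mutant is
# {P, Q, S, T} and its members are fully interchangeable biomass choices.
diamond_network <- function() {
  mets <- data.frame(id = c("N_e", "S", "P", "Q", "T"),
                     name = c("N_e", "S", "P", "Q", "T"),
                     compartment = c("e", "c", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction_record("EX_N", c(N_e = -1), -1000, 1000),
    reaction_record("R0", c(N_e = -1, S = 1), 0, 1000, gpr = "g0"),
    reaction_record("RP", c(S = -1, P = 1), 0, 1000, gpr = "gp"),
    reaction_record("RPT", c(P = -1, T = 1), 0, 1000, gpr = "gpt"),
    reaction_record("RQ", c(S = -1, Q = 1), 0, 1000, gpr = "gq"),
    reaction_record("RQT", c(Q = -1, T = 1), 0, 1000, gpr = "gqt"))
  net <- metabolic_network(mets, rxns, id = "diamond")
  experiments <- experiment_table(
    experiment_id = c("d1", "d2"),
    deleted_genes = c("g0", "gu"),
    media_id = "m_dia",
    observed = c("NG", "G"))
  net$genes <- sort(union(net$genes, "gu"))
  list(net = net, media = media_condition("m_dia", c(EX_N = 10)),
       experiments = experiments)
}

# By-product coupling: making M from N unavoidably co-produces W, which has no
# consumer. A biomass {M} therefore cannot carry flux under plain FBA until W
# is drained; the unique minimal dead-end sink set is {W}.
byproduct_network <- function() {
  mets <- data.frame(id = c("N_e", "N_c", "M", "W", "U"),
                     name = c("N_e", "N_c", "M", "W", "U"),
                     compartment = c("e", "c", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction_record("EX_N", c(N_e = -1), -1000, 1000),
    reaction_record("T_N", c(N_e = -1, N_c = 1), 0, 1000, gpr = "gt"),
    reaction_record("RB", c(N_c = -1, M = 1, W = 1), 0, 1000, gpr = "gb"),
    reaction_record("RU", c(N_c = -1, U = 1), 0, 1000, gpr = "gx"))
  net <- metabolic_network(mets, rxns, id = "byprod")
  experiments <- experiment_table(
    experiment_id = c("b1", "b2"),
    deleted_genes = c("gb", "gx"),
    media_id = "m_by",
    observed = c("NG", "G"))
  list(net = net, media = media_condition("m_by", c(EX_N = 10)),
       experiments = experiments)
}

# Convenience: named media list for build_lists() and friends.
media_list <- function(media) stats::setNames(list(media), media$id)
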