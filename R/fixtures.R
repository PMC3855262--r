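# Synthetic toy networks with planted biomasses and simulated knockout
# phenotypes. The generator assembles the structural motifs that drive
# blocked-metabolite analysis in real reconstructions: linear pathways fed by
# media nutrients, isozyme-duplicated reactions, parallel alternate routes,
# source-free closed cycles (net-production blocked despite feasible internal
# flux) and by-product couplings with no consumer.

#' Specification for a random fixture network
#'
#' @param n_linear_pathways number of nutrient-fed linear chains.
#' @param pathway_length length range (min, max) of each chain.
#' @param n_isozyme_pairs reactions duplicated under a second gene.
#' @param n_parallel_routes targets reachable via two independent routes.
#' @param n_closed_cycles source-free 3-cycles (all members blocked).
#' @param n_byproduct_couplings reactions emitting a consumer-less co-product.
#' @param planted_biomass_size number of planted biomass components.
#' @param n_media_nutrients nutrients with exchange + transport.
#' @param seed RNG seed fixing the network and phenotype draw exactly.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_linear_pathways = 3, pathway_length = c(2, 4),
                         n_isozyme_pairs = 1, n_parallel_routes = 1,
                         n_closed_cycles = 1, n_byproduct_couplings = 1,
                         planted_biomass_size = 3, n_media_nutrients = 2,
                         seed = 1) {
  spec <- list(n_linear_pathways = n_linear_pathways,
               pathway_length = pathway_length,
               n_isozyme_pairs = n_isozyme_pairs,
               n_parallel_routes = n_parallel_routes,
               n_closed_cycles = n_closed_cycles,
               n_byproduct_couplings = n_byproduct_couplings,
               planted_biomass_size = planted_biomass_size,
               n_media_nutrients = n_media_nutrients,
               seed = seed)
  if (any(unlist(spec[1:8]) < 0)) {
    stop("spec error: all counts must be nonnegative", call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random toy network from a fixture specification
#'
#' Deterministic under \code{spec$seed}. Every non-exchange reaction carries
#' its own gene; isozyme pairs are duplicate reactions under a second gene.
#' The planted biomass is drawn from metabolites constructively derived from
#' the media nutrients, so it is producible in the wild type by design.
#'
#' @param spec a [fixture_spec()].
#' @return list with \code{net} (a \code{metabolic_network}), \code{media}
#'   (a [media_condition()]), \code{planted} (component ids) and
#'   \code{derived} (all nutrient-derived metabolite ids).
#' @export
make_random_network <- function(spec) {
  with_seed(spec$seed, {
    mets <- character(0); comp <- character(0)
    rxns <- list(); gcount <- 0L
    add_met <- function(id, cp) {
      mets <<- c(mets, id); comp <<- c(comp, cp); id
    }
    next_gene <- function() {
      gcount <<- gcount + 1L
      sprintf("g%03d", gcount)
    }
    add_rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = next_gene()) {
      rxns[[id]] <<- reaction_record(id, stoich, lb, ub, gpr)
      id
    }
    derived <- character(0)
    uptakes <- numeric(0)
    for (k in seq_len(spec$n_media_nutrients)) {
      ext <- add_met(sprintf("nut%d_e", k), "e")
      cyt <- add_met(sprintf("nut%d_c", k), "c")
      add_rxn(sprintf("EX_nut%d", k), stats::setNames(-1, ext),
              lb = -1000, ub = 1000, gpr = "")
      add_rxn(sprintf("T_nut%d", k),
              stats::setNames(c(-1, 1), c(ext, cyt)))
      uptakes[sprintf("EX_nut%d", k)] <- 10
      derived <- c(derived, cyt)
    }
    mcount <- 0L
    next_met <- function() {
      mcount <<- mcount + 1L
      add_met(sprintf("m%03d_c", mcount), "c")
    }
    for (pw in seq_len(spec$n_linear_pathways)) {
      len <- sample(spec$pathway_length[1]:spec$pathway_length[2], 1)
      prev <- sample(derived, 1)
      for (s in seq_len(len)) {
        nm <- next_met()
        add_rxn(sprintf("R_p%d_s%d", pw, s),
                stats::setNames(c(-1, 1), c(prev, nm)))
        derived <- c(derived, nm)
        prev <- nm
      }
    }
    for (pr in seq_len(spec$n_parallel_routes)) {
      src <- sample(derived, 1)
      mid1 <- next_met(); mid2 <- next_met(); tgt <- next_met()
      add_rxn(sprintf("R_alt%d_a1", pr),
              stats::setNames(c(-1, 1), c(src, mid1)))
      add_rxn(sprintf("R_alt%d_a2", pr),
              stats::setNames(c(-1, 1), c(mid1, tgt)))
      add_rxn(sprintf("R_alt%d_b1", pr),
              stats::setNames(c(-1, 1), c(src, mid2)))
      add_rxn(sprintf("R_alt%d_b2", pr),
              stats::setNames(c(-1, 1), c(mid2, tgt)))
      derived <- c(derived, mid1, mid2, tgt)
    }
    for (bc in seq_len(spec$n_byproduct_couplings)) {
      src <- sample(derived, 1)
      main <- next_met(); side <- next_met()
      add_rxn(sprintf("R_by%d", bc),
              stats::setNames(c(-1, 1, 1), c(src, main, side)))
      derived <- c(derived, main, side)
    }
    cycle_members <- character(0)
    for (cy in seq_len(spec$n_closed_cycles)) {
      cm <- replicate(3, next_met())
      for (s in 1:3) {
        add_rxn(sprintf("R_cyc%d_s%d", cy, s),
                stats::setNames(c(-1, 1), c(cm[s], cm[s %% 3 + 1])))
      }
      cycle_members <- c(cycle_members, cm)
    }
    if (spec$n_isozyme_pairs > 0) {
      cand <- grep("^R_", names(rxns), value = TRUE)
      pick <- sample(cand, min(spec$n_isozyme_pairs, length(cand)))
      for (rid in pick) {
        r <- rxns[[rid]]
        add_rxn(paste0(rid, "_iso"), r$stoich, r$lower_bound, r$upper_bound)
      }
    }
    if (spec$planted_biomass_size > length(unique(derived))) {
      stop("spec error: planted biomass larger than the derived metabolite ",
           "pool", call. = FALSE)
    }
    planted <- sort(sample(unique(derived), spec$planted_biomass_size))
    md <- data.frame(id = mets, name = mets, compartment = comp,
                     stringsAsFactors = FALSE)
    net <- metabolic_network(md, rxns,
                             id = sprintf("fixture_seed%d", spec$seed))
    list(net = net,
         media = media_condition("fixture_media", uptakes),
         planted = planted,
         derived = sort(unique(derived)),
         cycle_members = sort(cycle_members))
  })
}

#' Simulate knockout growth phenotypes from a planted biomass
#'
#' A mutant is labeled no-growth exactly when some planted component is
#' net-production blocked in it (decided by the per-metabolite LP oracle,
#' which is the defining criterion); labels are then flipped independently
#' with probability \code{noise_rate}.
#'
#' @param net raw network.
#' @param planted planted biomass component ids (must be wild-type
#'   producible under \code{media}).
#' @param knockouts list of gene-id vectors, one per experiment; defaults to
#'   all single-gene deletions.
#' @param media a [media_condition()].
#' @param noise_rate label-flip probability.
#' @param seed RNG seed for the noise draw.
#' @param cfg a [blocking_config()].
#' @param method \code{"oracle"} (per-metabolite LPs, the defining criterion)
#'   or \code{"milp"} (one producibility MILP per mutant, equivalent and much
#'   faster on large fixtures).
#' @return experiments data.frame; attribute \code{"truth"} keeps the
#'   noiseless labels.
#' @export
plant_phenotypes <- function(net, planted, knockouts = NULL, media,
                             noise_rate = 0, seed = 1,
                             cfg = blocking_config(),
                             method = c("oracle", "milp")) {
  method <- match.arg(method)
  solver <- if (method == "oracle") producible_oracle else producible_set_milp
  if (is.null(knockouts)) knockouts <- as.list(net$genes)
  prepped <- apply_media(prepare_for_blocking(net, u_sink = cfg$big_m), media)
  wt <- solver(prepped, cfg, strain = "wt")
  bad <- intersect(planted, wt$blocked)
  if (length(bad)) {
    stop("spec error: planted component(s) not producible in the wild type: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cache <- list()
  truth <- character(length(knockouts))
  for (k in seq_along(knockouts)) {
    genes <- intersect(knockouts[[k]], net$genes)
    disabled <- names(prepped$reactions)[vapply(prepped$reactions,
      function(r) !is.null(r$gpr_tree) && !eval_gpr(r$gpr_tree, genes),
      logical(1))]
    sig <- paste(disabled, collapse = ",")
    if (is.null(cache[[sig]])) {
      mut_net <- prepped
      for (rid in disabled) {
        mut_net$reactions[[rid]]$lower_bound <- 0
        mut_net$reactions[[rid]]$upper_bound <- 0
      }
      mut <- if (length(disabled) == 0) wt
        else solver(mut_net, cfg, strain = "mut")
      cache[[sig]] <- list(blocked = candidate_blocked(wt, mut))
    }
    truth[k] <- if (length(intersect(cache[[sig]]$blocked, planted))) "NG"
      else "G"
  }
  observed <- with_seed(seed, {
    flip <- stats::runif(length(truth)) < noise_rate
    ifelse(flip, ifelse(truth == "NG", "G", "NG"), truth)
  })
  out <- experiment_table(
    experiment_id = sprintf("exp%03d", seq_along(knockouts)),
    deleted_genes = vapply(knockouts, paste, character(1), collapse = ";"),
    media_id = media$id,
    observed = observed)
  attr(out, "truth") <- truth
  out
}

#' Hand-built illustrative network for the modification workflow
#'
#' A ten-metabolite toy (an homage to the classic worked example of this class
#' of methods; the exact published topology is not claimed) in which the media
#' supplies A and G, metabolites I_ex and I are wild-type blocked by the media
#' choice, and four knockout experiments drive a predefined biomass
#' \{F, H\} to be modified by adding C and removing F while H, for which no
#' evidence exists, stays untouched.
#'
#' @return list with \code{net}, \code{media}, \code{experiments} and
#'   \code{mu} (the predefined component set).
#' @export
demo_fixture <- function() {
  mets <- data.frame(
    id = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "I_ex"),
    name = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "I external"),
    compartment = c("e", "c", "c", "c", "c", "c", "e", "c", "c", "e"),
    stringsAsFactors = FALSE)
  rxns <- list(
    reaction_record("EX_A", c(A = -1), -1000, 1000),
    reaction_record("EX_G", c(G = -1), -1000, 1000),
    reaction_record("EX_I", c(I_ex = -1), -1000, 1000),
    reaction_record("R1", c(A = -1, B = 1), 0, 1000, gpr = "g1"),
    reaction_record("R2", c(B = -1, C = 1), 0, 1000, gpr = "g2"),
    reaction_record("R3", c(C = -1, D = 1), 0, 1000, gpr = "g3"),
    reaction_record("R4", c(G = -1, F = 1), 0, 1000, gpr = "g4"),
    reaction_record("R5", c(B = -1, E = 1), 0, 1000, gpr = "g5"),
    reaction_record("R6", c(E = -1, H = 1), 0, 1000, gpr = "g6"),
    reaction_record("T_I", c(I_ex = -1, I = 1), 0, 1000, gpr = "gt"),
    reaction_record("BIOMASS_predef", c(F = -2e-4, H = -2e-4), 0, 1000))
  net <- metabolic_network(mets, rxns, biomass_ids = "BIOMASS_predef",
                           id = "demo")
  media <- media_condition("demo_media", c(EX_A = 10, EX_G = 10))
  experiments <- experiment_table(
    experiment_id = c("e1", "e2", "e3", "e4"),
    deleted_genes = c("g2", "g3", "g4", "gt"),
    media_id = "demo_media",
    observed = c("NG", "G", "G", "G"))
  list(net = net, media = media, experiments = experiments, mu = net$mu)
}
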