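# Alternative biomass components, essential precursors and the comparison of a
# proposed biomass against a predefined one.

#' Enumerate alternative metabolites for one biomass component
#'
#' All other proposed components are pinned in, the target is pinned out, and
#' the minimal-biomass IP is re-solved at unchanged agreement with uniform
#' (unweighted) costs. Every feasible solve yields replacement metabolites,
#' whose indicators are then pinned out in turn, until the problem becomes
#' infeasible and all alternatives are exhausted. A component with no feasible
#' replacement is "unique".
#'
#' @param proposal a \code{biomass_proposal}.
#' @param lists the \code{include_exclude_lists} the proposal was fit on.
#' @param target a component of \code{proposal$components}.
#' @param cap maximum number of enumeration rounds (guards pathological
#'   instances).
#' @return Character vector of alternative metabolite ids (possibly empty).
#' @export
enumerate_alternatives <- function(proposal, lists, target, cap = 50) {
  if (!target %in% proposal$components) {
    stop("usage error: '", target, "' is not a proposed component",
         call. = FALSE)
  }
  inst <- agreement_instance(lists, proposal$em, proposal$em_weight)
  fix_obj <- proposal$agreement
  keep <- setdiff(proposal$components, target)
  cost <- stats::setNames(rep(1, length(inst$universe)), inst$universe)
  alternatives <- character(0)
  for (round in seq_len(cap)) {
    fixed <- c(stats::setNames(rep(1, length(keep)), keep),
               stats::setNames(rep(0, 1 + length(alternatives)),
                               c(target, alternatives)))
    ap <- agreement_problem(inst, fixed = fixed, min_agreement = fix_obj,
                            cost = cost)
    res <- tryCatch(lp_solve(ap$p), error = function(e) NULL)
    if (is.null(res) || res$status == "infeasible") break
    sel <- inst$universe[res$x[seq_len(ap$nu)] > 0.5]
    found <- setdiff(sel, keep)
    if (length(found) == 0) break  # target was redundant; nothing replaces it
    alternatives <- c(alternatives, found)
  }
  sort(alternatives)
}

#' Essential precursors of a biomass set under robust media
#'
#' Builds a direction-decoupled flux system (v = v_for - v_rev, both
#' nonnegative) with sinks for every metabolite and requires every biomass
#' component's sink to carry at least \code{v_min} simultaneously. Each
#' candidate metabolite k outside the biomass is then removed from the system:
#' the forward direction of every reaction consuming k forward and the reverse
#' direction of every reaction consuming k in reverse are fixed to zero, along
#' with k's own exchange and sink. If the biomass demand becomes infeasible, k
#' is an essential precursor.
#'
#' @param net raw \code{metabolic_network}.
#' @param biomass nonempty set of biomass component metabolite ids.
#' @param robust_media a [media_condition()] unioning all experimentally
#'   tested conditions.
#' @param cfg a [blocking_config()] (its \code{v_min} is reused as the sink
#'   demand).
#' @param simultaneous require one flux vector producing all components at
#'   once (default); \code{FALSE} tests each component separately and is
#'   offered for diagnosis.
#' @param candidates metabolites to test (default: all outside the biomass).
#' @return Sorted character vector of essential precursor ids.
#' @export
essential_precursors <- function(net, biomass, robust_media,
                                 cfg = blocking_config(),
                                 simultaneous = TRUE, candidates = NULL) {
  stopifnot(length(biomass) > 0)
  prepped <- apply_media(prepare_for_blocking(net, u_sink = cfg$big_m),
                         robust_media)
  tri <- net_triplets(prepped)
  bnd <- net_bounds(prepped)
  nr <- length(tri$rxn_ids)
  # decoupled variables: columns 1..nr forward, nr+1..2nr reverse
  for_ub <- pmax(bnd$ub, 0); for_lb <- pmax(bnd$lb, 0)
  rev_ub <- pmax(-bnd$lb, 0); rev_lb <- pmax(-bnd$ub, 0)
  base_problem <- function() {
    p <- lp_new(2L * nr, "max")
    lp_set_bounds(p, lb = c(for_lb, rev_lb), ub = c(for_ub, rev_ub))
    nmet <- length(tri$met_ids)
    lp_add_rows(p, c(tri$i, tri$i), c(tri$j, nr + tri$j), c(tri$x, -tri$x),
                rep("=", nmet), rep(0, nmet))
    for (cc in prepped$coupling) {
      jj <- match(names(cc$coef), tri$rxn_ids)
      lp_add_rows(p, rep(1L, 2 * length(jj)), c(jj, nr + jj),
                  c(unname(cc$coef), -unname(cc$coef)), cc$sense, cc$rhs)
    }
    p
  }
  sink_col <- stats::setNames(match(paste0("SK_", tri$met_ids), tri$rxn_ids),
                              tri$met_ids)
  if (anyNA(sink_col[biomass])) {
    stop("usage error: biomass metabolite(s) not in network", call. = FALSE)
  }
  ex_of <- lapply(stats::setNames(tri$met_ids, tri$met_ids), function(m) {
    hits <- vapply(prepped$reactions, function(r)
      length(r$stoich) == 1L && names(r$stoich) == m, logical(1))
    setdiff(names(prepped$reactions)[hits], paste0("SK_", m))
  })
  demand_sets <- if (simultaneous) list(biomass) else as.list(biomass)
  feasible_when_killed <- function(k) {
    for (dem in demand_sets) {
      p <- base_problem()
      lp_set_bounds(p, lb = cfg$v_min, idx = sink_col[dem])
      if (!is.null(k)) {
        cons_f <- unique(tri$j[tri$i == match(k, tri$met_ids) & tri$x < 0])
        cons_r <- unique(tri$j[tri$i == match(k, tri$met_ids) & tri$x > 0])
        if (length(cons_f)) lp_set_bounds(p, lb = 0, ub = 0, idx = cons_f)
        if (length(cons_r)) {
          lp_set_bounds(p, lb = 0, ub = 0, idx = nr + cons_r)
        }
        kill <- c(match(ex_of[[k]], tri$rxn_ids), sink_col[k])
        lp_set_bounds(p, lb = 0, ub = 0, idx = c(kill, nr + kill))
      }
      if (!lp_feasible(p, time_limit = cfg$time_limit)) return(FALSE)
    }
    TRUE
  }
  if (!feasible_when_killed(NULL)) {
    stop("biomass set is not simultaneously producible under the robust ",
         "media; the proposal violates the precursor analysis precondition",
         call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- setdiff(tri$met_ids, biomass)
  }
  candidates <- sort(setdiff(candidates, biomass))
  ess <- candidates[!vapply(candidates, feasible_when_killed, logical(1))]
  sort(ess)
}

#' Categorize de novo components against a predefined biomass
#'
#' Each proposed component receives exactly one category, assigned in
#' precedence order: \code{direct_match} (member of the predefined set),
#' \code{alternative_of_predefined} (one of its interchangeable alternatives
#' is predefined), \code{downstream_of_predefined} (some predefined metabolite
#' is an essential precursor of it), \code{upstream_of_predefined} (it is an
#' essential precursor of some predefined component), else \code{unique}.
#'
#' @param de_novo proposed component ids (or a \code{biomass_proposal}).
#' @param predefined predefined component ids.
#' @param net raw network.
#' @param robust_media robust media condition.
#' @param lists the lists the proposal was fit on (for alternatives).
#' @param cfg a [blocking_config()].
#' @return data.frame \code{component_id}, \code{category}.
#' @export
categorize_components <- function(de_novo, predefined, net, robust_media,
                                  lists, cfg = blocking_config()) {
  proposal <- if (inherits(de_novo, "biomass_proposal")) de_novo
    else NULL
  comps <- if (is.null(proposal)) sort(de_novo) else proposal$components
  upstream_cache <- new.env(parent = emptyenv())
  precursors_of <- function(set_id, set) {
    if (!exists(set_id, upstream_cache, inherits = FALSE)) {
      assign(set_id, essential_precursors(net, set, robust_media, cfg),
             upstream_cache)
    }
    get(set_id, upstream_cache, inherits = FALSE)
  }
  cat_of <- function(c0) {
    if (c0 %in% predefined) return("direct_match")
    if (!is.null(proposal)) {
      alts <- enumerate_alternatives(proposal, lists, c0)
      if (length(intersect(alts, predefined))) {
        return("alternative_of_predefined")
      }
    }
    if (length(intersect(precursors_of(paste0("dn_", c0), c0), predefined))) {
      return("downstream_of_predefined")
    }
    for (p0 in predefined) {
      if (c0 %in% precursors_of(paste0("pd_", p0), p0)) {
        return("upstream_of_predefined")
      }
    }
    "unique"
  }
  data.frame(component_id = comps,
             category = vapply(comps, cat_of, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
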