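# Biomass component selection.
#
# Integer programs over membership indicators m_i: a no-growth experiment e is
# matched (n_e = 1) when the biomass contains some metabolite of its include
# list; a growth experiment e is matched (g_e = 1) when the biomass avoids its
# exclude list entirely. De novo selection maximizes (weighted) agreement and
# then optimizes a secondary component objective at fixed agreement;
# modification of a predefined biomass adds a lexicographic
# fewest-removals-then-fewest-additions stage.

#' Weighting scheme for secondary component selection
#'
#' @param mode \code{"minimal"}: uniform positive weights, yielding a
#'   minimum-cardinality biomass; \code{"weighted"}: metabolites in
#'   \code{preferred} (commonly amino acids and currency metabolites) carry a
#'   negative weight and are chosen preferentially among interchangeable
#'   options.
#' @param preferred metabolite ids preferred for inclusion (weighted mode).
#' @param preferred_weight,default_weight the two weights; must satisfy
#'   \code{preferred_weight < 0 < default_weight} in weighted mode.
#' @return A \code{weight_scheme} list.
#' @export
weight_scheme <- function(mode = c("minimal", "weighted"),
                          preferred = character(0),
                          preferred_weight = -1, default_weight = 1) {
  mode <- match.arg(mode)
  if (mode == "weighted" &&
      !(preferred_weight < 0 && default_weight > 0)) {
    stop("weighted mode requires preferred_weight < 0 < default_weight",
         call. = FALSE)
  }
  structure(list(mode = mode, preferred = preferred,
                 preferred_weight = preferred_weight,
                 default_weight = default_weight), class = "weight_scheme")
}

# Internal description of one agreement-IP instance.
#
# universe: decision metabolites (sorted); ng/g: experiment ids; in_sets /
# ex_sets: named lists of index vectors into universe; wts: per-experiment
# weights (EM pseudo-experiments included in ng with their own weight).
#' @keywords internal
agreement_instance <- function(lists, em = character(0), em_weight = 1,
                               extra_universe = character(0)) {
  universe <- sort(unique(c(lists$universe, em, extra_universe)))
  uidx <- stats::setNames(seq_along(universe), universe)
  ng <- names(lists$include)
  in_sets <- lapply(lists$include, function(s) unname(uidx[s]))
  g <- names(lists$exclude)
  ex_sets <- lapply(lists$exclude, function(s) unname(uidx[s]))
  wts <- lists$weights
  if (length(em)) {
    em_ids <- paste0("EM_", em)
    ng <- c(ng, em_ids)
    in_sets <- c(in_sets, stats::setNames(
      lapply(em, function(m) unname(uidx[m])), em_ids))
    wts <- c(wts, stats::setNames(rep(em_weight, length(em)), em_ids))
  }
  list(universe = universe, ng = ng, g = g,
       in_sets = in_sets, ex_sets = ex_sets, wts = wts,
       em = em, em_weight = em_weight)
}

# Evaluate the agreement of a concrete component set directly (no solver).
#' @keywords internal
agreement_of <- function(components, inst) {
  idx <- match(components, inst$universe)
  matched_ng <- inst$ng[vapply(inst$in_sets[inst$ng], function(s)
    length(intersect(s, idx)) > 0, logical(1))]
  matched_g <- inst$g[vapply(inst$ex_sets[inst$g], function(s)
    length(intersect(s, idx)) == 0, logical(1))]
  list(score = sum(inst$wts[matched_ng]) + sum(inst$wts[matched_g]),
       matched_ng = matched_ng, matched_g = matched_g)
}

# Build the agreement MILP. fixed: named numeric (metabolite id -> 0/1) pins
# membership variables; min_agreement adds the FixObj row; cost adds the
# secondary objective (named numeric over universe) to minimize, otherwise the
# agreement itself is maximized.
#' @keywords internal
agreement_problem <- function(inst, fixed = numeric(0), min_agreement = NULL,
                              cost = NULL, max_cost = NULL) {
  nu <- length(inst$universe)
  nng <- length(inst$ng); ngr <- length(inst$g)
  n <- nu + nng + ngr
  ncol_n <- nu + seq_len(nng)
  ncol_g <- nu + nng + seq_len(ngr)
  p <- lp_new(n, if (is.null(cost)) "max" else "min")
  lp_set_binary(p, seq_len(n))
  # n_e <= sum of include members
  for (k in seq_len(nng)) {
    s <- inst$in_sets[[inst$ng[k]]]
    if (length(s) == 0) {
      lp_set_bounds(p, ub = 0, idx = ncol_n[k])
    } else {
      lp_add_rows(p, rep(1L, length(s) + 1L), c(ncol_n[k], s),
                  c(1, rep(-1, length(s))), "<=", 0)
    }
  }
  # g_e <= 1 - m_i for every exclude member
  for (k in seq_len(ngr)) {
    s <- inst$ex_sets[[inst$g[k]]]
    for (i in s) {
      lp_add_rows(p, c(1L, 1L), c(ncol_g[k], i), c(1, 1), "<=", 1)
    }
  }
  agree_coef <- numeric(n)
  agree_coef[ncol_n] <- unname(inst$wts[inst$ng])
  agree_coef[ncol_g] <- unname(inst$wts[inst$g])
  if (is.null(cost)) {
    lp_set_objective(p, agree_coef)
  } else {
    obj <- numeric(n)
    obj[seq_len(nu)] <- unname(cost[inst$universe])
    lp_set_objective(p, obj)
  }
  if (!is.null(min_agreement)) {
    nz <- which(agree_coef != 0)
    lp_add_rows(p, rep(1L, length(nz)), nz, agree_coef[nz], ">=",
                min_agreement - 1e-6)
  }
  if (!is.null(max_cost)) {
    cvec <- numeric(n); cvec[seq_len(nu)] <- unname(cost[inst$universe])
    nz <- which(cvec != 0)
    if (length(nz)) {
      lp_add_rows(p, rep(1L, length(nz)), nz, cvec[nz], "<=", max_cost + 1e-6)
    }
  }
  if (length(fixed)) {
    idx <- match(names(fixed), inst$universe)
    if (anyNA(idx)) {
      stop("usage error: fixed metabolite(s) outside candidate universe: ",
           paste(names(fixed)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    lp_set_bounds(p, lb = unname(fixed), ub = unname(fixed), idx = idx)
  }
  list(p = p, nu = nu, inst = inst)
}

# Deterministic tie-break: scan metabolites in sorted id order and pin each to
# 1 when some optimum contains it, else to 0. Greedy inclusion of the smallest
# ids yields the lexicographically smallest optimal component set.
#' @keywords internal
lexi_minimal_solution <- function(inst, fixed, fix_obj, cost, opt_cost) {
  for (m in inst$universe) {
    if (m %in% names(fixed)) next
    trial <- c(fixed, stats::setNames(1, m))
    ap <- agreement_problem(inst, fixed = trial, min_agreement = fix_obj,
                            cost = cost, max_cost = opt_cost)
    fixed <- if (lp_feasible(ap$p)) trial else c(fixed, stats::setNames(0, m))
  }
  names(fixed)[fixed == 1]
}

#' Maximal achievable experimental agreement
#'
#' Solves the de novo agreement IP: choose biomass components so that the
#' weighted number of matched experiments is maximal. Analytically measured
#' components (\code{em}) enter as soft single-metabolite no-growth
#' pseudo-experiments, so phenotype data can still overrule a measurement.
#'
#' @param lists an \code{include_exclude_lists} from [build_lists()].
#' @param em optional experimentally measured biomass component ids.
#' @param em_weight weight of each measurement pseudo-experiment.
#' @return list with \code{fix_obj} (the maximal agreement), a witness
#'   \code{components} set and the \code{instance} used.
#' @export
max_agreement <- function(lists, em = character(0), em_weight = 1) {
  inst <- agreement_instance(lists, em, em_weight)
  if (length(inst$universe) == 0) {
    return(list(fix_obj = sum(inst$wts[inst$g]), components = character(0),
                instance = inst))
  }
  ap <- agreement_problem(inst)
  res <- lp_solve(ap$p)
  comps <- inst$universe[res$x[seq_len(ap$nu)] > 0.5]
  # report the exact combinatorial score of the witness (guards roundoff)
  list(fix_obj = agreement_of(comps, inst)$score, components = comps,
       instance = inst)
}

#' @keywords internal
component_costs <- function(inst, scheme) {
  cost <- stats::setNames(rep(scheme$default_weight, length(inst$universe)),
                          inst$universe)
  if (scheme$mode == "weighted") {
    cost[intersect(scheme$preferred, inst$universe)] <- scheme$preferred_weight
  }
  cost
}

#' @keywords internal
new_biomass_proposal <- function(components, inst, kind,
                                 secondary_objective = NA_real_,
                                 added = NULL, removed = NULL,
                                 unmodified = NULL, mu = NULL) {
  ag <- agreement_of(components, inst)
  structure(list(components = sort(components),
                 agreement = ag$score,
                 matched_ng = setdiff(ag$matched_ng,
                                      paste0("EM_", inst$em)),
                 matched_g = ag$matched_g,
                 em_pseudo = intersect(ag$matched_ng,
                                       paste0("EM_", inst$em)),
                 secondary_objective = secondary_objective,
                 kind = kind, added = added, removed = removed,
                 unmodified = unmodified, mu = mu,
                 sink_additions = character(0),
                 em = inst$em, em_weight = inst$em_weight,
                 instance = inst),
            class = "biomass_proposal")
}

#' @export
print.biomass_proposal <- function(x, ...) {
  cat("Biomass proposal (", x$kind, "): ", length(x$components),
      " components, agreement ", format(x$agreement), "\n", sep = "")
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  if (!is.null(x$added)) {
    cat("  added:", paste(x$added, collapse = ", "),
        "| removed:", paste(x$removed, collapse = ", "),
        "| unmodified:", paste(x$unmodified, collapse = ", "), "\n")
  }
  if (length(x$sink_additions)) {
    cat("  dead-end sink additions:",
        paste(x$sink_additions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Propose a de novo biomass at maximal agreement
#'
#' Re-solves the agreement IP with the agreement pinned to \code{fix_obj} and a
#' secondary objective minimizing the summed component weights ([weight_scheme()]):
#' minimal mode yields a minimum-cardinality biomass, weighted mode prefers
#' designated common metabolites among interchangeable options. Remaining ties
#' are broken deterministically toward the lexicographically smallest
#' component set (sorted metabolite ids).
#'
#' @inheritParams max_agreement
#' @param fix_obj maximal agreement from [max_agreement()] on the same inputs.
#' @param scheme a [weight_scheme()].
#' @return A \code{biomass_proposal}.
#' @export
select_de_novo <- function(lists, em = character(0),
                           fix_obj = NULL, scheme = weight_scheme(),
                           em_weight = 1) {
  inst <- agreement_instance(lists, em, em_weight)
  if (is.null(fix_obj)) {
    fix_obj <- max_agreement(lists, em, em_weight)$fix_obj
  }
  if (length(inst$universe) == 0) {
    return(new_biomass_proposal(character(0), inst, "de_novo",
                                secondary_objective = 0))
  }
  cost <- component_costs(inst, scheme)
  ap <- agreement_problem(inst, min_agreement = fix_obj, cost = cost)
  res <- lp_solve(ap$p)
  if (res$status == "infeasible") {
    stop("usage error: fix_obj ", fix_obj, " is not attainable on these ",
         "lists (stale value?)", call. = FALSE)
  }
  opt_cost <- sum(cost[inst$universe[res$x[seq_len(ap$nu)] > 0.5]])
  comps <- lexi_minimal_solution(inst, numeric(0), fix_obj, cost, opt_cost)
  new_biomass_proposal(comps, inst, "de_novo",
                       secondary_objective = opt_cost)
}

#' Modify a predefined biomass to maximize agreement
#'
#' Keeps the predefined component set \code{mu} except where experiments
#' contradict it. Solved lexicographically: (1) maximize weighted agreement
#' over the joint membership of predefined and candidate metabolites, (2) at
#' fixed agreement minimize the number of removals from \code{mu}, (3) at
#' fixed agreement and removals minimize the number of additions. Ties broken
#' as in [select_de_novo()].
#'
#' @inheritParams max_agreement
#' @param mu predefined biomass component ids (nonempty).
#' @param scheme reserved for weighted addition preferences; the lexicographic
#'   stages already determine the counts.
#' @return A \code{biomass_proposal} with \code{added}, \code{removed} and
#'   \code{unmodified} partitions.
#' @export
modify_biomass <- function(lists, mu, em = character(0),
                           scheme = weight_scheme(), em_weight = 1) {
  stopifnot(length(mu) > 0)
  inst <- agreement_instance(lists, em, em_weight, extra_universe = mu)
  in_mu <- inst$universe %in% mu
  # stage 1: maximal agreement over the joint universe
  ap1 <- agreement_problem(inst)
  fix_obj <- agreement_of(
    inst$universe[lp_solve(ap1$p)$x[seq_len(ap1$nu)] > 0.5], inst)$score
  # stage 2: fewest removals (maximize retained mu members)
  cost_rm <- stats::setNames(ifelse(in_mu, -1, 0), inst$universe)
  ap2 <- agreement_problem(inst, min_agreement = fix_obj, cost = cost_rm)
  res2 <- lp_solve(ap2$p)
  kept_opt <- -res2$objective
  # stage 3: fewest additions at that retention level
  cost_add <- stats::setNames(ifelse(in_mu, 0, 1), inst$universe)
  ap3 <- agreement_problem(inst, min_agreement = fix_obj, cost = cost_add,
                           max_cost = NULL)
  # pin retention via an extra row: sum over mu members >= kept_opt
  muidx <- which(in_mu)
  lp_add_rows(ap3$p, rep(1L, length(muidx)), muidx, rep(1, length(muidx)),
              ">=", kept_opt - 1e-6)
  res3 <- lp_solve(ap3$p)
  add_opt <- res3$objective
  # deterministic tie-break under both pinned counts (greedy inclusion of the
  # smallest ids, as in lexi_minimal_solution)
  fixed <- numeric(0)
  for (m in inst$universe) {
    trial <- c(fixed, stats::setNames(1, m))
    ap <- agreement_problem(inst, fixed = trial, min_agreement = fix_obj,
                            cost = cost_add, max_cost = add_opt)
    lp_add_rows(ap$p, rep(1L, length(muidx)), muidx, rep(1, length(muidx)),
                ">=", kept_opt - 1e-6)
    fixed <- if (lp_feasible(ap$p)) trial else c(fixed, stats::setNames(0, m))
  }
  comps <- names(fixed)[fixed == 1]
  new_biomass_proposal(comps, inst, "modification",
                       secondary_objective = add_opt,
                       added = sort(setdiff(comps, mu)),
                       removed = sort(setdiff(mu, comps)),
                       unmodified = sort(intersect(mu, comps)),
                       mu = sort(mu))
}

#' Serialize a biomass proposal as TSV
#'
#' @param proposal a \code{biomass_proposal}.
#' @param path output path.
#' @param lists optional lists for evidence counts.
#' @export
write_proposal <- function(proposal, path, lists = NULL) {
  status <- if (proposal$kind == "modification") {
    ids <- c(proposal$added, proposal$removed, proposal$unmodified,
             proposal$sink_additions)
    st <- c(rep("added", length(proposal$added)),
            rep("removed", length(proposal$removed)),
            rep("unmodified", length(proposal$unmodified)),
            rep("sink_role", length(proposal$sink_additions)))
    data.frame(metabolite_id = ids, status = st, stringsAsFactors = FALSE)
  } else {
    ids <- c(proposal$components, proposal$sink_additions)
    data.frame(metabolite_id = ids,
               status = c(rep("de_novo",
                              length(proposal$components)),
                          rep("sink_role", length(proposal$sink_additions))),
               stringsAsFactors = FALSE)
  }
  if (!is.null(lists)) {
    ft <- frequency_table(lists, focus = status$metabolite_id)
    status <- merge(status, ft, by = "metabolite_id", all.x = TRUE,
                    sort = TRUE)
  }
  utils::write.table(status, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
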