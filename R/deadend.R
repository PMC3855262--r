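# Dead-end by-product detection and biomass augmentation.
#
# A biomass chosen purely from blocked-metabolite evidence can force
# by-products that nothing in a growth experiment's network consumes; under
# plain FBA (no sinks) they would pin the biomass flux to zero. The detection
# MILP keeps sinks for all metabolites, demands a small biomass flux, and
# minimizes how many sinks are active; the active sinks are the dead-end
# by-products, which are then folded into the biomass as additional consumed
# species.

#' Detect dead-end by-products for one growth experiment
#'
#' @param net raw \code{metabolic_network} (predefined biomass reactions are
#'   removed internally so they cannot act as hidden drains).
#' @param biomass_components proposed component metabolite ids.
#' @param genes deleted gene ids of the experiment.
#' @param media a [media_condition()].
#' @param eps minimum biomass flux that must be sustainable (default 0.001).
#'   Internally the drain is solved with unit coefficients pinned at flux
#'   \code{eps}; by homogeneity of the flux system the resulting sink sets are
#'   invariant to the published coefficient scale, while the demanded fluxes
#'   stay well above solver tolerances.
#' @param cfg a [blocking_config()] (supplies the big-M and solver limits).
#' @param coefficient biomass stoichiometric magnitude per component (kept for
#'   interface symmetry with the growth predictor; the detection itself is
#'   scale-invariant, see \code{eps}).
#' @param experiment_id label for the report.
#' @param alternates number of alternative active-sink sets to search for via
#'   exclusion cuts.
#' @return A \code{deadend_report}: \code{active_sinks}, \code{alternates}
#'   (list of sets), \code{feasible} flag and the experiment id.
#' @export
deadend_byproducts <- function(net, biomass_components, genes = character(0),
                               media, eps = 0.001, cfg = blocking_config(),
                               coefficient = 2e-4, experiment_id = NA,
                               alternates = 3) {
  prepped <- apply_media(prepare_for_blocking(net, u_sink = cfg$big_m), media)
  prepped <- suppressWarnings(apply_knockout(prepped, genes))
  # The active-sink sets are invariant to the biomass coefficient scale (the
  # constraint system is homogeneous), so the detection problem is solved with
  # a unit-coefficient drain pinned at flux eps. At the published coefficient
  # (2e-4) the demanded fluxes (~2e-7) would sit below the solver's absolute
  # feasibility and integrality tolerances and the MILP would be degenerate.
  bio <- build_biomass_reaction(biomass_components, 1)
  prepped$reactions[[bio$id]] <- bio
  tri <- net_triplets(prepped)
  bnd <- net_bounds(prepped)
  nr <- length(tri$rxn_ids)
  mids <- sort(prepped$metabolites$id)
  nmet <- length(mids)
  sink_col <- match(paste0("SK_", mids), tri$rxn_ids)
  bio_col <- match(bio$id, tri$rxn_ids)
  solve_with <- function(banned) {
    p <- lp_new(nr + nmet, "min")
    lp_set_bounds(p, lb = bnd$lb, ub = bnd$ub, idx = seq_len(nr))
    lp_set_bounds(p, lb = eps, ub = eps, idx = bio_col)  # pinned demand
    scol <- nr + seq_len(nmet)
    lp_set_binary(p, scol)
    if (length(banned)) {
      lp_set_bounds(p, ub = 0, idx = scol[match(banned, mids)])
    }
    lp_add_rows(p, tri$i, tri$j, tri$x, rep("=", length(tri$met_ids)),
                rep(0, length(tri$met_ids)))
    for (cc in prepped$coupling) {
      jj <- match(names(cc$coef), tri$rxn_ids)
      lp_add_rows(p, rep(1L, length(jj)), jj, unname(cc$coef), cc$sense,
                  cc$rhs)
    }
    # x_i <= s_i: with the biomass pinned at flux eps, a forced by-product
    # sink carries ~eps (1e-3) flux, so a closed indicator violates the row
    # and the relaxation value eps/1 stays far above the solver's integer
    # tolerance; the unit cap is ample for the tiny demanded fluxes
    lp_add_rows(p, rep(seq_len(nmet), 2L), c(sink_col, scol),
                c(rep(1, nmet), rep(-1, nmet)),
                rep("<=", nmet), rep(0, nmet))
    obj <- numeric(p$n); obj[scol] <- 1
    lp_set_objective(p, obj)
    res <- tryCatch(lp_solve(p, time_limit = cfg$time_limit),
                    error = function(e) list(status = "failed"))
    if (res$status != "optimal") return(NULL)
    list(active = mids[res$x[nr + seq_len(nmet)] > 0.5],
         count = round(res$objective))
  }
  first <- solve_with(character(0))
  if (is.null(first)) {
    return(structure(list(experiment_id = experiment_id, eps = eps,
                          active_sinks = character(0), alternates = list(),
                          feasible = FALSE),
                     class = "deadend_report"))
  }
  alt_sets <- list()
  for (a in utils::head(sort(first$active), alternates)) {
    alt <- solve_with(a)
    if (!is.null(alt) && alt$count <= first$count &&
        !identical(sort(alt$active), sort(first$active))) {
      alt_sets[[length(alt_sets) + 1L]] <- sort(alt$active)
    }
  }
  structure(list(experiment_id = experiment_id, eps = eps,
                 active_sinks = sort(first$active),
                 alternates = unique(alt_sets), feasible = TRUE),
            class = "deadend_report")
}

#' @export
print.deadend_report <- function(x, ...) {
  cat("Dead-end report (experiment ", x$experiment_id, "): ", sep = "")
  if (!x$feasible) {
    cat("growth unattainable even with all sinks open\n")
  } else if (length(x$active_sinks) == 0) {
    cat("no dead-end by-products\n")
  } else {
    cat("by-products {", paste(x$active_sinks, collapse = ", "), "}; ",
        length(x$alternates), " alternate set(s)\n", sep = "")
  }
  invisible(x)
}

#' Augment a biomass proposal with dead-end by-product sinks
#'
#' Iterates [deadend_byproducts()] over every growth experiment the selection
#' IP matched, adds the union of active sinks to the biomass (tagged as
#' sink-role additions: they are consumed species, not evidence-supported
#' components), and repeats until no matched growth experiment needs a further
#' sink.
#'
#' @param proposal a \code{biomass_proposal}.
#' @param experiments experiments data.frame.
#' @param net raw network.
#' @param media_defs named list of media conditions.
#' @param eps minimum biomass flux (default 0.001).
#' @param cfg a [blocking_config()].
#' @param coefficient biomass stoichiometric magnitude.
#' @param max_rounds convergence guard.
#' @return The proposal with \code{sink_additions} and an \code{audit} trail
#'   (\code{unfixable} lists experiments no sink set can rescue).
#' @export
augment_biomass <- function(proposal, experiments, net, media_defs,
                            eps = 0.001, cfg = blocking_config(),
                            coefficient = 2e-4, max_rounds = 10) {
  targets <- intersect(proposal$matched_g, experiments$experiment_id)
  audit <- list()
  unfixable <- character(0)
  for (round in seq_len(max_rounds)) {
    new_sinks <- character(0)
    for (e in targets) {
      row <- experiments[experiments$experiment_id == e, , drop = FALSE][1, ]
      genes <- strsplit(row$deleted_genes, ";", fixed = TRUE)[[1]]
      genes <- intersect(trimws(genes[nzchar(trimws(genes))]), net$genes)
      rep_e <- deadend_byproducts(
        net, c(proposal$components, proposal$sink_additions),
        genes = genes, media = media_defs[[row$media_id]], eps = eps,
        cfg = cfg, coefficient = coefficient, experiment_id = e)
      if (!rep_e$feasible) {
        unfixable <- union(unfixable, e)
      } else if (length(rep_e$active_sinks)) {
        new_sinks <- union(new_sinks, rep_e$active_sinks)
        audit[[length(audit) + 1L]] <-
          list(round = round, experiment = e, added = rep_e$active_sinks)
      }
    }
    if (length(new_sinks) == 0) {
      proposal$audit <- audit
      proposal$unfixable <- unfixable
      return(proposal)
    }
    proposal$sink_additions <- sort(union(proposal$sink_additions, new_sinks))
  }
  stop("dead-end augmentation did not converge after ", max_rounds,
       " rounds; residual experiments: ",
       paste(targets, collapse = ", "), call. = FALSE)
}

#' Serialize dead-end reports as TSV
#' @param reports list of \code{deadend_report}s.
#' @param path output path.
#' @export
write_deadend_reports <- function(reports, path) {
  if (inherits(reports, "deadend_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(r) {
    main <- if (length(r$active_sinks)) {
      data.frame(experiment_id = r$experiment_id,
                 metabolite_id = r$active_sinks, role = "byproduct",
                 alternate_set_index = 0L)
    } else NULL
    alts <- if (length(r$alternates)) {
      do.call(rbind, lapply(seq_along(r$alternates), function(k) {
        data.frame(experiment_id = r$experiment_id,
                   metabolite_id = r$alternates[[k]], role = "byproduct",
                   alternate_set_index = k)
      }))
    } else NULL
    rbind(main, alts)
  }))
  if (is.null(rows)) {
    rows <- data.frame(experiment_id = character(0),
                       metabolite_id = character(0), role = character(0),
                       alternate_set_index = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
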