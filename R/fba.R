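# Qualitative growth prediction by flux balance analysis.
#
# A proposal becomes a biomass pseudo-reaction with a uniform arbitrary
# coefficient (the selection is qualitative: no abundances are estimated), and
# each experiment is scored by maximizing its flux under the experiment's
# media and knockout.

#' Build a qualitative biomass pseudo-reaction
#'
#' @param components nonempty metabolite ids (proposal components plus any
#'   dead-end sink additions).
#' @param coefficient uniform stoichiometric magnitude consumed per component
#'   (default 0.0002; qualitative growth calls are invariant to its positive
#'   scale).
#' @param id reaction id.
#' @return A [reaction_record()]: irreversible, consuming each component,
#'   producing nothing, bounds [0, 1000].
#' @export
build_biomass_reaction <- function(components, coefficient = 2e-4,
                                   id = "BIOMASS_proposed") {
  if (length(components) == 0) {
    stop("usage error: cannot build a biomass reaction from zero components",
         call. = FALSE)
  }
  stopifnot(coefficient != 0)
  reaction_record(id, stats::setNames(rep(-abs(coefficient),
                                          length(components)),
                                      sort(unique(components))),
                  lower_bound = 0, upper_bound = 1000, gpr = "",
                  name = "proposed biomass drain")
}

#' FBA growth call for one experiment
#'
#' Removes every predefined biomass reaction, applies media and knockout,
#' installs the candidate biomass reaction and maximizes its flux by plain LP
#' (no parsimony step, no sinks). Growth is called when the optimum exceeds
#' \code{growth_flux_threshold}.
#'
#' @param net raw \code{metabolic_network}.
#' @param biomass_rxn a [build_biomass_reaction()] result (or any
#'   \code{reaction_record} to maximize).
#' @param genes deleted gene ids.
#' @param media a [media_condition()].
#' @param growth_flux_threshold minimum optimum counted as growth (default
#'   1e-6; must sit far below \code{coefficient * v_min}).
#' @return \code{"G"} or \code{"NG"}, with attributes \code{flux} (the LP
#'   optimum) and \code{infeasible} (diagnostic flag).
#' @export
predict_growth <- function(net, biomass_rxn, genes = character(0), media,
                           growth_flux_threshold = 1e-6) {
  if (length(net$biomass_ids)) {
    net$reactions[intersect(net$biomass_ids, names(net$reactions))] <- NULL
    net$biomass_ids <- character(0)
  }
  net <- apply_media(net, media)
  net <- suppressWarnings(apply_knockout(net, genes))
  net$reactions[[biomass_rxn$id]] <- biomass_rxn
  tri <- net_triplets(net)
  bnd <- net_bounds(net)
  p <- lp_new(length(tri$rxn_ids), "max")
  lp_set_bounds(p, lb = bnd$lb, ub = bnd$ub)
  nmet <- length(tri$met_ids)
  lp_add_rows(p, tri$i, tri$j, tri$x, rep("=", nmet), rep(0, nmet))
  for (cc in net$coupling) {
    jj <- match(names(cc$coef), tri$rxn_ids)
    lp_add_rows(p, rep(1L, length(jj)), jj, unname(cc$coef), cc$sense, cc$rhs)
  }
  obj <- numeric(p$n); obj[match(biomass_rxn$id, tri$rxn_ids)] <- 1
  lp_set_objective(p, obj)
  res <- tryCatch(lp_solve(p), error = function(e) list(status = "failed",
                                                        objective = NA_real_))
  if (res$status != "optimal") {
    return(structure("NG", flux = NA_real_, infeasible = TRUE))
  }
  structure(if (res$objective > growth_flux_threshold) "G" else "NG",
            flux = res$objective, infeasible = FALSE)
}

#' FBA growth calls for a whole experiment table
#'
#' @param net raw network.
#' @param biomass_rxn biomass reaction to score.
#' @param experiments experiments data.frame.
#' @param media_defs named list of media conditions.
#' @param growth_flux_threshold see [predict_growth()].
#' @return data.frame \code{experiment_id}, \code{predicted}, \code{flux}.
#' @export
predict_growth_all <- function(net, biomass_rxn, experiments, media_defs,
                               growth_flux_threshold = 1e-6) {
  cache <- list()
  preds <- character(nrow(experiments)); flux <- numeric(nrow(experiments))
  for (k in seq_len(nrow(experiments))) {
    genes <- strsplit(experiments$deleted_genes[k], ";", fixed = TRUE)[[1]]
    genes <- sort(intersect(trimws(genes[nzchar(trimws(genes))]), net$genes))
    sig <- paste(experiments$media_id[k], paste(genes, collapse = ","),
                 sep = "|")
    if (is.null(cache[[sig]])) {
      cache[[sig]] <- predict_growth(
        net, biomass_rxn, genes, media_defs[[experiments$media_id[k]]],
        growth_flux_threshold)
    }
    preds[k] <- cache[[sig]]
    flux[k] <- attr(cache[[sig]], "flux")
  }
  data.frame(experiment_id = experiments$experiment_id, predicted = preds,
             flux = flux, stringsAsFactors = FALSE)
}

#' Tabulate growth-prediction agreement
#'
#' Counts correct qualitative calls per media condition and phenotype class
#' and overall. When a second prediction column is supplied the report also
#' lists the experiments mispredicted by exactly one of the two biomass
#' variants.
#'
#' @param predictions data.frame with \code{experiment_id}, \code{predicted}
#'   and optionally \code{predicted_alt}.
#' @param experiments experiments data.frame with \code{observed}.
#' @return An \code{agreement_report}: \code{by_class} table,
#'   \code{overall} percent, per-experiment records, and (comparison mode)
#'   \code{only_first_wrong} / \code{only_second_wrong}.
#' @export
agreement_report <- function(predictions, experiments) {
  m <- merge(experiments, predictions, by = "experiment_id")
  if (nrow(m) < nrow(experiments)) {
    stop("data error: missing prediction for some experiment(s)",
         call. = FALSE)
  }
  m$correct <- m$predicted == m$observed
  m$concordance <- ifelse(m$observed == "NG" & m$predicted == "NG", "TN",
                     ifelse(m$observed == "NG" & m$predicted == "G", "FP",
                       ifelse(m$observed == "G" & m$predicted == "G", "TP",
                              "FN")))
  agg <- stats::aggregate(correct ~ media_id + observed, data = m,
                          FUN = function(z) c(n = length(z), ok = sum(z)))
  by_class <- data.frame(media_id = agg$media_id, observed = agg$observed,
                         n_experiments = agg$correct[, "n"],
                         n_correct = agg$correct[, "ok"])
  by_class$percent <- 100 * by_class$n_correct / by_class$n_experiments
  rep <- list(by_class = by_class,
              overall = 100 * mean(m$correct),
              n = nrow(m),
              records = m[, c("experiment_id", "media_id", "observed",
                              "predicted", "concordance")])
  if (!is.null(predictions$predicted_alt)) {
    m$correct_alt <- m$predicted_alt == m$observed
    rep$overall_alt <- 100 * mean(m$correct_alt)
    rep$only_first_wrong <- m$experiment_id[!m$correct & m$correct_alt]
    rep$only_second_wrong <- m$experiment_id[m$correct & !m$correct_alt]
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Growth-prediction agreement: ", sprintf("%.1f%%", x$overall),
      " overall (", x$n, " experiments)\n", sep = "")
  print(x$by_class, row.names = FALSE)
  if (!is.null(x$overall_alt)) {
    cat("Comparison variant: ", sprintf("%.1f%%", x$overall_alt),
        "; mispredicted only by first: ", length(x$only_first_wrong),
        ", only by second: ", length(x$only_second_wrong), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize an agreement report
#' @param report an \code{agreement_report}.
#' @param path_tsv per-experiment records TSV path.
#' @param path_json summary JSON path (optional).
#' @export
write_agreement_report <- function(report, path_tsv, path_json = NULL) {
  utils::write.table(report$records, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(overall = report$overall,
                              by_class = report$by_class),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_tsv)
}
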