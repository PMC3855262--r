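# Top-level modelling interface: fit a biomass composition to knockout
# phenotype data and evaluate it by FBA.

#' Fit a biomass composition to growth-phenotype data
#'
#' Runs the full inference pipeline: mutant-specific blocked-metabolite
#' detection, include/exclude list construction, the maximal-agreement IP,
#' de novo selection (or modification of the network's predefined biomass),
#' optional dead-end by-product repair, and FBA re-evaluation of every
#' experiment.
#'
#' @param net a \code{metabolic_network}.
#' @param experiments experiments data.frame ([read_phenotypes()],
#'   [experiment_table()]).
#' @param media_defs named list of [media_condition()]s.
#' @param mode \code{"de_novo"} or \code{"modify"} (requires a predefined
#'   component set in \code{net$mu} or \code{mu}).
#' @param mu predefined components for \code{"modify"}; default \code{net$mu}.
#' @param em analytically measured biomass components (soft evidence).
#' @param scheme a [weight_scheme()].
#' @param cfg a [blocking_config()].
#' @param filter_max blocked-set size filter for uninformative mutants.
#' @param deadend_repair run [augment_biomass()] after selection.
#' @param coefficient biomass stoichiometric magnitude.
#' @param growth_flux_threshold FBA growth call threshold.
#' @param em_weight weight of each measurement pseudo-experiment.
#' @return A \code{biomass_fit} with methods \code{print}, \code{summary},
#'   \code{coef} (component ids), \code{predict} (growth calls for new
#'   experiments) and \code{plot} (evidence frequencies).
#' @export
#' @examples
#' \donttest{
#' fx <- demo_fixture()
#' fit <- fit_biomass(fx$net, fx$experiments,
#'                    media_defs = list(demo_media = fx$media))
#' coef(fit)
#' }
fit_biomass <- function(net, experiments, media_defs,
                        mode = c("de_novo", "modify"), mu = NULL,
                        em = character(0), scheme = weight_scheme(),
                        cfg = blocking_config(), filter_max = 100,
                        deadend_repair = TRUE, coefficient = 2e-4,
                        growth_flux_threshold = 1e-6, em_weight = 1) {
  mode <- match.arg(mode)
  cl <- match.call()
  lists <- build_lists(experiments, net, media_defs, cfg, filter_max)
  proposal <- if (mode == "de_novo") {
    ma <- max_agreement(lists, em, em_weight)
    select_de_novo(lists, em, fix_obj = ma$fix_obj, scheme = scheme,
                   em_weight = em_weight)
  } else {
    mu <- mu %||% net$mu
    if (length(mu) == 0) {
      stop("usage error: mode 'modify' needs a predefined component set",
           call. = FALSE)
    }
    modify_biomass(lists, mu, em, scheme, em_weight)
  }
  if (deadend_repair && length(proposal$components)) {
    proposal <- augment_biomass(proposal, experiments, net, media_defs,
                                cfg = cfg, coefficient = coefficient)
  }
  biomass_rxn <- if (length(c(proposal$components,
                              proposal$sink_additions))) {
    build_biomass_reaction(c(proposal$components, proposal$sink_additions),
                           coefficient)
  } else NULL
  predictions <- if (!is.null(biomass_rxn)) {
    predict_growth_all(net, biomass_rxn, experiments, media_defs,
                       growth_flux_threshold)
  } else {
    data.frame(experiment_id = experiments$experiment_id, predicted = "NG",
               flux = 0, stringsAsFactors = FALSE)
  }
  report <- agreement_report(predictions, experiments)
  structure(list(call = cl, mode = mode, network = net,
                 experiments = experiments, media_defs = media_defs,
                 lists = lists, proposal = proposal,
                 biomass_reaction = biomass_rxn,
                 predictions = predictions, report = report,
                 cfg = cfg, coefficient = coefficient,
                 growth_flux_threshold = growth_flux_threshold),
            class = "biomass_fit")
}

#' @export
print.biomass_fit <- function(x, ...) {
  cat("Biomass composition fit (", x$mode, ")\n", sep = "")
  print(x$proposal)
  cat(sprintf("FBA agreement: %.1f%% over %d experiments\n",
              x$report$overall, x$report$n))
  invisible(x)
}

#' @export
summary.biomass_fit <- function(object, ...) {
  out <- list(mode = object$mode,
              components = object$proposal$components,
              sink_additions = object$proposal$sink_additions,
              agreement_ip = object$proposal$agreement,
              report = object$report,
              frequency = frequency_table(object$lists),
              filtered_out = object$lists$filtered_out)
  class(out) <- "summary.biomass_fit"
  out
}

#' @export
print.summary.biomass_fit <- function(x, ...) {
  cat("Biomass fit (", x$mode, "): ", length(x$components), " components",
      if (length(x$sink_additions)) {
        paste0(" + ", length(x$sink_additions), " dead-end sinks")
      } else "", "\n", sep = "")
  cat("IP agreement score:", format(x$agreement_ip), "\n")
  print(x$report)
  cat("\nTop evidence frequencies:\n")
  print(utils::head(x$frequency, 10), row.names = FALSE)
  if (length(x$filtered_out)) {
    cat("Filtered out as uninformative:",
        paste(x$filtered_out, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.biomass_fit <- function(object, ...) {
  comps <- object$proposal$components
  roles <- rep("component", length(comps))
  if (object$mode == "modify") {
    roles[comps %in% object$proposal$added] <- "added"
    roles[comps %in% object$proposal$unmodified] <- "unmodified"
  }
  c(stats::setNames(roles, comps),
    stats::setNames(rep("sink_role", length(object$proposal$sink_additions)),
                    object$proposal$sink_additions))
}

#' Predict growth calls for (new) experiments
#'
#' @param object a \code{biomass_fit}.
#' @param newdata experiments data.frame; defaults to the fitted experiments.
#' @param ... unused.
#' @return data.frame \code{experiment_id}, \code{predicted}, \code{flux}.
#' @export
predict.biomass_fit <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$experiments
  if (is.null(object$biomass_reaction)) {
    return(data.frame(experiment_id = newdata$experiment_id,
                      predicted = "NG", flux = 0, stringsAsFactors = FALSE))
  }
  predict_growth_all(object$network, object$biomass_reaction, newdata,
                     object$media_defs, object$growth_flux_threshold)
}

#' @export
plot.biomass_fit <- function(x, top = 15, ...) {
  ft <- utils::head(frequency_table(x$lists), top)
  if (nrow(ft) == 0) {
    warning("no evidence to plot")
    return(invisible(x))
  }
  bar <- rbind(include = ft$include_count, exclude = -ft$exclude_count)
  graphics::barplot(bar, names.arg = ft$metabolite_id, beside = TRUE,
                    legend.text = c("include (NG)", "exclude (G)"),
                    las = 2, ylab = "list appearances",
                    main = "Evidence frequency by metabolite", ...)
  invisible(x)
}
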