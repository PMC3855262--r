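# Metabolic network container and the model-preparation operations: media
# application, gene knockouts and sink augmentation for producibility analysis.

#' Construct a reaction record
#'
#' @param id unique reaction identifier.
#' @param stoich named numeric vector of signed stoichiometric coefficients
#'   (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound flux bounds (consistent arbitrary units).
#' @param gpr gene-protein-reaction rule string (\code{""} = not
#'   gene-associated).
#' @param name human-readable name.
#' @return A \code{reaction_record} list.
#' @export
reaction_record <- function(id, stoich, lower_bound = -1000,
                            upper_bound = 1000, gpr = "", name = id) {
  stopifnot(nzchar(id), length(stoich) > 0, !is.null(names(stoich)))
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound exceeds upper_bound", call. = FALSE)
  }
  structure(list(id = id, name = name, stoich = stoich,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 gpr = gpr, gpr_tree = parse_gpr(gpr)),
            class = "reaction_record")
}

#' Construct a metabolic network
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (or a character vector of ids).
#' @param reactions list of [reaction_record()] objects.
#' @param genes character vector of gene ids; derived from the GPR rules when
#'   omitted.
#' @param coupling list of network-specific linear constraints, each
#'   \code{list(coef = <named numeric over reaction ids>, sense, rhs)}.
#' @param biomass_ids reaction ids of biomass pseudo-reactions (possibly
#'   several variants); all are removed before producibility analysis.
#' @param mu predefined biomass component set; defaults to the metabolites
#'   consumed by the first biomass reaction.
#' @param id model identifier.
#' @return A validated \code{metabolic_network} object.
#' @export
metabolic_network <- function(metabolites, reactions, genes = NULL,
                              coupling = list(), biomass_ids = character(0),
                              mu = NULL, id = "model") {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, name = metabolites,
                              compartment = "c", stringsAsFactors = FALSE)
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions, function(r)
      gpr_genes(r$gpr_tree)))))
  }
  net <- structure(list(id = id,
                        metabolites = metabolites,
                        reactions = reactions,
                        genes = genes,
                        coupling = coupling,
                        biomass_ids = biomass_ids,
                        mu = mu,
                        sink_ids = character(0)),
                   class = "metabolic_network")
  if (is.null(mu)) {
    net$mu <- if (length(biomass_ids)) {
      s <- reactions[[biomass_ids[1]]]$stoich
      sort(names(s)[s < 0])
    } else character(0)
  }
  validate_network(net)
  net
}

#' Validate structural invariants of a metabolic network
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a declared
#' metabolite, bound ordering, and that biomass/coupling references exist.
#'
#' @param net a \code{metabolic_network}.
#' @return The network, invisibly; stops with an integrity error otherwise.
#' @export
validate_network <- function(net) {
  mids <- net$metabolites$id
  if (anyDuplicated(mids)) {
    stop("integrity error: duplicate metabolite ids: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "), call. = FALSE)
  }
  rids <- vapply(net$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("integrity error: duplicate reaction ids", call. = FALSE)
  }
  for (r in net$reactions) {
    unknown <- setdiff(names(r$stoich), mids)
    if (length(unknown)) {
      stop("integrity error: reaction '", r$id,
           "' references undeclared metabolite '", unknown[1], "'",
           call. = FALSE)
    }
    if (r$lower_bound > r$upper_bound) {
      stop("integrity error: reaction '", r$id, "' has lower_bound > ",
           "upper_bound", call. = FALSE)
    }
  }
  if (length(setdiff(net$biomass_ids, rids))) {
    stop("integrity error: biomass_ids reference unknown reactions",
         call. = FALSE)
  }
  for (cc in net$coupling) {
    if (length(setdiff(names(cc$coef), rids))) {
      stop("integrity error: coupling constraint references unknown reaction",
           call. = FALSE)
    }
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network '", x$id, "': ", nrow(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions, ",
      length(x$genes), " genes\n", sep = "")
  ex <- exchange_ids(x)
  cat("  exchanges: ", length(ex), "; biomass reactions: ",
      length(x$biomass_ids), "; predefined components: ", length(x$mu),
      "\n", sep = "")
  invisible(x)
}

#' Identify exchange reactions
#'
#' An exchange reaction carries exactly one metabolite in its stoichiometry
#' (crossing the system boundary). By convention uptake is the flux direction
#' that produces the metabolite: negative flux for the usual
#' \code{met <-> (nothing)} orientation with coefficient -1. Sink reactions
#' added by [prepare_for_blocking()] are excluded.
#'
#' @param net a \code{metabolic_network}.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_ids <- function(net) {
  single <- vapply(net$reactions, function(r) length(r$stoich) == 1L,
                   logical(1))
  setdiff(names(net$reactions)[single],
          c(net$sink_ids, net$biomass_ids))
}

#' Define a media condition
#'
#' @param id media identifier.
#' @param allowed_uptakes named numeric vector: exchange reaction id ->
#'   maximum uptake magnitude (>= 0).
#' @param label free-text description.
#' @return A \code{media_condition} object.
#' @export
media_condition <- function(id, allowed_uptakes = numeric(0), label = id) {
  stopifnot(all(allowed_uptakes >= 0))
  structure(list(id = id, allowed_uptakes = allowed_uptakes, label = label),
            class = "media_condition")
}

#' Union several media conditions into a robust condition
#'
#' The robust media opens every exchange any input condition opens, each at
#' the maximum uptake magnitude seen across conditions. It is the default
#' environment for essential-precursor analysis, which should not depend on
#' which single tested condition is picked.
#'
#' @param media_defs list of [media_condition()]s.
#' @param id identifier of the combined condition.
#' @return A \code{media_condition}.
#' @export
robust_media <- function(media_defs, id = "robust") {
  if (inherits(media_defs, "media_condition")) media_defs <- list(media_defs)
  stopifnot(length(media_defs) > 0)
  all_ex <- sort(unique(unlist(lapply(media_defs, function(m)
    names(m$allowed_uptakes)))))
  up <- vapply(all_ex, function(e) {
    max(vapply(media_defs, function(m) {
      if (e %in% names(m$allowed_uptakes)) m$allowed_uptakes[[e]] else 0
    }, numeric(1)))
  }, numeric(1))
  media_condition(id, up, label = "union of tested conditions")
}

#' Apply a media condition to a network
#'
#' Closes the uptake direction of every exchange reaction, then opens the
#' listed uptakes at their stated magnitudes. Secretion bounds are untouched.
#'
#' @param net a \code{metabolic_network}.
#' @param media a [media_condition()].
#' @return A modified copy of \code{net}.
#' @export
apply_media <- function(net, media) {
  ex <- exchange_ids(net)
  unknown <- setdiff(names(media$allowed_uptakes), ex)
  if (length(unknown)) {
    stop("configuration error: media '", media$id,
         "' references unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (rid in ex) {
    r <- net$reactions[[rid]]
    coefsign <- sign(r$stoich[[1]])
    up <- media$allowed_uptakes[rid]
    mag <- if (rid %in% names(media$allowed_uptakes)) unname(up) else 0
    if (coefsign < 0) {          # uptake = negative flux
      net$reactions[[rid]]$lower_bound <- -mag
    } else {                     # uptake = positive flux
      net$reactions[[rid]]$upper_bound <- mag
    }
  }
  attr(net, "media_id") <- media$id
  net
}

#' Apply a gene knockout to a network
#'
#' Disables (bounds set to zero) every reaction whose GPR rule evaluates FALSE
#' in the absence of the deleted genes. Reactions without a GPR rule are never
#' disabled. Genes absent from the network are tolerated with a warning:
#' genome-wide phenotype datasets routinely contain genes outside the model.
#'
#' @param net a \code{metabolic_network}.
#' @param deleted_genes character vector of deleted gene ids.
#' @return A modified copy of \code{net}.
#' @export
apply_knockout <- function(net, deleted_genes) {
  deleted_genes <- unique(deleted_genes[nzchar(deleted_genes)])
  unknown <- setdiff(deleted_genes, net$genes)
  if (length(unknown)) {
    warning("gene(s) not in network, ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    deleted_genes <- intersect(deleted_genes, net$genes)
  }
  if (length(deleted_genes) == 0) return(net)
  for (rid in names(net$reactions)) {
    tree <- net$reactions[[rid]]$gpr_tree
    if (!is.null(tree) && !eval_gpr(tree, deleted_genes)) {
      net$reactions[[rid]]$lower_bound <- 0
      net$reactions[[rid]]$upper_bound <- 0
    }
  }
  net
}

#' Prepare a network for producibility analysis
#'
#' Removes every biomass pseudo-reaction (all variants: a predefined biomass
#' would otherwise act as a free drain) and adds, for each metabolite, an
#' irreversible unit sink reaction \code{SK_<metabolite>} with bounds
#' \code{[0, u_sink]}. Idempotent: sinks already present are not duplicated.
#'
#' @param net a \code{metabolic_network}.
#' @param u_sink sink capacity; large relative to the production threshold.
#' @return A modified copy with \code{net$sink_ids} populated.
#' @export
prepare_for_blocking <- function(net, u_sink = 1000) {
  if (length(net$biomass_ids)) {
    net$reactions[intersect(net$biomass_ids, names(net$reactions))] <- NULL
    net$removed_biomass_ids <- union(net$removed_biomass_ids, net$biomass_ids)
    net$biomass_ids <- character(0)
  }
  for (mid in net$metabolites$id) {
    sid <- paste0("SK_", mid)
    if (!is.null(net$reactions[[sid]])) next
    s <- stats::setNames(-1, mid)
    net$reactions[[sid]] <- reaction_record(sid, s, 0, u_sink, gpr = "",
                                            name = paste("sink for", mid))
    net$sink_ids <- c(net$sink_ids, sid)
  }
  net
}

#' Sparse stoichiometric triplets for a network
#' @return list(i, j, x, met_ids, rxn_ids) with 1-based indices.
#' @keywords internal
net_triplets <- function(net) {
  met_ids <- net$metabolites$id
  rxn_ids <- names(net$reactions)
  midx <- stats::setNames(seq_along(met_ids), met_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    s <- net$reactions[[j]]$stoich
    ii <- c(ii, unname(midx[names(s)]))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  list(i = ii, j = jj, x = xx, met_ids = met_ids, rxn_ids = rxn_ids)
}

#' Reaction bound vectors in reaction order
#' @keywords internal
net_bounds <- function(net) {
  list(lb = vapply(net$reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(net$reactions, `[[`, numeric(1), "upper_bound"))
}
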