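# Model, phenotype-table and media I/O.
#
# Networks are read from COBRA-style JSON or SBML Level 3 (fbc package:
# flux bounds as parameter references, GPRs as geneProductAssociation trees)
# and written as COBRA-style JSON. Phenotype tables and media definitions are
# plain TSV/JSON.

#' Read a metabolic network from file
#'
#' @param path file path.
#' @param dialect \code{"cobra-json"} or \code{"sbml"}; guessed from the file
#'   extension when omitted.
#' @param biomass_ids reaction ids to tag as biomass; when omitted, reactions
#'   whose id contains "biomass" (case-insensitive) are tagged.
#' @return A \code{metabolic_network}.
#' @export
read_model <- function(path, dialect = NULL, biomass_ids = NULL) {
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
      else "cobra-json"
  }
  dialect <- match.arg(dialect, c("cobra-json", "sbml"))
  net <- if (dialect == "cobra-json") read_model_json(path)
    else read_model_sbml(path)
  if (is.null(biomass_ids)) {
    biomass_ids <- grep("biomass", names(net$reactions), ignore.case = TRUE,
                        value = TRUE)
  }
  net$biomass_ids <- biomass_ids
  if (length(biomass_ids)) {
    s <- net$reactions[[biomass_ids[1]]]$stoich
    net$mu <- sort(names(s)[s < 0])
  }
  validate_network(net)
  net
}

#' @keywords internal
read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("format error: cannot parse COBRA JSON '", path,
                         "': ", conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("format error: '", path, "' lacks metabolites/reactions sections",
         call. = FALSE)
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(doc$metabolites, function(m)
      as.character(m$name %||% m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m)
      as.character(m$compartment %||% "c"), character(1)),
    stringsAsFactors = FALSE)
  rxns <- lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s) || length(s) == 0) {
      stop("format error: reaction '", r$id, "' has empty stoichiometry",
           call. = FALSE)
    }
    reaction_record(as.character(r$id), s,
                    lower_bound = as.numeric(r$lower_bound %||% -1000),
                    upper_bound = as.numeric(r$upper_bound %||% 1000),
                    gpr = as.character(r$gene_reaction_rule %||% ""),
                    name = as.character(r$name %||% r$id))
  })
  genes <- if (!is.null(doc$genes)) {
    vapply(doc$genes, function(g) as.character(g$id), character(1))
  } else NULL
  metabolic_network(mets, rxns, genes = genes,
                    id = as.character(doc$id %||% "model"))
}

#' Write a metabolic network as COBRA-style JSON
#'
#' @param net a \code{metabolic_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(net, path) {
  doc <- list(
    id = net$id,
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(k) {
      list(id = net$metabolites$id[k], name = net$metabolites$name[k],
           compartment = net$metabolites$compartment[k])
    }),
    reactions = lapply(net$reactions, function(r) {
      list(id = r$id, name = r$name,
           metabolites = as.list(r$stoich),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = r$gpr)
    }),
    genes = lapply(net$genes, function(g) list(id = g, name = g)))
  names(doc$reactions) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# SBML L3 + fbc reader -------------------------------------------------------

#' @keywords internal
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("format error: cannot parse SBML '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) {
    stop("format error: no <model> element in '", path, "'", call. = FALSE)
  }
  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)
  rnodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference",
                               ns)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sgn) {
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sgn * st, xml2::xml_attr(nodes, "species"))
    }
    s <- c(coef(reac, -1), coef(prod, +1))
    s <- tapply(s, names(s), sum)  # merge duplicated species refs
    s <- stats::setNames(as.numeric(s), names(s))
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- if (!is.na(lbref)) unname(pval[lbref]) else if (rev) -1000 else 0
    ub <- if (!is.na(ubref)) unname(pval[ubref]) else 1000
    gnode <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gnode, "xml_missing")) "" else sbml_gpr(
      xml2::xml_find_first(gnode, "./*"), ns)
    reaction_record(rid, s, lower_bound = lb, upper_bound = ub, gpr = gpr,
                    name = xml2::xml_attr(rn, "name") %||% rid)
  })
  gp <- xml2::xml_find_all(model,
                           ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "fbc:id")
  if (all(is.na(genes))) genes <- xml2::xml_attr(gp, "id")
  genes <- genes[!is.na(genes)]
  metabolic_network(mets, rxns, genes = if (length(genes)) genes else NULL,
                    id = xml2::xml_attr(model, "id") %||% "model")
}

# Render an fbc association node as a GPR string.
#' @keywords internal
sbml_gpr <- function(node, ns) {
  if (is.null(node) || inherits(node, "xml_missing")) return("")
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(g)
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, sbml_gpr, character(1), ns = ns)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

# Phenotype and media tables --------------------------------------------------

#' Read a growth-phenotype table
#'
#' Expects TSV columns \code{experiment_id}, \code{deleted_genes}
#' (semicolon-separated), \code{media_id} and either \code{phenotype}
#' (\code{G}/\code{NG}) or \code{fitness} (real); an optional \code{weight}
#' column defaults to 1. Fitness scores are classified with
#' [classify_phenotype()].
#'
#' @param path TSV path.
#' @param fitness_threshold growth/no-growth fitness cut-off.
#' @return A data.frame of experiments (one row each) with columns
#'   \code{experiment_id}, \code{deleted_genes}, \code{media_id},
#'   \code{observed}, \code{fitness}, \code{weight}.
#' @export
read_phenotypes <- function(path, fitness_threshold = -1) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "deleted_genes", "media_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("format error: phenotype table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$fitness)) tab$fitness <- NA_real_
  if (is.null(tab$phenotype)) tab$phenotype <- tab$observed %||% NA_character_
  if (is.null(tab$weight)) tab$weight <- 1
  obs <- character(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    obs[k] <- classify_phenotype(tab$phenotype[k], tab$fitness[k],
                                 fitness_threshold)
  }
  data.frame(experiment_id = as.character(tab$experiment_id),
             deleted_genes = as.character(tab$deleted_genes),
             media_id = as.character(tab$media_id),
             observed = obs,
             fitness = as.numeric(tab$fitness),
             weight = as.numeric(tab$weight),
             stringsAsFactors = FALSE)
}

#' Write a phenotype table as TSV
#' @param experiments experiments data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(experiments, path) {
  out <- experiments
  if (!is.null(out$observed) && is.null(out$phenotype)) {
    names(out)[names(out) == "observed"] <- "phenotype"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read media definitions
#'
#' JSON: an object \code{{media_id: {exchange_id: max_uptake, ...}, ...}}.
#' TSV: columns \code{media_id}, \code{exchange_id}, \code{max_uptake}.
#'
#' @param path file path (.json or .tsv).
#' @return Named list of [media_condition()] objects.
#' @export
read_media <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- lapply(names(doc), function(mid) {
      media_condition(mid, unlist(doc[[mid]]))
    })
    names(out) <- names(doc)
    return(out)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$media_id), function(d) {
    media_condition(d$media_id[1],
                    stats::setNames(as.numeric(d$max_uptake), d$exchange_id))
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
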