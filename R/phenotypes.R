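# Include/exclude metabolite lists from knockout phenotypes.
#
# Each experiment contributes its mutant-specific candidate blocked set either
# as an include list (no-growth: positive evidence for essentiality of some
# member) or an exclude list (growth: negative evidence for every member).

#' Classify a growth phenotype
#'
#' An explicit phenotype call overrides a fitness score. Fitness strictly
#' below the threshold means no growth, strictly above means growth; a score
#' exactly at the threshold is classified as growth and flagged with a
#' message, since only strict comparisons are defined.
#'
#' @param phenotype explicit call (\code{"G"}/\code{"NG"}) or \code{NA}.
#' @param fitness real fitness score or \code{NA}.
#' @param fitness_threshold cut-off (default -1).
#' @return \code{"G"} or \code{"NG"}.
#' @export
classify_phenotype <- function(phenotype = NA, fitness = NA,
                               fitness_threshold = -1) {
  if (!is.na(phenotype) && nzchar(phenotype)) {
    if (!phenotype %in% c("G", "NG")) {
      stop("data error: phenotype must be 'G' or 'NG', got '", phenotype, "'",
           call. = FALSE)
    }
    return(phenotype)
  }
  if (is.na(fitness)) {
    stop("data error: experiment has neither phenotype nor fitness",
         call. = FALSE)
  }
  if (fitness == fitness_threshold) {
    message("fitness exactly at threshold (", fitness_threshold,
            "); classified as growth")
    return("G")
  }
  if (fitness < fitness_threshold) "NG" else "G"
}

#' Assemble an experiments table
#'
#' Convenience constructor for in-memory experiment sets.
#'
#' @param experiment_id,deleted_genes,media_id,observed vectors (recycled);
#'   \code{deleted_genes} uses semicolons to separate multiple genes.
#' @param fitness,weight optional vectors.
#' @return Experiments data.frame as produced by [read_phenotypes()].
#' @export
experiment_table <- function(experiment_id, deleted_genes, media_id,
                             observed, fitness = NA_real_, weight = 1) {
  data.frame(experiment_id = as.character(experiment_id),
             deleted_genes = as.character(deleted_genes),
             media_id = as.character(media_id),
             observed = as.character(observed),
             fitness = as.numeric(fitness),
             weight = as.numeric(weight),
             stringsAsFactors = FALSE)
}

# Merge replicate rows (same knockout, media and call) by summing weights.
#' @keywords internal
merge_replicates <- function(experiments) {
  key <- paste(experiments$deleted_genes, experiments$media_id,
               experiments$observed, sep = "\r")
  if (!anyDuplicated(key)) return(experiments)
  keep <- !duplicated(key)
  merged <- experiments[keep, , drop = FALSE]
  merged$weight <- as.numeric(tapply(experiments$weight, key, sum)[key[keep]])
  merged
}

#' Build include/exclude metabolite lists for an experiment set
#'
#' For each experiment the knockout network is solved for producibility, the
#' wild-type blocked set (computed once per media and cached) is subtracted,
#' and the remaining candidates are stored under \code{include} (no-growth) or
#' \code{exclude} (growth). Mutants with more than \code{filter_max}
#' candidates are set aside as uninformative. No-growth experiments with an
#' empty candidate set are retained (they are unfixable mispredictions that
#' cap the achievable agreement).
#'
#' @param experiments experiments data.frame ([read_phenotypes()],
#'   [experiment_table()]).
#' @param net the raw \code{metabolic_network} (biomass still present).
#' @param media_defs named list of [media_condition()]s covering every
#'   \code{media_id} used.
#' @param cfg a [blocking_config()].
#' @param filter_max candidate-set size above which an experiment is dropped.
#' @param method \code{"milp"} (single producibility MILP per strain) or
#'   \code{"oracle"} (per-metabolite LPs).
#' @return An \code{include_exclude_lists} object: named lists \code{include}
#'   and \code{exclude} (experiment id -> metabolite ids), \code{filtered_out},
#'   \code{universe}, per-experiment \code{weights} and phenotype sets
#'   \code{ng}/\code{g}, plus the cached wild-type results.
#' @export
build_lists <- function(experiments, net, media_defs, cfg = blocking_config(),
                        filter_max = 100, method = c("milp", "oracle")) {
  method <- match.arg(method)
  solver <- if (method == "milp") producible_set_milp else producible_oracle
  experiments <- merge_replicates(experiments)
  miss <- setdiff(unique(experiments$media_id), names(media_defs))
  if (length(miss)) {
    stop("configuration error: no media definition for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  prepped <- prepare_for_blocking(net, u_sink = cfg$big_m)
  wt_cache <- list()
  run_cache <- list()
  include <- list(); exclude <- list()
  filtered_out <- character(0)
  unknown_genes <- character(0)
  ord <- order(experiments$experiment_id)   # order-independent output
  experiments <- experiments[ord, , drop = FALSE]
  for (k in seq_len(nrow(experiments))) {
    e <- experiments$experiment_id[k]
    mid <- experiments$media_id[k]
    if (is.null(wt_cache[[mid]])) {
      wt_net <- apply_media(prepped, media_defs[[mid]])
      wt_cache[[mid]] <- list(net = wt_net,
                              res = solver(wt_net, cfg, strain = "wt"))
    }
    genes <- strsplit(experiments$deleted_genes[k], ";", fixed = TRUE)[[1]]
    genes <- trimws(genes[nzchar(trimws(genes))])
    unknown_genes <- union(unknown_genes, setdiff(genes, net$genes))
    genes <- intersect(genes, net$genes)
    wt_net <- wt_cache[[mid]]$net
    # knockouts that disable the same reactions give identical partitions
    disabled <- names(wt_net$reactions)[vapply(wt_net$reactions, function(r) {
      !is.null(r$gpr_tree) && !eval_gpr(r$gpr_tree, genes)
    }, logical(1))]
    sig <- paste(mid, paste(disabled, collapse = ","), sep = "|")
    if (is.null(run_cache[[sig]])) {
      mut_net <- wt_net
      for (rid in disabled) {
        mut_net$reactions[[rid]]$lower_bound <- 0
        mut_net$reactions[[rid]]$upper_bound <- 0
      }
      mut <- if (length(disabled) == 0) wt_cache[[mid]]$res
        else solver(mut_net, cfg, strain = e)
      run_cache[[sig]] <- list(cand = candidate_blocked(wt_cache[[mid]]$res,
                                                        mut))
    }
    cand <- run_cache[[sig]]$cand
    if (length(cand) > filter_max) {
      filtered_out <- c(filtered_out, e)
    } else if (experiments$observed[k] == "NG") {
      include[[e]] <- cand
    } else {
      exclude[[e]] <- cand
    }
  }
  if (length(unknown_genes)) {
    warning("gene(s) not in network, ignored: ",
            paste(sort(unknown_genes), collapse = ", "), call. = FALSE)
  }
  retained <- setdiff(experiments$experiment_id, filtered_out)
  structure(list(
    include = include,
    exclude = exclude,
    filtered_out = filtered_out,
    universe = sort(unique(unlist(c(include, exclude)))),
    ng = intersect(retained,
                   experiments$experiment_id[experiments$observed == "NG"]),
    g = intersect(retained,
                  experiments$experiment_id[experiments$observed == "G"]),
    weights = stats::setNames(experiments$weight,
                              experiments$experiment_id),
    wild_type = lapply(wt_cache, `[[`, "res"),
    media_ids = stats::setNames(experiments$media_id,
                                experiments$experiment_id)),
    class = "include_exclude_lists")
}

#' @export
print.include_exclude_lists <- function(x, ...) {
  cat("Include/exclude lists: ", length(x$include), " include (NG), ",
      length(x$exclude), " exclude (G), ", length(x$filtered_out),
      " filtered out; universe of ", length(x$universe),
      " candidate metabolites\n", sep = "")
  invisible(x)
}

#' Evidence-frequency table
#'
#' Counts, per metabolite, appearances across include and exclude lists and
#' their difference. A positive difference indicates a potential agreement
#' gain from including the metabolite in the biomass; zero counts mean no
#' direct supporting or refuting evidence; equal nonzero counts are flagged
#' inconclusive.
#'
#' @param lists an \code{include_exclude_lists}.
#' @param focus optional metabolite subset to restrict/extend the table to
#'   (metabolites absent from all lists are reported with zero counts).
#' @return data.frame \code{metabolite_id}, \code{include_count},
#'   \code{exclude_count}, \code{difference}, \code{evidence}; sorted by
#'   difference (descending), ties by id.
#' @export
frequency_table <- function(lists, focus = NULL) {
  ids <- if (is.null(focus)) lists$universe else sort(unique(focus))
  inc <- table(factor(unlist(lists$include), levels = ids))
  exc <- table(factor(unlist(lists$exclude), levels = ids))
  out <- data.frame(metabolite_id = ids,
                    include_count = as.integer(inc),
                    exclude_count = as.integer(exc),
                    stringsAsFactors = FALSE)
  out$difference <- out$include_count - out$exclude_count
  out$evidence <- ifelse(out$include_count + out$exclude_count == 0,
                         "none",
                         ifelse(out$difference == 0, "inconclusive",
                                ifelse(out$difference > 0, "supporting",
                                       "refuting")))
  out <- out[order(-out$difference, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize include/exclude lists as TSV
#' @param lists an \code{include_exclude_lists}.
#' @param path output path.
#' @export
write_lists <- function(lists, path) {
  rows <- rbind(
    do.call(rbind, lapply(names(lists$include), function(e) {
      if (length(lists$include[[e]]) == 0) {
        return(data.frame(experiment_id = e, phenotype = "NG",
                          metabolite_id = NA_character_))
      }
      data.frame(experiment_id = e, phenotype = "NG",
                 metabolite_id = lists$include[[e]])
    })),
    do.call(rbind, lapply(names(lists$exclude), function(e) {
      if (length(lists$exclude[[e]]) == 0) {
        return(data.frame(experiment_id = e, phenotype = "G",
                          metabolite_id = NA_character_))
      }
      data.frame(experiment_id = e, phenotype = "G",
                 metabolite_id = lists$exclude[[e]])
    })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
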