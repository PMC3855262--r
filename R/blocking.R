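# Net-production-blocked metabolite detection.
#
# On a sink-augmented network (biomass removed, one irreversible unit sink per
# metabolite) a metabolite is producible if some steady-state flux vector
# pushes at least v_min through its sink. Because mass must actually leave
# through the sink, metabolites trapped in internal cycles are classified
# blocked even though nonzero cycle flux through them is feasible.

#' Configuration for producibility analysis
#'
#' @param v_min minimum net production regarded as "producible" (default
#'   0.0005 flux units).
#' @param big_m linking constant tying the sink flux to its binary indicator;
#'   also the sink capacity.
#' @param tol solver tolerance used when comparing fluxes to \code{v_min};
#'   kept at least 50x smaller than \code{v_min}.
#' @param time_limit per-solve wall limit in seconds.
#' @return A \code{blocking_config} list.
#' @export
blocking_config <- function(v_min = 5e-4, big_m = 1000, tol = 1e-7,
                            time_limit = 60) {
  stopifnot(v_min > 0, v_min < big_m, tol > 0)
  if (v_min / tol < 50) {
    stop("tolerance too loose: v_min/tol must be >= 50", call. = FALSE)
  }
  structure(list(v_min = v_min, big_m = big_m, tol = tol,
                 time_limit = time_limit), class = "blocking_config")
}

# Shared LP skeleton: flux variables for every reaction (sinks included),
# steady-state mass balance and any network-specific coupling rows.
#' @keywords internal
blocking_base_problem <- function(net, n_extra = 0L, sense = "max") {
  if (length(net$sink_ids) == 0) {
    stop("network has no sinks; call prepare_for_blocking() first",
         call. = FALSE)
  }
  tri <- net_triplets(net)
  bnd <- net_bounds(net)
  nr <- length(tri$rxn_ids)
  p <- lp_new(nr + n_extra, sense)
  lp_set_bounds(p, lb = bnd$lb, ub = bnd$ub, idx = seq_len(nr))
  nmet <- length(tri$met_ids)
  lp_add_rows(p, tri$i, tri$j, tri$x, rep("=", nmet), rep(0, nmet))
  for (cc in net$coupling) {
    jj <- match(names(cc$coef), tri$rxn_ids)
    lp_add_rows(p, rep(1L, length(jj)), jj, unname(cc$coef), cc$sense, cc$rhs)
  }
  list(p = p, tri = tri, n_rxn = nr)
}

#' @keywords internal
new_producibility_result <- function(net, producible, blocked,
                                     witness = NULL, strain = "wt") {
  structure(list(strain = strain,
                 media = attr(net, "media_id") %||% NA_character_,
                 producible = sort(producible),
                 blocked = sort(blocked),
                 witness = witness,
                 universe = sort(net$metabolites$id)),
            class = "producibility_result")
}

#' @export
print.producibility_result <- function(x, ...) {
  cat("Producibility (strain ", x$strain, ", media ",
      x$media, "): ", length(x$producible), " producible, ",
      length(x$blocked), " blocked\n", sep = "")
  if (length(x$blocked)) {
    cat("  blocked:", paste(x$blocked, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partition metabolites into producible/blocked via one MILP
#'
#' Maximizes the number of metabolites whose sink simultaneously carries at
#' least \code{v_min} flux: binaries \code{z_i} are linked to the sink fluxes
#' \code{x_i} by \code{v_min * z_i <= x_i <= big_m * z_i} under steady-state
#' mass balance and the network's flux bounds and coupling constraints.
#'
#' @param net sink-augmented network ([prepare_for_blocking()]), with media and
#'   knockouts already applied.
#' @param cfg a [blocking_config()].
#' @param strain label recorded in the result.
#' @return A \code{producibility_result}.
#' @export
producible_set_milp <- function(net, cfg = blocking_config(), strain = "wt") {
  base <- blocking_base_problem(net, n_extra = length(net$metabolites$id))
  p <- base$p; tri <- base$tri
  mids <- sort(tri$met_ids)                    # deterministic variable order
  nmet <- length(mids)
  zcol <- base$n_rxn + seq_len(nmet)           # z_i for mids[i]
  lp_set_binary(p, zcol)
  sink_col <- match(paste0("SK_", mids), tri$rxn_ids)
  if (anyNA(sink_col)) {
    stop("internal error: missing sink reaction for some metabolite",
         call. = FALSE)
  }
  # x_i - v_min z_i >= 0  and  x_i - big_m z_i <= 0
  n2 <- 2L * nmet
  lp_add_rows(p,
              i = c(seq_len(nmet), seq_len(nmet),
                    nmet + seq_len(nmet), nmet + seq_len(nmet)),
              j = c(sink_col, zcol, sink_col, zcol),
              x = c(rep(1, nmet), rep(-cfg$v_min, nmet),
                    rep(1, nmet), rep(-cfg$big_m, nmet)),
              sense = c(rep(">=", nmet), rep("<=", nmet)),
              rhs = rep(0, n2))
  obj <- numeric(p$n); obj[zcol] <- 1
  lp_set_objective(p, obj)
  res <- lp_solve(p, time_limit = cfg$time_limit)
  if (res$status != "optimal") {
    stop("internal error: producibility MILP not solved to optimality ",
         "(status ", res$status, ")", call. = FALSE)
  }
  z <- res$x[zcol] > 0.5
  witness <- stats::setNames(res$x[seq_len(base$n_rxn)], tri$rxn_ids)
  new_producibility_result(net, producible = mids[z], blocked = mids[!z],
                           witness = witness, strain = strain)
}

#' Partition metabolites via per-metabolite LPs (independent oracle)
#'
#' For each metabolite, maximizes its sink flux under the same steady-state
#' system without binaries; the metabolite is producible iff the optimum
#' reaches \code{v_min - tol}. This is the defining criterion and serves as
#' the reference against which the MILP is validated. Any optimal flux vector
#' additionally certifies every other sink it pushes past \code{v_min}, so
#' most metabolites are resolved without their own solve.
#'
#' @inheritParams producible_set_milp
#' @return A \code{producibility_result}.
#' @export
producible_oracle <- function(net, cfg = blocking_config(), strain = "wt") {
  base <- blocking_base_problem(net)
  p <- base$p; tri <- base$tri
  mids <- sort(tri$met_ids)
  sink_col <- stats::setNames(match(paste0("SK_", mids), tri$rxn_ids), mids)
  status <- stats::setNames(rep(NA, length(mids)), mids)
  for (m in mids) {
    if (!is.na(status[m])) next
    obj <- numeric(p$n); obj[sink_col[m]] <- 1
    lp_set_objective(p, obj)
    res <- lp_solve(p, time_limit = cfg$time_limit)
    if (res$status != "optimal") {
      stop("internal error: oracle LP for '", m, "' returned status ",
           res$status, call. = FALSE)
    }
    status[m] <- res$objective >= cfg$v_min - cfg$tol
    if (status[m]) {           # witness certifies co-produced metabolites
      cert <- res$x[sink_col] >= cfg$v_min - cfg$tol
      status[is.na(status) & cert] <- TRUE
    }
  }
  new_producibility_result(net, producible = mids[status],
                           blocked = mids[!status], strain = strain)
}

#' Mutant-specific candidate blocked metabolites
#'
#' Metabolites blocked in the mutant but not in the wild type; wild-type
#' blocked metabolites are removed from consideration because their inclusion
#' in a biomass would make the wild type unable to grow.
#'
#' @param wt,mut \code{producibility_result}s on the same media and metabolite
#'   universe.
#' @return Sorted character vector of candidate metabolite ids.
#' @export
candidate_blocked <- function(wt, mut) {
  if (!identical(wt$universe, mut$universe)) {
    stop("usage error: wild-type and mutant results cover different ",
         "metabolite universes", call. = FALSE)
  }
  if (!identical(wt$media, mut$media)) {
    stop("usage error: wild-type and mutant results are for different media",
         call. = FALSE)
  }
  sort(setdiff(mut$blocked, wt$blocked))
}

#' Serialize producibility results as TSV
#'
#' @param results list of \code{producibility_result}s.
#' @param path output path.
#' @export
write_producibility <- function(results, path) {
  if (inherits(results, "producibility_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(metabolite_id = c(r$producible, r$blocked),
               strain = r$strain, media = r$media,
               status = c(rep("producible", length(r$producible)),
                          rep("blocked", length(r$blocked))),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$strain, rows$metabolite_id), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
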