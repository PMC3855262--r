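# Independent brute-force oracles used to validate the optimization code.

# Reachability closure for the purely irreversible fixture networks: a
# metabolite is net-producible iff some available reaction whose substrates
# are all producible makes it, starting from the media nutrients. Valid only
# when all non-exchange reactions are irreversible with nonnegative uptake
# capacity, which holds for every network the synthetic generator emits.
closure_producible <- function(net, media, genes = character(0)) {
  net <- apply_media(net, media)
  net <- suppressWarnings(apply_knockout(net, genes))
  avail <- character(0)
  for (rid in exchange_ids(net)) {
    r <- net$reactions[[rid]]
    m <- names(r$stoich)
    coefsign <- sign(r$stoich[[1]])
    uptake_open <- if (coefsign < 0) r$lower_bound < 0 else r$upper_bound > 0
    if (uptake_open) avail <- union(avail, m)
  }
  internal <- setdiff(names(net$reactions),
                      c(exchange_ids(net), net$biomass_ids, net$sink_ids))
  repeat {
    grew <- FALSE
    for (rid in internal) {
      r <- net$reactions[[rid]]
      if (r$upper_bound <= 0) next
      subs <- names(r$stoich)[r$stoich < 0]
      prods <- names(r$stoich)[r$stoich > 0]
      if (all(subs %in% avail) && !all(prods %in% avail)) {
        avail <- union(avail, prods)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sort(avail)
}

# Exhaustive maximal agreement over all 2^k component subsets, vectorized over
# bitmasks. Returns the optimum and the smallest cardinality attaining it.
bf_agreement <- function(lists) {
  inst <- qbiomass:::agreement_instance(lists)
  k <- length(inst$universe)
  stopifnot(k <= 15)
  subsets <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))  # 2^k x k
  score <- numeric(nrow(subsets))
  for (e in inst$ng) {
    s <- inst$in_sets[[e]]
    hit <- if (length(s) == 0) rep(FALSE, nrow(subsets))
      else rowSums(subsets[, s, drop = FALSE]) > 0
    score <- score + inst$wts[[e]] * hit
  }
  for (e in inst$g) {
    s <- inst$ex_sets[[e]]
    hit <- if (length(s) == 0) rep(TRUE, nrow(subsets))
      else rowSums(subsets[, s, drop = FALSE]) == 0
    score <- score + inst$wts[[e]] * hit
  }
  best <- max(score)
  sizes <- rowSums(subsets)
  list(fix_obj = best, min_size = min(sizes[score == best]))
}

# Random include/exclude instance over k candidate metabolites (no network).
random_lists <- function(k, n_ng, n_g, seed) {
  set.seed(seed)
  universe <- sprintf("c%02d", seq_len(k))
  include <- lapply(seq_len(n_ng), function(i)
    sort(sample(universe, sample.int(min(5, k), 1))))
  names(include) <- sprintf("ng%02d", seq_len(n_ng))
  exclude <- lapply(seq_len(n_g), function(i)
    sort(sample(universe, sample.int(min(3, k), 1))))
  names(exclude) <- sprintf("g%02d", seq_len(n_g))
  wts <- stats::setNames(sample(1:3, n_ng + n_g, replace = TRUE),
                         c(names(include), names(exclude)))
  structure(list(include = include, exclude = exclude,
                 filtered_out = character(0),
                 universe = sort(unique(unlist(c(include, exclude)))),
                 ng = names(include), g = names(exclude),
                 weights = wts),
            class = "include_exclude_lists")
}

# Brute-force minimum number of open sinks that lets a biomass over
# `components` carry flux >= eps: closes all sinks except a candidate subset
# and checks LP feasibility, by increasing subset size.
bf_min_sinks <- function(net, components, genes, media, eps = 0.001,
                         coefficient = 2e-4, cfg = blocking_config()) {
  prepped <- apply_media(prepare_for_blocking(net, u_sink = cfg$big_m), media)
  prepped <- suppressWarnings(apply_knockout(prepped, genes))
  bio <- build_biomass_reaction(components, coefficient)
  prepped$reactions[[bio$id]] <- bio
  mids <- sort(prepped$metabolites$id)
  stopifnot(length(mids) <= 12)
  feasible_with <- function(open) {
    n2 <- prepped
    for (m in setdiff(mids, open)) {
      n2$reactions[[paste0("SK_", m)]]$upper_bound <- 0
    }
    n2$reactions[[bio$id]]$lower_bound <- eps
    tri <- qbiomass:::net_triplets(n2); bnd <- qbiomass:::net_bounds(n2)
    p <- qbiomass:::lp_new(length(tri$rxn_ids), "max")
    qbiomass:::lp_set_bounds(p, lb = bnd$lb, ub = bnd$ub)
    nm <- length(tri$met_ids)
    qbiomass:::lp_add_rows(p, tri$i, tri$j, tri$x, rep("=", nm), rep(0, nm))
    qbiomass:::lp_feasible(p)
  }
  for (size in 0:length(mids)) {
    sets <- utils::combn(mids, size, simplify = FALSE)
    for (s in sets) if (feasible_with(s)) return(size)
  }
  NA_integer_
}
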