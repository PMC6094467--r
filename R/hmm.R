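# Hidden Markov model over offspring inheritance states.
#
# At each locus an offspring is in one of four states AC, AD, BC, BD (which
# homolog it inherited from each parent).  Along the map the two parental
# indicators switch independently with the interval's recombination
# fraction; a marker emits its state's phenotype class with probability
# 1 - eps, or any one of the other classes with probability eps/(c-1).
# Missing observations are uninformative (emission 1 in every state).

#' Resolve marker phases along a group from pairwise linkage
#'
#' Builds, per parent, a maximum spanning tree (by LOD) over the markers
#' informative for that parent and propagates homolog orientations from the
#' first marker along the tree; a marker's flip is the parity of repulsion
#' edges on its tree path.
#'
#' @param pairwise a [pairwise_linkage()] object.
#' @param markers markers to phase (default all in `pairwise`).
#' @return tibble (marker, flip_lat, flip_moy); flips are FALSE for markers
#'   uninformative for that parent.
#' @export
resolve_phases <- function(pairwise, markers = pairwise$markers) {
  out <- tibble(marker = markers, flip_lat = FALSE, flip_moy = FALSE)
  for (parent in c("lat", "moy")) {
    ip <- pairwise$informative[markers, parent]
    ids <- markers[ip]
    if (length(ids) < 2) next
    lod <- pairwise$lod[ids, ids, drop = FALSE]
    flip <- (if (parent == "lat") pairwise$flip_lat else
               pairwise$flip_moy)[ids, ids, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(lod * (lod > 0),
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
    ori <- rep(NA, length(ids))
    names(ori) <- ids
    for (comp in igraph::decompose(mst)) {
      vs <- igraph::V(comp)$name
      ori[vs[[1]]] <- FALSE
      bfs <- igraph::bfs(comp, root = vs[[1]], father = TRUE)
      ord <- igraph::V(comp)$name[as.integer(bfs$order)]
      fathers <- setNames(igraph::V(comp)$name[as.integer(bfs$father)],
                          igraph::V(comp)$name)
      for (v in ord[-1]) {
        f <- fathers[[v]]
        ori[[v]] <- xor(ori[[f]], flip[f, v])
      }
    }
    ori[is.na(ori)] <- FALSE
    out[[paste0("flip_", parent)]] <- unname(ori[match(markers, ids)])
    out[[paste0("flip_", parent)]][!ip] <- FALSE
  }
  out$flip_lat[is.na(out$flip_lat)] <- FALSE
  out$flip_moy[is.na(out$flip_moy)] <- FALSE
  out
}

#' Build an inheritance HMM for an ordered linkage group
#'
#' @param map tibble (marker, pos) in map order.
#' @param classmaps named list of *phased* class maps (apply
#'   [resolve_phases()] flips with [flip_classmap()] first if phases came
#'   from two-point analysis).
#' @param eps genotyping error rate (emission misclassification).
#' @param map_function map function giving interval recombination fractions
#'   from adjacent positions.
#' @param r_min floor on interval recombination fractions (0 keeps
#'   coincident loci perfectly linked; the transition matrix degenerates to
#'   the identity there).
#' @return object of class `inheritance_model`.
#' @export
build_inheritance_model <- function(map, classmaps, eps = 0.01,
                                    map_function = c("haldane", "kosambi"),
                                    r_min = 0) {
  map_function <- match.arg(map_function)
  stopifnot(!is.unsorted(map$pos))
  missing_cm <- setdiff(map$marker, names(classmaps))
  if (length(missing_cm))
    abort(paste0("no phased class map for: ",
                 paste(head(missing_cm, 5), collapse = ", ")))
  cms <- classmaps[map$marker]
  enc <- encode_classmaps(cms)
  rk <- pmax(distance_to_rf(diff(map$pos), map_function), r_min)
  structure(list(markers = map$marker, pos = map$pos, rk = rk,
                 classmaps = cms, cmaps = enc$cmaps,
                 nclasses = enc$nclasses, eps = eps,
                 map_function = map_function),
            class = "inheritance_model")
}

# 4x4 state transition matrix for one interval.
transition_matrix <- function(r) {
  p1 <- matrix(c(1 - r, r, r, 1 - r), 2)
  p1 %x% p1   # Latham switch (outer) x Moy switch (inner)
}

# Emission probabilities at locus t as a 4 x o matrix.
emission_probs <- function(model, obs_t, t) {
  o <- length(obs_t)
  K <- model$nclasses[[t]]
  E <- matrix(1, 4, o)
  seen <- obs_t > 0
  if (any(seen)) {
    for (s in 1:4) {
      cm <- model$cmaps[t, s]
      E[s, seen] <- ifelse(cm == obs_t[seen], 1 - model$eps,
                           if (K > 1) model$eps / (K - 1) else model$eps)
    }
  }
  E
}

#' Forward-backward state posteriors
#'
#' @param model an `inheritance_model`.
#' @param calls marker x individual character call matrix in model order
#'   (rows may be named; matched by `model$markers` when so).
#' @return list: `posterior` (array m x 4 x o), `loglik` (per offspring),
#'   states dimension named AC, AD, BC, BD.
#' @export
forward_backward <- function(model, calls) {
  obs <- encode_model_obs(model, calls)
  m <- nrow(obs); o <- ncol(obs)
  Ts <- lapply(model$rk, transition_matrix)
  alpha <- vector("list", m)
  logc <- matrix(0, m, o)
  a <- emission_probs(model, obs[1, ], 1) * 0.25
  sc <- colSums(a)
  if (any(sc <= 0)) abort("zero forward probability (impossible data at locus 1)")
  a <- sweep(a, 2, sc, "/")
  logc[1, ] <- log(sc)
  alpha[[1]] <- a
  for (t in seq_len(m)[-1]) {
    a <- crossprod(Ts[[t - 1]], a) * emission_probs(model, obs[t, ], t)
    sc <- colSums(a)
    if (any(sc <= 0)) abort("zero forward probability (impossible data)")
    a <- sweep(a, 2, sc, "/")
    logc[t, ] <- log(sc)
    alpha[[t]] <- a
  }
  loglik <- colSums(logc)
  post <- array(NA_real_, c(m, 4, o),
                dimnames = list(model$markers, STATE_LABELS, colnames(calls)))
  b <- matrix(1, 4, o)
  post[m, , ] <- alpha[[m]]
  for (t in rev(seq_len(m - 1))) {
    b <- Ts[[t]] %*% (b * emission_probs(model, obs[t + 1, ], t + 1))
    b <- sweep(b, 2, colSums(b), "/")
    g <- alpha[[t]] * b
    post[t, , ] <- sweep(g, 2, colSums(g), "/")
  }
  list(posterior = post, loglik = loglik)
}

encode_model_obs <- function(model, calls) {
  if (!is.null(rownames(calls)) &&
      all(model$markers %in% rownames(calls)))
    calls <- calls[model$markers, , drop = FALSE]
  stopifnot(nrow(calls) == length(model$markers))
  encode_observations(calls, model$classmaps)
}

#' Viterbi reconstruction of inheritance states and recombinations
#'
#' Runs the HMM for each offspring to identify the chromosome configuration
#' most likely to give the observed genotypes, and records the inferred
#' homolog switches per interval and parent (the (m-1) x o recombination
#' matrices).
#'
#' @inheritParams forward_backward
#' @return object of class `recombination_matrix`: list with `states`
#'   (m x o integer matrix, 1..4 = AC..BD), `lat`, `moy` ((m-1) x o 0/1
#'   switch matrices), `markers`, `n_offspring`.
#' @export
reconstruct_states <- function(model, calls) {
  obs <- encode_model_obs(model, calls)
  m <- nrow(obs); o <- ncol(obs)
  logT <- lapply(model$rk, function(r) log(transition_matrix(r)))
  delta <- t(log(emission_probs(model, obs[1, ], 1) * 0.25))   # o x 4
  psi <- array(0L, c(max(m - 1, 1), o, 4))
  for (t in seq_len(m)[-1]) {
    lt <- logT[[t - 1]]
    cand <- array(NA_real_, c(o, 4, 4))   # offspring x to x from
    for (sp in 1:4) cand[, , sp] <- delta[, sp] + rep(lt[sp, ], each = o)
    best <- apply(cand, c(1, 2), which.max)
    for (s in 1:4) psi[t - 1, , s] <- best[, s]
    dmax <- apply(cand, c(1, 2), max)
    delta <- dmax + t(log(emission_probs(model, obs[t, ], t)))
  }
  states <- matrix(0L, m, o)
  states[m, ] <- max.col(delta, ties.method = "first")
  if (m > 1) {
    for (t in rev(seq_len(m - 1))) {
      states[t, ] <- psi[cbind(t, seq_len(o), states[t + 1, ])]
    }
  }
  lat_h <- (states - 1L) %/% 2L
  moy_h <- (states - 1L) %% 2L
  lat_sw <- abs(diff(lat_h))
  moy_sw <- abs(diff(moy_h))
  structure(list(states = states, lat = lat_sw, moy = moy_sw,
                 markers = model$markers, n_offspring = o),
            class = "recombination_matrix")
}

#' Mean inferred recombinations per offspring
#'
#' @param R a `recombination_matrix` from [reconstruct_states()].
#' @return total inferred homolog switches (both parents) divided by the
#'   number of offspring.
#' @export
hmm_mean <- function(R) {
  if (R$n_offspring == 0) abort("no offspring")
  (sum(R$lat) + sum(R$moy)) / R$n_offspring
}

# Interval recombination fractions for an arbitrary candidate order,
# derived from the markers' map positions.  Raw adjacent two-point
# estimates are too noisy at short range (a 2 cM interval has a ~15%
# chance of zero observed recombinants at n ~ 184, collapsing rhat to 0
# and distorting the Viterbi transition costs); the fitted positions pool
# information over many pairs.
order_rk <- function(ord_ids, pos, map_function, r_min = 1e-3,
                     r_max = 0.4999) {
  d <- abs(diff(pos[ord_ids]))
  pmin(pmax(distance_to_rf(d, map_function), r_min), r_max)
}

#' Improve a marker order by HMM recombination counts
#'
#' Greedy search over local moves: swapping each marker with its neighbour
#' and trying every ordering of each consecutive marker triplet.  The move
#' that most reduces the total number of Viterbi-inferred recombinations
#' across offspring is applied, interval distances are re-derived from the
#' markers' fitted positions, and the search repeats until no
#' move helps.  Exclusion of each marker is evaluated and *reported* (a
#' marker whose removal saves many recombinations is suspect) but never
#' applied automatically.
#'
#' @param map tibble (marker, pos) in current order.
#' @param calls marker x individual call matrix.
#' @param classmaps named list of phased class maps.
#' @param eps genotyping error rate for the HMM.
#' @param map_function map function.
#' @param max_sweeps cap on accepted moves.
#' @return list: `map` (improved, with positions re-accumulated along the
#'   final order), `moves` (tibble of accepted moves),
#'   `exclusion_report` (tibble marker, saved_recombinations on the final
#'   order), `total_before`, `total_after`, `hmm_mean_before`,
#'   `hmm_mean_after`.
#' @export
improve_order <- function(map, calls, classmaps, eps = 0.01,
                          map_function = c("haldane", "kosambi"),
                          max_sweeps = 50) {
  map_function <- match.arg(map_function)
  ids <- map$marker
  pos0 <- setNames(map$pos, ids)
  obs_all <- encode_observations(calls[ids, , drop = FALSE], classmaps[ids])
  rownames(obs_all) <- ids
  enc <- encode_classmaps(classmaps[ids])
  rownames(enc$cmaps) <- ids
  names(enc$nclasses) <- ids
  o <- ncol(obs_all)
  total_for <- function(ord) {
    rk <- order_rk(ord, pos0, map_function)
    cpp_viterbi_recombinations(obs_all[ord, , drop = FALSE],
                               enc$cmaps[ord, , drop = FALSE],
                               enc$nclasses[ord], rk, eps)
  }
  ord <- ids
  total0 <- total_for(ord)
  total <- total0
  moves <- list()
  for (sweep in seq_len(max_sweeps)) {
    m <- length(ord)
    best <- list(gain = 0)
    for (i in seq_len(m - 1)) {               # adjacent swaps
      cand <- ord
      cand[c(i, i + 1)] <- cand[c(i + 1, i)]
      tt <- total_for(cand)
      if (total - tt > best$gain)
        best <- list(gain = total - tt, ord = cand, total = tt,
                     move = sprintf("swap %s <-> %s", ord[i], ord[i + 1]))
    }
    perms3 <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (i in seq_len(max(m - 2, 0))) {       # triplet reorderings
      idx <- i:(i + 2)
      for (p in perms3) {
        cand <- ord
        cand[idx] <- ord[idx][p]
        tt <- total_for(cand)
        if (total - tt > best$gain)
          best <- list(gain = total - tt, ord = cand, total = tt,
                       move = sprintf("triplet %s (%s)",
                                      paste(ord[idx], collapse = ","),
                                      paste(p, collapse = "")))
      }
    }
    if (best$gain <= 0) break
    ord <- best$ord
    total <- best$total
    moves[[length(moves) + 1L]] <- tibble(sweep = sweep, move = best$move,
                                          saved = best$gain,
                                          total_after = total)
  }
  excl <- vapply(seq_along(ord), function(i) {
    total - total_for(ord[-i])
  }, 1)
  new_pos <- c(0, cumsum(abs(diff(pos0[ord]))))
  list(map = tibble(marker = ord, pos = new_pos),
       moves = list_rbind(moves) %||% tibble(),
       exclusion_report = tibble(marker = ord, saved_recombinations = excl),
       total_before = total0, total_after = total,
       hmm_mean_before = total0 / o, hmm_mean_after = total / o)
}
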