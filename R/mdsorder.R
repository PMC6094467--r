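# Marker ordering within a linkage group: weighted metric MDS (SMACOF
# majorization), outlier removal, principal-curve projection, and the
# nearest-neighbour fit (NNfit) criterion for comparing candidate orders.

# Weighted least-squares metric MDS by SMACOF iterative majorization.
# delta: target distances (only pairs with w > 0 enter the stress);
# w: symmetric non-negative weights, zero diagonal.
smacof_wmds <- function(delta, w, dims = 3, max_iter = 300, tol = 1e-8,
                        init = NULL) {
  m <- nrow(delta)
  V <- -w
  diag(V) <- rowSums(w)
  Vinv <- solve(V + 1 / m) - 1 / m    # Moore-Penrose inverse on 1-orthogonal
  if (is.null(init)) {
    d0 <- delta
    d0[w == 0] <- NA
    d0 <- complete_distances(d0)
    init <- cmdscale(d0, k = dims)
    if (ncol(init) < dims)
      init <- cbind(init, matrix(0, m, dims - ncol(init)))
  }
  X <- init
  dist_mat <- function(X) as.matrix(dist(X))
  stress_of <- function(D) sum(w * (delta - D)^2) / 2
  D <- dist_mat(X)
  stress <- stress_of(D)
  for (it in seq_len(max_iter)) {
    Dpos <- D
    Dpos[Dpos == 0] <- Inf
    B <- -w * delta / Dpos
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- Vinv %*% (B %*% X)
    D <- dist_mat(X)
    new_stress <- stress_of(D)
    if (stress > 0 && (stress - new_stress) / stress < tol) {
      stress <- new_stress
      break
    }
    stress <- new_stress
  }
  list(conf = X, stress = stress, iterations = it)
}

# Fill unobserved distances by shortest paths over observed ones (used only
# to initialise the configuration; the stress never sees these entries).
complete_distances <- function(d) {
  if (!anyNA(d)) return(d)
  g <- igraph::graph_from_adjacency_matrix(
    ifelse(is.na(d), 0, d), mode = "undirected", weighted = TRUE, diag = FALSE)
  sp <- igraph::distances(g)
  out <- ifelse(is.na(d), sp, d)
  out[!is.finite(out)] <- max(out[is.finite(out)]) * 1.5
  out
}

# Principal curve through a configuration: alternate smoothing of each
# coordinate against arc-length and re-projection onto the fitted curve.
fit_principal_curve <- function(X, iterations = 10, grid_mult = 10) {
  m <- nrow(X)
  pc1 <- prcomp(X)$x[, 1]
  lambda <- rank(pc1, ties.method = "first") + 0
  for (it in seq_len(iterations)) {
    grid <- seq(min(lambda), max(lambda), length.out = max(grid_mult * m, 50))
    curve <- vapply(seq_len(ncol(X)), function(d) {
      fit <- smooth.spline(lambda, X[, d], df = min(max(4, m / 5), m - 1))
      predict(fit, grid)$y
    }, numeric(length(grid)))
    seg <- sqrt(rowSums((curve[-1, , drop = FALSE] -
                         curve[-nrow(curve), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    # nearest curve point per marker
    idx <- vapply(seq_len(m), function(i) {
      which.min(rowSums((curve - matrix(X[i, ], nrow(curve), ncol(X),
                                        byrow = TRUE))^2))
    }, integer(1))
    new_lambda <- arc[idx]
    if (max(abs(new_lambda - lambda)) < 1e-9 * max(arc[length(arc)], 1)) {
      lambda <- new_lambda
      break
    }
    lambda <- new_lambda
  }
  lambda
}

#' Order markers by weighted MDS and a principal curve
#'
#' Target distances are the two-point estimates converted by the map
#' function; pair weights are LOD or LOD^2 (zero for uninformative pairs).
#' The weighted stress is minimised by SMACOF majorization; markers whose
#' mean weighted residual exceeds `outlier_sd` robust SDs are removed once
#' and the MDS rerun; a principal curve through the configuration gives the
#' linear order, and arc-length positions are rescaled so inter-marker
#' distances are consistent (in the weighted least-squares sense) with the
#' two-point estimates.
#'
#' @param pairwise a [pairwise_linkage()] object.
#' @param weighting "lod2" (default) or "lod".
#' @param dims 2 or 3.
#' @param map_function map function for converting r to cM.
#' @param outlier_sd robust-SD multiplier for outlier removal.
#' @return object of class `mds_map`: list with `map` (tibble marker, pos,
#'   ordered), `stress`, `outliers`, `weighting`, `dims`, `nnfit` (filled by
#'   [nnfit()] via [order_markers()], NA here).
#' @export
mds_order <- function(pairwise, weighting = c("lod2", "lod"), dims = 3,
                      map_function = c("haldane", "kosambi"),
                      outlier_sd = 3) {
  weighting <- match.arg(weighting)
  map_function <- match.arg(map_function)
  ids <- pairwise$markers
  if (length(ids) < 4) abort("need at least 4 markers to order")
  r <- pairwise$r
  w <- if (weighting == "lod") pairwise$lod else pairwise$lod^2
  diag(w) <- 0
  w[is.na(r)] <- 0
  check_connected(w, ids)
  delta <- rf_to_distance(ifelse(is.na(r), 0, r), map_function)
  run <- function(keep) {
    fit <- smacof_wmds(delta[keep, keep], w[keep, keep], dims = dims)
    fit$keep <- keep
    fit
  }
  finalize <- function(fit) {
    lambda <- fit_principal_curve(fit$conf)
    ord <- order(lambda)
    lam <- sort(lambda)
    # rescale arc length against the two-point distances (WLS through origin)
    dl <- abs(outer(lambda, lambda, "-"))
    wk <- w[fit$keep, fit$keep]
    num <- sum(wk * delta[fit$keep, fit$keep] * dl)
    den <- sum(wk * dl^2)
    scale <- if (den > 0) num / den else 1
    tibble(marker = ids[fit$keep][ord], pos = (lam - lam[[1]]) * scale)
  }
  keep <- seq_along(ids)
  fit <- run(keep)
  map_full <- finalize(fit)
  # single-pass outlier removal on mean weighted absolute residual
  D <- as.matrix(dist(fit$conf))
  wk <- w[keep, keep]
  res <- abs(delta[keep, keep] - D)
  mr <- rowSums(wk * res) / pmax(rowSums(wk), .Machine$double.eps)
  bad <- mr > median(mr) + outlier_sd * mad(mr)
  outliers <- ids[keep][bad]
  map <- map_full
  if (any(bad) && sum(!bad) >= 4) {
    keep2 <- keep[!bad]
    # removing an outlier can sever the only informative bridge to a set of
    # markers; such markers are left unplaced alongside the outliers
    g <- igraph::graph_from_adjacency_matrix(w[keep2, keep2] > 0,
                                             mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      sever <- keep2[comp$membership != which.max(comp$csize)]
      outliers <- c(outliers, ids[sever])
      keep2 <- setdiff(keep2, sever)
    }
    if (length(keep2) >= 4) {
      fit2 <- run(keep2)
      map2 <- finalize(fit2)
      # guard: accept the removal only if it does not degrade the order
      # quality of the retained markers (outliers can be the sole bridges
      # between the two parents' marker sets, and losing them can let the
      # configuration fold)
      pw_sub <- subset_pairwise(pairwise, map2$marker)
      nn_before <- nnfit(map_full[map_full$marker %in% map2$marker, ],
                         pw_sub, map_function)$mean
      nn_after <- nnfit(map2, pw_sub, map_function)$mean
      if (nn_after <= nn_before + 1e-9) {
        fit <- fit2
        map <- map2
      } else {
        outliers <- character()
      }
    }
  }
  structure(list(map = map, stress = fit$stress, outliers = outliers,
                 weighting = weighting, dims = dims, nnfit = NA_real_,
                 map_function = map_function),
            class = "mds_map")
}

check_connected <- function(w, ids) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- table(comp$membership)
    small <- ids[comp$membership != as.integer(names(which.max(sizes)))]
    abort(paste0("linkage weight graph is disconnected; separated markers: ",
                 paste(head(small, 10), collapse = ", "),
                 if (length(small) > 10) " ..."))
  }
  invisible(TRUE)
}

#' Nearest-neighbour fit of a marker order
#'
#' For each marker, the sum of absolute differences between the observed
#' two-point map distance and the fitted map-position difference to the
#' nearest *informative* neighbour (non-zero LOD) on either side; the mean
#' over markers is the order-comparison criterion.
#'
#' @param map tibble (marker, pos), ordered.
#' @param pairwise a [pairwise_linkage()] object covering the markers.
#' @param map_function map function for converting r to distance.
#' @return list(mean, per_marker) where per_marker is a tibble (marker,
#'   nn_left, nn_right, term).
#' @export
nnfit <- function(map, pairwise, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  ids <- map$marker
  pos <- map$pos
  m <- length(ids)
  lod <- pairwise$lod[ids, ids, drop = FALSE]
  robs <- pairwise$r[ids, ids, drop = FALSE]
  terms <- numeric(m)
  nnl <- nnr <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    term <- 0
    left <- rev(seq_len(i - 1))
    jl <- left[which(lod[i, left] > 0)[1]]
    if (length(jl) && !is.na(jl)) {
      term <- term + abs(rf_to_distance(robs[i, jl], map_function) -
                           abs(pos[i] - pos[jl]))
      nnl[i] <- ids[jl]
    }
    right <- seq_len(m)[-seq_len(i)]
    jr <- right[which(lod[i, right] > 0)[1]]
    if (length(jr) && !is.na(jr)) {
      term <- term + abs(rf_to_distance(robs[i, jr], map_function) -
                           abs(pos[i] - pos[jr]))
      nnr[i] <- ids[jr]
    }
    terms[i] <- term
  }
  list(mean = mean(terms),
       per_marker = tibble(marker = ids, nn_left = nnl, nn_right = nnr,
                           term = terms))
}

#' Fit candidate orders and select the best by mean NNfit
#'
#' Fits every combination of weighting and dimensionality, scores each with
#' [nnfit()], and selects the order with minimal mean NNfit (ties broken
#' toward LOD^2 weighting and 3 dimensions).
#'
#' @param pairwise a [pairwise_linkage()] object.
#' @param weightings,dims candidate settings.
#' @inheritParams mds_order
#' @return the selected `mds_map` (with `nnfit` filled) plus a `candidates`
#'   attribute tabulating all fits.
#' @export
order_markers <- function(pairwise, weightings = c("lod2", "lod"),
                          dims = c(3, 2),
                          map_function = c("haldane", "kosambi"),
                          outlier_sd = 3) {
  map_function <- match.arg(map_function)
  grid <- expand.grid(weighting = weightings, dims = dims,
                      stringsAsFactors = FALSE)
  fits <- pmap(grid, function(weighting, dims) {
    fit <- mds_order(pairwise, weighting = weighting, dims = dims,
                     map_function = map_function, outlier_sd = outlier_sd)
    fit$nnfit <- nnfit(fit$map, pairwise, map_function)$mean
    fit
  })
  cand <- tibble(weighting = grid$weighting, dims = grid$dims,
                 nnfit = map_dbl(fits, "nnfit"),
                 stress = map_dbl(fits, "stress"),
                 n_outliers = map_int(fits, ~ length(.x$outliers)))
  # minimal NNfit; ties toward lod2 weighting and 3 dimensions
  pref <- order(cand$nnfit, cand$weighting != "lod2", cand$dims != 3)
  best <- fits[[pref[[1]]]]
  attr(best, "candidates") <- cand
  best
}

#' Orient a map to agree with anchor positions
#'
#' Reverses the map when its positions correlate negatively (Spearman) with
#' the anchor's cM positions.
#'
#' @param map_fit an `mds_map` or a tibble (marker, pos).
#' @param anchor_pos named numeric vector of anchor cM positions.
#' @return the input with positions reversed if needed.
#' @export
orient_map <- function(map_fit, anchor_pos) {
  tbl <- if (inherits(map_fit, "mds_map")) map_fit$map else map_fit
  shared <- intersect(tbl$marker, names(anchor_pos))
  if (length(shared) >= 2) {
    rho <- suppressWarnings(
      cor(tbl$pos[match(shared, tbl$marker)], anchor_pos[shared],
          method = "spearman"))
    if (!is.na(rho) && rho < 0) {
      tbl <- tbl[rev(seq_len(nrow(tbl))), ]
      tbl$pos <- max(tbl$pos) - tbl$pos
    }
  }
  if (inherits(map_fit, "mds_map")) {
    map_fit$map <- tbl
    map_fit
  } else tbl
}

#' @export
print.mds_map <- function(x, ...) {
  cat("<mds_map> ", nrow(x$map), " markers, length ",
      round(max(x$map$pos), 1), " cM, ", x$weighting, " weighting, ",
      x$dims, "-d, stress ", signif(x$stress, 4),
      if (!is.na(x$nnfit)) paste0(", mean NNfit ", signif(x$nnfit, 4)),
      "\n", sep = "")
  if (length(x$outliers))
    cat("  outliers removed: ", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
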