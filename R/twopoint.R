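# Two-point linkage: pre-ordering filters, pairwise recombination fractions,
# LOD scores and phases.

#' Pre-ordering marker filters
#'
#' Collapses duplicate markers (identical call vectors, missing included) to
#' one representative, then excludes markers by missingness (round 1: more
#' than 40 missing values; round 2: 45 or more) and by extreme segregation
#' distortion (chi-square against the marker type's expected class ratio,
#' p < 1e-4).
#'
#' @param calls marker x individual call matrix.
#' @param classmaps named list of class maps (expected ratios derive from
#'   the four equiprobable inheritance states).
#' @param round 1 or 2 (second-round missingness rule is more lenient).
#' @param max_missing,missing_ge overrides for the round thresholds.
#' @param distortion_p distortion exclusion level.
#' @return list(retained, duplicates, excluded): retained marker names, a
#'   tibble mapping duplicates to their representative, and a tibble of
#'   exclusions with reasons.
#' @export
prefilter <- function(calls, classmaps, round = 1,
                      max_missing = NULL, distortion_p = 1e-4) {
  ids <- rownames(calls)
  key <- apply(calls, 1, function(x) paste(ifelse(is.na(x), ".", x),
                                           collapse = ""))
  rep_id <- ids[match(key, key)]       # first marker with each pattern
  dup <- tibble(marker = ids, representative = rep_id)[ids != rep_id, ]
  keep <- ids[ids == rep_id]
  excl <- list()
  miss <- rowSums(is.na(calls[keep, , drop = FALSE]))
  bad_miss <- if (round == 1) {
    miss > (max_missing %||% 40)
  } else {
    miss >= (max_missing %||% 45)
  }
  excl$missing <- keep[bad_miss]
  keep <- keep[!bad_miss]
  dist_p <- vapply(keep, function(id) {
    cm <- classmaps[[id]]
    cls <- marker_classes(cm)
    obs <- table(factor(calls[id, ], levels = cls))
    exp_r <- as.numeric(expected_class_freqs(cm))
    if (sum(obs) == 0 || length(cls) < 2) return(1)
    chisq_ratio_p(as.numeric(obs), exp_r)
  }, 1)
  excl$distorted <- keep[dist_p < distortion_p]
  keep <- keep[dist_p >= distortion_p]
  excluded <- list_rbind(compact_null(imap(excl, function(m, reason) {
    if (!length(m)) NULL else tibble(marker = m, reason = reason)
  })))
  list(retained = keep, duplicates = dup, excluded = excluded)
}

# Integer encoding of classmaps for the C++ kernels: per marker, the class
# index (into its own alphabet) emitted by each state, 0 = emits missing.
encode_classmaps <- function(classmaps) {
  m <- length(classmaps)
  cm_int <- matrix(0L, m, 4)
  ncls <- integer(m)
  for (i in seq_len(m)) {
    cls <- marker_classes(classmaps[[i]])
    ncls[[i]] <- length(cls)
    cm_int[i, ] <- ifelse(is.na(classmaps[[i]]), 0L,
                          match(classmaps[[i]], cls))
  }
  list(cmaps = cm_int, nclasses = ncls)
}

#' Estimate the recombination fraction for one marker pair
#'
#' Maximum-likelihood estimate over the four relative phases by EM on the
#' joint phenotype-class counts; LOD = log10 L(rhat) / L(0.5).  Pairs
#' heterozygous in different single parents are uninformative about
#' recombination and return LOD 0 with an undefined rhat.
#'
#' @param calls1,calls2 call vectors (same individuals, same order).
#' @param cm1,cm2 class maps of the two markers (reference phase).
#' @param r_init,max_iter,tol EM control.
#' @return one-row tibble: rhat, lod, phase_lat, phase_moy ("coupling" /
#'   "repulsion" relative to the reference phases, NA when that parent is
#'   uninformative), informative.
#' @export
estimate_rf <- function(calls1, calls2, cm1, cm2,
                        r_init = 0.25, max_iter = 200, tol = 1e-6) {
  ip1 <- informative_parents(cm1); ip2 <- informative_parents(cm2)
  shared <- ip1 & ip2
  if (!any(shared)) {
    return(tibble(rhat = NA_real_, lod = 0, phase_lat = NA_character_,
                  phase_moy = NA_character_, informative = FALSE))
  }
  enc <- encode_classmaps(list(cm1, cm2))
  obs <- encode_observations(rbind(calls1, calls2), list(cm1, cm2))
  res <- cpp_pair_em(obs, enc$cmaps, enc$nclasses,
                     matrix(c(1L, 2L), 1), r_init, max_iter, tol,
                     1e-6, 0.4999)
  tibble(rhat = res$rhat[[1]], lod = max(res$lod[[1]], 0),
         phase_lat = if (shared[["lat"]])
           c("coupling", "repulsion")[res$flip_lat[[1]] + 1] else NA_character_,
         phase_moy = if (shared[["moy"]])
           c("coupling", "repulsion")[res$flip_moy[[1]] + 1] else NA_character_,
         informative = TRUE)
}

#' Pairwise recombination-fraction and LOD matrices for a group
#'
#' Runs the EM of [estimate_rf()] over every informative marker pair.
#'
#' @param calls marker x individual call matrix (rownames = markers).
#' @param classmaps named list of class maps in the same order.
#' @param lod_cap value placed on the LOD diagonal.
#' @inheritParams estimate_rf
#' @return object of class `pairwise_linkage`: list with `markers` and
#'   symmetric matrices `r` (diagonal 0, NA for uninformative pairs), `lod`
#'   (diagonal `lod_cap`, 0 for uninformative pairs), and logical flip
#'   matrices `flip_lat`, `flip_moy` giving the ML relative phases.
#' @export
pairwise_linkage <- function(calls, classmaps, lod_cap = 50,
                             r_init = 0.25, max_iter = 200, tol = 1e-6) {
  m <- nrow(calls)
  if (m < 2) abort("need at least two markers")
  ids <- rownames(calls)
  classmaps <- classmaps[ids]
  enc <- encode_classmaps(classmaps)
  obs <- encode_observations(calls, classmaps)
  ip <- t(vapply(classmaps, informative_parents, logical(2)))
  pr <- t(combn(m, 2))
  shared <- (ip[pr[, 1], 1] & ip[pr[, 2], 1]) |
            (ip[pr[, 1], 2] & ip[pr[, 2], 2])
  rmat <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  lmat <- matrix(0, m, m, dimnames = list(ids, ids))
  flat <- matrix(FALSE, m, m, dimnames = list(ids, ids))
  fmoy <- flat
  if (any(shared)) {
    use <- pr[shared, , drop = FALSE]
    res <- cpp_pair_em(obs, enc$cmaps, enc$nclasses,
                       use, r_init, max_iter, tol, 1e-6, 0.4999)
    idx <- cbind(use[, 1], use[, 2])
    rmat[idx] <- res$rhat
    lmat[idx] <- pmax(res$lod, 0)
    flat[idx] <- res$flip_lat == 1
    fmoy[idx] <- res$flip_moy == 1
    rmat[idx[, 2:1, drop = FALSE]] <- rmat[idx]
    lmat[idx[, 2:1, drop = FALSE]] <- lmat[idx]
    flat[idx[, 2:1, drop = FALSE]] <- flat[idx]
    fmoy[idx[, 2:1, drop = FALSE]] <- fmoy[idx]
  }
  diag(rmat) <- 0
  diag(lmat) <- lod_cap
  structure(list(markers = ids, r = rmat, lod = lmat,
                 flip_lat = flat, flip_moy = fmoy,
                 informative = ip, lod_cap = lod_cap),
            class = "pairwise_linkage")
}

#' Restrict a pairwise-linkage object to a marker subset
#'
#' @param pw a [pairwise_linkage()] object.
#' @param ids markers to keep.
#' @return a `pairwise_linkage` over `ids`.
#' @export
subset_pairwise <- function(pw, ids) {
  stopifnot(all(ids %in% pw$markers))
  structure(list(markers = ids, r = pw$r[ids, ids], lod = pw$lod[ids, ids],
                 flip_lat = pw$flip_lat[ids, ids],
                 flip_moy = pw$flip_moy[ids, ids],
                 informative = pw$informative[ids, , drop = FALSE],
                 lod_cap = pw$lod_cap),
            class = "pairwise_linkage")
}

#' Markers in the largest linked component
#'
#' Markers only reachable through zero-LOD (uninformative) pairs cannot be
#' placed on a common map; this returns the largest connected component of
#' the positive-LOD graph.
#'
#' @param pw a [pairwise_linkage()] object.
#' @return character vector of marker names.
#' @export
largest_linked_component <- function(pw) {
  lod <- pw$lod
  diag(lod) <- 0
  g <- igraph::graph_from_adjacency_matrix(lod > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  pw$markers[comp$membership == which.max(comp$csize)]
}

#' @export
print.pairwise_linkage <- function(x, ...) {
  cat("<pairwise_linkage> ", length(x$markers), " markers, ",
      sum(x$lod[upper.tri(x$lod)] > 0), " informative pairs\n", sep = "")
  invisible(x)
}
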