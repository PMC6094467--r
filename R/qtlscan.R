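# HMM-based QTL interval mapping: grid genotype probabilities, the LOD
# scan, permutation thresholds, support intervals and the key-parent call,
# plus the neighbour-window comparator used in the profile-smoothness
# simulation study.

#' QTL genotype probabilities on a cM grid
#'
#' Inserts uninformative pseudo-loci at the grid positions and returns
#' forward-backward posteriors of the four inheritance classes there.
#'
#' @param model an `inheritance_model` for the linkage group.
#' @param calls marker x individual call matrix.
#' @param step grid step in cM.
#' @param at optional explicit grid positions (overrides `step`).
#' @return object of class `genotype_probs`: list with `positions` and
#'   `probs` (array positions x 4 x offspring, rows summing to 1).
#' @export
genotype_probs <- function(model, calls, step = 1, at = NULL) {
  grid <- at %||% seq(0, max(model$pos), by = step)
  calls <- calls[model$markers, , drop = FALSE]
  pos_all <- c(model$pos, grid)
  is_pseudo <- c(rep(FALSE, length(model$pos)), rep(TRUE, length(grid)))
  ord <- order(pos_all, is_pseudo)
  nm <- c(model$markers, sprintf("pseudo_%g", grid))[ord]
  cms <- c(model$classmaps,
           rep(list(setNames(rep(NA_character_, 4), STATE_LABELS)),
               length(grid)))[ord]
  names(cms) <- nm
  ext_calls <- rbind(calls,
                     matrix(NA_character_, length(grid), ncol(calls)))[ord, ,
                                                                       drop = FALSE]
  rownames(ext_calls) <- nm
  ext_model <- build_inheritance_model(
    tibble(marker = nm, pos = pos_all[ord]), cms, eps = model$eps,
    map_function = model$map_function)
  fb <- forward_backward(ext_model, ext_calls)
  pseudo_idx <- match(sprintf("pseudo_%g", grid), nm)
  probs <- fb$posterior[pseudo_idx, , , drop = FALSE]
  dimnames(probs)[[1]] <- sprintf("%g", grid)
  structure(list(positions = grid, probs = probs,
                 markers = tibble(marker = model$markers, pos = model$pos)),
            class = "genotype_probs")
}

# Fit the four-class-means model at one position; returns NULL if the
# probability matrix is essentially rank-deficient (< 2).
fit_position <- function(X, y, rss0) {
  qx <- qr(X)
  if (qx$rank < 2) return(NULL)
  cf <- rep(NA_real_, 4)
  fit <- qr.coef(qx, y)
  cf[seq_along(fit)] <- fit
  res <- y - X %*% ifelse(is.na(cf), 0, cf)
  rss1 <- sum(res^2)
  n <- length(y)
  df <- n - qx$rank
  sigma2 <- rss1 / df
  R <- qr.R(qx)[seq_len(qx$rank), seq_len(qx$rank), drop = FALSE]
  pv <- qx$pivot[seq_len(qx$rank)]
  covb <- chol2inv(chol(crossprod(R))) * sigma2
  cov4 <- matrix(NA_real_, 4, 4)
  cov4[pv, pv] <- covb
  se <- rep(NA_real_, 4)
  se[pv] <- sqrt(diag(covb))
  list(lod = (n / 2) * log10(rss0 / rss1),
       pvar = 100 * (1 - rss1 / rss0),
       means = cf, se = se, cov = cov4, rss1 = rss1, df = df)
}

#' HMM interval-mapping scan of one linkage group
#'
#' At each grid position the trait is regressed on the four genotype-class
#' probabilities (class-means parameterization, no separate intercept);
#' LOD = (n/2) log10(RSS0/RSS1) against the overall-mean model and
#' %variance = 100 (1 - RSS1/RSS0).
#'
#' @param probs a [genotype_probs()] object.
#' @param trait named numeric vector (names = offspring); missing values
#'   are dropped listwise.
#' @param lg linkage-group label carried into the result.
#' @param min_n minimum non-missing offspring.
#' @return object of class `qtl_scan`: list with `profile` (tibble: pos,
#'   lod, pvar, mean_AC..mean_BD, se_AC..se_BD), `peak` (one-row tibble
#'   with support intervals, nearest marker and key parent), `n`, `lg`.
#' @export
scan_qtl <- function(probs, trait, lg = NA_character_, min_n = 30) {
  offs <- dimnames(probs$probs)[[3]]
  trait <- trait[offs]
  ok <- !is.na(trait)
  if (sum(ok) < min_n) abort("fewer than min_n offspring with trait values")
  y <- as.numeric(trait[ok])
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 <= 0) abort("trait is constant")
  covs <- list()
  rows <- map(seq_along(probs$positions), function(p) {
    X <- t(probs$probs[p, , ok])
    fit <- fit_position(X, y, rss0)
    if (!is.null(fit))
      covs[[as.character(probs$positions[[p]])]] <<- fit$cov
    if (is.null(fit)) {
      warn(sprintf("skipping rank-deficient position %g cM",
                   probs$positions[[p]]))
      return(NULL)
    }
    tibble(pos = probs$positions[[p]], lod = fit$lod, pvar = fit$pvar,
           mean_AC = fit$means[[1]], mean_AD = fit$means[[2]],
           mean_BC = fit$means[[3]], mean_BD = fit$means[[4]],
           se_AC = fit$se[[1]], se_AD = fit$se[[2]],
           se_BC = fit$se[[3]], se_BD = fit$se[[4]])
  })
  profile <- list_rbind(compact_null(rows))
  peak_i <- which.max(profile$lod)          # leftmost on ties
  peak <- profile[peak_i, ]
  si <- support_intervals(profile, drops = c(1, 2))
  nearest <- if (nrow(probs$markers)) {
    probs$markers$marker[[which.min(abs(probs$markers$pos - peak$pos))]]
  } else NA_character_
  kp <- key_parent(
    means = c(peak$mean_AC, peak$mean_AD, peak$mean_BC, peak$mean_BD),
    ses = c(peak$se_AC, peak$se_AD, peak$se_BC, peak$se_BD),
    df = n - 4, cov = covs[[as.character(peak$pos)]])
  peak <- peak |>
    mutate(lg = lg, n = n,
           lower1 = si$lower[si$drop == 1], upper1 = si$upper[si$drop == 1],
           lower2 = si$lower[si$drop == 2], upper2 = si$upper[si$drop == 2],
           nearest_marker = nearest, key_parent = kp$label)
  structure(list(profile = profile, peak = peak, n = n, lg = lg,
                 key_parent = kp),
            class = "qtl_scan")
}

#' LOD support intervals around a profile peak
#'
#' The maximal contiguous interval containing the (leftmost) peak over
#' which LOD >= peak - drop.
#'
#' @param profile tibble with columns pos and lod.
#' @param drops numeric drops (1- and 2-LOD by convention).
#' @return tibble (drop, lower, upper).
#' @export
support_intervals <- function(profile, drops = c(1, 2)) {
  peak_i <- which.max(profile$lod)
  peak <- profile$lod[[peak_i]]
  list_rbind(map(drops, function(d) {
    ok <- profile$lod >= peak - d
    lo <- peak_i
    while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- peak_i
    while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
    tibble(drop = d, lower = profile$pos[[lo]], upper = profile$pos[[hi]])
  }))
}

#' Which parent's alleles drive a QTL
#'
#' The first parent's contrast is (AC+AD)/2 - (BC+BD)/2 (its homolog
#' substitution), the second parent's (AC+BC)/2 - (AD+BD)/2; each is tested
#' by a t-test on the estimated class means at `alpha`.
#'
#' @param means,ses length-4 class means and standard errors (AC, AD, BC,
#'   BD).
#' @param df residual degrees of freedom.
#' @param alpha test level.
#' @param cov optional 4x4 covariance of the estimated means; when given,
#'   contrast variances account for the (often strong) correlation between
#'   class-mean estimates from soft genotype probabilities.
#' @return list(label in {"Latham","Moy","Both","none"}, p_lat, p_moy).
#' @export
key_parent <- function(means, ses, df, alpha = 0.05, cov = NULL) {
  contrast_p <- function(wts) {
    # restrict to estimable classes (a rank-deficient fit merges classes the
    # marker data cannot separate) and renormalize each side to +/- 1/2
    avail <- !is.na(means)
    w <- ifelse(avail, wts, 0)
    sp <- sum(w[w > 0]); sn <- -sum(w[w < 0])
    if (sp == 0 || sn == 0) return(NA_real_)
    w[w > 0] <- w[w > 0] * 0.5 / sp
    w[w < 0] <- w[w < 0] * 0.5 / sn
    est <- sum(w * means, na.rm = TRUE)
    v <- if (!is.null(cov)) {
      cs <- cov[avail, avail, drop = FALSE]
      if (anyNA(cs)) sum((w * ses)^2, na.rm = TRUE) else
        drop(t(w[avail]) %*% cs %*% w[avail])
    } else sum((w * ses)^2, na.rm = TRUE)
    se <- sqrt(v)
    if (!is.finite(se) || se == 0) return(NA_real_)
    2 * pt(abs(est / se), df, lower.tail = FALSE)
  }
  p_lat <- contrast_p(c(0.5, 0.5, -0.5, -0.5))
  p_moy <- contrast_p(c(0.5, -0.5, 0.5, -0.5))
  sig_lat <- !is.na(p_lat) && p_lat < alpha
  sig_moy <- !is.na(p_moy) && p_moy < alpha
  label <- if (sig_lat && sig_moy) "Both" else if (sig_lat) "Latham" else
    if (sig_moy) "Moy" else {
      warn("neither parental contrast significant at the QTL peak")
      "none"
    }
  list(label = label, p_lat = p_lat, p_moy = p_moy)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the trait across offspring, records the genome-wide maximum LOD
#' per permutation over all linkage groups, and returns the empirical
#' (1 - alpha) quantile.
#'
#' @param probs_list list of [genotype_probs()] objects (one per linkage
#'   group).
#' @param trait named numeric trait vector.
#' @param n_perm number of permutations (>= 20).
#' @param alpha genome-wide significance level.
#' @param seed optional seed for the permutation stream.
#' @return list(threshold, max_lods).
#' @export
permutation_threshold <- function(probs_list, trait, n_perm = 200,
                                  alpha = 0.05, seed = NULL) {
  if (n_perm < 20) abort("n_perm must be at least 20")
  if (!is.null(seed)) set.seed(seed)
  offs <- dimnames(probs_list[[1]]$probs)[[3]]
  trait <- trait[offs]
  ok <- !is.na(trait)
  y <- as.numeric(trait[ok])
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 <= 0)            # constant trait: every LOD is 0
    return(list(threshold = 0, max_lods = rep(0, n_perm)))
  yty <- sum(y^2)
  # thin Q factors per position, stacked per linkage group
  qs <- map(probs_list, function(gp) {
    Qs <- map(seq_along(gp$positions), function(p) {
      X <- t(gp$probs[p, , ok])
      qx <- qr(X)
      if (qx$rank < 2) return(NULL)
      qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    })
    Qs <- compact_null(Qs)
    list(Q = do.call(cbind, Qs),
         idx = rep(seq_along(Qs), vapply(Qs, ncol, 1L)))
  })
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  max_lods <- rep(-Inf, n_perm)
  for (q in qs) {
    M <- crossprod(q$Q, Y)                   # (sum rank) x n_perm
    ssfit <- rowsum(M^2, q$idx)              # positions x n_perm
    rss1 <- pmax(yty - ssfit, 1e-12)
    lod <- (n / 2) * log10(rss0 / rss1)
    max_lods <- pmax(max_lods, apply(lod, 2, max))
  }
  list(threshold = unname(quantile(max_lods, 1 - alpha)),
       max_lods = max_lods)
}

#' Neighbour-window genotype probabilities (local comparator)
#'
#' Computes grid genotype probabilities from only the `k` nearest
#' non-missing markers around each position (by map distance), ignoring
#' everything beyond the window -- the way default interval-mapping
#' software computes QTL genotype probabilities from up to five
#' neighbouring markers.  On maps where most markers segregate from one
#' parent the window often carries no information about the other parent,
#' which reproduces the characteristically irregular LOD profile of that
#' approach.
#'
#' @param model an `inheritance_model`.
#' @param calls marker x individual call matrix.
#' @param k total number of neighbouring markers used.
#' @param step grid step in cM.
#' @return a `genotype_probs` object.
#' @export
neighbor_window_probs <- function(model, calls, k = 5, step = 1) {
  calls <- calls[model$markers, , drop = FALSE]
  grid <- seq(0, max(model$pos), by = step)
  o <- ncol(calls)
  offs <- colnames(calls)
  probs <- array(NA_real_, c(length(grid), 4, o),
                 dimnames = list(sprintf("%g", grid), STATE_LABELS, offs))
  miss <- is.na(calls)
  for (p in seq_along(grid)) {
    g <- grid[[p]]
    window_of <- function(nonmiss) {
      avail <- which(nonmiss)
      avail[order(abs(model$pos[avail] - g))] |> head(k) |> sort()
    }
    keys <- vapply(seq_len(o), function(j) {
      paste(window_of(!miss[, j]), collapse = ",")
    }, character(1))
    for (key in unique(keys)) {
      js <- which(keys == key)
      idx <- as.integer(strsplit(key, ",")[[1]])
      if (!length(idx)) {
        probs[p, , js] <- 0.25
        next
      }
      sub_model <- build_inheritance_model(
        tibble(marker = model$markers[idx], pos = model$pos[idx]),
        model$classmaps[idx], eps = model$eps,
        map_function = model$map_function)
      gp <- genotype_probs(sub_model, calls[idx, js, drop = FALSE], at = g)
      probs[p, , js] <- gp$probs[1, , ]
    }
  }
  structure(list(positions = grid, probs = probs,
                 markers = tibble(marker = model$markers, pos = model$pos)),
            class = "genotype_probs")
}

#' Mean absolute second difference of a LOD profile
#'
#' The profile-roughness measure used to compare scan methods.
#'
#' @param lod numeric LOD values on an equally spaced grid.
#' @return mean |second difference|.
#' @export
profile_roughness <- function(lod) {
  mean(abs(diff(lod, differences = 2)))
}
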