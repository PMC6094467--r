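# Independent oracles used across tests.  These deliberately reimplement
# quantities by brute force (enumeration / grid search) so that the fast
# implementation paths are checked against something that shares no code
# with them.

# Pure-R log-likelihood of one marker pair at recombination fraction r,
# under a given relative phase (flip of either parent at marker 2).
# Works on the cross-tab of observed class pairs, so the grid search stays
# cheap while remaining independent of the EM implementation.
pair_loglik_r <- function(c1, c2, cm1, cm2, r, flip_lat = FALSE,
                          flip_moy = FALSE) {
  sm <- vapply(1:4, function(s) {
    l <- (s - 1) %/% 2; m <- (s - 1) %% 2
    if (flip_lat) l <- 1 - l
    if (flip_moy) m <- 1 - m
    2 * l + m + 1
  }, numeric(1))
  key <- paste(ifelse(is.na(c1), ".", c1), ifelse(is.na(c2), ".", c2))
  tab <- table(key)
  ll <- 0
  for (nm in names(tab)) {
    parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
    p <- 0
    for (s1 in 1:4) {
      e1 <- parts[1] == "." || (!is.na(cm1[s1]) && cm1[s1] == parts[1])
      if (!e1) next
      for (s2 in 1:4) {
        e2 <- parts[2] == "." ||
          (!is.na(cm2[sm[s2]]) && cm2[sm[s2]] == parts[2])
        if (!e2) next
        d <- ((s1 - 1) %/% 2 != (s2 - 1) %/% 2) +
             ((s1 - 1) %% 2 != (s2 - 1) %% 2)
        p <- p + 0.25 * r^d * (1 - r)^(2 - d)
      }
    }
    ll <- ll + tab[[nm]] * log(p)
  }
  ll
}

# Grid-search MLE of r over all four phases (coarse pass then refinement).
grid_rf_mle <- function(c1, c2, cm1, cm2) {
  best <- list(ll = -Inf, r = NA)
  for (fl in c(FALSE, TRUE)) for (fm in c(FALSE, TRUE)) {
    coarse <- seq(0.001, 0.499, by = 0.01)
    lls <- vapply(coarse, function(r)
      pair_loglik_r(c1, c2, cm1, cm2, r, fl, fm), 1)
    r0 <- coarse[which.max(lls)]
    fine <- seq(max(0.0005, r0 - 0.015), min(0.4995, r0 + 0.015), by = 0.0005)
    lls2 <- vapply(fine, function(r)
      pair_loglik_r(c1, c2, cm1, cm2, r, fl, fm), 1)
    i <- which.max(lls2)
    if (lls2[i] > best$ll) best <- list(ll = lls2[i], r = fine[i])
  }
  best
}

# Exhaustive-enumeration forward likelihood and posteriors for an
# inheritance HMM with m loci (4^m state paths).
enumerate_hmm <- function(model, obs_calls) {
  m <- length(model$markers)
  Ts <- lapply(model$rk, gbsqtl:::transition_matrix)
  emis <- function(t, s, call) {
    if (is.na(call)) return(1)
    cls <- gbsqtl:::marker_classes(model$classmaps[[t]])
    K <- length(cls)
    oc <- match(call, cls)
    if (is.na(oc)) return(1)
    if (!is.na(model$classmaps[[t]][s]) &&
        model$classmaps[[t]][s] == cls[oc]) 1 - model$eps else
      if (K > 1) model$eps / (K - 1) else model$eps
  }
  paths <- as.matrix(expand.grid(rep(list(1:4), m)))
  tot <- 0
  post <- matrix(0, m, 4)
  best <- list(p = -1, path = NULL)
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    p <- 0.25
    for (t in seq_len(m)) {
      if (t > 1) p <- p * Ts[[t - 1]][s[t - 1], s[t]]
      p <- p * emis(t, s[t], obs_calls[t])
    }
    tot <- tot + p
    for (t in seq_len(m)) post[t, s[t]] <- post[t, s[t]] + p
    if (p > best$p) best <- list(p = p, path = s)
  }
  list(loglik = log(tot), posterior = post / tot, viterbi = best$path,
       viterbi_prob = best$p)
}

# Deterministic spaced marker set with explicit phases, handy for HMM and
# order-improvement tests.
spaced_markers <- function(n, spacing = 2, types = "ABxAA", seed = 1) {
  withr::with_seed(seed, {
    type <- rep_len(types, n)
    ph <- t(vapply(type, gbsqtl:::phase_alleles_for_type, character(4)))
    tibble::tibble(
      marker = sprintf("m%03d", seq_len(n)), lg = "LG1",
      pos = (seq_len(n) - 1) * spacing, type = type,
      lat1 = ph[, 1], lat2 = ph[, 2], moy1 = ph[, 3], moy2 = ph[, 4],
      classmap = purrr::pmap(list(ph[, 1], ph[, 2], ph[, 3], ph[, 4]),
                             classmap_from_alleles))
  })
}

# Log joint probability of one specific state path given observations.
path_logprob <- function(model, obs_calls, path) {
  Ts <- lapply(model$rk, gbsqtl:::transition_matrix)
  lp <- log(0.25)
  for (t in seq_along(path)) {
    if (t > 1) lp <- lp + log(Ts[[t - 1]][path[t - 1], path[t]])
    call <- obs_calls[t]
    if (!is.na(call)) {
      cls <- gbsqtl:::marker_classes(model$classmaps[[t]])
      K <- length(cls)
      hit <- !is.na(model$classmaps[[t]][path[t]]) &&
        model$classmaps[[t]][path[t]] == call
      lp <- lp + log(if (hit) 1 - model$eps else
        if (K > 1) model$eps / (K - 1) else model$eps)
    }
  }
  lp
}
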