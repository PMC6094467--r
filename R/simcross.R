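# Synthetic outbred-F1 crosses with GbS-style read counts.
#
# The generator emulates the statistical structure of the Glen Moy x Latham
# raspberry population: ~184 offspring, seven linkage groups of 85-130 cM,
# and a strongly imbalanced marker composition (most markers heterozygous in
# one parent only), including the two null-allele configurations.  Depths
# are negative binomial, scaled by a per-individual library-size factor and
# by the number of amplifiable haplotypes: an AO genotype runs at half the
# AA depth and OO yields no reads.

#' Configuration for a synthetic cross
#'
#' Defaults reproduce the reference population's structure: 184 offspring,
#' seven linkage groups with the published map lengths, and the imbalanced
#' marker-type composition reported for LG2 (62% heterozygous in the first
#' parent only, 20% in the second only, 18% other types, here split
#' 8% ABxAB, 7% ABxAO and 3% AOxBO).
#'
#' @param n_offspring number of offspring.
#' @param lg_lengths named numeric vector of linkage-group lengths in cM.
#' @param n_markers markers per linkage group (recycled).
#' @param type_proportions named proportions over the segregation types
#'   ABxAA, AAxAB, ABxAB, ABxAO, AOxBO (must sum to 1; ABxAO is split at
#'   random between the two orientations ABxAO and AOxAB).
#' @param mean_depth mean reads per individual per SNP.
#' @param depth_dispersion negative-binomial size parameter per haplotype
#'   (smaller = more overdispersed).
#' @param depth_sdlog SD (log scale) of the per-individual library-size
#'   factor.  GbS libraries differ strongly in read yield between
#'   individuals; this spread is what elongates the heterozygote cluster
#'   along the inclined line and makes the functional-regression fit
#'   identifiable.  Parents receive a fixed size factor of 4 (they are
#'   sequenced repeatedly in practice).
#' @param error_rate probability a read reports the wrong allele.
#' @param missing_rate probability a call is dropped to (0, 0) regardless of
#'   genotype (library failure etc.).
#' @param map_function "haldane" (default) or "kosambi".
#' @param qtl list of QTL specifications from [qtl_spec()].
#' @param seed integer seed, or NULL.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_offspring = 184,
                       lg_lengths = c(LG1 = 114.1, LG2 = 107.1, LG3 = 128.2,
                                      LG4 = 91.5, LG5 = 85.4, LG6 = 88.6,
                                      LG7 = 100.2),
                       n_markers = 100,
                       type_proportions = c(ABxAA = 0.62, AAxAB = 0.20,
                                            ABxAB = 0.08, ABxAO = 0.07,
                                            AOxBO = 0.03),
                       mean_depth = 30,
                       depth_dispersion = 5,
                       depth_sdlog = 0.4,
                       error_rate = 0.01,
                       missing_rate = 0.02,
                       map_function = c("haldane", "kosambi"),
                       qtl = list(),
                       seed = NULL) {
  map_function <- match.arg(map_function)
  stopifnot(n_offspring >= 1, all(lg_lengths > 0), mean_depth > 0,
            depth_dispersion > 0, missing_rate >= 0, missing_rate < 1)
  if (error_rate < 0 || error_rate >= 0.5)
    abort("error_rate must lie in [0, 0.5)")
  stopifnot(depth_sdlog >= 0)
  need <- c("ABxAA", "AAxAB", "ABxAB", "ABxAO", "AOxBO")
  if (!setequal(names(type_proportions), need))
    abort("type_proportions must be named over ABxAA, AAxAB, ABxAB, ABxAO, AOxBO")
  type_proportions <- type_proportions[need]
  if (abs(sum(type_proportions) - 1) > 1e-9)
    abort("type_proportions must sum to 1")
  if (is.null(names(lg_lengths)))
    names(lg_lengths) <- paste0("LG", seq_along(lg_lengths))
  n_markers <- rep_len(n_markers, length(lg_lengths))
  structure(list(n_offspring = as.integer(n_offspring),
                 lg_lengths = lg_lengths, n_markers = n_markers,
                 type_proportions = type_proportions,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 depth_sdlog = depth_sdlog,
                 error_rate = error_rate, missing_rate = missing_rate,
                 map_function = map_function, qtl = qtl, seed = seed),
            class = "sim_config")
}

#' Balanced-map counterpart of the default configuration
#'
#' A blackcurrant-like composition with similar numbers of markers
#' heterozygous in each parent (28% / 28% / 44% other types, split
#' 24% ABxAB, 14% ABxAO, 6% AOxBO), used for the balanced-map
#' simulation study.
#'
#' @inheritParams sim_config
#' @param ... passed to [sim_config()].
#' @export
sim_config_balanced <- function(lg_lengths = c(LG1 = 100), ...) {
  sim_config(lg_lengths = lg_lengths,
             type_proportions = c(ABxAA = 0.28, AAxAB = 0.28, ABxAB = 0.24,
                                  ABxAO = 0.14, AOxBO = 0.06), ...)
}

#' Configuration for the QTL-mapping simulation study
#'
#' Two study designs: "imbalanced" places a single additive QTL at 67 cM on
#' an LG2-like group (107.1 cM, 62/20/18 marker composition, mostly
#' first-parent markers); "balanced" places the same-sized QTL at 29 cM on
#' a blackcurrant-like group (28/28/44 composition).  Marker data are
#' complete: no genotyping error, no missing values, no distortion.  The
#' QTL explains ~15% of the trait variance (the size of the PCO4 ripening
#' QTL), acting through the first parent.
#'
#' @param map "imbalanced" or "balanced".
#' @param n_markers markers on the simulated group.
#' @param pvar QTL size as a proportion of trait variance.
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
qtl_study_config <- function(map = c("imbalanced", "balanced"),
                             n_markers = 200, pvar = 0.15, seed = NULL) {
  map <- match.arg(map)
  means <- qtl_means_for_pvar(pvar, parent = "lat")
  if (map == "imbalanced") {
    sim_config(lg_lengths = c(LG2 = 107.1), n_markers = n_markers,
               error_rate = 0, missing_rate = 0,
               qtl = list(qtl_spec("LG2", 67, means)), seed = seed)
  } else {
    sim_config_balanced(lg_lengths = c(LG1 = 100), n_markers = n_markers,
                        error_rate = 0, missing_rate = 0,
                        qtl = list(qtl_spec("LG1", 29, means)), seed = seed)
  }
}

#' Specify a simulated QTL
#'
#' @param lg linkage-group name.
#' @param pos position in cM (must lie on the group).
#' @param means named numeric vector of the four genotype-class means
#'   (AC, AD, BC, BD).
#' @param sd residual (environmental) standard deviation.
#' @return a `qtl_spec` list.
#' @export
qtl_spec <- function(lg, pos, means, sd = 1) {
  stopifnot(length(means) == 4)
  if (is.null(names(means))) names(means) <- STATE_LABELS
  means <- means[STATE_LABELS]
  structure(list(lg = lg, pos = pos, means = means, sd = sd),
            class = "qtl_spec")
}

#' Class means for a QTL explaining a target fraction of variance
#'
#' Returns additive class means for the chosen key parent such that, with
#' residual SD `sd`, the QTL explains approximately `pvar` of the trait
#' variance (between-class variance d^2/4 against total d^2/4 + sd^2).
#'
#' @param pvar target proportion of variance explained (e.g. 0.15).
#' @param sd residual SD.
#' @param parent "lat", "moy" or "both" (equal effects from each parent).
#' @return named numeric vector of class means (AC, AD, BC, BD).
#' @export
qtl_means_for_pvar <- function(pvar, sd = 1, parent = c("lat", "moy", "both")) {
  parent <- match.arg(parent)
  v <- pvar / (1 - pvar) * sd^2
  if (parent == "both") {
    d <- sqrt(v / 2) * 2   # two independent contrasts, each d^2/4 = v/2
    m <- c(0, d / 2, d / 2, d) - d / 2
  } else {
    d <- 2 * sqrt(v)
    m <- if (parent == "lat") c(0, 0, d, d) - d / 2 else c(0, d, 0, d) - d / 2
  }
  setNames(m, STATE_LABELS)
}

#' Simulate marker positions, types and phases
#'
#' Marker positions are uniform on each linkage group, types drawn with the
#' configured proportions, and the assignment of alleles to parental
#' homologs (the phase) randomized and recorded.
#'
#' @param config a [sim_config()].
#' @return tibble with one row per marker: marker, lg, pos, type, phased
#'   alleles lat1, lat2, moy1, moy2, and a `classmap` list-column.
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$n_markers < 1)) abort("every linkage group needs >= 1 marker")
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$type_proportions
  types_all <- c("ABxAA", "AAxAB", "ABxAB", "ABxAO", "AOxAB", "AOxBO")
  probs <- c(p[["ABxAA"]], p[["AAxAB"]], p[["ABxAB"]],
             p[["ABxAO"]] / 2, p[["ABxAO"]] / 2, p[["AOxBO"]])
  res <- imap(as.list(config$lg_lengths), function(len, lg) {
    k <- config$n_markers[[match(lg, names(config$lg_lengths))]]
    pos <- sort(runif(k, 0, len))
    type <- sample(types_all, k, replace = TRUE, prob = probs)
    ph <- t(vapply(type, phase_alleles_for_type, character(4)))
    tibble(marker = sprintf("s%s_%03d", sub("^LG", "", lg), seq_len(k)),
           lg = lg, pos = pos, type = type,
           lat1 = ph[, 1], lat2 = ph[, 2], moy1 = ph[, 3], moy2 = ph[, 4])
  })
  out <- list_rbind(res)
  out$classmap <- pmap(out[c("lat1", "lat2", "moy1", "moy2")],
                       classmap_from_alleles)
  out
}

phase_alleles_for_type <- function(type) {
  pair <- function(a) sample(a, 2L)
  switch(type,
    ABxAA = c(pair(c("A", "B")), "A", "A"),
    AAxAB = c("A", "A", pair(c("A", "B"))),
    ABxAB = c(pair(c("A", "B")), pair(c("A", "B"))),
    ABxAO = c(pair(c("A", "B")), pair(c("A", "O"))),
    AOxAB = c(pair(c("A", "O")), pair(c("A", "B"))),
    AOxBO = c(pair(c("A", "O")), pair(c("B", "O"))))
}

#' Simulate meioses along the map
#'
#' For each offspring and parent, the inherited homolog is a two-state
#' Markov chain along the ordered positions: between loci d cM apart the
#' homolog switches with probability given by the inverse map function
#' (Haldane: r = (1 - exp(-2d/100))/2), independently in the two parents
#' (sex-averaged recombination, no interference under Haldane).
#'
#' @param markers tibble from [simulate_map()] (columns lg, pos).
#' @param n_offspring number of offspring meioses to draw.
#' @param map_function "haldane" or "kosambi".
#' @param extra_positions optional named list (by lg) of additional cM
#'   positions (e.g. QTLs) at which inheritance is recorded.
#' @return object of class `inheritance_truth`: per linkage group a list
#'   with `pos`, `marker` (NA for extra positions), and integer matrices
#'   `lat`, `moy` (positions x offspring, values 1/2).
#' @export
simulate_meioses <- function(markers, n_offspring,
                             map_function = c("haldane", "kosambi"),
                             extra_positions = NULL) {
  map_function <- match.arg(map_function)
  out <- lapply(split(markers, markers$lg), function(mk) {
    mk <- mk[order(mk$pos), ]
    lg <- mk$lg[[1]]
    pos <- mk$pos
    name <- mk$marker
    ex <- extra_positions[[lg]]
    if (length(ex)) {
      pos <- c(pos, ex)
      name <- c(name, rep(NA_character_, length(ex)))
      o <- order(pos)
      pos <- pos[o]; name <- name[o]
    }
    r <- distance_to_rf(diff(pos), map_function)
    draw <- function() {
      g <- matrix(1L, length(pos), n_offspring)
      g[1, ] <- sample(1:2, n_offspring, replace = TRUE)
      if (length(r)) {
        sw <- matrix(rbinom(length(r) * n_offspring, 1L, rep(r, n_offspring)),
                     length(r), n_offspring)
        csw <- matrix(apply(sw, 2, cumsum), length(r), n_offspring)
        g[-1, ] <- 1L + (g[rep(1, length(r)), ] + csw + 1L) %% 2L
      }
      g
    }
    list(lg = lg, pos = pos, marker = name, lat = draw(), moy = draw())
  })
  out <- out[unique(markers$lg)]
  structure(out, n_offspring = n_offspring, class = "inheritance_truth")
}

# Inheritance state index (1..4 for AC, AD, BC, BD) at each recorded
# position of one linkage group.
state_index <- function(truth_lg) {
  2L * (truth_lg$lat - 1L) + truth_lg$moy
}

#' Emit read-count observations for simulated markers
#'
#' Per individual and SNP the read depth is negative binomial with mean
#' `mean_depth` times the individual's library-size factor, scaled by the
#' number of amplifiable haplotypes: null (O) alleles contribute no reads,
#' so AO genotypes run at half the AA depth and OO genotypes yield zero
#' reads (missing downstream).  For a heterozygote the major-allele count
#' is binomial(depth, 1/2); for a homozygote all reads carry its allele
#' except errors at rate `error_rate`.  Parents ("Latham", "Moy") are
#' emitted alongside offspring.
#'
#' @param truth an `inheritance_truth`.
#' @param markers tibble from [simulate_map()].
#' @param config the [sim_config()].
#' @return list with `counts` (long tibble: snp_id, lg, quality, individual,
#'   major, minor), `true_calls` (marker x individual character matrix of
#'   true phenotype classes, offspring only) and `individuals`.
#' @export
emit_observations <- function(truth, markers, config) {
  o <- attr(truth, "n_offspring")
  offspring <- sprintf("off%03d", seq_len(o))
  eps <- config$error_rate
  sdl <- config$depth_sdlog %||% 0
  # per-individual library-size factors; parents sequenced ~4x deeper
  size_f <- c(4, 4, exp(rnorm(o, -sdl^2 / 2, sdl)))
  rows <- list()
  true_calls <- list()
  for (lg in names(truth)) {
    tl <- truth[[lg]]
    keep <- !is.na(tl$marker)
    mk <- markers[match(tl$marker[keep], markers$marker), ]
    lat_h <- tl$lat[keep, , drop = FALSE]
    moy_h <- tl$moy[keep, , drop = FALSE]
    for (i in seq_len(nrow(mk))) {
      al_lat <- c(mk$lat1[[i]], mk$lat2[[i]])[lat_h[i, ]]
      al_moy <- c(mk$moy1[[i]], mk$moy2[[i]])[moy_h[i, ]]
      # parents first: Latham carries lat1/lat2, Moy moy1/moy2
      a1 <- c(mk$lat1[[i]], mk$moy1[[i]], al_lat)
      a2 <- c(mk$lat2[[i]], mk$moy2[[i]], al_moy)
      n <- length(a1)
      n_active <- (a1 != "O") + (a2 != "O")
      depth <- rnbinom(n, mu = config$mean_depth * size_f * n_active / 2,
                       size = config$depth_dispersion) * (n_active > 0)
      het <- a1 != a2 & n_active == 2
      p_major <- ifelse(het, 0.5,
                        ifelse(a1 == "A" | a2 == "A", 1 - eps, eps))
      major <- rbinom(n, depth, p_major)
      minor <- depth - major
      # parents (first two entries) are pooled from several runs and are
      # not subject to single-library dropout
      drop <- runif(n) < config$missing_rate & c(FALSE, FALSE, rep(TRUE, o))
      major[drop] <- 0L; minor[drop] <- 0L
      qual <- round(sum(major + minor) * rgamma(1, shape = 20, rate = 4))
      rows[[length(rows) + 1L]] <- tibble(
        snp_id = mk$marker[[i]], lg = lg, quality = qual,
        individual = c("Latham", "Moy", offspring),
        major = as.integer(major), minor = as.integer(minor))
      true_calls[[mk$marker[[i]]]] <- phenotype_of(al_lat, al_moy)
    }
  }
  tc <- do.call(rbind, true_calls)
  colnames(tc) <- offspring
  list(counts = list_rbind(rows), true_calls = tc,
       individuals = c("Latham", "Moy", offspring))
}

#' Simulate a quantitative trait with known QTLs
#'
#' The trait is the sum, over QTLs, of the class mean of the offspring's
#' inheritance state (AC/AD/BC/BD) at the QTL position, plus Gaussian noise
#' with the specification's residual SD (a single residual draw; SDs add in
#' quadrature across QTLs).
#'
#' @param truth an `inheritance_truth` that records the QTL positions.
#' @param qtl list of [qtl_spec()]s.
#' @return tibble (individual, trait) with attribute `r2_true`, the realized
#'   R^2 of the trait on the true QTL states.
#' @export
simulate_trait <- function(truth, qtl) {
  o <- attr(truth, "n_offspring")
  total <- numeric(o)
  sd2 <- 0
  states <- list()
  for (q in qtl) {
    tl <- truth[[q$lg]]
    if (is.null(tl)) abort(paste0("QTL linkage group ", q$lg, " not simulated"))
    j <- which(abs(tl$pos - q$pos) < 1e-9)
    if (!length(j)) abort("QTL position was not recorded in the meioses")
    st <- state_index(tl)[j[[1]], ]
    total <- total + q$means[st]
    sd2 <- sd2 + q$sd^2
    states[[length(states) + 1L]] <- st
  }
  y <- total + rnorm(o, 0, sqrt(sd2))
  r2 <- if (length(states)) {
    f <- interaction(as.data.frame(states))
    fitted <- ave(y, f)
    1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  } else NA_real_
  out <- tibble(individual = sprintf("off%03d", seq_len(o)), trait = y)
  attr(out, "r2_true") <- r2
  out
}

#' Simulate plot-level ripening score profiles
#'
#' Scores on the 1-7 developmental scale (1 = bud break ... 7 = over-ripe)
#' are produced by thresholding a latent logistic progression: plot i
#' reaches stage s at day mid_i + scale * qlogis((s - 1.5)/6), where mid_i
#' shifts with the offspring's QTL state (class means interpreted as day
#' shifts) plus plot-level noise.  Scores are non-decreasing in time by
#' construction.
#'
#' @param truth an `inheritance_truth` recording the QTL positions.
#' @param qtl list of [qtl_spec()]s whose class means are timing shifts in
#'   days (their `sd` is ignored; use `plot_sd`).
#' @param dates numeric vector of increasing scoring days.
#' @param n_rep replicate plots per offspring genotype (>= 2).
#' @param base_mid day at which an unshifted plot is midway through ripening.
#' @param scale logistic time scale (days).
#' @param plot_sd SD of the plot-level timing noise in days.
#' @return long tibble: plot, individual, date, score.
#' @export
simulate_ripening_profiles <- function(truth, qtl, dates, n_rep = 2,
                                       base_mid = 40, scale = 8,
                                       plot_sd = 1) {
  stopifnot(all(diff(dates) > 0), n_rep >= 1)
  o <- attr(truth, "n_offspring")
  shift <- numeric(o)
  for (q in qtl) {
    tl <- truth[[q$lg]]
    j <- which(abs(tl$pos - q$pos) < 1e-9)
    if (!length(j)) abort("QTL position was not recorded in the meioses")
    shift <- shift + q$means[state_index(tl)[j[[1]], ]]
  }
  stages <- 2:7
  thresh <- qlogis((stages - 1.5) / 6)
  rows <- lapply(seq_len(o), function(i) {
    mids <- base_mid + shift[[i]] + rnorm(n_rep, 0, plot_sd)
    list_rbind(lapply(seq_len(n_rep), function(rr) {
      cross <- mids[[rr]] + scale * thresh
      score <- vapply(dates, function(t) 1L + sum(cross <= t), integer(1))
      tibble(plot = sprintf("off%03d_p%d", i, rr),
             individual = sprintf("off%03d", i),
             date = dates, score = score)
    }))
  })
  list_rbind(rows)
}

#' Simulate a complete cross
#'
#' Convenience wrapper: map, meioses (including QTL positions), read-count
#' observations and traits, under the configuration's seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cross` with elements `config`, `markers`,
#'   `truth`, `counts`, `true_calls`, `individuals`, and `trait` (NULL if no
#'   QTLs configured).
#' @export
simulate_cross <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  markers <- simulate_map(config)
  extra <- NULL
  if (length(config$qtl)) {
    extra <- lapply(split(config$qtl, vapply(config$qtl, `[[`, "", "lg")),
                    function(qs) vapply(qs, `[[`, 0, "pos"))
    for (lg in names(extra)) {
      len <- config$lg_lengths[[lg]]
      if (is.null(len) || any(extra[[lg]] < 0 | extra[[lg]] > len))
        abort("QTL position lies off the simulated map")
    }
  }
  truth <- simulate_meioses(markers, config$n_offspring, config$map_function,
                            extra_positions = extra)
  obs <- emit_observations(truth, markers, config)
  trait <- if (length(config$qtl)) simulate_trait(truth, config$qtl)
  structure(c(list(config = config, markers = markers, truth = truth,
                   trait = trait), obs),
            class = "sim_cross")
}
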