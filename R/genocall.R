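# Read-support filtering and genotype calling from allele read counts.

#' Filter SNPs on read support, quality and heterozygosity
#'
#' Applies the three pre-mapping filters: (i) retain only SNPs averaging at
#' least `min_mean_depth` reads per individual (for 184 offspring and the
#' default of 10 this equals a total read count of at least 1840); (ii)
#' retain only SNPs with quality score >= `min_quality`; (iii) remove SNPs
#' whose provisional heterozygosity is >= `max_het` percent.  A provisional
#' heterozygote is an individual with both alleles seen at >= 2 reads, among
#' individuals with at least 2 reads in total.
#'
#' @param counts long count tibble (snp_id, quality, individual, major,
#'   minor); parent rows are excluded from the depth and heterozygosity
#'   computations.
#' @param n_individuals number of offspring used for the mean-depth rule.
#' @param parents individual labels treated as parents.
#' @param min_mean_depth,min_quality,max_het filter thresholds.
#' @return the retained rows of `counts`, with an attribute
#'   `filter_summary` tabulating removals per rule.
#' @export
filter_snps <- function(counts, n_individuals,
                        parents = c("Latham", "Moy"),
                        min_mean_depth = 10, min_quality = 10000,
                        max_het = 90) {
  if (n_individuals <= 0) abort("n_individuals must be positive")
  off <- counts[!counts$individual %in% parents, ]
  per <- off |>
    group_by(.data$snp_id) |>
    summarise(
      total = sum(.data$major + .data$minor),
      quality = .data$quality[[1]],
      het = {
        tot <- .data$major + .data$minor
        denom <- sum(tot >= 2)
        if (denom == 0) 0 else
          100 * sum(.data$major >= 2 & .data$minor >= 2) / denom
      },
      .groups = "drop") |>
    mutate(pass_depth = .data$total >= min_mean_depth * n_individuals,
           pass_quality = .data$quality >= min_quality,
           pass_het = .data$het < max_het)
  keep <- per$snp_id[per$pass_depth & per$pass_quality & per$pass_het]
  out <- counts[counts$snp_id %in% keep, ]
  attr(out, "filter_summary") <- c(
    n_in = nrow(per),
    fail_depth = sum(!per$pass_depth),
    fail_quality = sum(!per$pass_quality),
    fail_het = sum(!per$pass_het),
    n_out = length(keep))
  out
}

# Errors-in-both-variables (orthogonal/Deming, error-variance ratio 1) line.
deming_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- if (abs(sxy) < 1e-12) {
    if (syy >= sxx) 1e6 else 0
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  list(slope = slope, intercept = my - slope * mx)
}

#' Fit the inclined heterozygote line for one SNP
#'
#' Fits a functional-regression (orthogonal, unit error-variance ratio) line
#' through the presumed heterozygotes on square-root count axes; the square
#' root stabilises the count variance and the orthogonal fit recognises
#' random variation in both counts.  The heterozygote seed set (minor-allele
#' fraction within `seed_band`, total reads >= 4) is refined by iterating
#' fit -> classify -> refit to convergence.
#'
#' @param major,minor integer read counts for one SNP across individuals.
#' @param seed_band minor-fraction window for the initial heterozygote set.
#' @param min_het minimum number of heterozygote candidates (both counts
#'   >= 2) required; below this the SNP is unclassifiable.
#' @param max_iter,tol refinement control (change in slope).
#' @return list(slope, intercept, n_het, iterations) or NULL if
#'   unclassifiable.
#' @export
fit_het_line <- function(major, minor, seed_band = c(0.15, 0.85),
                         min_het = 5, max_iter = 10, tol = 1e-6) {
  tot <- major + minor
  frac <- ifelse(tot > 0, minor / tot, NA_real_)
  het <- !is.na(frac) & frac >= seed_band[[1]] & frac <= seed_band[[2]] &
    tot >= 4
  if (sum(het & major >= 2 & minor >= 2) < min_het) return(NULL)
  fit <- deming_fit(sqrt(major[het]), sqrt(minor[het]))
  for (it in seq_len(max_iter)) {
    calls <- classify_offspring(major, minor, fit)
    het2 <- !is.na(calls) & calls == "AB" & major >= 2 & minor >= 2
    if (sum(het2) < min_het) break
    new <- deming_fit(sqrt(major[het2]), sqrt(minor[het2]))
    done <- abs(new$slope - fit$slope) < tol
    fit <- new
    het <- het2
    if (done) break
  }
  list(slope = fit$slope, intercept = fit$intercept,
       n_het = sum(het), iterations = it)
}

#' Classify individuals at one SNP from read counts
#'
#' Each individual is classified as AA, BB or AB according to whether its
#' square-root count point lies closest (perpendicular distance) to the
#' horizontal axis, the vertical axis, or the inclined heterozygote line.
#' Individuals with both counts <= 1 are missing.  Distance ties break
#' toward AB (conservative for linkage).
#'
#' @param major,minor read counts.
#' @param line fit from [fit_het_line()].
#' @return character vector of calls in {"AA","AB","BB"} or NA.
#' @export
classify_offspring <- function(major, minor, line) {
  x <- sqrt(major); y <- sqrt(minor)
  d_aa <- y                                     # horizontal axis (minor ~ 0)
  d_bb <- x                                     # vertical axis (major ~ 0)
  d_ab <- abs(line$slope * x - y + line$intercept) /
    sqrt(1 + line$slope^2)
  d <- cbind(AB = d_ab, AA = d_aa, BB = d_bb)   # AB first: ties go to AB
  call <- colnames(d)[max.col(-d, ties.method = "first")]
  call[major <= 1 & minor <= 1] <- NA_character_
  call
}

#' Assess a SNP's genotype classification
#'
#' The per-individual major-allele proportion is regressed on the genotype
#' class and R^2 (percent variance explained) computed.  The classification
#' is rejected if it is monomorphic among offspring, if R^2 < 50, or if the
#' offspring classes are clearly incompatible with the parental calls
#' (unless the pattern matches a null-allele configuration, which is flagged
#' rather than rejected).
#'
#' @param calls offspring calls (character, NA = missing).
#' @param major,minor offspring read counts (same order).
#' @param parent_calls length-2 character vector (first parent, second
#'   parent), NA allowed.
#' @param min_r2 rejection threshold in percent.
#' @param min_called minimum non-missing offspring.
#' @return list(accept, r2, reason) where reason is "" when accepted or one
#'   of "too_few_calls", "monomorphic", "low_r2", "incompatible".
#' @export
assess_classification <- function(calls, major, minor, parent_calls,
                                  min_r2 = 50, min_called = 20) {
  ok <- !is.na(calls)
  if (sum(ok) < min_called)
    return(list(accept = FALSE, r2 = NA_real_, reason = "too_few_calls"))
  classes <- class_table(calls)
  if (length(classes) < 2)
    return(list(accept = FALSE, r2 = NA_real_, reason = "monomorphic"))
  tot <- major + minor
  pa <- ifelse(tot > 0, major / tot, NA_real_)
  use <- ok & !is.na(pa)
  fitted <- ave(pa[use], calls[use])
  sst <- sum((pa[use] - mean(pa[use]))^2)
  r2 <- if (sst > 0) 100 * (1 - sum((pa[use] - fitted)^2) / sst) else 0
  if (r2 < min_r2)
    return(list(accept = FALSE, r2 = r2, reason = "low_r2"))
  if (incompatible_with_parents(names(classes), parent_calls))
    return(list(accept = FALSE, r2 = r2, reason = "incompatible"))
  list(accept = TRUE, r2 = r2, reason = "")
}

# Offspring classes with supported frequency (ignores classes explainable
# as rare miscalls: <= max(2, 1% of called offspring)).
class_table <- function(calls) {
  tab <- table(calls[!is.na(calls)])
  # a genuine segregating class is >= 25% of offspring in every supported
  # configuration; miscall noise sits far below 5%
  floor_n <- max(3, 0.05 * sum(tab))
  tab[tab > floor_n]
}

# TRUE when the observed offspring classes cannot arise from the parental
# calls even allowing a null allele.  Unknown parents never force rejection.
incompatible_with_parents <- function(obs_classes, parent_calls) {
  p <- parent_calls
  if (any(is.na(p))) return(FALSE)
  hets <- sum(p == "AB")
  if (hets >= 1) return(FALSE)        # het parent: 2 or 3 classes all possible
  # both parents called homozygous
  if (p[[1]] == p[[2]]) {
    # e.g. AA x AA: offspring should be monomorphic; segregation implies a
    # null or an error -- AO x AO would give A-only plus missing, so any
    # second class with real support is incompatible
    return(length(obs_classes) > 1)
  }
  # different homozygotes: expected all AB; an approx 1:1:1 three-class
  # pattern is the AOxBO null signature -> compatible (flagged elsewhere)
  if (setequal(obs_classes, c("AA", "AB", "BB"))) return(FALSE)
  !setequal(obs_classes, "AB")
}

#' Assign a segregation type to an accepted SNP
#'
#' Two offspring classes with one heterozygous parent give the 1:1 types
#' (ABxAA when the first parent is heterozygous, AAxAB when the second is);
#' three classes with both parents heterozygous give ABxAB (1:2:1); three
#' classes with one apparently homozygous parent are flagged as an ABxAO /
#' AOxAB null candidate (2:1:1), and three classes with the parents as
#' different homozygotes as an AOxBO candidate (1:1:1 plus missing).
#'
#' @param calls offspring calls.
#' @param parent_calls length-2 character vector (first parent, second).
#' @return list(type, het_parent) where type is one of "ABxAA", "AAxAB",
#'   "ABxAB", "null_candidate", "aoxbo_candidate", "rejected" and
#'   het_parent (for null candidates) names the heterozygous parent
#'   ("lat"/"moy"/NA).
#' @export
assign_segregation_type <- function(calls, parent_calls) {
  classes <- names(class_table(calls))
  p <- parent_calls
  lat_het <- !is.na(p[[1]]) && p[[1]] == "AB"
  moy_het <- !is.na(p[[2]]) && p[[2]] == "AB"
  n_cl <- length(classes)
  if (n_cl == 2 && "AB" %in% classes) {
    if (lat_het && !moy_het) return(list(type = "ABxAA", het_parent = "lat"))
    if (moy_het && !lat_het) return(list(type = "AAxAB", het_parent = "moy"))
    if (is.na(p[[1]]) && is.na(p[[2]]))
      return(list(type = "rejected", het_parent = NA_character_))
    if (is.na(p[[1]]) || is.na(p[[2]])) {
      # one parent unknown: attribute the segregation to the unknown parent
      # only if the known one is homozygous
      if (!is.na(p[[1]]) && p[[1]] != "AB")
        return(list(type = "AAxAB", het_parent = "moy"))
      if (!is.na(p[[2]]) && p[[2]] != "AB")
        return(list(type = "ABxAA", het_parent = "lat"))
      return(list(type = if (lat_het) "ABxAA" else "AAxAB",
                  het_parent = if (lat_het) "lat" else "moy"))
    }
  }
  if (n_cl == 3) {
    if (lat_het && moy_het) return(list(type = "ABxAB", het_parent = NA))
    if (lat_het && !moy_het) return(list(type = "null_candidate",
                                         het_parent = "lat"))
    if (moy_het && !lat_het) return(list(type = "null_candidate",
                                         het_parent = "moy"))
    if (!is.na(p[[1]]) && !is.na(p[[2]]) && p[[1]] != p[[2]])
      return(list(type = "aoxbo_candidate", het_parent = NA_character_))
  }
  list(type = "rejected", het_parent = NA_character_)
}

#' Call genotypes for every SNP in a count table
#'
#' Runs the per-SNP pipeline: heterozygote-line fit, classification of
#' parents and offspring, fit assessment and segregation typing.
#'
#' @param counts long count tibble (snp_id, quality, individual, major,
#'   minor).
#' @param parents the two parent labels, first parent ("Latham" side) first.
#' @inheritParams fit_het_line
#' @return tibble with one row per SNP: snp_id, slope, intercept, r2,
#'   accept, reason, type, het_parent, parent_lat, parent_moy, n_called,
#'   and `calls`, a list-column of named offspring call vectors.
#' @export
call_genotypes <- function(counts, parents = c("Latham", "Moy"),
                           seed_band = c(0.15, 0.85), min_het = 5) {
  split(counts, counts$snp_id)[unique(counts$snp_id)] |>
    map(function(d) {
      is_par <- d$individual %in% parents
      line <- fit_het_line(d$major[!is_par], d$minor[!is_par],
                           seed_band = seed_band, min_het = min_het)
      if (is.null(line)) {
        return(tibble(snp_id = d$snp_id[[1]], slope = NA_real_,
                      intercept = NA_real_, r2 = NA_real_, accept = FALSE,
                      reason = "unclassifiable", type = "rejected",
                      het_parent = NA_character_, parent_lat = NA_character_,
                      parent_moy = NA_character_, n_called = 0L,
                      calls = list(NULL)))
      }
      all_calls <- classify_offspring(d$major, d$minor, line)
      pl <- all_calls[match(parents, d$individual)]
      off <- !is_par
      calls <- setNames(all_calls[off], d$individual[off])
      asmt <- assess_classification(calls, d$major[off], d$minor[off], pl)
      ty <- if (asmt$accept) assign_segregation_type(calls, pl) else
        list(type = "rejected", het_parent = NA_character_)
      tibble(snp_id = d$snp_id[[1]], slope = line$slope,
             intercept = line$intercept, r2 = asmt$r2,
             accept = asmt$accept, reason = asmt$reason, type = ty$type,
             het_parent = ty$het_parent %||% NA_character_,
             parent_lat = pl[[1]], parent_moy = pl[[2]],
             n_called = sum(!is.na(calls)), calls = list(calls))
    }) |>
    list_rbind()
}

#' Extract a marker-by-individual call matrix from a calls tibble
#'
#' @param calls_tbl output of [call_genotypes()] (or any tibble with
#'   `snp_id` and a `calls` list-column).
#' @return character matrix, rows = SNPs, columns = individuals.
#' @export
calls_matrix <- function(calls_tbl) {
  keep <- !vapply(calls_tbl$calls, is.null, TRUE)
  calls_tbl <- calls_tbl[keep, ]
  inds <- names(calls_tbl$calls[[1]])
  out <- t(vapply(calls_tbl$calls, function(x) x[inds], character(length(inds))))
  rownames(out) <- calls_tbl$snp_id
  colnames(out) <- inds
  out
}
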