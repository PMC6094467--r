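# Detection and recoding of null-allele segregation patterns.
#
# A null allele O produces no reads, so AO phenotypes look like AA and OO
# looks like missing.  Two configurations occur: AB x AO (one parent
# heterozygous, the other apparently homozygous, offspring in three classes
# ~2:1:1) and AO x BO (parents apparently different homozygotes, offspring
# in three classes ~1:1:1 with excess missing from OO genotypes).

chisq_ratio_p <- function(obs, ratio) {
  exp_p <- ratio / sum(ratio)
  stat <- sum((obs - sum(obs) * exp_p)^2 / (sum(obs) * exp_p))
  pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}

#' Detect the AB x AO null-allele pattern at one marker
#'
#' Detected when one parent is heterozygous, the other apparently
#' homozygous, the offspring show all three phenotype classes, and the
#' class counts are consistent with the expected 2:1:1 ratio (the underlying
#' genotypes AA:AO:AB:BO segregate 1:1:1:1) by a chi-square goodness-of-fit
#' test at `alpha`.
#'
#' @param calls offspring phenotype calls ("AA"/"AB"/"BB"/NA).
#' @param parent_calls length-2 character vector (first parent, second).
#' @param alpha chi-square significance level for *rejecting* the ratio.
#' @return list(detected, het_parent ("lat"/"moy"), hom_class (the apparent
#'   homozygote class, whose parent carries O), p_ratio).
#' @export
detect_abxao <- function(calls, parent_calls, alpha = 0.001) {
  no <- list(detected = FALSE, het_parent = NA_character_,
             hom_class = NA_character_, p_ratio = NA_real_)
  p <- parent_calls
  if (any(is.na(p))) return(no)
  lat_het <- p[[1]] == "AB"; moy_het <- p[[2]] == "AB"
  if (lat_het == moy_het) return(no)
  hom_class <- if (lat_het) p[[2]] else p[[1]]
  if (!hom_class %in% c("AA", "BB")) return(no)
  tab <- table(factor(calls, levels = c("AA", "AB", "BB")))
  if (any(tab == 0)) return(no)
  ratio <- if (hom_class == "AA") c(2, 1, 1) else c(1, 1, 2)
  pv <- chisq_ratio_p(as.numeric(tab), ratio)
  list(detected = pv > alpha,
       het_parent = if (lat_het) "lat" else "moy",
       hom_class = hom_class, p_ratio = pv)
}

#' Split an AB x AO marker into its 1:1 and 3:1 derived markers
#'
#' The allele unique to the heterozygous parent segregates 1:1 (the "n1"
#' marker: carrier coded "Bc", non-carrier "B-"); the shared allele shows
#' dominant 3:1 segregation because AA and AO cannot be distinguished (the
#' "n3" marker: present "Ap", absent "A-").
#'
#' @param calls offspring phenotype calls.
#' @param hom_class apparent class of the homozygous parent ("AA" or "BB").
#' @return list(n1, n3) of derived call vectors (NA preserved).
#' @export
split_abxao <- function(calls, hom_class = "AA") {
  stopifnot(hom_class %in% c("AA", "BB"))
  rare <- if (hom_class == "AA") "BB" else "AA"   # class unique to het parent
  n1 <- ifelse(is.na(calls), NA_character_,
               ifelse(calls %in% c("AB", rare), "Bc", "B-"))
  n3 <- ifelse(is.na(calls), NA_character_,
               ifelse(calls %in% c("AB", hom_class), "Ap", "A-"))
  list(n1 = n1, n3 = n3)
}

#' Detect the AO x BO null-allele pattern at one marker
#'
#' Requires (a) the three offspring phenotype classes in a 1:1:1 ratio (not
#' rejected at `alpha`), (b) parents called as different homozygotes, (c)
#' each allele's read counts associating (R^2 > `r2_threshold`) with a
#' different parent's anchor classes (the major allele with one parent's
#' additive effect, the minor with the other's), and (d) missingness at the
#' marker above the marker-set median (the OO genotypes are called missing).
#'
#' @param calls offspring phenotype calls (named by individual).
#' @param major,minor named offspring read counts.
#' @param parent_calls length-2 character vector.
#' @param anchors_lat,anchors_moy anchor tibbles (as in
#'   [marker_regression()]) informative for the first and second parent.
#' @param median_missing median per-marker missing count across the marker
#'   set.
#' @param alpha ratio-test level; `r2_threshold` association threshold.
#' @return list(detected, p_ratio, r2_major_lat, r2_major_moy,
#'   r2_minor_lat, r2_minor_moy, n_missing).
#' @export
detect_aoxbo <- function(calls, major, minor, parent_calls,
                         anchors_lat, anchors_moy, median_missing,
                         alpha = 0.001, r2_threshold = 25) {
  out <- list(detected = FALSE, p_ratio = NA_real_,
              r2_major_lat = NA_real_, r2_major_moy = NA_real_,
              r2_minor_lat = NA_real_, r2_minor_moy = NA_real_,
              n_missing = sum(is.na(calls)))
  p <- parent_calls
  if (any(is.na(p)) || any(!p %in% c("AA", "BB")) || p[[1]] == p[[2]])
    return(out)
  tab <- table(factor(calls, levels = c("AA", "AB", "BB")))
  if (any(tab == 0)) return(out)
  out$p_ratio <- chisq_ratio_p(as.numeric(tab), c(1, 1, 1))
  best_r2 <- function(y, anchors) {
    res <- marker_regression(y, anchors, min_joint = 20)
    if (!nrow(res)) 0 else max(res$r2)
  }
  out$r2_major_lat <- best_r2(major, anchors_lat)
  out$r2_major_moy <- best_r2(major, anchors_moy)
  out$r2_minor_lat <- best_r2(minor, anchors_lat)
  out$r2_minor_moy <- best_r2(minor, anchors_moy)
  cross_assoc <-
    (out$r2_major_lat > r2_threshold && out$r2_minor_moy > r2_threshold) ||
    (out$r2_major_moy > r2_threshold && out$r2_minor_lat > r2_threshold)
  out$detected <- out$p_ratio > alpha && cross_assoc &&
    out$n_missing > median_missing
  out
}

#' Per-offspring overall missing rates
#'
#' @param calls marker x individual call matrix.
#' @return named numeric vector of missing proportions per individual.
#' @export
offspring_missing_rates <- function(calls) {
  colMeans(is.na(calls))
}

#' Impute OO genotypes and recode an AO x BO marker as AB x CD ("n4")
#'
#' Offspring with an overall missing rate below `threshold` have their
#' missing value at this marker imputed as the OO genotype; offspring with
#' higher overall missingness keep the value missing (their missingness is
#' more plausibly technical).  Phenotypes map to the four classes of an
#' AB x CD coded marker: "AA" (= AO), "AB", "BB" (= BO), "OO".
#'
#' @param calls offspring phenotype calls at the marker.
#' @param overall_missing per-offspring overall missing rates (same order).
#' @param threshold imputation cutoff on the overall missing rate.
#' @return character vector of n4-coded calls.
#' @export
impute_oo <- function(calls, overall_missing, threshold = 0.1) {
  out <- calls
  imp <- is.na(calls) & overall_missing < threshold
  out[imp] <- "OO"
  out
}

#' Recode null candidates across a calls table
#'
#' Applies [detect_abxao()] / [split_abxao()] to every null candidate and
#' [impute_oo()] to every detected AO x BO marker, returning derived-marker
#' rows with the field's "n1"/"n3"/"n4" name prefixes (the leading "s" of a
#' SNP name is replaced; otherwise the prefix is prepended).
#'
#' @param calls_tbl output of [call_genotypes()].
#' @param aoxbo_ids snp_ids confirmed as AO x BO (e.g. via [detect_aoxbo()]).
#' @param threshold OO-imputation threshold on overall offspring missingness.
#' @return tibble (snp_id, source_id, kind, het_parent, hom_class, calls)
#'   of derived markers.
#' @export
recode_null_markers <- function(calls_tbl, aoxbo_ids = character(),
                                threshold = 0.1) {
  cm <- calls_matrix(calls_tbl[calls_tbl$n_called > 0, ])
  overall <- offspring_missing_rates(cm)
  rows <- list()
  pfx <- function(id, p) ifelse(grepl("^s", id), sub("^s", p, id),
                                paste0(p, id))
  for (i in seq_len(nrow(calls_tbl))) {
    row <- calls_tbl[i, ]
    calls <- row$calls[[1]]
    if (row$type == "null_candidate") {
      det <- detect_abxao(calls, c(row$parent_lat, row$parent_moy))
      if (!det$detected) next
      sp <- split_abxao(calls, det$hom_class)
      rows[[length(rows) + 1L]] <- tibble(
        snp_id = pfx(row$snp_id, "n1"), source_id = row$snp_id, kind = "n1",
        het_parent = det$het_parent, hom_class = det$hom_class,
        calls = list(sp$n1))
      rows[[length(rows) + 1L]] <- tibble(
        snp_id = pfx(row$snp_id, "n3"), source_id = row$snp_id, kind = "n3",
        het_parent = det$het_parent, hom_class = det$hom_class,
        calls = list(sp$n3))
    } else if (row$snp_id %in% aoxbo_ids) {
      n4 <- impute_oo(calls, overall[names(calls)], threshold)
      rows[[length(rows) + 1L]] <- tibble(
        snp_id = pfx(row$snp_id, "n4"), source_id = row$snp_id, kind = "n4",
        het_parent = NA_character_, hom_class = NA_character_,
        calls = list(n4))
    }
  }
  list_rbind(rows)
}
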