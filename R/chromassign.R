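# Preliminary allocation of SNPs to linkage groups by marker regression
# against an anchor map.

#' Per-individual major-allele proportion
#'
#' P_A = major / (major + minor); individuals with zero total depth are
#' missing.  Under ABxAA / AAxAB segregation P_A clusters near 0.5 and 1.0;
#' under ABxAB near 0.0, 0.5 and 1.0, so P_A carries the segregation signal
#' without requiring genotype calls.
#'
#' @param counts long count tibble (snp_id, individual, major, minor).
#' @return tibble (snp_id, individual, p_a).
#' @export
major_allele_proportion <- function(counts) {
  counts |>
    mutate(tot = .data$major + .data$minor,
           p_a = ifelse(.data$tot > 0, .data$major / .data$tot, NA_real_)) |>
    select("snp_id", "individual", "p_a")
}

# One-way ANOVA of y on a class factor by direct sums of squares.
# Returns R^2 in percent and the F-test p-value.
anova_r2 <- function(y, cls) {
  ok <- !is.na(y) & !is.na(cls)
  y <- y[ok]; cls <- as.character(cls[ok])
  n <- length(y)
  tab <- table(cls)
  k <- length(tab)
  if (k < 2 || any(tab < 2) || n < k + 1) return(c(r2 = NA_real_, p = NA_real_))
  gm <- mean(y)
  mns <- tapply(y, cls, mean)
  ssb <- sum(tab * (mns - gm)^2)
  sst <- sum((y - gm)^2)
  if (sst <= 0) return(c(r2 = 0, p = 1))
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  c(r2 = 100 * ssb / sst, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Test association of a SNP's P_A with every anchor marker
#'
#' One-way analysis of variance of P_A on each anchor marker's genotype
#' classes (marker regression mapping, the parametric analogue of the
#' Kruskal-Wallis test): R^2 = 100 SSB/SST and the F-test p-value.  Anchors
#' with fewer than two classes of >= 2 observations, or fewer than
#' `min_joint` joint non-missing observations, are skipped.
#'
#' @param p_a named numeric vector of P_A per individual.
#' @param anchors anchor map tibble: marker, lg, pos, and a `calls`
#'   list-column of named per-individual class labels.
#' @param min_joint minimum joint observations per anchor.
#' @return tibble (marker, lg, pos, r2, p), one row per usable anchor.
#' @export
marker_regression <- function(p_a, anchors, min_joint = 50) {
  rows <- pmap(anchors[c("marker", "lg", "pos", "calls")],
               function(marker, lg, pos, calls) {
    cls <- calls[names(p_a)]
    ok <- sum(!is.na(p_a) & !is.na(cls))
    if (ok < min_joint) return(NULL)
    st <- anova_r2(p_a, cls)
    if (is.na(st[["r2"]])) return(NULL)
    tibble(marker = marker, lg = lg, pos = pos,
           r2 = st[["r2"]], p = st[["p"]])
  })
  list_rbind(compact_null(rows))
}

compact_null <- function(x) x[!vapply(x, is.null, TRUE)]

#' Allocate SNPs to linkage groups
#'
#' For each SNP, the best anchor (max R^2) per linkage group is found; the
#' SNP is allocated to a group if exactly one group exceeds `r2_threshold`
#' (strictly greater), declared "multi-LG" if two or more do, and left
#' unallocated otherwise.
#'
#' @param counts long count tibble for the SNPs to allocate.
#' @param anchors anchor map as in [marker_regression()].
#' @param r2_threshold allocation threshold (percent).
#' @param parents parent labels excluded from the ANOVA (offspring only).
#' @param min_joint passed to [marker_regression()].
#' @return tibble: snp_id, decision ("LG..", "multi-LG", "unallocated"),
#'   best_marker, best_pos, best_r2, best_p, and a `per_lg` list-column of
#'   per-group best R^2 tables.
#' @export
allocate_snps <- function(counts, anchors, r2_threshold = 25,
                          parents = c("Latham", "Moy"), min_joint = 50) {
  pa <- major_allele_proportion(counts[!counts$individual %in% parents, ])
  split(pa, pa$snp_id)[unique(pa$snp_id)] |>
    imap(function(d, snp) {
      v <- setNames(d$p_a, d$individual)
      res <- marker_regression(v, anchors, min_joint = min_joint)
      if (!nrow(res)) {
        return(tibble(snp_id = snp, decision = "unallocated",
                      best_marker = NA_character_, best_pos = NA_real_,
                      best_r2 = NA_real_, best_p = NA_real_,
                      per_lg = list(res)))
      }
      best <- res |> group_by(.data$lg) |>
        slice_max(.data$r2, n = 1, with_ties = FALSE) |> ungroup()
      over <- best[best$r2 > r2_threshold, ]
      decision <- if (nrow(over) == 1) over$lg[[1]] else
        if (nrow(over) >= 2) "multi-LG" else "unallocated"
      top <- best[which.max(best$r2), ]
      tibble(snp_id = snp, decision = decision,
             best_marker = top$marker, best_pos = top$pos,
             best_r2 = top$r2, best_p = top$p, per_lg = list(best))
    }) |>
    list_rbind()
}
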