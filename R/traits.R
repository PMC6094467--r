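# QTL-ready traits from plot-level ripening score profiles: principal
# coordinates of the city-block distances and interpolated stage times.

#' Principal-coordinate scores of ripening profiles
#'
#' Classical principal coordinates (metric scaling) of the city-block (L1)
#' distance matrix between plot score profiles: the double-centred
#' -D^2/2 matrix is eigendecomposed and coordinates are eigenvectors scaled
#' by the square root of their eigenvalues, ordered by eigenvalue.
#' Negative eigenvalues (non-Euclidean L1 configurations) are
#' reported, and only positive-eigenvalue axes are returned as coordinates.
#' Axes are oriented so that high values correspond to slower ripening
#' (negative correlation with the plot's mean score across dates), making
#' a high first coordinate mean a longer ripening period.
#'
#' @param profiles long tibble (plot, individual, date, score) or a
#'   plot x date score matrix with rownames.
#' @return list: `coords` (tibble plot, individual, PCO1..), `eigenvalues`
#'   (all, including any negative), `plot_individual` mapping.
#' @export
pco_scores <- function(profiles) {
  if (inherits(profiles, "data.frame")) {
    wide <- profiles |>
      pivot_wider(id_cols = c("plot", "individual"),
                  names_from = "date", values_from = "score")
    ind <- wide$individual
    mat <- as.matrix(wide[, -(1:2)])
    rownames(mat) <- wide$plot
  } else {
    mat <- profiles
    ind <- rep(NA_character_, nrow(mat))
  }
  if (nrow(mat) < 3) abort("need at least 3 plots")
  D <- dist(mat, method = "manhattan")
  if (max(D) == 0) {
    # all profiles identical: zero dispersion, all coordinates 0
    coords <- matrix(0, nrow(mat), 1)
    eig <- rep(0, nrow(mat))
  } else {
    k <- nrow(mat) - 1
    pco <- suppressWarnings(cmdscale(D, k = k, eig = TRUE))
    eig <- pco$eig
    pos <- which(eig > max(eig) * 1e-10 & seq_along(eig) <= ncol(pco$points))
    coords <- pco$points[, pos, drop = FALSE]
  }
  mean_score <- rowMeans(mat)
  for (j in seq_len(ncol(coords))) {
    r <- suppressWarnings(cor(coords[, j], mean_score))
    if (!is.na(r) && r > 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCO", seq_len(ncol(coords)))
  out <- bind_cols(tibble(plot = rownames(mat), individual = ind),
                   as_tibble(coords))
  list(coords = out, eigenvalues = eig)
}

#' Select PCO axes differing among offspring genotypes
#'
#' One-way ANOVA of each axis over offspring genotypes (replicate plots
#' within genotype); axes with p < `alpha` are retained and their genotype
#' means become trait values for QTL mapping.  Without replication the
#' test is impossible and all axes pass through with a warning.
#'
#' @param coords tibble from [pco_scores()]`$coords` (plot, individual,
#'   PCO1..).
#' @param alpha retention threshold.
#' @return list: `traits` (tibble individual x retained axes, genotype
#'   means), `tests` (tibble axis, p, retained).
#' @export
select_axes <- function(coords, alpha = 0.001) {
  axes <- grep("^PCO", names(coords), value = TRUE)
  reps <- table(coords$individual)
  if (all(reps < 2)) {
    warn("no replicate plots per genotype; axis selection skipped")
    tests <- tibble(axis = axes, p = NA_real_, retained = TRUE)
  } else {
    tests <- list_rbind(map(axes, function(ax) {
      st <- anova_r2(coords[[ax]], coords$individual)
      tibble(axis = ax, p = st[["p"]], retained = !is.na(st[["p"]]) &&
               st[["p"]] < alpha)
    }))
  }
  keep <- tests$axis[tests$retained]
  traits <- coords |>
    group_by(.data$individual) |>
    summarise(across(all_of(keep), mean), .groups = "drop")
  list(traits = traits, tests = tests)
}

#' Interpolate the time to reach each ripening stage
#'
#' For stage s, the crossing day is linearly interpolated between the last
#' date with score < s and the first date with score >= s; a stage already
#' reached at the first scoring date gets that date; a stage never reached
#' is missing.  Decreasing scores (scoring noise) are cleaned by a running
#' maximum first.
#'
#' @param profiles long tibble (plot, individual, date, score).
#' @param stages stages to interpolate (default 2..6).
#' @return tibble (plot, individual, stage, day).
#' @export
interpolate_stage_times <- function(profiles, stages = 2:6) {
  profiles |>
    group_by(.data$plot, .data$individual) |>
    arrange(.data$date, .by_group = TRUE) |>
    summarise(stage_times = list({
      sc <- cummax(.data$score)
      dt <- .data$date
      map_dbl(stages, function(s) {
        if (sc[[1]] >= s) return(dt[[1]])
        i <- which(sc >= s)[1]
        if (is.na(i)) return(NA_real_)
        d0 <- dt[[i - 1]]; d1 <- dt[[i]]
        s0 <- sc[[i - 1]]; s1 <- sc[[i]]
        d0 + (d1 - d0) * (s - s0) / (s1 - s0)
      })
    }), .groups = "drop") |>
    mutate(stage = list(stages)) |>
    unnest(c("stage_times", "stage")) |>
    select("plot", "individual", "stage", day = "stage_times")
}
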