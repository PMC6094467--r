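# End-to-end pipeline: filter -> allocate -> call -> null-recode ->
# two-point -> MDS order -> HMM check -> QTL scan.

#' Reference-phase class map for a called marker type
#'
#' @param type one of "ABxAA", "AAxAB", "ABxAB", "n1", "n3", "n4".
#' @param hom_class apparent class of the homozygous parent for the 1:1
#'   types ("AA" or "BB").
#' @param het_parent "lat" or "moy" for the n1/n3 derived types.
#' @return a class map (states AC, AD, BC, BD) in an arbitrary but fixed
#'   reference phase; true phases are resolved from two-point linkage.
#' @export
reference_classmap <- function(type, hom_class = "AA", het_parent = "lat") {
  h <- if (identical(hom_class, "BB")) "B" else "A"
  switch(type,
    ABxAA = classmap_from_alleles("A", "B", h, h),
    AAxAB = classmap_from_alleles(h, h, "A", "B"),
    ABxAB = classmap_from_alleles("A", "B", "A", "B"),
    n1 = if (het_parent == "lat")
      derive_classmap("A", "B", "A", "O", "n1") else
      derive_classmap("A", "O", "A", "B", "n1"),
    n3 = if (het_parent == "lat")
      derive_classmap("A", "B", "A", "O", "n3") else
      derive_classmap("A", "O", "A", "B", "n3"),
    n4 = derive_classmap("A", "O", "B", "O", "n4"),
    abort(paste0("no reference class map for type ", type)))
}

# Apply resolved phase flips to reference class maps.
apply_phases <- function(classmaps, phases) {
  out <- classmaps
  for (i in seq_len(nrow(phases))) {
    id <- phases$marker[[i]]
    cm <- out[[id]]
    if (phases$flip_lat[[i]]) cm <- flip_classmap(cm, "lat")
    if (phases$flip_moy[[i]]) cm <- flip_classmap(cm, "moy")
    out[[id]] <- cm
  }
  out
}

#' Run the full mapping pipeline
#'
#' Executes the stages in workflow order: read-support filtering,
#' allocation to linkage groups against the anchor map, genotype calling,
#' null-allele detection and recoding, two-point linkage, MDS ordering,
#' HMM map checking with local order improvement, and (when a trait is
#' supplied) HMM interval mapping with a genome-wide permutation threshold.
#'
#' @param counts long count tibble (snp_id, quality, individual, major,
#'   minor) including the two parent rows.
#' @param anchors anchor map tibble: marker, lg, pos, calls (named
#'   list-column), and optionally `parent` ("lat"/"moy"/"both") used for
#'   AOxBO detection.
#' @param trait optional named numeric trait vector for QTL scanning.
#' @param config a [pipeline_config()].
#' @param parents parent labels in `counts` (first parent first).
#' @return list of stage outputs: `filtered`, `allocation`, `calls`,
#'   `null_markers`, per-LG `groups` (pairwise, map, order improvement,
#'   HMM summaries), `scans` and `threshold` (if a trait was given), and a
#'   per-LG `summary` tibble.
#' @export
run_pipeline <- function(counts, anchors, trait = NULL,
                         config = pipeline_config(),
                         parents = c("Latham", "Moy")) {
  set.seed(config$seed)
  n_off <- length(setdiff(unique(counts$individual), parents))
  filtered <- filter_snps(counts, n_off, parents = parents,
                          min_mean_depth = config$min_mean_depth,
                          min_quality = config$min_quality,
                          max_het = config$max_het)
  alloc <- allocate_snps(filtered, anchors, r2_threshold = config$alloc_r2,
                         parents = parents)
  single <- alloc$snp_id[!alloc$decision %in% c("multi-LG", "unallocated")]
  calls_tbl <- call_genotypes(
    filtered[filtered$snp_id %in% single, ], parents = parents) |>
    left_join(alloc[c("snp_id", "decision")], by = "snp_id") |>
    rename(lg = "decision")

  # null-allele handling -----------------------------------------------
  aoxbo_ids <- character()
  if ("parent" %in% names(anchors)) {
    anchors_lat <- anchors[anchors$parent == "lat", ]
    anchors_moy <- anchors[anchors$parent == "moy", ]
    cand <- calls_tbl[calls_tbl$type == "aoxbo_candidate", ]
    if (nrow(cand) && nrow(anchors_lat) && nrow(anchors_moy)) {
      med_miss <- median(vapply(calls_tbl$calls[calls_tbl$n_called > 0],
                                function(x) sum(is.na(x)), 1))
      aoxbo_ids <- cand$snp_id[map_lgl(seq_len(nrow(cand)), function(i) {
        d <- filtered[filtered$snp_id == cand$snp_id[[i]] &
                        !filtered$individual %in% parents, ]
        detect_aoxbo(cand$calls[[i]],
                     setNames(d$major, d$individual),
                     setNames(d$minor, d$individual),
                     c(cand$parent_lat[[i]], cand$parent_moy[[i]]),
                     anchors_lat, anchors_moy, med_miss,
                     alpha = config$null_alpha,
                     r2_threshold = config$alloc_r2)$detected
      })]
    }
  }
  nulls <- recode_null_markers(calls_tbl, aoxbo_ids = aoxbo_ids,
                               threshold = config$oo_impute_below)

  # assemble the per-LG marker sets ------------------------------------
  base <- calls_tbl |>
    filter(.data$type %in% c("ABxAA", "AAxAB", "ABxAB")) |>
    mutate(kind = .data$type,
           hom_class = case_when(
             .data$type == "ABxAA" ~ coalesce(.data$parent_moy, "AA"),
             .data$type == "AAxAB" ~ coalesce(.data$parent_lat, "AA"),
             TRUE ~ "AA"))
  drv <- if (nrow(nulls)) {
    nulls |>
      left_join(calls_tbl[c("snp_id", "lg")],
                by = c(source_id = "snp_id")) |>
      mutate(hom_class = coalesce(.data$hom_class, "AA"))
  } else NULL
  loci <- bind_rows(
    base[c("snp_id", "lg", "kind", "het_parent", "hom_class", "calls")],
    if (!is.null(drv)) drv[c("snp_id", "lg", "kind", "het_parent",
                             "hom_class", "calls")])
  loci$classmap <- pmap(loci[c("kind", "hom_class", "het_parent")],
                        function(kind, hom_class, het_parent)
                          reference_classmap(kind, hom_class,
                                             het_parent %||% "lat"))

  groups <- lapply(split(loci, loci$lg), function(lg_loci) {
    lg <- lg_loci$lg[[1]]
    cm_list <- setNames(lg_loci$classmap, lg_loci$snp_id)
    calls <- calls_matrix(lg_loci)
    pf <- prefilter(calls, cm_list, round = 2,
                    max_missing = config$missing_ge_round2,
                    distortion_p = config$distortion_p)
    keep <- pf$retained
    if (length(keep) < 4) return(NULL)
    pw <- pairwise_linkage(calls[keep, , drop = FALSE], cm_list[keep])
    linked <- largest_linked_component(pw)
    if (length(linked) < length(pw$markers)) {
      warn(sprintf("%s: %d marker(s) not linked to the main group, left unplaced",
                   lg, length(pw$markers) - length(linked)))
      if (length(linked) < 4) return(NULL)
      pw <- subset_pairwise(pw, linked)
    }
    fit <- order_markers(pw, map_function = config$map_function)
    anchor_pos <- setNames(anchors$pos[anchors$lg == lg],
                           anchors$marker[anchors$lg == lg])
    fit <- orient_map(fit, anchor_pos)
    phases <- resolve_phases(pw, fit$map$marker)
    phased_cm <- apply_phases(cm_list[fit$map$marker], phases)
    imp <- improve_order(fit$map, calls, phased_cm,
                         eps = config$error_rate,
                         map_function = config$map_function)
    model <- build_inheritance_model(imp$map, phased_cm,
                                     eps = config$error_rate,
                                     map_function = config$map_function)
    list(lg = lg, prefilter = pf, pairwise = pw, mds = fit,
         phases = phases, improvement = imp, model = model,
         calls = calls, types = lg_loci[c("snp_id", "kind")])
  })
  groups <- compact_null(groups)

  scans <- threshold <- NULL
  if (!is.null(trait) && length(groups)) {
    probs <- lapply(groups, function(g)
      genotype_probs(g$model, g$calls, step = config$grid_step))
    scans <- lapply(seq_along(groups), function(i)
      scan_qtl(probs[[i]], trait, lg = groups[[i]]$lg))
    names(scans) <- names(groups)
    threshold <- permutation_threshold(probs, trait,
                                       n_perm = config$n_perm,
                                       alpha = config$alpha)
  }

  summary <- list_rbind(map(groups, function(g) {
    ty <- table(factor(g$types$kind[g$types$snp_id %in% g$improvement$map$marker],
                       levels = c("ABxAA", "AAxAB", "ABxAB",
                                  "n1", "n3", "n4")))
    tibble(lg = g$lg, n_mapped = nrow(g$improvement$map),
           length_cm = max(g$improvement$map$pos),
           ABxAA = ty[["ABxAA"]], AAxAB = ty[["AAxAB"]],
           ABxAB = ty[["ABxAB"]], n1 = ty[["n1"]], n3 = ty[["n3"]],
           n4 = ty[["n4"]],
           hmm_mean_before = g$improvement$hmm_mean_before,
           hmm_mean_after = g$improvement$hmm_mean_after)
  }))
  list(filtered = filtered, allocation = alloc, calls = calls_tbl,
       null_markers = nulls, groups = groups, scans = scans,
       threshold = threshold, summary = summary, config = config)
}
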