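test_that("ABxAO detection follows the 2:1:1 chi-square rule", {
  calls_211 <- rep(c("AA", "AB", "BB"), c(92, 46, 46))
  det <- detect_abxao(calls_211, c("AB", "AA"))
  expect_true(det$detected)
  expect_identical(det$het_parent, "lat")
  expect_identical(det$hom_class, "AA")
  # a 1:2:1 with both parents het is not an ABxAO pattern
  det2 <- detect_abxao(rep(c("AA", "AB", "BB"), c(46, 92, 46)), c("AB", "AB"))
  expect_false(det2$detected)
  # counts (120, 30, 30): chi-square = 15 against 2:1:1 at n = 180
  obs <- c(120, 30, 30)
  expd <- 180 * c(2, 1, 1) / 4
  expect_equal(sum((obs - expd)^2 / expd), 20)
  det3 <- detect_abxao(rep(c("AA", "AB", "BB"), c(120, 30, 30)), c("AB", "AA"))
  expect_false(det3$detected)
  expect_lt(det3$p_ratio, 0.001)
})

test_that("splitting an ABxAO marker yields 1:1 and 3:1 derived alleles", {
  # truth table
  sp <- split_abxao(c("AA", "AB", "BB", NA), hom_class = "AA")
  expect_identical(sp$n1, c("B-", "Bc", "Bc", NA))
  expect_identical(sp$n3, c("Ap", "Ap", "A-", NA))
  # 2:1:1 phenotypes at n = 184 -> n1 92:92 and n3 138:46
  calls <- rep(c("AA", "AB", "BB"), c(92, 46, 46))
  sp2 <- split_abxao(calls, "AA")
  expect_equal(as.numeric(table(sp2$n1)[c("Bc", "B-")]), c(92, 92))
  expect_equal(as.numeric(table(sp2$n3)[c("Ap", "A-")]), c(138, 46))
  # re-merging the split markers reproduces the original phenotypes
  remerge <- dplyr::case_when(
    sp2$n1 == "Bc" & sp2$n3 == "Ap" ~ "AB",
    sp2$n1 == "Bc" & sp2$n3 == "A-" ~ "BB",
    sp2$n1 == "B-" ~ "AA")
  expect_identical(remerge, calls)
  # derived class maps segregate 1:1 and 3:1 over the four states
  n1_cm <- derive_classmap("A", "B", "A", "O", "n1")
  n3_cm <- derive_classmap("A", "B", "A", "O", "n3")
  expect_equal(as.numeric(table(n1_cm)), c(2, 2))
  expect_equal(sort(as.numeric(table(n3_cm))), c(1, 3))
})

test_that("OO imputation applies the 10% overall-missingness rule", {
  calls <- c(a = "AA", b = NA, c = NA, d = "AB")
  overall <- c(a = 0, b = 0.05, c = 0.4, d = 0)
  imp <- impute_oo(calls, overall)
  expect_identical(unname(imp), c("AA", "OO", NA, "AB"))
})

test_that("AOxBO loci are detected and impute to ~1:1:1:1 at n = 5000", {
  cfg <- sim_config(n_offspring = 5000, lg_lengths = c(LG1 = 60),
                    n_markers = 14,
                    type_proportions = c(ABxAA = 0.35, AAxAB = 0.25,
                                         ABxAB = 0.1, ABxAO = 0.2,
                                         AOxBO = 0.1),
                    missing_rate = 0.02, seed = 29)
  cross <- simulate_cross(cfg)
  mk <- cross$markers
  calls <- cross$true_calls
  overall <- offspring_missing_rates(calls)
  for (id in mk$marker[mk$type == "AOxBO"]) {
    n4 <- impute_oo(calls[id, ], overall, threshold = 0.5)
    tab <- table(factor(n4, levels = c("AA", "AB", "BB", "OO")))
    expect_gt(gbsqtl:::chisq_ratio_p(as.numeric(tab), c(1, 1, 1, 1)), 0.001)
  }
  # n1 / n3 ratios for the ABxAO loci
  for (i in which(mk$type %in% c("ABxAO", "AOxAB"))) {
    hom <- if (mk$type[[i]] == "ABxAO") "AA" else "AA"
    sp <- split_abxao(calls[mk$marker[[i]], ], hom)
    t1 <- table(sp$n1)
    t3 <- table(sp$n3)
    expect_gt(gbsqtl:::chisq_ratio_p(as.numeric(t1), c(1, 1)), 0.001)
    expect_gt(gbsqtl:::chisq_ratio_p(as.numeric(t3)[order(names(t3))],
                                     c(1, 3)), 0.001)
  }
})

test_that("AOxBO detection is sensitive and specific at n = 184, depth 30", {
  hits <- 0; total <- 0; false_hits <- 0; abxab_total <- 0
  for (seed in c(21, 22, 23)) {
    cfg <- sim_config(n_offspring = 184, lg_lengths = c(LG1 = 80),
                      n_markers = 60,
                      type_proportions = c(ABxAA = 0.4, AAxAB = 0.25,
                                           ABxAB = 0.25, ABxAO = 0,
                                           AOxBO = 0.1),
                      mean_depth = 30, seed = seed)
    cross <- simulate_cross(cfg)
    mk <- cross$markers
    tbl <- call_genotypes(cross$counts)
    spread <- function(x, k) x[unique(round(seq(1, length(x),
                                                length.out = k)))]
    anchor_tbl <- function(ids, par)
      tibble::tibble(marker = ids, lg = "LG1",
                     pos = mk$pos[match(ids, mk$marker)], parent = par,
                     calls = lapply(ids, function(i) cross$true_calls[i, ]))
    anchors_lat <- anchor_tbl(spread(mk$marker[mk$type == "ABxAA"], 8), "lat")
    anchors_moy <- anchor_tbl(spread(mk$marker[mk$type == "AAxAB"], 8), "moy")
    cm <- calls_matrix(tbl)
    med_miss <- median(rowSums(is.na(cm)))
    run_detect <- function(row) {
      d <- cross$counts[cross$counts$snp_id == row$snp_id &
                          !cross$counts$individual %in% c("Latham", "Moy"), ]
      detect_aoxbo(row$calls[[1]], setNames(d$major, d$individual),
                   setNames(d$minor, d$individual),
                   c(row$parent_lat, row$parent_moy),
                   anchors_lat, anchors_moy, med_miss)$detected
    }
    for (id in mk$marker[mk$type == "AOxBO"]) {
      total <- total + 1
      row <- tbl[tbl$snp_id == id, ]
      if (row$type == "aoxbo_candidate" && run_detect(row))
        hits <- hits + 1
    }
    for (id in mk$marker[mk$type == "ABxAB"]) {
      abxab_total <- abxab_total + 1
      row <- tbl[tbl$snp_id == id, ]
      if (run_detect(row)) false_hits <- false_hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(false_hits / abxab_total, 0.01)
})
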