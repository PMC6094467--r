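test_that("simulated maps honour configured type proportions and determinism", {
  cfg <- sim_config(lg_lengths = c(LG1 = 100), n_markers = 1000, seed = 11)
  mk <- simulate_map(cfg)
  expect_equal(nrow(mk), 1000)
  frac_lat <- mean(mk$type == "ABxAA")
  expect_gt(frac_lat, 0.57)
  expect_lt(frac_lat, 0.67)
  mk2 <- simulate_map(cfg)
  expect_identical(mk, mk2)
  # degenerate mixture
  cfg2 <- sim_config(lg_lengths = c(LG1 = 50), n_markers = 30,
                     type_proportions = c(ABxAA = 1, AAxAB = 0, ABxAB = 0,
                                          ABxAO = 0, AOxBO = 0), seed = 2)
  expect_true(all(simulate_map(cfg2)$type == "ABxAA"))
  expect_error(sim_config(error_rate = 0.6), "error_rate")
  expect_error(sim_config(type_proportions = c(ABxAA = 1)), "type_proportions")
})

test_that("meioses switch between loci at the inverse-Haldane rate", {
  mk <- tibble::tibble(marker = c("a", "b"), lg = "LG1", pos = c(0, 10))
  set.seed(4)
  tr <- simulate_meioses(mk, 50000)
  r_exp <- (1 - exp(-2 * 10 / 100)) / 2
  expect_equal(r_exp, 0.0906, tolerance = 1e-3)
  for (par in c("lat", "moy")) {
    f <- mean(tr$LG1[[par]][1, ] != tr$LG1[[par]][2, ])
    se <- sqrt(r_exp * (1 - r_exp) / 50000)
    expect_lt(abs(f - r_exp), 3 * se)
  }
  # duplicate positions never switch
  mk0 <- tibble::tibble(marker = c("a", "b"), lg = "LG1", pos = c(5, 5))
  tr0 <- simulate_meioses(mk0, 2000)
  expect_true(all(tr0$LG1$lat[1, ] == tr0$LG1$lat[2, ]))
  # crossover count per meiosis ~ length/100 under Haldane
  cfg <- sim_config(lg_lengths = c(LG1 = 100), n_markers = 200, seed = 6)
  tr1 <- simulate_meioses(simulate_map(cfg), 2000)
  xo <- (sum(abs(diff(tr1$LG1$lat))) + sum(abs(diff(tr1$LG1$moy)))) / (2 * 2000)
  expect_equal(xo, 1, tolerance = 0.1)
})

test_that("read-count emissions follow the depth and error model", {
  cfg <- sim_config(n_offspring = 300, lg_lengths = c(LG1 = 10), n_markers = 30,
                    error_rate = 0, missing_rate = 0, depth_sdlog = 0,
                    seed = 8)
  cross <- simulate_cross(cfg)
  off <- cross$counts[!cross$counts$individual %in% c("Latham", "Moy"), ]
  truth_long <- cross$true_calls[cbind(
    match(off$snp_id, rownames(cross$true_calls)),
    match(off$individual, colnames(cross$true_calls)))]
  # error-free homozygotes carry zero minor reads
  expect_true(all(off$minor[!is.na(truth_long) & truth_long == "AA"] == 0))
  # true OO (missing truth at AOxBO loci) yields zero reads
  oo <- is.na(truth_long)
  expect_true(length(oo) > 0)
  expect_true(all(off$major[oo] + off$minor[oo] == 0))
  # heterozygote minor fraction ~ 1/2 (binomial split)
  het <- !is.na(truth_long) & truth_long == "AB" & (off$major + off$minor) > 0
  fr <- off$minor[het] / (off$major + off$minor)[het]
  expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(sum(het)))
})

test_that("segregation ratios match marker type at n = 5000", {
  cfg <- sim_config(n_offspring = 5000, lg_lengths = c(LG1 = 40),
                    n_markers = 12,
                    type_proportions = c(ABxAA = 0.25, AAxAB = 0.25,
                                         ABxAB = 0.2, ABxAO = 0.2,
                                         AOxBO = 0.1), seed = 13)
  cross <- simulate_cross(cfg)
  expected <- list(
    ABxAA = c(1, 1), AAxAB = c(1, 1), ABxAB = c(1, 2, 1),
    ABxAO = c(2, 1, 1), AOxAB = c(2, 1, 1), AOxBO = c(1, 1, 1))
  for (i in seq_len(nrow(cross$markers))) {
    ty <- cross$markers$type[[i]]
    calls <- cross$true_calls[cross$markers$marker[[i]], ]
    tab <- table(calls)
    ratio <- expected[[ty]]
    # orientation: sort both for the 1:1 and symmetric cases
    p <- gbsqtl:::chisq_ratio_p(sort(as.numeric(tab), decreasing = TRUE),
                                sort(ratio, decreasing = TRUE))
    expect_gt(p, 0.001)
  }
})

test_that("simulated traits realize the configured QTL size", {
  r2s <- vapply(1:8, function(s) {
    cfg <- sim_config(lg_lengths = c(LG1 = 100), n_markers = 10, seed = s,
                      qtl = list(qtl_spec("LG1", 40,
                                          qtl_means_for_pvar(0.15,
                                                             parent = "lat"))))
    cross <- simulate_cross(cfg)
    attr(cross$trait, "r2_true")
  }, 1)
  expect_lt(abs(mean(r2s) * 100 - 15), 4)
  # residual SD 0 -> exactly the class means
  cfg0 <- sim_config(lg_lengths = c(LG1 = 50), n_markers = 5, seed = 3,
                     qtl = list(qtl_spec("LG1", 25, c(1, 2, 3, 4), sd = 0)))
  cross0 <- simulate_cross(cfg0)
  expect_true(all(cross0$trait$trait %in% 1:4))
  # off-map QTL errors
  cfgbad <- sim_config(lg_lengths = c(LG1 = 50), n_markers = 5, seed = 3,
                       qtl = list(qtl_spec("LG1", 60, c(0, 0, 0, 0))))
  expect_error(simulate_cross(cfgbad), "off the simulated map")
})

test_that("ripening profiles are monotone and shift with the QTL state", {
  cfg <- sim_config(n_offspring = 60, lg_lengths = c(LG1 = 50), n_markers = 5,
                    seed = 9,
                    qtl = list(qtl_spec("LG1", 25, c(0, 0, 5, 5))))
  cross <- simulate_cross(cfg)
  dates <- seq(10, 80, by = 1)
  prof <- simulate_ripening_profiles(cross$truth, cross$config$qtl, dates,
                                     plot_sd = 0)
  mono <- prof |> dplyr::group_by(plot) |>
    dplyr::summarise(ok = !is.unsorted(score)) |> dplyr::pull(ok)
  expect_true(all(mono))
  expect_true(all(prof$score %in% 1:7))
  # stage times shift by the configured 5 days for the shifted classes
  st <- interpolate_stage_times(prof, stages = 4)
  tl <- cross$truth$LG1
  j <- which(abs(tl$pos - 25) < 1e-9)
  lat_h <- tl$lat[j, ]
  per_ind <- st |> dplyr::group_by(individual) |>
    dplyr::summarise(day = mean(day, na.rm = TRUE))
  shift <- c(0, 5)[lat_h[match(per_ind$individual,
                               sprintf("off%03d", 1:60))]]
  d <- tapply(per_ind$day, shift, mean)
  expect_equal(unname(d["5"] - d["0"]), 5, tolerance = 0.3)
  # no QTL effect, no noise -> one shared profile
  prof0 <- simulate_ripening_profiles(cross$truth, list(), dates, plot_sd = 0)
  wide <- tidyr::pivot_wider(prof0, id_cols = plot, names_from = date,
                             values_from = score)
  expect_equal(nrow(dplyr::distinct(wide[, -1])), 1)
})
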