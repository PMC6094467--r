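study_fixture <- function(seed = 3, map = "imbalanced") {
  cfg <- qtl_study_config(map, seed = seed)
  cross <- simulate_cross(cfg)
  mk <- cross$markers
  cms <- setNames(mk$classmap, mk$marker)
  model <- build_inheritance_model(mk[c("marker", "pos")], cms, eps = 0.002)
  list(cross = cross, model = model,
       trait = setNames(cross$trait$trait, cross$trait$individual))
}

test_that("grid genotype probabilities behave at informative and missing loci", {
  mk <- spaced_markers(6, 10, "AOxBO", seed = 4)
  cms <- lapply(seq_len(6), function(i)
    derive_classmap(mk$lat1[[i]], mk$lat2[[i]], mk$moy1[[i]], mk$moy2[[i]],
                    "n4"))
  names(cms) <- mk$marker
  model <- build_inheritance_model(mk[c("marker", "pos")], cms, eps = 0)
  # offspring fixed in state 1 (AC) everywhere
  calls <- matrix(vapply(cms, `[`, "", 1), 6, 1,
                  dimnames = list(mk$marker, "o1"))
  gp <- genotype_probs(model, calls, at = c(0, 25, 50))
  # at a fully informative marker position the posterior is a point mass
  expect_equal(unname(gp$probs["0", , 1]), c(1, 0, 0, 0), tolerance = 1e-4)
  # midpoint between two informative markers 10 cM apart: closed form
  r <- distance_to_rf(5)
  p_stay <- (1 - r)^2 / ((1 - r)^2 + r^2)   # per parent, conditional on
  gp5 <- genotype_probs(model, calls, at = 5)  # matching flanks
  expect_equal(unname(gp5$probs[1, , 1])[1], p_stay^2, tolerance = 1e-6)
  # all data missing -> 1/4 at every position
  calls_na <- matrix(NA_character_, 6, 1, dimnames = list(mk$marker, "o1"))
  gp_na <- genotype_probs(model, calls_na, at = c(0, 30))
  expect_true(all(abs(gp_na$probs - 0.25) < 1e-12))
  # rows sum to one
  expect_true(all(abs(apply(gp$probs, c(1, 3), sum) - 1) < 1e-9))
})

test_that("the scan recovers a deterministic class trait completely", {
  fx <- study_fixture(seed = 5)
  gp <- genotype_probs(fx$model, fx$cross$true_calls, step = 2)
  tl <- fx$cross$truth$LG2
  j <- which(abs(tl$pos - 67) < 1e-9)
  st <- gbsqtl:::state_index(tl)[j, ]
  y <- setNames(as.numeric(st == 1), sprintf("off%03d", 1:184))
  sc <- scan_qtl(gp, y)
  expect_gt(max(sc$profile$pvar), 95)
  expect_lt(abs(sc$peak$pos - 67), 5)
  # LOD is invariant to affine trait transformations
  sc2 <- scan_qtl(gp, 3 - 7 * y)
  expect_equal(sc$profile$lod, sc2$profile$lod, tolerance = 1e-8)
  # %var within [0, 100] and monotone with LOD at fixed n
  expect_true(all(sc$profile$pvar >= 0 & sc$profile$pvar <= 100))
  expect_equal(order(sc$profile$pvar), order(sc$profile$lod))
})

test_that("support intervals follow the drop rule", {
  prof <- tibble::tibble(pos = 40:60,
                         lod = 6 - 0.5 * abs(40:60 - 50))
  si <- support_intervals(prof)
  expect_equal(si$lower[si$drop == 1], 48)
  expect_equal(si$upper[si$drop == 1], 52)
  expect_equal(si$lower[si$drop == 2], 46)
  # nesting
  expect_lte(si$lower[si$drop == 2], si$lower[si$drop == 1])
  expect_gte(si$upper[si$drop == 2], si$upper[si$drop == 1])
  # flat profile -> whole group
  flat <- tibble::tibble(pos = 0:30, lod = rep(1, 31))
  sif <- support_intervals(flat)
  expect_equal(c(sif$lower[1], sif$upper[1]), c(0, 30))
})

test_that("key-parent calls follow the parental contrasts", {
  ses <- rep(0.05, 4)
  expect_identical(key_parent(c(0, 0, 1, 1), ses, df = 180)$label, "Latham")
  expect_identical(key_parent(c(0, 1, 0, 1), ses, df = 180)$label, "Moy")
  expect_identical(key_parent(c(0, 1, 1, 2), ses, df = 180)$label, "Both")
  expect_warning(kp <- key_parent(c(0.5, 0.5, 0.5, 0.5), rep(1, 4), df = 180),
                 "contrast")
  expect_identical(kp$label, "none")
})

test_that("permutation thresholds are deterministic and degenerate correctly", {
  fx <- study_fixture(seed = 7)
  gp <- genotype_probs(fx$model, fx$cross$true_calls, step = 4)
  y0 <- setNames(rep(1, 184), sprintf("off%03d", 1:184))
  th0 <- permutation_threshold(list(gp), y0, n_perm = 25, seed = 1)
  expect_equal(th0$threshold, 0, tolerance = 1e-8)
  y <- setNames(rnorm(184), sprintf("off%03d", 1:184))
  th1 <- permutation_threshold(list(gp), y, n_perm = 30, seed = 9)
  th2 <- permutation_threshold(list(gp), y, n_perm = 30, seed = 9)
  expect_equal(th1$threshold, th2$threshold)
  expect_error(permutation_threshold(list(gp), y, n_perm = 10), "n_perm")
  # threshold grows with genome size (more groups scanned)
  fx2 <- study_fixture(seed = 8)
  gp2 <- genotype_probs(fx2$model, fx2$cross$true_calls, step = 4)
  th_many <- permutation_threshold(list(gp, gp2, gp, gp2, gp, gp2), y,
                                   n_perm = 60, seed = 11)
  th_one <- permutation_threshold(list(gp), y, n_perm = 60, seed = 11)
  expect_gt(th_many$threshold, th_one$threshold)
})

test_that("a wide neighbour window reproduces the full HMM", {
  mk <- spaced_markers(8, 8, c("ABxAA", "ABxAB"), seed = 21)
  cms <- setNames(mk$classmap, mk$marker)
  model <- build_inheritance_model(mk[c("marker", "pos")], cms, eps = 0.01)
  set.seed(22)
  tr <- simulate_meioses(mk[c("marker", "lg", "pos")], 30)
  st <- gbsqtl:::state_index(tr$LG1)
  calls <- matrix(NA_character_, 8, 30, dimnames = list(mk$marker, NULL))
  for (i in 1:8) calls[i, ] <- mk$classmap[[i]][st[i, ]]
  colnames(calls) <- sprintf("o%02d", 1:30)
  full <- genotype_probs(model, calls, step = 8)
  win <- neighbor_window_probs(model, calls, k = 8, step = 8)
  expect_lt(max(abs(full$probs[dimnames(win$probs)[[1]], , ] - win$probs)),
            1e-10)
})
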