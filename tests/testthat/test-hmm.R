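simple_model <- function(n = 5, spacing = 5, eps = 0.01,
                         types = c("ABxAA", "ABxAB", "AAxAB"), seed = 2) {
  mk <- spaced_markers(n, spacing, types, seed = seed)
  build_inheritance_model(mk[c("marker", "pos")],
                          setNames(mk$classmap, mk$marker), eps = eps)
}

test_that("transition and emission structure behaves at the extremes", {
  T0 <- gbsqtl:::transition_matrix(0)
  expect_equal(T0, diag(4))
  Th <- gbsqtl:::transition_matrix(0.5)
  expect_equal(Th, matrix(0.25, 4, 4))
  expect_true(all(abs(rowSums(gbsqtl:::transition_matrix(0.123)) - 1) < 1e-12))
  # all observations missing -> posterior 1/4 everywhere
  model <- simple_model()
  calls <- matrix(NA_character_, 5, 3,
                  dimnames = list(model$markers, c("o1", "o2", "o3")))
  fb <- forward_backward(model, calls)
  expect_true(all(abs(fb$posterior - 0.25) < 1e-12))
  expect_true(all(is.finite(fb$loglik)))
})

test_that("forward-backward matches exhaustive enumeration (50 random cases)", {
  set.seed(55)
  for (case in 1:50) {
    m <- sample(2:4, 1)
    eps <- runif(1, 0.001, 0.2)
    types <- sample(c("ABxAA", "AAxAB", "ABxAB", "ABxAO", "AOxBO"), m, TRUE)
    mk <- spaced_markers(m, spacing = runif(1, 1, 30), types, seed = case)
    model <- build_inheritance_model(mk[c("marker", "pos")],
                                     setNames(mk$classmap, mk$marker),
                                     eps = eps)
    obs <- vapply(seq_len(m), function(t) {
      cls <- gbsqtl:::marker_classes(model$classmaps[[t]])
      sample(c(cls, NA), 1)
    }, character(1))
    calls <- matrix(obs, m, 1, dimnames = list(model$markers, "o1"))
    fb <- forward_backward(model, calls)
    oracle <- enumerate_hmm(model, obs)
    expect_equal(fb$loglik[[1]], oracle$loglik, tolerance = 1e-10)
    expect_lt(max(abs(fb$posterior[, , 1] - oracle$posterior)), 1e-10)
    # Viterbi path probability matches the enumerated best path
    vit <- reconstruct_states(model, calls)
    p_vit <- exp(path_logprob(model, obs, vit$states[, 1]))
    expect_equal(p_vit, oracle$viterbi_prob, tolerance = 1e-10)
  }
})

test_that("reversing the marker order leaves the likelihood unchanged", {
  model <- simple_model(n = 8, seed = 6)
  set.seed(7)
  mk <- spaced_markers(8, 5, c("ABxAA", "ABxAB", "AAxAB"), seed = 6)
  tr <- simulate_meioses(mk[c("marker", "lg", "pos")], 20)
  st <- gbsqtl:::state_index(tr$LG1)
  calls <- matrix(NA_character_, 8, 20, dimnames = list(mk$marker, NULL))
  for (i in 1:8) calls[i, ] <- mk$classmap[[i]][st[i, ]]
  colnames(calls) <- sprintf("o%02d", 1:20)
  fb <- forward_backward(model, calls)
  rev_map <- tibble::tibble(marker = rev(mk$marker),
                            pos = max(mk$pos) - rev(mk$pos))
  model_r <- build_inheritance_model(rev_map,
                                     setNames(mk$classmap, mk$marker),
                                     eps = model$eps)
  fb_r <- forward_backward(model_r, calls[rev(mk$marker), ])
  expect_equal(fb$loglik, fb_r$loglik, tolerance = 1e-8)
})

test_that("recombination matrices count the planted crossovers", {
  mk <- spaced_markers(20, 3, "ABxAB", seed = 10)
  model <- build_inheritance_model(mk[c("marker", "pos")],
                                   setNames(mk$classmap, mk$marker),
                                   eps = 0.01)
  # offspring with zero crossovers
  calls0 <- matrix(mk$classmap |> purrr::map_chr(1), 20, 1,
                   dimnames = list(mk$marker, "o1"))
  R0 <- reconstruct_states(model, calls0)
  expect_equal(sum(R0$lat) + sum(R0$moy), 0)
  expect_equal(hmm_mean(R0), 0)
  # one Latham crossover between markers 5 and 6
  st <- c(rep(1, 5), rep(3, 15))   # AC then BC
  calls1 <- matrix(vapply(1:20, function(i) mk$classmap[[i]][st[i]], ""),
                   20, 1, dimnames = list(mk$marker, "o1"))
  R1 <- reconstruct_states(model, calls1)
  expect_equal(which(R1$lat[, 1] == 1), 5)
  expect_equal(sum(R1$moy), 0)
  # column sums are total recombinations per offspring
  expect_equal(sum(R1$lat) + sum(R1$moy), 1)
  expect_error(hmm_mean(list(lat = R1$lat[, 0], moy = R1$moy[, 0],
                             n_offspring = 0)), "offspring")
})

test_that("hmm_mean on a fully informative 100 cM group is close to 2", {
  # fully state-identifying (four-class) markers every cM: the inferred
  # recombination count matches the Haldane expectation of one crossover
  # per parent per meiosis
  n <- 100
  mk <- tibble::tibble(marker = sprintf("m%03d", 1:n), lg = "LG1",
                       pos = seq(0, 99, length.out = n))
  cm4 <- derive_classmap("A", "O", "B", "O", "n4")
  cms <- setNames(rep(list(cm4), n), mk$marker)
  set.seed(51)
  tr <- simulate_meioses(mk, 184)
  st <- gbsqtl:::state_index(tr$LG1)
  calls <- matrix(cm4[st], n, 184, dimnames = list(mk$marker, sprintf("off%03d", 1:184)))
  model <- build_inheritance_model(mk[c("marker", "pos")], cms, eps = 0.005)
  R <- reconstruct_states(model, calls)
  expect_lt(abs(hmm_mean(R) - 2), 0.15)
  # and it matches the true planted count up to double crossovers falling
  # inside a single ~1 cM interval (invisible in principle)
  true_sw <- sum(abs(diff(tr$LG1$lat))) + sum(abs(diff(tr$LG1$moy)))
  inferred <- sum(R$lat) + sum(R$moy)
  expect_lte(inferred, true_sw)
  expect_lte(true_sw - inferred, 5)
})

test_that("improve_order repairs an injected swap and reports exclusions", {
  mk <- spaced_markers(30, 2, c("ABxAA", "ABxAA", "ABxAB", "AAxAB"),
                       seed = 12)
  set.seed(13)
  tr <- simulate_meioses(mk[c("marker", "lg", "pos")], 184)
  st <- gbsqtl:::state_index(tr$LG1)
  calls <- matrix(NA_character_, 30, 184, dimnames = list(mk$marker, NULL))
  for (i in 1:30) calls[i, ] <- mk$classmap[[i]][st[i, ]]
  colnames(calls) <- sprintf("off%03d", 1:184)
  cms <- setNames(mk$classmap, mk$marker)
  pw <- pairwise_linkage(calls, cms)
  map_true <- mk[c("marker", "pos")]
  # true order is a local optimum
  imp0 <- improve_order(map_true, calls, cms, eps = 0)
  expect_equal(nrow(imp0$moves), 0)
  expect_equal(imp0$hmm_mean_before, imp0$hmm_mean_after)
  # inject an adjacent swap
  bad <- map_true
  bad[15:16, "marker"] <- bad[16:15, ][["marker"]]
  imp <- improve_order(bad, calls, cms, eps = 0)
  expect_identical(imp$map$marker, map_true$marker)
  expect_lt(imp$total_after, imp$total_before)
  expect_equal(imp$hmm_mean_after, imp0$hmm_mean_after)
  # a badly scored marker shows the largest exclusion benefit
  calls_bad <- calls
  shuffle <- sample(184, 37)
  cls <- gbsqtl:::marker_classes(cms[["m010"]])
  calls_bad["m010", shuffle] <- sample(cls, 37, TRUE)
  imp2 <- improve_order(map_true, calls_bad, cms, eps = 0)
  er <- imp2$exclusion_report
  expect_identical(er$marker[which.max(er$saved_recombinations)], "m010")
})
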