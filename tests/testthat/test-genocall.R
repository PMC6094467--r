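make_counts <- function(snp_id, major, minor, quality = 50000,
                        individuals = sprintf("off%03d", seq_along(major))) {
  tibble::tibble(snp_id = snp_id, quality = quality,
                 individual = individuals, major = major, minor = minor)
}

test_that("filter_snps applies the depth, quality and heterozygosity rules", {
  n <- 184
  base <- function(id, per_ind_major, per_ind_minor, quality) {
    make_counts(id, per_ind_major, per_ind_minor, quality)
  }
  # depth boundary at n = 184: total 1839 removed, 1840 kept
  maj <- rep(10, n); maj[1] <- 9
  cts <- dplyr::bind_rows(
    base("depth1839", maj, rep(0, n), 50000),
    base("depth1840", rep(10, n), rep(0, n), 50000),
    base("qual9999", rep(20, n), rep(0, n), 9999),
    base("qual10000", rep(20, n), rep(0, n), 10000))
  kept <- unique(filter_snps(cts, n)$snp_id)
  expect_setequal(kept, c("depth1840", "qual10000"))
  # heterozygosity boundary: 90% of scoreable individuals het -> removed
  het_cts <- function(id, n_het) {
    major <- c(rep(15, n_het), rep(30, 100 - n_het))
    minor <- c(rep(15, n_het), rep(0, 100 - n_het))
    make_counts(id, major, minor)
  }
  cts2 <- dplyr::bind_rows(het_cts("het90", 90), het_cts("het89", 89))
  expect_identical(unique(filter_snps(cts2, 100)$snp_id), "het89")
  # idempotence
  f1 <- filter_snps(cts, n)
  f2 <- filter_snps(f1, n)
  attr(f1, "filter_summary") <- attr(f2, "filter_summary") <- NULL
  expect_identical(f1, f2)
  expect_error(filter_snps(cts, 0), "n_individuals")
})

test_that("the functional-regression heterozygote line is recovered", {
  # exact line y = x
  maj <- rep(c(100, 225, 400), 10)
  line <- fit_het_line(maj, maj)
  expect_equal(line$slope, 1, tolerance = 1e-8)
  expect_equal(line$intercept, 0, tolerance = 1e-8)
  # y = 0.5 x with symmetric perpendicular noise on sqrt axes
  set.seed(42)
  x <- runif(500, 5, 20)              # sqrt-scale positions along the line
  y <- 0.5 * x
  ang <- atan(0.5)
  noise <- rnorm(500, 0, 0.3)
  xs <- x - noise * sin(ang)
  ys <- y + noise * cos(ang)
  fit <- gbsqtl:::deming_fit(xs, ys)
  expect_lt(abs(fit$slope - 0.5), 0.05)
  # swapping axes inverts the slope
  fit_sw <- gbsqtl:::deming_fit(ys, xs)
  expect_equal(fit_sw$slope, 1 / fit$slope, tolerance = 0.02)
  # too few heterozygote candidates -> unclassifiable
  expect_null(fit_het_line(c(30, 30, 30, 28), c(0, 1, 0, 0)))
})

test_that("offspring classification follows nearest-line geometry", {
  line <- list(slope = 1, intercept = 0)
  expect_identical(classify_offspring(1, 1, line), NA_character_)
  expect_identical(classify_offspring(25, 0, line), "AA")
  expect_identical(classify_offspring(0, 25, line), "BB")
  # (13, 12): perpendicular distance to y = x is tiny vs sqrt(12) to the axes
  expect_identical(classify_offspring(13, 12, line), "AB")
  d_ab <- abs(sqrt(13) - sqrt(12)) / sqrt(2)
  expect_lt(d_ab, sqrt(12))
  # scaling an individual's counts by a common factor leaves the call alone
  set.seed(1)
  maj <- c(rbinom(50, 30, 0.5), rpois(25, 30), rep(0, 25))
  min_ <- c(30 - maj[1:50], rpois(25, 0.3), rpois(25, 30))
  calls1 <- classify_offspring(maj, min_, line)
  calls2 <- classify_offspring(3 * maj, 3 * min_, line)
  keep <- !is.na(calls1)
  expect_identical(calls1[keep], calls2[keep])
})

test_that("classification assessment rejects monomorphic, low-R2 and incompatible fits", {
  n <- 100
  calls_mono <- rep("AA", n)
  maj <- rep(30, n); min_ <- rep(0, n)
  res <- assess_classification(calls_mono, maj, min_, c("AA", "AA"))
  expect_false(res$accept)
  expect_identical(res$reason, "monomorphic")
  # perfectly separated classes -> R2 = 100, accepted
  calls <- rep(c("AA", "AB"), each = 50)
  maj2 <- c(rep(30, 50), rep(15, 50))
  min2 <- c(rep(0, 50), rep(15, 50))
  res2 <- assess_classification(calls, maj2, min2, c("AB", "AA"))
  expect_true(res2$accept)
  expect_equal(res2$r2, 100, tolerance = 1e-8)
  # R2 boundary at 50
  set.seed(7)
  pa_signal <- c(rep(1, 50), rep(0.5, 50))
  make_pa_counts <- function(noise_sd) {
    pa <- pmin(pmax(pa_signal + rnorm(n, 0, noise_sd), 0), 1)
    list(maj = round(100 * pa), min = round(100 * (1 - pa)))
  }
  lo <- make_pa_counts(0.4)
  res_lo <- assess_classification(calls, lo$maj, lo$min, c("AB", "AA"))
  expect_false(res_lo$accept)
  expect_identical(res_lo$reason, "low_r2")
  expect_lt(res_lo$r2, 50)
  # both parents the same homozygote but offspring segregate -> incompatible
  res3 <- assess_classification(calls, maj2, min2, c("AA", "AA"))
  expect_identical(res3$reason, "incompatible")
  # unknown parent does not force rejection
  res4 <- assess_classification(calls, maj2, min2, c(NA, "AA"))
  expect_true(res4$accept)
})

test_that("segregation types are assigned from class patterns and parents", {
  two_cl <- rep(c("AA", "AB"), c(90, 94))
  expect_identical(assign_segregation_type(two_cl, c("AB", "AA"))$type, "ABxAA")
  expect_identical(assign_segregation_type(two_cl, c("AA", "AB"))$type, "AAxAB")
  three_121 <- rep(c("AA", "AB", "BB"), c(46, 92, 46))
  expect_identical(assign_segregation_type(three_121, c("AB", "AB"))$type,
                   "ABxAB")
  three_211 <- rep(c("AA", "AB", "BB"), c(92, 46, 46))
  ty <- assign_segregation_type(three_211, c("AB", "AA"))
  expect_identical(ty$type, "null_candidate")
  expect_identical(ty$het_parent, "lat")
  expect_identical(
    assign_segregation_type(rep(c("AA", "AB", "BB"), c(60, 62, 58)),
                            c("AA", "BB"))$type, "aoxbo_candidate")
  expect_identical(assign_segregation_type(rep("AB", 100),
                                           c("AA", "AA"))$type, "rejected")
})

test_that("calls on simulated data are >= 99% accurate at depth 30", {
  cfg <- sim_config(n_offspring = 184, lg_lengths = c(LG1 = 60),
                    n_markers = 60,
                    type_proportions = c(ABxAA = 0.4, AAxAB = 0.3,
                                         ABxAB = 0.3, ABxAO = 0, AOxBO = 0),
                    mean_depth = 30, error_rate = 0.01, seed = 17)
  cross <- simulate_cross(cfg)
  tbl <- call_genotypes(cross$counts)
  expect_true(all(tbl$accept))
  cm <- calls_matrix(tbl)
  truth <- cross$true_calls[rownames(cm), colnames(cm)]
  ok <- !is.na(cm) & !is.na(truth)
  expect_gte(mean(cm[ok] == truth[ok]), 0.99)
  # type identification is exact on this clean simulation
  expect_identical(unname(tbl$type),
                   unname(cross$markers$type[match(tbl$snp_id,
                                                   cross$markers$marker)]))
})
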