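# Arm-level copy number: weighted averaging, clipping, and the two calling
# rules (threshold on the arm estimate; >50%-of-weight fraction rule).

gene_tab <- function(weight, log2_ratio, arm = "3p", sample = "S1") {
  data.frame(sample_id = sample, gene = paste0("G", seq_along(weight)),
             arm = arm, weight = weight, log2_ratio = log2_ratio,
             stringsAsFactors = FALSE)
}

test_that("the arm estimate is the weighted mean of gene copy numbers, clipped to [0, 4]", {
  # constant copy number is invariant to weights
  expect_equal(as.numeric(arm_copy_number(gene_tab(c(2, 5, 0.1), c(0, 0, 0)))), 2)
  # hand-computed: weights (1, 3), copy numbers (0, 2) -> (0*1 + 2*3)/4
  expect_equal(as.numeric(arm_copy_number(gene_tab(c(1, 3), c(-Inf, 0)))), 1.5)
  # single gene at log2 ratio 1 -> cn 4, at the clip boundary
  expect_equal(as.numeric(arm_copy_number(gene_tab(1, 1))), 4)
  # amplification clips to 4 but the raw value is preserved
  est <- arm_copy_number(gene_tab(1, 2))
  expect_equal(as.numeric(est), 4)
  expect_equal(attr(est, "raw"), 8)
  # deep loss clips to 0 from below is impossible (cn >= 0 by construction)
  expect_gte(as.numeric(arm_copy_number(gene_tab(1, -10))), 0)
})

test_that("the weighted mean matches an independently coded closed form on random tables", {
  set.seed(7)
  for (i in 1:500) {
    n <- sample(1:40, 1)
    w <- stats::runif(n, 0, 5)
    l <- stats::rnorm(n, 0, 1)
    est <- arm_copy_number(gene_tab(w, l))
    # independent route: explicit loop accumulation
    num <- 0; den <- 0
    for (j in seq_len(n)) { num <- num + w[j] * 2 * 2^l[j]; den <- den + w[j] }
    expect_equal(as.numeric(est), min(4, max(0, num / den)), tolerance = 1e-12)
  }
})

test_that("threshold calls honor the inclusive <=1 loss and >=3 gain boundaries", {
  expect_identical(call_arm_threshold(c(0.9, 1, 1 + 1e-9, 2, 3 - 1e-9, 3, 3.7)),
                   c("loss", "loss", "neutral", "neutral", "neutral",
                     "gain", "gain"))
  expect_identical(call_arm_threshold(NA_real_), NA_character_)
})

test_that("the fraction rule requires a strict weight majority", {
  # 60% of weight gained -> gain
  expect_identical(call_arm_fraction(gene_tab(c(6, 4), c(log2(3.5 / 2), 0))), "gain")
  # exactly 50% -> neutral (strict inequality)
  expect_identical(call_arm_fraction(gene_tab(c(5, 5), c(log2(3.5 / 2), 0))), "neutral")
  # all genes neutral -> neutral; majority lost -> loss
  expect_identical(call_arm_fraction(gene_tab(c(1, 1), c(0, 0))), "neutral")
  expect_identical(call_arm_fraction(gene_tab(c(7, 3), c(-2, 0))), "loss")
})

test_that("weight scale invariance and homogeneous-arm rule agreement hold", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    w <- stats::runif(n, 0.1, 3)
    l <- stats::rnorm(n)
    a <- arm_copy_number(gene_tab(w, l))
    b <- arm_copy_number(gene_tab(w * 37.5, l))
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
    expect_identical(call_arm_fraction(gene_tab(w, l)),
                     call_arm_fraction(gene_tab(w * 37.5, l)))
    # homogeneous arm: both rules agree
    l0 <- stats::rnorm(1)
    hom <- gene_tab(w, rep(l0, n))
    expect_identical(call_arm_threshold(as.numeric(arm_copy_number(hom))),
                     call_arm_fraction(hom))
  }
})

test_that("zero total weight yields a warned no-call", {
  expect_warning(est <- arm_copy_number(gene_tab(c(0, 0), c(1, 1))), "no-call")
  expect_true(is.na(est))
  expect_warning(expect_true(is.na(call_arm_fraction(gene_tab(0, 1)))), "no-call")
})

test_that("the cohort arm matrix reports per-arm alteration frequencies", {
  recs <- do.call(rbind, lapply(1:10, function(i) {
    gene_tab(c(1, 1), c(-2, -2), arm = "3p", sample = paste0("S", i))
  }))
  recs <- rbind(recs, gene_tab(1, 0, arm = "5q", sample = "S1"))
  est <- arm_copy_table(recs, rule = "threshold")
  cm <- cohort_arm_matrix(est)
  f3p <- cm$frequencies[cm$frequencies$arm == "3p", ]
  expect_identical(f3p$n_samples, 10L)
  expect_equal(f3p$frac_loss, 1.0)
  expect_identical(dim(cm$calls), c(2L, 10L))
  expect_identical(unname(cm$calls["5q", "S1"]), "neutral")

  empty <- cohort_arm_matrix(est[0, ])
  expect_identical(nrow(empty$frequencies), 0L)

  # arm_copy_table agrees with the scalar entry points per group
  one <- est[est$sample_id == "S1" & est$arm == "3p", ]
  expect_equal(one$cn_arm, 1 / 2)  # 2*2^-2 = 0.5
  expect_identical(one$call, "loss")
  expect_identical(one$rule_used, "threshold")
})
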