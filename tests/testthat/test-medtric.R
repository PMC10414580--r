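test_that("per-label contributions follow the three scoring branches", {
  cat3 <- diagnosis_catalog(c("A", "B", "C"))
  w <- matrix(0.5, 3, 3)
  diag(w) <- 1
  prev <- c(A = 4L, B = 5L, C = 1L)

  cfg1 <- metric_config(cat3, significance = 1, similarity = w)
  # correct prediction: +s/n
  expect_equal(label_contribution("A", "A", "A", prev, cfg1), 0.25)
  # missed: -s/n
  cfg2 <- metric_config(cat3, significance = 2, similarity = w)
  expect_equal(label_contribution("A", "A", character(0), prev, cfg2), -0.5)
  # extra: s/n* * (mean similarity to truth - 1), n* = max prevalence in truth
  expect_equal(
    label_contribution("C", c("A", "B"), c("A", "B", "C"), prev, cfg1),
    (1 / 5) * (0.5 - 1))
  # untouched code contributes nothing
  expect_equal(label_contribution("C", "A", "A", prev, cfg1), 0)
})

test_that("contradiction penalties hit both members of a predicted pair", {
  cat2 <- diagnosis_catalog(c("hypo", "hyper"))
  cfg <- metric_config(cat2, contradiction = list(c("hypo", "hyper")))
  prev <- c(hypo = 2L, hyper = 5L)
  z <- c("hypo", "hyper")
  expect_equal(contradiction_penalty("hypo", z, prev, cfg), -1 / 2)
  expect_equal(contradiction_penalty("hyper", z, prev, cfg), -1 / 5)
  expect_equal(contradiction_penalty("hypo", "hypo", prev, cfg), 0)
  # unpredicted code is never penalised
  expect_equal(contradiction_penalty("hyper", "hypo", prev, cfg), 0)
  # zero matrix: no penalty anywhere
  cfg0 <- metric_config(cat2)
  expect_equal(contradiction_penalty("hypo", z, prev, cfg0), 0)
  # never-observed predicted code falls back to the prevalence floor
  prev0 <- c(hypo = 0L, hyper = 1L)
  expect_equal(contradiction_penalty("hypo", z, prev0, cfg), -1)
})

test_that("instance totals match hand-computed singleton cases", {
  cat3 <- diagnosis_catalog(c("A", "B", "C"))
  cfg <- metric_config(cat3, similarity = 0.5)

  es1 <- evaluation_set(list(c("A", "B")), list(c("A", "B")), cat3)
  expect_equal(instance_score(c("A", "B"), c("A", "B"), es1, cfg)$total, 2)

  es2 <- evaluation_set(list(c("A", "B", "C")), list(character(0)), cat3)
  expect_equal(instance_score(c("A", "B", "C"), character(0), es2,
                              cfg)$total, -3)

  es3 <- evaluation_set(list("A"), list("B"), cat3)
  br <- instance_score("A", "B", es3, cfg)
  expect_equal(br$total, -1 + (0.5 - 1))
  expect_equal(br$per_code_a[["A"]], -1)
  expect_equal(br$per_code_a[["B"]], -0.5)
  expect_equal(sum(br$per_code_a) + sum(br$per_code_b), br$total)
})

test_that("the two printed contingencies score 0.833, witnessing prevalence
           invariance", {
  cfg <- metric_config(diagnosis_catalog(c("X", "A", "B")))
  m1 <- medtric(table5_case1(), cfg)
  m2 <- medtric(table5_case2(), cfg)
  expect_equal(round(m1$score, 3), 0.833)
  expect_equal(round(m2$score, 3), 0.833)
  expect_equal(m1$score, m2$score, tolerance = 1e-12)
  expect_equal(m1$score, 5 / 6, tolerance = 1e-12)
})

test_that("normalisation anchors: empty predictions 0, perfect 1", {
  set.seed(401)
  for (i in 1:20) {
    case <- rand_case(P_max = 5, N_max = 15, with_contra = (i %% 2 == 0))
    es <- case$es
    null_es <- evaluation_set(es$truth,
                              rep(list(character(0)), length(es$truth)),
                              es$catalog)
    perf_es <- evaluation_set(es$truth, es$truth, es$catalog)
    expect_equal(medtric(null_es, case$config)$score, 0, tolerance = 1e-9)
    expect_equal(medtric(perf_es, case$config)$score, 1, tolerance = 1e-9)
  }
})

test_that("missing one of three equally significant conditions scores 2/3", {
  ct <- diagnosis_catalog(c("CRBBB", "AF", "QAb"))
  es <- evaluation_set(list(c("CRBBB", "AF", "QAb")),
                       list(c("CRBBB", "AF")), ct)
  expect_equal(medtric(es, metric_config(ct))$score, 2 / 3,
               tolerance = 1e-12)
  # and the anchors hold for this singleton too, whatever the config
  cfg2 <- metric_config(ct, significance = c(CRBBB = 3, AF = 0.5, QAb = 1),
                        similarity = 0.9)
  empty <- evaluation_set(list(c("CRBBB", "AF", "QAb")),
                          list(character(0)), ct)
  perf <- evaluation_set(list(c("CRBBB", "AF", "QAb")),
                         list(c("CRBBB", "AF", "QAb")), ct)
  expect_identical(medtric(empty, cfg2)$score, 0)
  expect_identical(medtric(perf, cfg2)$score, 1)
})

test_that("score is invariant to significance rescaling and instance
           duplication", {
  set.seed(402)
  for (i in 1:10) {
    case <- rand_case()
    base <- medtric(case$es, case$config)$score
    for (c_scale in c(0.1, 7)) {
      cfg_scaled <- metric_config(case$es$catalog,
                                  significance = case$config$significance *
                                    c_scale,
                                  similarity = case$config$similarity,
                                  contradiction = case$config$contradiction)
      expect_equal(medtric(case$es, cfg_scaled)$score, base,
                   tolerance = 1e-9)
    }
    m <- sample(2:4, 1)
    es_dup <- evaluation_set(rep(case$es$truth, m),
                             rep(case$es$prediction, m), case$es$catalog)
    expect_equal(medtric(es_dup, case$config)$score, base, tolerance = 1e-9)
  }
})

test_that("missed penalties strictly dominate extra-prediction penalties", {
  set.seed(403)
  for (i in 1:25) {
    case <- rand_case(P_max = 5, N_max = 12)
    es <- case$es
    cfg <- case$config
    for (inst in seq_along(es$truth)) {
      y <- es$truth[[inst]]
      extras <- setdiff(es$prediction[[inst]], y)
      n_star <- max(es$prevalence[y])
      for (j in extras) {
        term <- label_contribution(j, y, es$prediction[[inst]],
                                   es$prevalence, cfg)
        expect_lt(term, 0)
        expect_gt(term, -cfg$significance[[j]] / n_star)
        # the printed bound -s_j/n_j applies when j is no more prevalent
        # than the instance's dominant truth code
        if (es$prevalence[[j]] > 0 && es$prevalence[[j]] <= n_star)
          expect_gt(term, -cfg$significance[[j]] / es$prevalence[[j]])
      }
    }
  }
})

test_that("per-instance totals fall strictly with each extra error", {
  ct <- synthetic_catalog(8)
  cfg <- metric_config(ct, similarity = 0.8)
  y <- ct$codes[1:4]
  es <- evaluation_set(list(y), list(y), ct)

  t_of <- function(z) instance_score(y, z, es, cfg)$total
  # dropping one more correct label strictly decreases the total
  drops <- sapply(4:0, function(k) t_of(y[seq_len(k)]))
  expect_true(all(diff(drops) < 0))
  # adding one more extra label strictly decreases the total
  adds <- sapply(0:4, function(k) t_of(c(y, ct$codes[4 + seq_len(k)])))
  expect_true(all(diff(adds) < 0))
  # any wrong diagnosis scores strictly below the all-missed prediction
  t_empty <- t_of(character(0))
  for (k in 1:4)
    expect_lt(t_of(ct$codes[4 + seq_len(k)]), t_empty)
})

test_that("breakdowns reconcile with the aggregate raw total", {
  set.seed(404)
  case <- rand_case(with_contra = TRUE)
  res <- medtric(case$es, case$config, breakdowns = TRUE)
  expect_length(res$breakdowns, length(case$es$truth))
  totals <- vapply(res$breakdowns, `[[`, numeric(1), "total")
  expect_equal(sum(totals), res$raw_t, tolerance = 1e-12)
  expect_equal(res$score,
               (res$raw_t - res$null_t) / (res$perfect_t - res$null_t))
})

test_that("clinical-order margin is negative across its guarantee region", {
  set.seed(405)
  for (i in 1:20) {
    P <- sample(3:6, 1)
    catalog <- synthetic_catalog(P)
    fn <- sample(1:3, P, replace = TRUE)
    fp <- vapply(fn, function(f) sample(0:(2 * f), 1), integer(1))
    es <- margin_set(catalog, 8, fn, fp)
    cfg <- metric_config(catalog, significance = runif(P, 0.5, 2),
                         similarity = runif(1, 0.05, 0.95))
    xi <- clinical_order_margin(es, cfg)
    expect_true(all(xi < 0))
  }
})

test_that("margin region widens to fp < 3 fn when similarity floor is 1/3", {
  set.seed(406)
  for (i in 1:10) {
    P <- sample(3:6, 1)
    catalog <- synthetic_catalog(P)
    fn <- sample(1:3, P, replace = TRUE)
    fp <- vapply(fn, function(f) sample(0:(3 * f - 1), 1), integer(1))
    es <- margin_set(catalog, 10, fn, fp)
    cfg <- metric_config(catalog, similarity = 1 / 3)
    xi <- clinical_order_margin(es, cfg)
    expect_true(all(xi < 0))
  }
  # no false positives at all: the margin is negative however w is chosen
  catalog <- synthetic_catalog(4)
  es <- margin_set(catalog, 5, fn = rep(2L, 4), fp = rep(0L, 4))
  cfg <- metric_config(catalog, similarity = 0.99)
  expect_true(all(clinical_order_margin(es, cfg) < 0))
})
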