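test_that("contingency counts validate and build from databases", {
  expect_error(label_contingency("l", 100, 20, 10, 15), "counts must")
  expect_error(label_contingency("l", 0, 0, 0, 0), "n_total")
  cc <- label_contingency("l", 100, 20, 10, 5)
  expect_equal(cc$n_both, 5L)

  fx <- toy_fixture()
  cc2 <- build_contingency(fx$db, fx$seed, "reward")
  expect_equal(cc2$n_total, fx$expected$reward$n_total)
  expect_equal(cc2$n_seed, fx$expected$reward$n_seed)
  expect_equal(cc2$n_label, fx$expected$reward$n_label)
  expect_equal(cc2$n_both, fx$expected$reward$n_both)

  # absent label: zero counts with a warning
  expect_warning(cc3 <- build_contingency(fx$db, fx$seed, "absent"),
                 "does not occur")
  expect_equal(cc3$n_label, 0L)
  expect_equal(cc3$n_both, 0L)

  # whole-brain seed: n_seed = n_total, n_both = n_label
  wb <- whole_brain_seed(fx$grid)
  cc4 <- build_contingency(fx$db, wb, "memory")
  expect_equal(cc4$n_seed, cc4$n_total)
  expect_equal(cc4$n_both, cc4$n_label)
})

test_that("forward inference matches the enumeration oracle", {
  cc <- label_contingency("l", 1000, 40, 50, 8)
  fw <- forward_inference(cc)
  expect_equal(fw$p, enum_binom_tail(8, 40, 0.05), tolerance = 1e-12)
  expect_true(fw$significant)    # 8/40 = 0.2 >> 0.05, p ~ 1e-5

  # observed rate at the base rate: no significance, p >= 0.5
  cc2 <- label_contingency("l", 100, 20, 10, 2)   # 2/20 = 10/100
  fw2 <- forward_inference(cc2)
  expect_gte(fw2$p, 0.5)
  expect_false(fw2$significant)

  # n_both = 0: tail covers everything
  cc3 <- label_contingency("l", 100, 20, 10, 0)
  expect_equal(forward_inference(cc3)$p, 1)
  expect_false(forward_inference(cc3)$significant)

  # monotone non-increasing in n_both at fixed margins
  ps <- vapply(0:10, function(b)
    forward_inference(label_contingency("l", 200, 30, 60, b))$p, 0)
  expect_true(all(diff(ps) <= 0))

  # undefined when the label is absent
  fw4 <- forward_inference(label_contingency("l", 100, 0, 10, 0))
  expect_true(is.na(fw4$p))
  expect_false(fw4$significant)
})

test_that("reverse inference follows Bayes and the Pearson chi-square", {
  # worked Bayes arithmetic: posterior = P(A|T) P(T) / P(A) = n_both/n_seed
  cc <- label_contingency("l", 1000, 40, 50, 8)
  rv <- reverse_inference(cc)
  expect_equal(rv$posterior, 8 / 50)
  expect_equal((8 / 40) * (40 / 1000) / (50 / 1000), rv$posterior,
               tolerance = 1e-15)

  # independence-constructed table: chi2 = 0, p = 1
  cc0 <- label_contingency("l", 100, 20, 10, 2)
  rv0 <- reverse_inference(cc0)
  expect_equal(rv0$chi2, 0, tolerance = 1e-12)
  expect_equal(rv0$p, 1)

  # random tables vs the textbook statistic (chisq.test as cross-check)
  set.seed(10)
  for (i in 1:20) {
    nt <- sample(50:500, 1)
    ns <- sample(5:(nt / 2), 1)
    nl <- sample(5:(nt / 2), 1)
    nb <- sample(max(0, ns + nl - nt):min(ns, nl), 1)
    cc <- label_contingency("l", nt, nl, ns, nb)
    rv <- reverse_inference(cc)
    o <- matrix(c(nb, ns - nb, nl - nb, nt - nl - ns + nb), 2, 2)
    if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
      expect_true(rv$undefined)
      next
    }
    ref <- suppressWarnings(stats::chisq.test(o, correct = FALSE))
    expect_equal(rv$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(rv$p, ref$p.value, tolerance = 1e-10)
    # posterior identity, cross-multiplied in exact integer arithmetic
    expect_identical(nb * nt * nl * ns, ns * (nb * nl) * nt)
    expect_equal(rv$posterior * ns, nb, tolerance = 1e-12)
  }

  # degenerate margin flagged undefined
  rvd <- reverse_inference(label_contingency("l", 100, 0, 10, 0))
  expect_true(rvd$undefined)
  expect_false(rvd$significant)
})

test_that("robust flags are rare under independent labels", {
  set.seed(11)
  n_sim <- 10000
  nt <- 500L; ns <- 50L
  nl <- stats::rbinom(n_sim, nt, 0.1)
  false_robust <- 0L
  for (i in seq_len(n_sim)) {
    if (nl[i] == 0) next
    nb <- stats::rhyper(1, ns, nt - ns, nl[i])
    cc <- label_contingency("l", nt, nl[i], ns, nb)
    if (isTRUE(forward_inference(cc)$significant) &&
        isTRUE(reverse_inference(cc)$significant))
      false_robust <- false_robust + 1L
  }
  # dominated by the stricter of the two 0.001-level tests
  expect_lte(false_robust / n_sim, 0.001 + 3 * sqrt(0.001 / n_sim))
})

test_that("decode_seed flags planted enrichment and sizes its table", {
  g <- small_grid(16)
  seed <- make_sphere_seed(c(0, 0, 0), 5, g, "s")
  # constructed database: 60 seed experiments of which 40 carry the label,
  # 240 non-seed experiments of which 12 carry it
  mk <- function(id, in_seed, labs)
    experiment(id, 15, if (in_seed) c(0, 0, 0) else c(10, 8, 0), labs)
  exps <- c(
    lapply(1:40, function(i) mk(sprintf("s1_%02d", i), TRUE, "reward")),
    lapply(1:20, function(i) mk(sprintf("s0_%02d", i), TRUE, character())),
    lapply(1:12, function(i) mk(sprintf("b1_%02d", i), FALSE, "reward")),
    lapply(1:228, function(i) mk(sprintf("b0_%03d", i), FALSE, "other")))
  db <- coordinate_database(exps, g)
  tab <- decode_seed(db, seed)
  expect_s3_class(tab, "decoding_table")
  expect_equal(nrow(tab), 2L)
  rw <- tab[tab$label == "reward", ]
  expect_true(rw$robust)
  expect_false(tab[tab$label == "other", ]$robust)

  # single-label taxonomy
  expect_equal(nrow(decode_seed(db, seed, taxonomy = "reward")), 1L)
})

test_that("hierarchical labels expand to their parents on request", {
  g <- small_grid(12)
  seed <- make_sphere_seed(c(0, 0, 0), 4, g, "s")
  db <- coordinate_database(list(
    experiment("a", 10, c(0, 0, 0), "Cognition.Memory.Explicit"),
    experiment("b", 10, c(8, 6, 0), "Cognition")), g)
  cc_off <- suppressWarnings(
    build_contingency(db, seed, "Cognition", expand_prefixes = FALSE))
  cc_on <- build_contingency(db, seed, "Cognition", expand_prefixes = TRUE)
  expect_equal(cc_off$n_label, 1L)
  expect_equal(cc_on$n_label, 2L)
  expect_equal(cc_on$n_both, 1L)
})

test_that("Benjamini-Hochberg matches an independent step-up", {
  set.seed(12)
  for (k in 1:5) {
    p <- stats::runif(sample(5:40, 1))^2
    bh <- stats::p.adjust(p, method = "BH")
    # independent step-up implementation
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    ref <- numeric(n)
    ref[o] <- adj
    expect_equal(bh, ref, tolerance = 1e-12)
  }
})

test_that("contrast decoding applies FDR and the masking rule", {
  g <- small_grid(16)
  sA <- make_sphere_seed(c(-8, 0, 0), 5, g, "A")
  sB <- make_sphere_seed(c(8, 0, 0), 5, g, "B")
  mk <- function(id, where, labs) {
    focus <- switch(where, a = c(-8, 0, 0), b = c(8, 0, 0),
                    none = c(0, 10, 0))
    experiment(id, 15, focus, labs)
  }
  # "reward" enriched in A (robust individually), "common" everywhere
  exps <- c(
    lapply(1:35, function(i) mk(sprintf("a1_%02d", i), "a",
                                c("reward", "common"))),
    lapply(1:15, function(i) mk(sprintf("a0_%02d", i), "a", "common")),
    lapply(1:5, function(i) mk(sprintf("b1_%02d", i), "b",
                               c("reward", "common"))),
    lapply(1:45, function(i) mk(sprintf("b0_%02d", i), "b", "common")),
    lapply(1:200, function(i) mk(sprintf("n_%03d", i), "none",
                                 c("common", "other")[1 + (i %% 2)])))
  db <- coordinate_database(exps, g)
  ct <- contrast_decoding(db, sA, sB)
  ra <- ct$a[ct$a$label == "reward", ]
  expect_true(ra$reported)
  expect_false(ct$b[ct$b$label == "reward", ]$reported)

  # masking counterexample: "common" is universal in A and B selections,
  # so the contrast cannot report it; craft a label contrast-significant
  # but NOT individually robust: "skew" present in most A-only and no
  # B-only experiments, yet at the database base rate overall
  exps2 <- c(
    lapply(1:30, function(i) mk(sprintf("a1_%02d", i), "a", "skew")),
    lapply(1:10, function(i) mk(sprintf("a0_%02d", i), "a", character())),
    lapply(1:40, function(i) mk(sprintf("b0_%02d", i), "b", character())),
    lapply(1:150, function(i) mk(sprintf("n1_%03d", i), "none", "skew")),
    lapply(1:50, function(i) mk(sprintf("n0_%03d", i), "none", character())))
  db2 <- coordinate_database(exps2, g)
  tabA <- decode_seed(db2, sA)
  expect_false(tabA[tabA$label == "skew", ]$robust)
  ct2 <- contrast_decoding(db2, sA, sB, taxonomy = "skew")
  # the raw contrast is overwhelming but masking excludes the label
  expect_lt(ct2$a$p_fdr[1], 0.05)
  expect_false(ct2$a$reported[1])

  # identical seeds: no experiment is exclusive to either side
  ct3 <- contrast_decoding(db, sA, sA)
  expect_false(any(ct3$a$reported))
  expect_false(any(ct3$b$reported))
})

test_that("decoding conjunction is the intersection of robust sets", {
  mktab <- function(labels, robust) {
    tab <- data.frame(label = labels, robust = robust)
    tab
  }
  ta <- mktab(c("x", "y", "z"), c(TRUE, TRUE, FALSE))
  tb <- mktab(c("x", "y", "z"), c(FALSE, TRUE, TRUE))
  expect_equal(conjunction_decoding(ta, tb), "y")
  expect_equal(conjunction_decoding(ta, ta), c("x", "y"))
  tc <- mktab(c("x", "y"), c(TRUE, TRUE))
  expect_error(conjunction_decoding(ta, tc), "taxonomies")
  td <- mktab(c("x", "y", "z"), c(FALSE, FALSE, TRUE))
  expect_equal(conjunction_decoding(ta, td), character())

  set.seed(13)
  for (k in 1:5) {
    labs <- paste0("l", 1:12)
    ra <- stats::runif(12) < 0.4
    rb <- stats::runif(12) < 0.4
    got <- conjunction_decoding(mktab(labs, ra), mktab(labs, rb))
    expect_setequal(got, labs[ra & rb])
  }
})

test_that("forward inference p-values drive seed profiles consistently", {
  # verbose consistency check between decode_seed rows and the per-label
  # primitives on a mid-sized constructed database
  g <- small_grid(12)
  seed <- make_sphere_seed(c(0, 0, 0), 4, g, "s")
  set.seed(14)
  exps <- lapply(1:80, function(i) {
    hit <- i <= 25
    labs <- c(if (stats::runif(1) < (0.6 * hit + 0.1)) "reward",
              if (stats::runif(1) < 0.3) "memory")
    experiment(sprintf("e%02d", i), sample(8:30, 1),
               if (hit) c(0, 0, 0) else c(8, -6, 2), labs)
  })
  db <- coordinate_database(exps, g)
  tab <- decode_seed(db, seed)
  for (r in seq_len(nrow(tab))) {
    cc <- suppressWarnings(build_contingency(db, seed, tab$label[r]))
    expect_equal(tab$forward_p[r], forward_inference(cc)$p)
    expect_equal(tab$reverse_chi2[r], reverse_inference(cc)$chi2)
    expect_equal(tab$robust[r],
                 forward_inference(cc)$significant &&
                   reverse_inference(cc)$significant)
  }
})
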