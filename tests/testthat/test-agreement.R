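test_that("self-agreement is diagonal with kappa 1 and 100% specific agreement", {
  set.seed(21)
  h <- hypnogram(sample(stage_levels(), 200, replace = TRUE))
  m <- confusion_matrix(h, h)
  expect_equal(sum(m) - sum(diag(m)), 0)
  expect_equal(cohens_kappa(m), 1)
  for (s in stage_levels()) {
    sa <- specific_agreement(stage_collapse(m, s))
    expect_equal(unname(sa[c("PA", "NA", "OA")]), c(100, 100, 100))
  }
})

test_that("confusion counts, kappa and PA/NA/OA match brute-force oracles on 500 random pairs", {
  for (i in 1:500) {
    p <- random_hypnogram_pair(n = sample(5:40, 1), seed = 9000 + i)
    ref <- hypnogram(p$ref); cand <- hypnogram(p$cand)
    m <- confusion_matrix(ref, cand)
    expect_identical(unclass(m)[, ], oracle_confusion(p$ref, p$cand)[, ])
    expect_equal(suppressWarnings(cohens_kappa(m)),
                 oracle_kappa(p$ref, p$cand), tolerance = 1e-12)
    for (s in c("W", "N2", "R")) {
      expect_equal(specific_agreement(stage_collapse(m, s)),
                   oracle_pnoa(p$ref, p$cand, s), tolerance = 1e-12)
    }
  }
})

test_that("kappa matches the hand-worked 2x2 example and is near zero for independent scorers", {
  # 2x2 example embedded in the W/N1 corner: counts [[45,5],[15,35]]
  m <- matrix(0, 5, 5, dimnames = list(stage_levels(), stage_levels()))
  m["W", "W"] <- 45; m["W", "N1"] <- 5; m["N1", "W"] <- 15; m["N1", "N1"] <- 35
  expect_equal(cohens_kappa(m), 0.6, tolerance = 1e-12)

  p <- random_hypnogram_pair(1e4, seed = 31)
  expect_lt(abs(cohens_kappa(confusion_matrix(hypnogram(p$ref), hypnogram(p$cand)))),
            0.05)
})

test_that("swapping scorers transposes the matrix, preserves kappa and OA, and swaps b and c", {
  p <- random_hypnogram_pair(300, seed = 41)
  ref <- hypnogram(p$ref); cand <- hypnogram(p$cand)
  m <- confusion_matrix(ref, cand); mt <- confusion_matrix(cand, ref)
  expect_equal(unclass(mt)[, ], t(unclass(m)[, ]))
  expect_equal(cohens_kappa(m), cohens_kappa(mt), tolerance = 1e-12)
  for (s in stage_levels()) {
    a <- stage_collapse(m, s); b <- stage_collapse(mt, s)
    expect_equal(a[["b"]], b[["c"]])
    expect_equal(a[["c"]], b[["b"]])
    expect_equal(specific_agreement(a)[c("PA", "NA", "OA")],
                 specific_agreement(b)[c("PA", "NA", "OA")])
  }
})

test_that("per-stage collapses conserve counts and pooled PA equals observed agreement", {
  p <- random_hypnogram_pair(500, seed = 51)
  m <- confusion_matrix(hypnogram(p$ref), hypnogram(p$cand))
  n <- attr(m, "n")
  for (s in stage_levels()) {
    cl <- stage_collapse(m, s)
    expect_equal(cl[["a"]] + cl[["b"]] + cl[["c"]] + cl[["d"]], n)
  }
  # algebraic identity: pooled 2a/(2a+b+c) over stages = sum(diag)/n
  mm <- somnostage:::agreement_metrics(m)
  expect_equal(mm$total[["PA"]], 100 * sum(diag(m)) / n, tolerance = 1e-12)
})

test_that("row percentages sum to 100, flag empty rows, and match the reference table", {
  p <- random_hypnogram_pair(400, seed = 61)
  rp <- row_percentages(confusion_matrix(hypnogram(p$ref), hypnogram(p$cand)))
  expect_equal(unname(rowSums(rp)), rep(100, 5), tolerance = 1e-9)

  m <- matrix(0, 5, 5); m[1, 1] <- 10
  rp2 <- row_percentages(m)
  expect_true(all(is.na(rp2[2:5, ])))
  expect_equal(rp2[1, 1], 100)

  ref <- clinical_reference_tables()$confusion_percent
  expect_equal(unname(rowSums(ref)), rep(100, 5), tolerance = 0.1)
})

test_that("kappa interpretation follows right-closed Landis-Koch breakpoints", {
  expect_identical(interpret_kappa(0.85), "almost perfect")
  expect_identical(interpret_kappa(-0.1), "poor")
  expect_identical(interpret_kappa(0.20), "slight")
  expect_identical(interpret_kappa(0.21), "fair")
  expect_identical(interpret_kappa(0.80), "substantial")
  expect_identical(interpret_kappa(1), "almost perfect")
  expect_error(interpret_kappa(1.2), class = "somnostage_input_error")
  custom <- kappa_scale(c(0, 0.5), c("bad", "ok", "good"))
  expect_identical(interpret_kappa(0.4, custom), "ok")
})

test_that("degenerate agreement cases are flagged, not propagated", {
  h <- hypnogram(rep("N2", 50))
  m <- confusion_matrix(h, h)
  expect_warning(k <- cohens_kappa(m), "undefined")
  expect_true(is.na(k))
  cl <- stage_collapse(m, "W")  # a=0, b=c=0, d=n
  sa <- specific_agreement(cl)
  expect_true(is.na(sa[["PA"]]))
  expect_equal(unname(sa[c("NA", "OA")]), c(100, 100))
})

test_that("bootstrap report: identical subjects give zero-width CIs; seeds reproduce", {
  p <- random_hypnogram_pair(120, seed = 71)
  pair <- list(reference = hypnogram(p$ref), candidate = hypnogram(p$cand))
  rep1 <- bootstrap_agreement(rep(list(pair), 4), R = 100, seed = 5)
  for (s in stage_levels()) {
    d <- rep1$per_stage[[s]]
    expect_equal(d$lo, d$median, tolerance = 1e-12)
    expect_equal(d$hi, d$median, tolerance = 1e-12)
  }
  rep2 <- bootstrap_agreement(rep(list(pair), 4), R = 100, seed = 5)
  expect_identical(rep1$per_stage, rep2$per_stage)
  expect_identical(rep1$total, rep2$total)
})

test_that("two-subject bootstrap median equals the mixed-pool value (exact enumeration)", {
  # subject 1 agrees perfectly; subject 2 half the time on W/N2
  h1 <- hypnogram(rep(c("W", "N2", "N3", "R", "N1"), each = 8))
  s2r <- hypnogram(rep(c("W", "N2"), each = 20))
  s2c <- hypnogram(c(rep("W", 10), rep("N2", 10), rep("N2", 10), rep("W", 10)))
  pairs <- list(list(reference = h1, candidate = h1),
                list(reference = s2r, candidate = s2c))
  # enumerate the three possible resamples by brute force
  refs <- list(c(as.character(h1), as.character(h1)),
               c(as.character(h1), as.character(s2r)),
               c(as.character(s2r), as.character(s2r)))
  cands <- list(c(as.character(h1), as.character(h1)),
                c(as.character(h1), as.character(s2c)),
                c(as.character(s2c), as.character(s2c)))
  oa_vals <- sort(vapply(1:3, function(i) {
    mean(vapply(stage_levels(), function(s) oracle_pnoa(refs[[i]], cands[[i]], s)[["OA"]],
                numeric(1)))
  }, numeric(1)))
  rep1 <- bootstrap_agreement(pairs, R = 1001, seed = 9)
  expect_equal(rep1$total$median[rep1$total$metric == "OA"], oa_vals[2],
               tolerance = 1e-9)
})

test_that("metrics undefined in most resamples are reported as undefined with a diagnostic", {
  h <- hypnogram(rep("N2", 30))
  pair <- list(reference = h, candidate = h)  # N3 never used: PA undefined
  expect_warning(rep1 <- bootstrap_agreement(list(pair), R = 50, seed = 3),
                 "undefined")
  expect_true(is.na(rep1$per_stage[["N3"]]$median[1]))
})

test_that("bootstrap CIs cover a known population agreement in at least 90% of trials", {
  prop <- c(W = 0.2, N1 = 0.15, N2 = 0.4, N3 = 0.05, R = 0.2)
  noise <- clinical_reference_tables()$confusion_percent / 100
  pop_pa <- 100 * sum(prop * diag(noise))  # population pooled PA = sum pi_s C_ss
  hits <- 0
  for (trial in 1:200) {
    set.seed(5000 + trial)
    pairs <- lapply(1:15, function(i) {
      truth <- hypnogram(sample(stage_levels(), 200, replace = TRUE, prob = prop))
      list(reference = truth,
           candidate = corrupt_hypnogram(truth, noise, seed = 5000 + trial * 31 + i))
    })
    r <- bootstrap_agreement(pairs, R = 200, seed = trial)
    tot <- r$total[r$total$metric == "PA", ]
    if (tot$lo <= pop_pa && pop_pa <= tot$hi) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("agreement report serialises to JSON and the overlay plot is written", {
  p <- random_hypnogram_pair(60, seed = 81)
  pair <- list(reference = hypnogram(p$ref), candidate = hypnogram(p$cand))
  r <- suppressWarnings(bootstrap_agreement(list(pair, pair), R = 50, seed = 2))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_agreement_report(r, jpath)
  back <- jsonlite::read_json(jpath)
  expect_equal(back$kappa, r$kappa, tolerance = 1e-9)
  expect_equal(back$R, 50)

  ppath <- withr::local_tempfile(fileext = ".png")
  hypnogram_overlay(pair$reference, pair$candidate, ppath)
  expect_true(file.exists(ppath) && file.size(ppath) > 0)
  expect_error(hypnogram_overlay(pair$reference, hypnogram(rep("W", 3)), ppath),
               class = "somnostage_input_error")
})
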