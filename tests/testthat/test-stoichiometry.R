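test_that("the pair filter keeps exactly non-rejected-green + non-rejected-farred", {
  ## enumerate all label combinations and compare with the predicate
  g_classes <- c("rejected", "1-step")
  f_classes <- c("rejected", "1-step", "2-step", "3-and-higher")
  combos <- expand.grid(g = g_classes, f = f_classes, stringsAsFactors = FALSE)
  nfr <- 60
  g_tr <- sapply(combos$g, function(cl) {
    if (cl == "1-step") make_staircase(nfr, 30, 120) else rep(200, nfr)
  })
  f_tr <- sapply(combos$f, function(cl) {
    switch(cl,
           "rejected" = rep(200, nfr),
           "1-step" = make_staircase(nfr, 30, 120),
           "2-step" = make_staircase(nfr, c(20, 40), c(120, 120)),
           "3-and-higher" = make_staircase(nfr, c(15, 30, 45), c(120, 110, 130)))
  })
  colnames(g_tr) <- colnames(f_tr) <- seq_len(nrow(combos))
  pairs <- data.frame(pair_id = seq_len(nrow(combos)),
                      green_id = seq_len(nrow(combos)),
                      farred_id = seq_len(nrow(combos)))
  cp <- run_pipeline(pairs, g_tr, f_tr)
  expected <- combos$g != "rejected" & combos$f != "rejected"
  expect_equal(cp$retained, expected)
  ## conservation: retained + excluded = input
  expect_equal(sum(cp$retained) + sum(!cp$retained), nrow(combos))
  ## spot checks from the rule
  expect_false(cp$retained[cp$green_class == "1-step" &
                           cp$farred_class == "rejected"][1])
  expect_true(all(cp$retained[cp$green_class == "1-step" &
                              cp$farred_class == "2-step"]))
})

test_that("orphan traces are excluded and counted", {
  nfr <- 60
  g_tr <- cbind("1" = make_staircase(nfr, 30, 120))
  f_tr <- cbind("1" = make_staircase(nfr, 30, 120))
  pairs <- data.frame(pair_id = 1:2, green_id = c(1, 2), farred_id = c(1, 9))
  cp <- run_pipeline(pairs, g_tr, f_tr)
  expect_equal(nrow(cp), 1)
  expect_equal(attr(cp, "n_orphan"), 1L)
})

test_that("replicate summaries compute percentages and the oligomeric fraction", {
  d <- data.frame(
    genotype = "wt", bio_rep = 1, tech_rep = 1,
    farred_class = rep(c("1-step", "2-step", "3-and-higher"), c(6, 3, 1)),
    retained = TRUE)
  s <- summarize_stoich(d)
  expect_equal(s$technical$pct_1step, 60)
  expect_equal(s$technical$pct_2step, 30)
  expect_equal(s$technical$pct_3plus, 10)
  expect_equal(s$technical$oligomeric_pct, 40)
  expect_equal(s$technical$pct_1step + s$technical$pct_2step +
                 s$technical$pct_3plus, 100, tolerance = 1e-9)
  ## all monomeric: zero oligomeric
  d2 <- within(d, farred_class <- "1-step")
  expect_equal(summarize_stoich(d2)$technical$oligomeric_pct, 0)
})

test_that("summaries are invariant to row order and to splitting a replicate", {
  set.seed(31)
  d <- data.frame(
    genotype = rep(c("wt", "mut"), each = 60),
    bio_rep = rep(rep(1:2, each = 30), 2),
    tech_rep = rep(rep(1:3, each = 10), 4),
    farred_class = sample(c("1-step", "2-step", "3-and-higher"), 120, TRUE),
    retained = TRUE)
  s1 <- summarize_stoich(d)
  s2 <- summarize_stoich(d[sample(nrow(d)), ])
  expect_equal(s1$technical[order(s1$technical$genotype, s1$technical$bio_rep,
                                  s1$technical$tech_rep), ],
               s2$technical[order(s2$technical$genotype, s2$technical$bio_rep,
                                  s2$technical$tech_rep), ],
               ignore_attr = TRUE)
  expect_equal(s1$biological$oligomeric_pct, s2$biological$oligomeric_pct)
})

test_that("biological replicates pool technical counts", {
  d <- data.frame(
    genotype = "wt", bio_rep = 1,
    tech_rep = rep(1:2, c(10, 30)),
    farred_class = c(rep("1-step", 10),              # tech 1: 0% oligomeric
                     rep(c("2-step"), 30)),          # tech 2: 100% oligomeric
    retained = TRUE)
  s <- summarize_stoich(d)
  expect_equal(s$biological$oligomeric_pct, 75)       # pooled 30/40
  expect_equal(s$biological$oligomeric_pct_avg, 50)   # mean of 0 and 100
})

test_that("nested ANOVA equals one-way on biological means for balanced designs", {
  set.seed(32)
  tech <- expand.grid(genotype = c("wt", "mut"), bio_rep = 1:4, tech_rep = 1:3)
  tech$oligomeric_pct <- rnorm(nrow(tech), 40, 5) +
    ifelse(tech$genotype == "mut", -8, 0)
  cmp <- compare_groups(tech)
  bm <- aggregate(oligomeric_pct ~ genotype + bio_rep, tech, mean)
  ref <- anova(lm(oligomeric_pct ~ genotype, bm))
  expect_equal(cmp$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_equal(cmp$F, ref[["F value"]][1], tolerance = 1e-9)
  ## identical replicate values in both genotypes: F = 0, p = 1
  t2 <- expand.grid(genotype = c("wt", "mut"), bio_rep = 1:4, tech_rep = 1:3)
  t2$oligomeric_pct <- c(35, 40, 45, 50)[t2$bio_rep]
  cmp2 <- compare_groups(t2)
  expect_equal(cmp2$F, 0, tolerance = 1e-9)
  expect_equal(cmp2$p_value, 1, tolerance = 1e-9)
  ## guards
  expect_error(compare_groups(tech[tech$genotype == "wt", ]), ">= 2 genotypes")
  one_bio <- tech[tech$genotype == "wt" | tech$bio_rep == 1, ]
  expect_error(compare_groups(one_bio), "biological replicates")
})

test_that("a true 15-point genotype shift is detected with high power", {
  ## Monte-Carlo power at the replicate structure of a typical experiment:
  ## 9 vs 10 biological replicates, sd 5, shift 15
  set.seed(33)
  rejections <- 0
  for (i in 1:200) {
    bio_a <- rnorm(9, 40, 5); bio_b <- rnorm(10, 25, 5)
    tech <- rbind(
      data.frame(genotype = "a", bio_rep = rep(1:9, each = 2),
                 tech_rep = rep(1:2, 9),
                 oligomeric_pct = rep(bio_a, each = 2) + rnorm(18, 0, 2)),
      data.frame(genotype = "b", bio_rep = rep(1:10, each = 2),
                 tech_rep = rep(1:2, 10),
                 oligomeric_pct = rep(bio_b, each = 2) + rnorm(20, 0, 2)))
    if (compare_groups(tech)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 200, 0.90)
})

test_that("end-to-end trace-level stoichiometry recovery is unbiased", {
  ## true oligomeric fraction 40% among complexes with one green and >= 1
  ## far-red fluorophore; no blinking, full labeling
  acq <- acquisition_params(blink_rate = 0)
  m <- stoich_model(p_farred = c("1" = 0.6, "2" = 0.3, "3" = 0.1))
  tr <- simulate_complexes(m, 400, c(2000, 2000), min_separation = 0, seed = 81)
  ts <- simulate_traces(tr, acq, seed = 82)
  pairs <- data.frame(pair_id = tr$complex_id, green_id = tr$complex_id,
                      farred_id = tr$complex_id)
  cp <- run_pipeline(pairs, ts$green, ts$farred)
  cp$genotype <- "wt"; cp$bio_rep <- 1; cp$tech_rep <- 1
  s <- summarize_stoich(cp)
  expect_lt(abs(s$technical$oligomeric_pct - 40), 7)
})
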