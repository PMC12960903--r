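test_that("Fickett TESTCODE matches an independent reference implementation", {
  panel <- read.delim(test_path("fickett-panel.tsv"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    expect_equal(fickett_score(panel$seq[i]), panel$expected[i],
                 tolerance = 1e-4)
  }
  # determinism
  s <- panel$seq[1]
  expect_identical(fickett_score(s), fickett_score(s))
  expect_error(fickett_score(""), "length")
  expect_error(fickett_score("NNNN"), "no A/C/G/T")
})

test_that("hexamer tables normalize per class and are symmetric for identical sets", {
  set.seed(7)
  seqs <- replicate(5, random_dna(120))
  tab <- build_hexamer_table(seqs, seqs)
  expect_equal(sum(tab$coding), 1)
  expect_equal(sum(tab$noncoding), 1)
  expect_true(all(tab$coding > 0) && all(tab$noncoding > 0))
  # identical counting forced via a 6-nt input where both stepping modes
  # see the same single hexamer: log-ratios vanish
  t6 <- build_hexamer_table("ATGGCA", "ATGGCA")
  expect_equal(unname(t6$log_ratio["ATGGCA"]), 0)
  expect_equal(max(abs(t6$log_ratio)), 0)
  # sub-hexamer sequences contribute nothing (pure pseudo-count table)
  t_short <- build_hexamer_table(c("ATGGA", "CCC"), "TTTT")
  expect_equal(max(abs(t_short$log_ratio)), 0)
  expect_error(build_hexamer_table(character(0), seqs), "non-empty")
})

test_that("hexamer scoring averages in-frame log-ratios with degenerate rules", {
  expect_equal(hexamer_score("ATGGCAGCA", uniform_hexamer_table()), 0)
  expect_equal(hexamer_score("ATGAA", uniform_hexamer_table()), 0)
  # table where every in-frame hexamer of the input has ratio e -> score 1
  tab <- uniform_hexamer_table()
  s <- "ATGGCAGCGTAA"
  hx <- substring(s, seq(1, nchar(s) - 5, 3), seq(6, nchar(s), 3))
  tab$log_ratio[hx] <- 1
  expect_equal(hexamer_score(s, tab), 1)
  # hexamers containing N are skipped
  tabN <- uniform_hexamer_table()
  tabN$log_ratio[] <- 5
  expect_equal(hexamer_score("ATGGCANNN", tabN), 5) # only 1 valid in-frame hexamer
  expect_equal(hexamer_score("NNNNNNNNN", tabN), 0)
})

test_that("coding probability follows the logistic closed form", {
  tab <- uniform_hexamer_table()
  fv <- list(orf_length = 300, orf_coverage = 0.5, fickett = 1.0, hexamer = 0.2)
  m0 <- coding_model(tab, c(0, 0, 0, 0, 0))
  expect_equal(coding_probability(fv, m0), 0.5)
  m10 <- coding_model(tab, c(10, 0, 0, 0, 0))
  expect_equal(coding_probability(fv, m10), 1 / (1 + exp(-10)))
  # length enters as its natural log
  ml <- coding_model(tab, c(0, 1, 0, 0, 0))
  expect_equal(coding_probability(fv, ml), stats::plogis(log(300)))
})

test_that("probability is monotone in every positively weighted feature", {
  tab <- uniform_hexamer_table()
  m <- coding_model(tab, c(-2, 0.8, 1.5, 2.0, 1.2))
  base <- list(orf_length = 150, orf_coverage = 0.4, fickett = 0.9,
               hexamer = 0.1)
  for (f in names(base)) {
    grid <- seq_len(8)
    probs <- vapply(grid, function(k) {
      fv <- base
      fv[[f]] <- base[[f]] * (1 + k / 10)
      coding_probability(fv, m)
    }, 0)
    expect_true(all(diff(probs) > 0))
  }
})

test_that("classification uses prob >= cutoff with user override semantics", {
  expect_equal(classify_coding(0.5, 0.5), "coding") # boundary counts as coding
  expect_equal(classify_coding(0, 0.3), "noncoding")
  expect_equal(classify_coding(c(0.2, 0.49, 0.5, 0.9), 0.5),
               c("noncoding", "noncoding", "coding", "coding"))
  expect_error(classify_coding(0.5, 1.5))
  expect_equal(species_cutoff("human"), 0.364)
  expect_error(species_cutoff("axolotl"), "no recommended cutoff")
})

test_that("training recovers planted separation on held-out data", {
  sets <- simulate_training_sets(220, 220, seed = 91)
  tr_c <- sets$coding[1:150]; te_c <- sets$coding[151:220]
  tr_n <- sets$noncoding[1:150]; te_n <- sets$noncoding[151:220]
  m <- train_coding_model(tr_c, tr_n, seed = 1)
  score1 <- function(s) {
    sel <- rank_and_select(enumerate_orfs(s), s, m)
    if (is.null(sel$primary)) 0 else sel$primary$coding_prob
  }
  p_c <- vapply(te_c, score1, 0)
  p_n <- vapply(te_n, score1, 0)
  acc <- (sum(p_c >= m$cutoff) + sum(p_n < m$cutoff)) / (length(p_c) + length(p_n))
  expect_gte(acc, 0.95)
  # coding examples score above cutoff in >= 95% of held-out cases
  expect_gte(mean(p_c >= m$cutoff), 0.95)
})

test_that("model serialization round-trips probabilities bit-exactly", {
  m <- train_fixture_model(seed = 17, n_per_class = 60)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_coding_model(m, path)
  m2 <- load_coding_model(path)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$cutoff, m$cutoff)
  expect_identical(m2$hexamer_table$coding, m$hexamer_table$coding)
  set.seed(3)
  for (i in 1:10) {
    s <- paste0("ATG", random_dna(60), "TAA")
    tx <- paste0(random_dna(20), s, random_dna(20))
    fv <- orf_features(s, tx, m$hexamer_table)
    fv2 <- orf_features(s, tx, m2$hexamer_table)
    expect_identical(coding_probability(fv, m), coding_probability(fv2, m2))
  }
})

test_that("training is deterministic and errors on ORF-free classes", {
  sets <- simulate_training_sets(40, 40, seed = 5)
  m1 <- train_coding_model(sets$coding, sets$noncoding, seed = 9)
  m2 <- train_coding_model(sets$coding, sets$noncoding, seed = 9)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_error(train_coding_model(c("CCCCCCCCCCCC"), sets$noncoding),
               "training error")
})
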