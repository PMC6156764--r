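make_ct <- function(d_ctrl, d_cond) {
  # reference gene fixed at Ct 20; target Ct = 20 + dCt
  data.frame(
    sample = rep(c("ctrl", "cond"), each = 6),
    gene = rep(rep(c("TARGET", "RPL37A"), each = 3), 2),
    ct = c(20 + d_ctrl + c(-0.1, 0, 0.1), 20 + c(-0.1, 0, 0.1),
           20 + d_cond + c(-0.1, 0, 0.1), 20 + c(-0.1, 0, 0.1)))
}

test_that("delta-delta-Ct fold changes follow the printed convention", {
  expect_equal(ddct_fold_change(make_ct(2, 2), "TARGET", "cond",
                                "ctrl")$fold_change, 1.0)
  # ddCt = dCt_ctrl - dCt_cond = 1 -> fold 2^-1
  r <- ddct_fold_change(make_ct(3, 2), "TARGET", "cond", "ctrl")
  expect_equal(r$dd_ct, 1); expect_equal(r$fold_change, 0.5)
  # ddCt = -2 -> fold 4
  r2 <- ddct_fold_change(make_ct(1, 3), "TARGET", "cond", "ctrl")
  expect_equal(r2$dd_ct, -2); expect_equal(r2$fold_change, 4.0)
})

test_that("fold change is strictly decreasing in ddCt and errors without reference", {
  dd <- seq(-3, 3, by = 0.5)
  folds <- sapply(dd, function(d)
    ddct_fold_change(make_ct(0, -d), "TARGET", "cond", "ctrl")$fold_change)
  expect_true(all(diff(folds) < 0))
  bad <- make_ct(1, 1); bad <- bad[bad$gene != "RPL37A", ]
  expect_error(ddct_fold_change(bad, "TARGET", "cond", "ctrl"),
               "reference gene missing")
})

test_that("co-IP normalization reproduces hand arithmetic", {
  rec <- data.frame(condition = c("pos", "m1", "m2"),
                    tead_signal = c(8, 4, 6),
                    flag_signal = c(2, 2, 4),
                    igg_signal = c(1, 1, 2))
  out <- coip_normalize(rec, "pos")
  expect_equal(out$relative_binding[out$condition == "pos"], 1.0)
  # m1: tead halved, flag/igg unchanged -> 0.5
  expect_equal(out$relative_binding[out$condition == "m1"], 0.5)
  # m2 step by step: raw = 6/(4/2) = 3; pos raw = 8/(2/1) = 4 -> 0.75
  expect_equal(out$relative_binding[out$condition == "m2"], 3 / 4)
  set.seed(5)
  rnd <- data.frame(condition = c("pos", letters[1:4]),
                    tead_signal = runif(5, 1, 10),
                    flag_signal = runif(5, 1, 10),
                    igg_signal = runif(5, 1, 10))
  out2 <- coip_normalize(rnd, "pos")
  for (i in 1:5) {
    raw_i <- rnd$tead_signal[i] / (rnd$flag_signal[i] / rnd$igg_signal[i])
    raw_p <- rnd$tead_signal[1] / (rnd$flag_signal[1] / rnd$igg_signal[1])
    expect_equal(out2$relative_binding[i], raw_i / raw_p)
  }
  rec$flag_signal[2] <- 0
  expect_error(coip_normalize(rec, "pos"), "positive")
})

test_that("luciferase normalization is a guarded ratio", {
  expect_equal(luciferase_normalize(10, 10), 1.0)
  expect_equal(luciferase_normalize(0, 5), 0.0)
  expect_equal(luciferase_normalize(6, 3), 2.0)
  expect_error(luciferase_normalize(5, 0), "positive")
})

test_that("spreading classification splits areas at the cutoff", {
  expect_equal(spreading_classify(c(100, 130)),
               c(fraction_below = 0.5, fraction_above = 0.5))
  expect_equal(unname(spreading_classify(c(10, 20, 30))[1]), 1.0)
  # ties count as below
  expect_equal(unname(spreading_classify(c(120, 121))[1]), 0.5)
  expect_equal(unname(spreading_classify(120)[1]), 1.0)
  set.seed(6)
  fr <- spreading_classify(runif(100, 50, 200))
  expect_equal(sum(fr), 1)
  expect_error(spreading_classify(numeric(0)), "empty")
})

test_that("alanine cassettes tile the scanned region exactly", {
  set.seed(8)
  seq600 <- paste(sample(strsplit("CDEFGHIKLMNPQRSTVWY", "")[[1]],
                         600, replace = TRUE), collapse = "")
  mut <- alanine_cassette_mutants(seq600, 376, 424, 7)
  expect_length(mut, 7)
  expect_named(mut, paste0("A", 1:7))
  # the first cassette substitutes residues 376-382
  expect_equal(substr(mut[["A1"]], 376, 382), "AAAAAAA")
  expect_equal(substr(mut[["A1"]], 383, 600), substr(seq600, 383, 600))
  # position-wise diff oracle: each mutant differs at exactly 7 positions,
  # all alanine, and the cassettes tile 376..424 without gaps or overlap
  covered <- integer(0)
  for (m in mut) {
    pos <- which(strsplit(m, "")[[1]] != strsplit(seq600, "")[[1]])
    expect_length(pos, 7)
    expect_true(all(strsplit(m, "")[[1]][pos] == "A"))
    expect_true(length(intersect(covered, pos)) == 0)
    covered <- c(covered, pos)
  }
  expect_equal(sort(covered), 376:424)
  # cassette length equal to the region gives one mutant
  one <- alanine_cassette_mutants(seq600, 376, 424, 49)
  expect_length(one, 1)
  expect_error(alanine_cassette_mutants(seq600, 376, 424, 10),
               "not divisible")
  expect_error(alanine_cassette_mutants("ABZ", 1, 2), "amino-acid")
})

test_that("interval arithmetic is 1-based inclusive", {
  expect_equal(interval_length(376, 424), 49)
  expect_equal(interval_length(1, 1), 1)
  expect_equal(interval_length(291, 592), 302)
  expect_error(interval_length(5, 4), "start")
})

test_that("the fragment registry resolves the eight constructs and aliases", {
  reg <- fragment_registry()
  expect_equal(nrow(reg), 8)
  a9 <- fragment_registry("α9")          # Greek-alpha alias
  expect_equal(c(a9$start, a9$end), c(376, 424))
  expect_equal(fragment_registry("a9")$length, 49)
  glo <- fragment_registry("Glo")
  expect_equal(c(glo$start, glo$end), c(1, 290))
  expect_equal(fragment_registry("a7-13")$end, 582)
  expect_error(fragment_registry("a99"), "unknown construct")
})

test_that("FASTA round-trips preserve names and sequences", {
  seqs <- c(wt = "MDHLFQKVDH", A1 = "AAAAAAAVDH")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, path)
  expect_identical(read_fasta_sequences(path), seqs)
})
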